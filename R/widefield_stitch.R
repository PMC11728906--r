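# Planning of translation-stage tile positions and feather-blended stitching
# of ex vivo tiles into the wide-field volume. Stage positions are trusted
# (hardware-accurate); no cross-tile registration is performed.

#' Plan translation-stage tile positions to cover an extent
#'
#' Per axis, the smallest tile count n with
#' `tile_fov + (n - 1) * step >= extent` is used, with positions evenly
#' spaced by `step` starting at 0.
#'
#' @param extent_um lateral extent to cover; scalar or c(x, y).
#' @param tile_fov_um tile field of view (scalar).
#' @param step_um stage step between tile origins; must be `< tile_fov_um` so
#'   adjacent tiles overlap.
#' @return object of class `tile_plan`: `positions_um` data.frame (x, y tile
#'   origins), `n_xy`, `tile_fov_um`, `step_um`, `min_overlap_um`.
#' @export
plan_tiles <- function(extent_um, tile_fov_um, step_um) {
  if (step_um >= tile_fov_um)
    stop("planning error: step >= tile field of view leaves no overlap")
  ext <- rep_len(as.numeric(extent_um), 2L)
  n_axis <- function(e) {
    if (tile_fov_um >= e) 1L
    else as.integer(ceiling((e - tile_fov_um) / step_um)) + 1L
  }
  n <- vapply(ext, n_axis, 1L)
  pos <- expand.grid(x = (seq_len(n[1]) - 1L) * step_um,
                     y = (seq_len(n[2]) - 1L) * step_um)
  structure(list(positions_um = pos, n_xy = n, tile_fov_um = tile_fov_um,
                 step_um = step_um,
                 min_overlap_um = tile_fov_um - step_um),
            class = "tile_plan")
}

#' Stitch ex vivo tiles into a wide-field volume
#'
#' Tiles must share voxel spacings and carry `origin_um` on a common voxel
#' lattice (stage positions). Overlaps are feather-blended: each tile's
#' weight ramps linearly from 0 at its lateral edges to 1 at `feather_um`
#' inward, and weights are normalized to sum to 1 wherever at least one tile
#' contributes. Voxels covered by no tile hold the no-data sentinel `NA`
#' (replace with 0 via `na_value`).
#'
#' @param tiles list of [oct_volume()]s with `origin_um` set.
#' @param feather_um feather width; default half the smallest tile overlap.
#' @param na_value value for uncovered voxels (default `NA`).
#' @return a wide-field [oct_volume()] with origin at the minimum tile origin.
#' @export
stitch_tiles <- function(tiles, feather_um = NULL, na_value = NA_real_) {
  stopifnot(length(tiles) >= 1, all(vapply(tiles, inherits, TRUE, "oct_volume")))
  t1 <- tiles[[1]]
  spx <- t1$spacing_x_um; spy <- t1$spacing_y_um; dz <- t1$spacing_z_um
  for (tl in tiles) {
    if (abs(tl$spacing_x_um - spx) > 1e-9 || abs(tl$spacing_y_um - spy) > 1e-9 ||
        abs(tl$spacing_z_um - dz) > 1e-9)
      stop("spacing mismatch between tiles")
    if (dim(tl$intensity)[1] != dim(t1$intensity)[1])
      stop("tiles must share depth dimension")
  }
  org <- t(vapply(tiles, `[[`, numeric(2), "origin_um"))
  o0 <- c(min(org[, 1]), min(org[, 2]))
  ox <- (org[, 1] - o0[1]) / spx; oy <- (org[, 2] - o0[2]) / spy
  if (max(abs(ox - round(ox))) > 1e-6 || max(abs(oy - round(oy))) > 1e-6)
    stop("tile origins must lie on a common voxel lattice")
  ox <- round(ox); oy <- round(oy)
  nxs <- vapply(tiles, function(t) dim(t$intensity)[3], 1L)
  nys <- vapply(tiles, function(t) dim(t$intensity)[2], 1L)
  NX <- max(ox + nxs); NY <- max(oy + nys); NZ <- dim(t1$intensity)[1]
  if (is.null(feather_um)) {
    ov <- Inf
    for (i in seq_along(tiles)) for (j in seq_along(tiles)) {
      if (i == j) next
      ovx <- min(ox[i] + nxs[i], ox[j] + nxs[j]) - max(ox[i], ox[j])
      ovy <- min(oy[i] + nys[i], oy[j] + nys[j]) - max(oy[i], oy[j])
      if (ovx > 0 && ovy > 0) ov <- min(ov, max(ovx * spx, ovy * spy))
    }
    feather_um <- if (is.finite(ov)) ov / 2 else max(spx, spy)
  }
  num <- array(0, c(NZ, NY, NX)); den <- array(0, c(NZ, NY, NX))
  for (i in seq_along(tiles)) {
    ny <- nys[i]; nx <- nxs[i]
    ry <- pmin(seq_len(ny) - 0.5, ny - seq_len(ny) + 0.5) * spy
    rx <- pmin(seq_len(nx) - 0.5, nx - seq_len(nx) + 0.5) * spx
    w2 <- outer(pmin(ry / feather_um, 1), pmin(rx / feather_um, 1), pmin)
    w3 <- aperm(array(w2, c(ny, nx, NZ)), c(3, 1, 2))
    ys <- (oy[i] + 1):(oy[i] + ny); xs <- (ox[i] + 1):(ox[i] + nx)
    num[, ys, xs] <- num[, ys, xs] + w3 * tiles[[i]]$intensity
    den[, ys, xs] <- den[, ys, xs] + w3
  }
  out <- num / den
  out[den == 0] <- na_value
  if (anyNA(out)) out[is.na(out)] <- na_value
  covered <- den > 0
  if (is.na(na_value)) {
    # oct_volume requires finite intensities; encode no-data as 0 and attach
    # the coverage mask
    out[!covered] <- 0
  }
  vol <- oct_volume(out, dz, spy, spx, role = "wide_field",
                    origin_um = o0)
  attr(vol, "coverage") <- covered[1, , ]
  vol
}
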