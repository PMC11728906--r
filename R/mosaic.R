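# Placement of in vivo tiles into the wide-field ex vivo frame: coarse
# placement from the 3x3 session grid anchored on the suture fiducial, fine
# rigid refinement by masked normalized cross-correlation (NCC) of
# surface-flattened en face planes over translation, in-plane rotation and a
# depth-plane (dz) search, tissue-type classification, success assessment and
# per-tissue-type success reporting.

#' A rigid tile pose in the wide-field frame
#'
#' @param tx_um,ty_um lateral position of the tile center (um, wide-field
#'   coordinates).
#' @param theta_deg in-plane (yaw) rotation in degrees, in (-180, 180].
#' @param dz_um depth-offset adjustment applied to the tile's en face
#'   sampling, mirroring the manual depth-plane scrolling of the protocol.
#' @export
rigid_pose2d <- function(tx_um, ty_um, theta_deg = 0, dz_um = 0) {
  th <- ((theta_deg + 180) %% 360) - 180
  if (th == -180) th <- 180
  structure(list(tx_um = as.numeric(tx_um), ty_um = as.numeric(ty_um),
                 theta_deg = th, dz_um = as.numeric(dz_um)),
            class = "rigid_pose2d")
}

#' @export
print.rigid_pose2d <- function(x, ...) {
  cat(sprintf("<rigid_pose2d> t = (%.1f, %.1f) um, theta = %.2f deg, dz = %.1f um\n",
              x$tx_um, x$ty_um, x$theta_deg, x$dz_um))
  invisible(x)
}

#' Masked normalized cross-correlation over all translations
#'
#' FFT formulation of NCC restricted, per shift, to the overlap of the two
#' validity masks (`NA` pixels are excluded). Returns the NCC value and
#' overlap pixel count for every translation of `moving` over `fixed`.
#'
#' @param fixed,moving numeric matrices; `NA` marks no-data pixels.
#' @param min_overlap_px shifts with fewer overlapping valid pixels are `NA`.
#' @return list: `ncc` and `n` matrices indexed by `shift_y` x `shift_x`,
#'   where shift (sy, sx) overlays `moving[i, j]` on `fixed[i + sy, j + sx]`.
#' @export
masked_ncc <- function(fixed, moving, min_overlap_px = 16) {
  nfr <- nrow(fixed); nfc <- ncol(fixed)
  nmr <- nrow(moving); nmc <- ncol(moving)
  P1 <- stats::nextn(nfr + nmr - 1L, c(2, 3, 5))
  P2 <- stats::nextn(nfc + nmc - 1L, c(2, 3, 5))
  mf <- 1 - is.na(fixed); mm <- 1 - is.na(moving)
  f <- fixed; f[is.na(f)] <- 0
  m <- moving; m[is.na(m)] <- 0
  pad <- function(a) { o <- matrix(0, P1, P2); o[seq_len(nrow(a)), seq_len(ncol(a))] <- a; o }
  Ff <- stats::fft(pad(f)); Ff2 <- stats::fft(pad(f * f)); Fmf <- stats::fft(pad(mf))
  Gm <- Conj(stats::fft(pad(m))); Gm2 <- Conj(stats::fft(pad(m * m)))
  Gmm <- Conj(stats::fft(pad(mm)))
  xc <- function(A, B) Re(stats::fft(A * B, inverse = TRUE)) / (P1 * P2)
  n <- round(xc(Fmf, Gmm))
  sf <- xc(Ff, Gmm)
  sm <- xc(Fmf, Gm)
  sff <- xc(Ff2, Gmm)
  smm <- xc(Fmf, Gm2)
  sfm <- xc(Ff, Gm)
  ok <- n >= max(min_overlap_px, 2)
  n_ok <- ifelse(ok, n, NA_real_)
  varf <- sff - sf^2 / n_ok
  varm <- smm - sm^2 / n_ok
  den <- sqrt(pmax(varf, 0) * pmax(varm, 0))
  ncc <- (sfm - sf * sm / n_ok) / den
  ncc[!is.finite(ncc) | den < 1e-9] <- NA_real_
  ncc <- pmin(pmax(ncc, -1), 1)
  # reorder FFT wrap-around into sequential shifts -(nm-1) .. (nf-1)
  ord1 <- c(P1 - ((nmr - 1):1) + 1L, 1:nfr)
  ord2 <- c(P2 - ((nmc - 1):1) + 1L, 1:nfc)
  list(ncc = ncc[ord1, ord2], n = n[ord1, ord2],
       shift_y = -(nmr - 1):(nfr - 1), shift_x = -(nmc - 1):(nfc - 1))
}

# resample a plane image to a different pixel spacing (bilinear)
resample_plane <- function(img, from_sp, to_sp) {
  if (abs(from_sp / to_sp - 1) < 1e-9) return(img)
  nr2 <- max(2L, round(nrow(img) * from_sp / to_sp))
  nc2 <- max(2L, round(ncol(img) * from_sp / to_sp))
  ys <- (seq_len(nr2) - 1) * to_sp / from_sp + 1
  xs <- (seq_len(nc2) - 1) * to_sp / from_sp + 1
  matrix(bilinear_sample(img, rep(xs, each = nr2), rep(ys, times = nc2)),
         nr2, nc2)
}

#' Coarse placement of session tiles from the suture anchor
#'
#' The anchor tile is posed so that its detected suture centroid lands on the
#' wide-field suture centroid, with initial rotation equal to the signed
#' difference of the two suture axes. Every other tile is offset from the
#' anchor by its grid displacement times the nominal step, rotated into the
#' anchor's frame. Initial dz is 0.
#'
#' @param session a [scan_session()].
#' @param anchor_in_vivo suture [fiducial_mark()] detected in the anchor
#'   tile's en face plane (tile coordinates, um).
#' @param anchor_ex_vivo suture mark detected in the wide-field en face plane.
#' @param tile_fov_um lateral tile extent, to locate the tile center relative
#'   to the in vivo mark.
#' @return named list of [rigid_pose2d()], one per session tile (names are
#'   the `volume` entries of the session).
#' @export
coarse_place <- function(session, anchor_in_vivo, anchor_ex_vivo,
                         tile_fov_um = session$tile_fov_um) {
  stopifnot(inherits(session, "scan_session"))
  if (is.null(anchor_in_vivo) || is.null(anchor_ex_vivo))
    stop("missing anchor fiducial detection")
  d_ax <- anchor_ex_vivo$axis_deg - anchor_in_vivo$axis_deg
  theta <- ((d_ax + 90) %% 180) - 90       # axes are mod 180
  th <- theta * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  p_tile <- anchor_in_vivo$centroid_um - c(tile_fov_um / 2, tile_fov_um / 2)
  anchor_center <- anchor_ex_vivo$centroid_um - as.vector(R %*% p_tile)
  tiles <- session$tiles
  a <- tiles[session$anchor_index, ]
  poses <- vector("list", nrow(tiles))
  names(poses) <- as.character(tiles$volume)
  for (i in seq_len(nrow(tiles))) {
    dgrid <- c(tiles$grid_col[i] - a$grid_col,
               tiles$grid_row[i] - a$grid_row) * session$nominal_step_um
    t_i <- anchor_center + as.vector(R %*% dgrid)
    poses[[i]] <- rigid_pose2d(t_i[1], t_i[2], theta_deg = theta, dz_um = 0)
  }
  poses
}

#' Refine a tile pose by masked NCC with rotation and depth search
#'
#' Exhaustively searches the pose grid (translation window, in-plane rotation,
#' depth-plane offset dz), scoring each candidate by masked NCC between the
#' tile's dB-scaled surface-flattened en face plane (at `depth_offset_um + dz`)
#' and the wide-field en face plane, then refines translation to sub-voxel by
#' local quadratic fit. Rotation and dz use a coarse-to-fine two-stage grid.
#' Ties are broken toward the smallest `|theta|`, then `|dz|`, then distance
#' from the initial pose.
#'
#' @param tile in vivo tile [oct_volume()].
#' @param wide_field wide-field [oct_volume()] (ignored when `wf_plane` given).
#' @param init initial [rigid_pose2d()] from [coarse_place()].
#' @param search list: `trans_um` translation half-window, `theta_deg`
#'   rotation half-range, `theta_step_deg` fine step, `dz_um` depth half-range,
#'   `dz_step_voxels` depth step in axial voxels.
#' @param depth_offset_um nominal en face depth below the surface.
#' @param wf_plane optional precomputed wide-field [extract_enface()] plane
#'   (reused across tiles for speed).
#' @param min_overlap_frac minimum fraction of the tile's valid area that must
#'   overlap wide-field data; below it the tile is unregistrable (score -1).
#' @param plane_smooth_um Gaussian smoothing (um) applied to both dB planes
#'   before correlation. This matches the effective resolutions of the two
#'   systems and suppresses speckle, which is uncorrelated between them, so
#'   the NCC responds to tissue structure rather than speckle noise.
#' @return list: `pose` (refined [rigid_pose2d()]), `score` (best NCC in
#'   `[-1, 1]`, -1 when unregistrable).
#' @export
refine_tile <- function(tile, wide_field = NULL, init,
                        search = list(), depth_offset_um = 100,
                        wf_plane = NULL, min_overlap_frac = 0.25,
                        plane_smooth_um = 120) {
  stopifnot(inherits(tile, "oct_volume"), inherits(init, "rigid_pose2d"))
  se <- utils::modifyList(list(trans_um = 2000, theta_deg = 10,
                               theta_step_deg = 0.5, dz_um = 200,
                               dz_step_voxels = 2), search)
  if (is.null(wf_plane)) {
    wf_surf <- detect_surface(wide_field)
    wf_plane <- extract_enface(wide_field, wf_surf, depth_offset_um)
  }
  spy <- wf_plane$spacing_y_um; spx <- wf_plane$spacing_x_um
  tile_fov_x <- dim(tile)[3] * tile$spacing_x_um
  tile_fov_y <- dim(tile)[2] * tile$spacing_y_um
  half_x <- tile_fov_x / 2 + se$trans_um + 2 * spx
  half_y <- tile_fov_y / 2 + se$trans_um + 2 * spy
  # fixed image: wide-field crop around the initial pose, in dB
  cx0 <- max(1L, floor((init$tx_um - half_x) / spx) + 1L)
  cx1 <- min(ncol(wf_plane$image), ceiling((init$tx_um + half_x) / spx) + 1L)
  cy0 <- max(1L, floor((init$ty_um - half_y) / spy) + 1L)
  cy1 <- min(nrow(wf_plane$image), ceiling((init$ty_um + half_y) / spy) + 1L)
  if (cx1 - cx0 < 4 || cy1 - cy0 < 4)
    return(list(pose = init, score = -1))
  fixed_lin <- wf_plane$image[cy0:cy1, cx0:cx1]
  fixed <- to_decibels(fixed_lin)
  fixed[is.na(fixed_lin)] <- NA
  sm_px <- plane_smooth_um / ((spx + spy) / 2) / 2
  if (sm_px > 0.3) fixed <- smooth_gauss(fixed, sm_px)
  crop_origin <- c((cx0 - 1) * spx, (cy0 - 1) * spy)

  tile_surf <- detect_surface(tile)
  dz_step <- se$dz_step_voxels * tile$spacing_z_um
  dz_all <- if (se$dz_um > 0) seq(-se$dz_um, se$dz_um, by = dz_step) else 0
  dz_all <- dz_all[depth_offset_um + dz_all >= 0]
  th_all <- if (se$theta_deg > 0)
    seq(-se$theta_deg, se$theta_deg, by = se$theta_step_deg) else 0

  # coarse-to-fine: subsample each grid to <= ~11 values, then refine locally
  coarsen <- function(v, nmax = 11L) {
    if (length(v) <= nmax) return(v)
    v[unique(round(seq(1, length(v), length.out = nmax)))]
  }
  th_coarse <- coarsen(th_all); dz_coarse <- coarsen(dz_all)

  plane_cache <- new.env(parent = emptyenv())
  get_plane <- function(dz) {
    key <- sprintf("%.6f", dz)
    if (!is.null(plane_cache[[key]])) return(plane_cache[[key]])
    p <- extract_enface(tile, tile_surf, depth_offset_um + dz)
    img <- to_decibels(p$image)
    img[is.na(p$image)] <- NA
    if (sm_px > 0.3) img <- smooth_gauss(img, sm_px)
    img <- resample_plane(img, tile$spacing_x_um, spx)
    # tile reference pixel (the tile center used by the pose convention),
    # mapped through the resampling
    ref <- c((floor(dim(tile)[2] / 2)) * tile$spacing_y_um / spy + 1,
             (floor(dim(tile)[3] / 2)) * tile$spacing_x_um / spx + 1)
    res <- list(img = img, ref = ref)
    plane_cache[[key]] <- res
    res
  }

  best <- list(score = -Inf, key = c(Inf, Inf, Inf))
  eval_combo <- function(theta, dz) {
    pl <- get_plane(dz)
    rot <- rotate_plane(pl$img, theta)
    mov <- rot$image
    n_valid <- sum(!is.na(mov))
    if (n_valid < 16) return(invisible(NULL))
    # tile reference pixel in the rotated moving image
    thr <- theta * pi / 180
    din <- c(pl$ref[1] - (nrow(pl$img) + 1) / 2,
             pl$ref[2] - (ncol(pl$img) + 1) / 2)      # (dy, dx)
    ref_rot <- c(rot$center[1] + sin(thr) * din[2] + cos(thr) * din[1],
                 rot$center[2] + cos(thr) * din[2] - sin(thr) * din[1])
    r <- masked_ncc(fixed, mov,
                    min_overlap_px = max(16, min_overlap_frac * n_valid))
    # tile-center position for each shift; restrict to the search window
    pos_x <- crop_origin[1] + (r$shift_x + ref_rot[2] - 1) * spx
    pos_y <- crop_origin[2] + (r$shift_y + ref_rot[1] - 1) * spy
    in_x <- abs(pos_x - init$tx_um) <= se$trans_um
    in_y <- abs(pos_y - init$ty_um) <= se$trans_um
    ncc <- r$ncc[in_y, in_x, drop = FALSE]
    if (!length(ncc) || all(is.na(ncc))) return(invisible(NULL))
    pk <- which(ncc == max(ncc, na.rm = TRUE), arr.ind = TRUE)[1, ]
    sc <- ncc[pk[1], pk[2]]
    sy_idx <- which(in_y)[pk[1]]; sx_idx <- which(in_x)[pk[2]]
    # sub-voxel quadratic refinement on the full surface
    full <- r$ncc
    oy <- ox <- 0
    if (sy_idx > 1 && sy_idx < nrow(full) &&
        all(is.finite(full[(sy_idx - 1):(sy_idx + 1), sx_idx])))
      oy <- parabolic_offset(full[sy_idx - 1, sx_idx], full[sy_idx, sx_idx],
                             full[sy_idx + 1, sx_idx])
    if (sx_idx > 1 && sx_idx < ncol(full) &&
        all(is.finite(full[sy_idx, (sx_idx - 1):(sx_idx + 1)])))
      ox <- parabolic_offset(full[sy_idx, sx_idx - 1], full[sy_idx, sx_idx],
                             full[sy_idx, sx_idx + 1])
    tx <- crop_origin[1] + (r$shift_x[sx_idx] + ox + ref_rot[2] - 1) * spx
    ty <- crop_origin[2] + (r$shift_y[sy_idx] + oy + ref_rot[1] - 1) * spy
    key <- c(abs(theta), abs(dz),
             sqrt((tx - init$tx_um)^2 + (ty - init$ty_um)^2))
    better <- sc > best$score + 1e-9 ||
      (abs(sc - best$score) <= 1e-9 &&
         isTRUE(all(key <= best$key)) && any(key < best$key))
    if (better)
      best <<- list(score = sc, key = key,
                    pose = rigid_pose2d(tx, ty, theta, dz))
    invisible(NULL)
  }

  for (dz in dz_coarse) for (th in th_coarse) eval_combo(th, dz)
  if (is.finite(best$score)) {
    # fine pass around the coarse optimum
    th_b <- best$pose$theta_deg; dz_b <- best$pose$dz_um
    th_fine <- th_all[abs(th_all - th_b) <= diff(range(th_coarse)) /
                        max(1, length(th_coarse) - 1) + 1e-9]
    th_fine <- setdiff(th_fine, th_coarse)
    dz_fine <- dz_all[abs(dz_all - dz_b) <= diff(range(dz_coarse)) /
                        max(1, length(dz_coarse) - 1) + 1e-9]
    dz_fine <- setdiff(dz_fine, dz_coarse)
    for (th in th_fine) eval_combo(th, dz_b)
    for (dz in dz_fine) eval_combo(best$pose$theta_deg, dz)
  }
  if (!is.finite(best$score))
    return(list(pose = init, score = -1))
  list(pose = best$pose, score = best$score)
}

#' Classify the tissue content of an en face plane
#'
#' Applies the 90 % field-of-view rule: a plane is labeled `dense` or
#' `adipose` when more than `frac` of its valid area is that type, else
#' `mixed`. Per-pixel type comes either from a supplied ground-truth class map
#' or from an intensity rule: adipose where the dB of the locally averaged
#' linear intensity falls below `adipose_threshold_db` (adipose cell interiors
#' backscatter far less than dense stroma; the default threshold is
#' calibrated to the phantom generator's reflectivity scale, where dense
#' tissue sits near 0 dB).
#'
#' @param plane an [extract_enface()] plane, valid over at least half its area.
#' @param class_map optional integer matrix (1 = dense, 2 = adipose) matching
#'   the plane.
#' @param adipose_threshold_db dB threshold of the intensity rule.
#' @param frac dominance fraction (0.90 per the protocol).
#' @param smooth_um lateral averaging scale before the dB rule.
#' @return list: `label` in dense/adipose/mixed, `dense_fraction`,
#'   `adipose_fraction`.
#' @export
classify_tissue <- function(plane, class_map = NULL, adipose_threshold_db = -5,
                            frac = 0.9, smooth_um = 300) {
  if (!is.null(class_map)) {
    sel <- class_map %in% c(1L, 2L)
    if (!any(sel)) stop("class map has no tissue pixels")
    df <- mean(class_map[sel] == 1L)
  } else {
    stopifnot(inherits(plane, "en_face_plane"))
    img <- plane$image
    if (mean(!is.na(img)) < 0.5)
      stop("insufficient valid area for classification")
    sp <- (plane$spacing_x_um + plane$spacing_y_um) / 2
    sm <- smooth_gauss(img, max(0.8, smooth_um / sp / 2))
    db <- to_decibels(sm)
    db[is.na(sm)] <- NA
    df <- mean(db >= adipose_threshold_db, na.rm = TRUE)
  }
  af <- 1 - df
  label <- if (df > frac) "dense" else if (af > frac) "adipose" else "mixed"
  list(label = label, dense_fraction = df, adipose_fraction = af)
}

#' Success assessment for one placement
#'
#' An automated surrogate for the protocol's two-rater agreement: a placement
#' succeeds when its registration score reaches `score_threshold` and its
#' mean positional residual against already-placed neighboring tiles (which
#' share the ~1 mm grid overlap) does not exceed `consistency_threshold_um`.
#'
#' @param score registration NCC score in `[-1, 1]`.
#' @param overlap_consistency_um mean residual against adjacent placed tiles
#'   (um); `NA` when the tile has no placed neighbor (gate passes).
#' @param score_threshold,consistency_threshold_um gate thresholds
#'   (package defaults, not protocol constants).
#' @return logical.
#' @export
assess_success <- function(score, overlap_consistency_um = NA,
                           score_threshold = 0.3,
                           consistency_threshold_um = 1500) {
  isTRUE(score >= score_threshold) &&
    (is.na(overlap_consistency_um) ||
       overlap_consistency_um <= consistency_threshold_um)
}

#' Mean grid-consistency residual of each placed tile
#'
#' For each tile, the mean over its 4-neighbors in the session grid of the
#' distance between the observed relative placement and the relative offset
#' implied by the grid step (rotated by the anchor orientation).
#'
#' @param poses named list of refined [rigid_pose2d()] (names = session
#'   `volume` entries).
#' @param session the [scan_session()].
#' @return numeric vector of residuals (um), `NA` where a tile has no
#'   neighbor, named like `poses`.
#' @export
grid_consistency <- function(poses, session) {
  tiles <- session$tiles
  th <- poses[[session$anchor_index]]$theta_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  step <- session$nominal_step_um
  out <- rep(NA_real_, nrow(tiles))
  names(out) <- names(poses)
  for (i in seq_len(nrow(tiles))) {
    res <- c()
    for (j in seq_len(nrow(tiles))) {
      if (i == j) next
      dr <- tiles$grid_row[j] - tiles$grid_row[i]
      dc <- tiles$grid_col[j] - tiles$grid_col[i]
      if (abs(dr) + abs(dc) != 1) next
      expected <- as.vector(R %*% (c(dc, dr) * step))
      obs <- c(poses[[j]]$tx_um - poses[[i]]$tx_um,
               poses[[j]]$ty_um - poses[[i]]$ty_um)
      res <- c(res, sqrt(sum((obs - expected)^2)))
    }
    if (length(res)) out[i] <- mean(res)
  }
  out
}

#' Per-tissue-type co-registration summary from per-class counts
#'
#' @param scanned,coregistered named numeric vectors with entries `dense`,
#'   `adipose`, `mixed`: tiles scanned and successfully co-registered per
#'   tissue class.
#' @return data.frame with one row per class plus a totals row; percentages
#'   rounded to the nearest integer.
#' @export
coregistration_summary <- function(scanned, coregistered) {
  cls <- c("dense", "adipose", "mixed")
  s <- scanned[cls]; s[is.na(s)] <- 0
  k <- coregistered[cls]; k[is.na(k)] <- 0
  if (any(k > s)) stop("co-registered counts exceed scanned counts")
  tot_s <- sum(s); tot_k <- sum(k)
  if (tot_s < 1) stop("no placements to summarize")
  pct <- function(a, b) {
    b <- rep_len(b, length(a))
    out <- rep(0, length(a))
    out[b > 0] <- round(100 * a[b > 0] / b[b > 0])
    out
  }
  data.frame(
    tissue_class = c(cls, "all"),
    n_scanned = as.integer(c(s, tot_s)),
    pct_of_total = as.integer(c(pct(s, tot_s), 100)),
    n_coregistered = as.integer(c(k, tot_k)),
    success_pct = as.integer(c(pct(k, s), pct(tot_k, tot_s))),
    row.names = NULL)
}

#' Summarize a list of mosaic placements
#'
#' @param placements list of placement records, each with `tissue_class`
#'   (dense/adipose/mixed) and logical `success`.
#' @return the [coregistration_summary()] table.
#' @export
summarize_placements <- function(placements) {
  if (!length(placements)) stop("no placements to summarize")
  cls <- vapply(placements, `[[`, "", "tissue_class")
  suc <- vapply(placements, `[[`, NA, "success")
  coregistration_summary(table(factor(cls, c("dense", "adipose", "mixed"))),
                         table(factor(cls[suc], c("dense", "adipose", "mixed"))))
}

#' Place all session tiles into the wide-field frame
#'
#' End-to-end mosaic stage: wide-field en face extraction, suture detection in
#' both frames, coarse placement, per-tile refinement, tissue classification,
#' grid-consistency computation and success assessment.
#'
#' @param session a [scan_session()].
#' @param tile_volumes named list of in vivo tile [oct_volume()]s (names =
#'   session `volume` entries).
#' @param wide_field the wide-field [oct_volume()].
#' @param search,depth_offset_um passed to [refine_tile()].
#' @param score_threshold,consistency_threshold_um passed to
#'   [assess_success()].
#' @param classify_args list of extra arguments for [classify_tissue()].
#' @return list with `placements` (one record per tile: `tile_id`, `pose`,
#'   `score`, `tissue_class`, `overlap_consistency_um`, `success`, `flags`),
#'   `summary` (per-tissue-type data.frame), `anchor` fiducial marks.
#' @export
build_mosaic <- function(session, tile_volumes, wide_field,
                         search = list(), depth_offset_um = 100,
                         score_threshold = 0.3,
                         consistency_threshold_um = 1500,
                         classify_args = list()) {
  wf_surf <- detect_surface(wide_field)
  wf_plane <- extract_enface(wide_field, wf_surf, depth_offset_um)
  mark_ex <- detect_suture(wf_plane)
  anchor_name <- as.character(session$tiles$volume[session$anchor_index])
  anchor_tile <- tile_volumes[[anchor_name]]
  a_surf <- detect_surface(anchor_tile)
  a_plane <- extract_enface(anchor_tile, a_surf, depth_offset_um)
  mark_in <- detect_suture(a_plane)
  init <- coarse_place(session, mark_in, mark_ex)

  refined <- list(); scores <- c(); classes <- c()
  for (nm in names(init)) {
    tl <- tile_volumes[[nm]]
    r <- refine_tile(tl, init = init[[nm]], search = search,
                     depth_offset_um = depth_offset_um, wf_plane = wf_plane)
    refined[[nm]] <- r$pose
    scores[nm] <- r$score
    surf <- detect_surface(tl)
    pl <- extract_enface(tl, surf, depth_offset_um)
    classes[nm] <- do.call(classify_tissue, c(list(pl), classify_args))$label
  }
  cons <- grid_consistency(refined, session)
  placements <- lapply(names(init), function(nm) {
    i <- match(nm, names(init))
    list(tile_id = nm, pose = refined[[nm]], score = unname(scores[nm]),
         tissue_class = unname(classes[nm]),
         overlap_consistency_um = unname(cons[nm]),
         success = assess_success(scores[nm], cons[nm], score_threshold,
                                  consistency_threshold_um),
         flags = session$tiles$flags[i])
  })
  names(placements) <- names(init)
  list(placements = placements, summary = summarize_placements(placements),
       anchor = list(in_vivo = mark_in, ex_vivo = mark_ex),
       wf_plane = wf_plane)
}
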