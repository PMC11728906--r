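# Tissue-surface detection and surface-flattened en face extraction. The
# co-registration convention compares en face planes at a fixed depth below
# the local tissue surface (100 um by default), so the surface must be found
# per A-scan and the plane sampled relative to it.

#' Detect the tissue surface in an OCT volume
#'
#' Per A-scan, the surface is the first depth at which the (axially
#' median-filtered) intensity exceeds `intensity_floor_fraction` times the
#' column maximum; the resulting depth map is then laterally median-smoothed
#' over `smooth_um`. Columns whose maximum lies below the global noise floor
#' are marked invalid (no surface).
#'
#' @param vol an [oct_volume()].
#' @param smooth_um lateral median-smoothing window (um).
#' @param intensity_floor_fraction per-column adaptive threshold fraction.
#' @param noise_floor_fraction columns with maximum below this fraction of the
#'   global maximum have no detectable surface.
#' @return object of class `surface_map`: `depth_index` (y, x; 1-based z index
#'   of the first tissue voxel) and logical `valid`.
#' @export
detect_surface <- function(vol, smooth_um = 50,
                           intensity_floor_fraction = 0.3,
                           noise_floor_fraction = 0.02) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensity)
  nz <- d[1]; N <- d[2] * d[3]
  inten <- vol$intensity
  # light lateral averaging per z-slice tames speckle before thresholding
  if (d[2] > 6 && d[3] > 6) {
    for (z in seq_len(nz)) inten[z, , ] <- smooth_gauss(inten[z, , ], 1)
  }
  m <- matrix(inten, nz)
  # 3-point axial median, vectorized across all A-scans
  up <- rbind(m[1, , drop = FALSE], m[-nz, , drop = FALSE])
  dn <- rbind(m[-1, , drop = FALSE], m[nz, , drop = FALSE])
  med <- pmax(pmin(up, dn), pmin(pmax(up, dn), m))
  cmax <- apply(m, 2, max)
  # robust reference: air columns sit orders of magnitude below tissue columns
  gref <- stats::quantile(cmax, 0.9)
  valid <- cmax > noise_floor_fraction * gref
  if (!any(valid)) stop("no surface: entire volume below the noise floor")
  thr <- rep(intensity_floor_fraction * cmax, each = nz)
  hit <- med >= thr
  first <- apply(hit, 2, function(v) if (any(v)) which.max(v) else NA_integer_)
  first[!valid] <- NA_integer_
  depth <- matrix(as.numeric(first), d[2], d[3])
  k <- max(3L, round(smooth_um / ((vol$spacing_x_um + vol$spacing_y_um) / 2)))
  if (any(!is.na(depth)) && (d[2] > k && d[3] > k)) {
    filled <- depth
    if (anyNA(filled)) filled[is.na(filled)] <- stats::median(depth, na.rm = TRUE)
    sm <- smooth_median(filled, k)
    depth[!is.na(depth)] <- sm[!is.na(depth)]
  }
  depth <- round(pmin(pmax(depth, 1), nz))
  structure(list(depth_index = depth,
                 valid = matrix(valid, d[2], d[3]) & !is.na(depth)),
            class = "surface_map")
}

#' Extract a surface-flattened en face plane
#'
#' Samples the intensity a fixed physical offset below the detected surface
#' (nearest voxel; the offset is much larger than the axial spacing, so axial
#' interpolation is immaterial). Positions where the surface is invalid or the
#' offset runs past the bottom of the volume are `NA`.
#'
#' @param vol an [oct_volume()].
#' @param surface a [detect_surface()] result for `vol`.
#' @param depth_offset_um depth below the surface (um, >= 0); the
#'   co-registration convention uses 100.
#' @return object of class `en_face_plane`: `image` (y, x), `depth_offset_um`,
#'   `source_id`, `spacing_y_um`, `spacing_x_um`.
#' @export
extract_enface <- function(vol, surface, depth_offset_um = 100) {
  stopifnot(inherits(vol, "oct_volume"), inherits(surface, "surface_map"))
  if (depth_offset_um < 0) stop("depth offset must be non-negative")
  d <- dim(vol$intensity)
  k <- round(depth_offset_um / vol$spacing_z_um)
  zi <- surface$depth_index + k
  ok <- surface$valid & !is.na(zi) & zi >= 1 & zi <= d[1]
  img <- matrix(NA_real_, d[2], d[3])
  if (any(ok)) {
    yy <- row(zi)[ok]; xx <- col(zi)[ok]
    img[cbind(yy, xx)] <- vol$intensity[cbind(zi[ok], yy, xx)]
  }
  structure(list(image = img, depth_offset_um = depth_offset_um,
                 source_id = vol$tile_id %||% vol$role,
                 spacing_y_um = vol$spacing_y_um,
                 spacing_x_um = vol$spacing_x_um),
            class = "en_face_plane")
}

#' @export
print.en_face_plane <- function(x, ...) {
  cat(sprintf("<en_face_plane> %d x %d px at %.0f um below surface (source %s)\n",
              nrow(x$image), ncol(x$image), x$depth_offset_um, x$source_id))
  invisible(x)
}
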