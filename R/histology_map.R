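# Mapping the wide-field en face frame to bread-loaf histology: the section
# grid overlay, per-section shrinkage correction factors, and selection of
# the best-matching B-scan for each section. Sections compare against
# cross-sectional (z, x) planes -- never en face planes -- matching how the
# specimen is sectioned.

#' A histology section
#'
#' @param image 2-D (depth x width) structure image of the section.
#' @param section_index 1-based bread-loaf section number.
#' @param fresh_width_um specimen width measured on the fresh tissue at the
#'   section line.
#' @param section_width_um width measured on the section image (after
#'   processing shrinkage).
#' @param spacing_z_um,spacing_x_um pixel spacings of `image`.
#' @return object of class `histology_section`; its `correction_factor` is
#'   `fresh_width_um / section_width_um`.
#' @export
histology_section <- function(image, section_index, fresh_width_um,
                              section_width_um, spacing_z_um = 1,
                              spacing_x_um = 1) {
  if (fresh_width_um <= 0 || section_width_um <= 0)
    stop("widths must be positive")
  structure(list(image = image, section_index = as.integer(section_index),
                 fresh_width_um = fresh_width_um,
                 section_width_um = section_width_um,
                 correction_factor = fresh_width_um / section_width_um,
                 spacing_z_um = spacing_z_um, spacing_x_um = spacing_x_um),
            class = "histology_section")
}

#' Shrinkage correction factor
#'
#' The ratio of fresh-tissue width to histology-section width at the same
#' location; section dimensions are multiplied by this factor before
#' matching. Each slide gets its own factor (shrinkage varies within a
#' shaving).
#'
#' @param fresh_width_um,section_width_um widths (um), both positive.
#' @return the dimensionless factor `c`.
#' @export
shrinkage_factor <- function(fresh_width_um, section_width_um) {
  if (any(fresh_width_um <= 0) || any(section_width_um <= 0))
    stop("widths must be positive")
  fresh_width_um / section_width_um
}

#' Overlay the bread-loaf section grid on a wide-field en face plane
#'
#' Derives the specimen mask from the plane (tissue against dark background),
#' then places equally spaced section lines along the sectioning axis (y),
#' the first at half-spacing from the specimen edge. Flipping the orientation
#' code mirrors the line positions about the specimen midline.
#'
#' @param plane wide-field [extract_enface()] plane.
#' @param spacing_um bread-loaf section thickness (~4000-5000 um).
#' @param orientation_code `"up"` or `"down"`: which inked edge is at the top;
#'   `"down"` mirrors the grid.
#' @param mask_threshold specimen threshold as a fraction of the robust
#'   maximum of the smoothed plane.
#' @return object of class `section_grid`: `line_positions_um` (y), `spacing_um`,
#'   `orientation_code`, `specimen_range_um`.
#' @export
overlay_grid <- function(plane, spacing_um, orientation_code = c("up", "down"),
                         mask_threshold = 0.15) {
  stopifnot(inherits(plane, "en_face_plane"))
  orientation_code <- match.arg(orientation_code)
  img <- plane$image
  img[is.na(img)] <- 0
  sm <- smooth_gauss(img, 2)
  thr <- mask_threshold * stats::quantile(sm, 0.99)
  mask <- sm > thr
  rows <- which(apply(mask, 1, any))
  if (!length(rows)) stop("no specimen found in plane")
  y0 <- (min(rows) - 1) * plane$spacing_y_um
  y1 <- (max(rows) - 1) * plane$spacing_y_um
  if (spacing_um > (y1 - y0))
    stop("section spacing exceeds the specimen extent")
  pos <- section_line_positions(y0, y1, spacing_um)
  if (orientation_code == "down") pos <- sort(y1 + y0 - pos)
  structure(list(line_positions_um = pos, spacing_um = spacing_um,
                 orientation_code = orientation_code,
                 specimen_range_um = c(y0, y1)),
            class = "section_grid")
}

# binary tissue-structure map of a (z, x) image: solid tissue vs
# adipose/void, the representation experts actually compare across modalities
structure_map <- function(img, threshold_db = -5, smooth_px = 1.5) {
  sm <- smooth_gauss(img, smooth_px)
  db <- to_decibels(sm)
  db >= threshold_db
}

#' Match a histology section to its B-scan
#'
#' Rescales the section laterally by its shrinkage correction factor, reduces
#' both the section and candidate B-scans to binary tissue-structure maps
#' (solid vs adipose/void), and returns the B-scan index within
#' `search_halfwidth_um` of the grid line that maximizes the Dice overlap.
#' Ties are broken toward the grid line.
#'
#' @param section a [histology_section()].
#' @param wide_field wide-field [oct_volume()].
#' @param grid_line_um y position of the section's grid line (um).
#' @param search_halfwidth_um search half-window around the line (um).
#' @param threshold_db structure-map threshold.
#' @return list: `index` (best B-scan, 1-based y index), `score` (Dice in
#'   `[0, 1]`), `scores` (per candidate), `candidates` (indices).
#' @export
match_bscan <- function(section, wide_field, grid_line_um,
                        search_halfwidth_um = 1000, threshold_db = -5) {
  stopifnot(inherits(section, "histology_section"),
            inherits(wide_field, "oct_volume"))
  d <- dim(wide_field$intensity)
  spy <- wide_field$spacing_y_um; spx <- wide_field$spacing_x_um
  yc <- round(grid_line_um / spy) + 1L
  if (yc < 1 || yc > d[2]) stop("grid line outside the volume")
  hw <- round(search_halfwidth_um / spy)
  cand <- max(1L, yc - hw):min(d[2], yc + hw)
  # undo shrinkage: scale the section back to fresh lateral dimensions
  cf <- section$correction_factor
  img <- section$image
  n_new <- max(2L, round(ncol(img) * cf))
  xi <- seq(1, ncol(img), length.out = n_new)
  img_f <- t(apply(img, 1, function(r)
    stats::approx(seq_along(r), r, xout = xi)$y))
  sec_bin <- structure_map(img_f, threshold_db)
  nzs <- nrow(sec_bin)
  scores <- vapply(cand, function(yi) {
    b <- wide_field$intensity[, yi, ]
    b_bin <- structure_map(b, threshold_db)
    # center-align laterally; compare over the common width and depth
    w <- min(ncol(b_bin), ncol(sec_bin))
    zz <- min(nrow(b_bin), nzs)
    off_b <- (ncol(b_bin) - w) %/% 2; off_s <- (ncol(sec_bin) - w) %/% 2
    A <- b_bin[seq_len(zz), off_b + seq_len(w)]
    B <- sec_bin[seq_len(zz), off_s + seq_len(w)]
    2 * sum(A & B) / max(1, sum(A) + sum(B))
  }, 0)
  best <- which(scores == max(scores))
  best <- best[which.min(abs(cand[best] - yc))]
  list(index = cand[best], score = scores[best], scores = scores,
       candidates = cand)
}
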