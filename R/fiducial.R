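# Cavity-suture fiducial detection. The suture is a bright elongated ridge at
# a known width scale in the en face plane; it is detected by grayscale
# top-hat filtering at that scale, thresholding, connected-component labeling
# and second-moment gating on elongation and width. No learning is needed.

#' A fiducial mark
#' @param centroid_um (x, y) centroid in plane coordinates (um).
#' @param axis_deg principal orientation in degrees, modulo 180, measured from
#'   the +x axis toward +y.
#' @param length_um,width_um component extents (um).
#' @param confidence detector confidence in `[0, 1]`.
#' @param multiplicity TRUE when more than one candidate passed the gates.
#' @export
fiducial_mark <- function(centroid_um, axis_deg, length_um, width_um,
                          confidence, multiplicity = FALSE) {
  if (length_um < width_um || width_um <= 0)
    stop("fiducial must satisfy length >= width > 0")
  structure(list(centroid_um = unname(as.numeric(centroid_um)),
                 axis_deg = unname(((axis_deg %% 180) + 180) %% 180),
                 length_um = unname(length_um), width_um = unname(width_um),
                 confidence = unname(max(0, min(1, confidence))),
                 multiplicity = isTRUE(multiplicity)),
            class = "fiducial_mark")
}

#' Detect the cavity suture in an en face plane
#'
#' @param plane an [extract_enface()] plane with valid data over at least half
#'   its area.
#' @param expected_width_um acceptance band for the ridge width (um).
#' @param min_elongation minimum length/width ratio of a suture candidate.
#' @param min_length_um minimum ridge length; sutures are millimeter-scale,
#'   which separates them from chance alignments of bright speckle.
#' @param threshold_fraction top-hat threshold as a fraction of the top-hat
#'   maximum.
#' @return a [fiducial_mark()] (with `multiplicity` flagged when several
#'   candidates pass, mirroring the two-suture situation where a long
#'   orientation suture coexists with the short cavity suture), or `NULL`
#'   when no elongated bright component within the width band exists.
#' @export
detect_suture <- function(plane, expected_width_um = c(100, 600),
                          min_elongation = 3, min_length_um = 1000,
                          threshold_fraction = 0.3) {
  stopifnot(inherits(plane, "en_face_plane"))
  img <- plane$image
  valid_frac <- mean(!is.na(img))
  if (valid_frac < 0.5)
    stop("insufficient data: en face plane is mostly empty")
  img[is.na(img)] <- 0
  sp <- (plane$spacing_x_um + plane$spacing_y_um) / 2
  # smooth at ~quarter the expected suture width to suppress speckle while
  # keeping the ridge
  img_s <- smooth_gauss(img, max(1, 0.25 * mean(expected_width_um) / sp))
  brush_px <- 2L * as.integer(ceiling(max(expected_width_um) / sp / 2)) + 1L
  ref <- EBImage::Image(t(img_s))            # EBImage frames are [x, y]
  th <- EBImage::whiteTopHat(ref, EBImage::makeBrush(brush_px, "disc"))
  thm <- EBImage::imageData(th)
  mx <- max(thm)
  bg <- stats::median(thm)
  md <- stats::mad(thm, center = bg)
  if (mx <= 0 || (mx - bg) < 4 * md + 1e-12)
    return(NULL)                             # no ridge stands out
  # hysteresis: a candidate component must reach the strong level somewhere
  # and is delineated at the weak level; both floored above the background
  # bulk so a speckle-only plane cannot produce closable chains
  weak <- thm > bg + max(threshold_fraction * (mx - bg), 3 * md)
  strong <- thm > bg + max(1.8 * threshold_fraction * (mx - bg), 6 * md)
  # bridge speckle-induced gaps along the ridge before labeling
  close_px <- max(3L, 2L * as.integer(
    ceiling(mean(expected_width_um) / sp / 2)) + 1L)
  mask <- EBImage::closing(EBImage::Image(weak * 1),
                           EBImage::makeBrush(close_px, "disc")) > 0.5
  lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
  nobj <- max(lab)
  if (nobj < 1) return(NULL)
  seeded <- unique(EBImage::imageData(lab)[strong & EBImage::imageData(lab) > 0])
  if (!length(seeded)) return(NULL)
  mom <- EBImage::computeFeatures.moment(lab, ref)
  mom <- matrix(mom, ncol = 5,
                dimnames = list(NULL, c("m.cx", "m.cy", "m.majoraxis",
                                        "m.eccentricity", "m.theta")))
  cand <- list()
  for (i in seq_len(nrow(mom))) {
    if (!(i %in% seeded)) next
    major <- mom[i, "m.majoraxis"]
    minor <- major * sqrt(1 - min(mom[i, "m.eccentricity"], 0.999999)^2)
    if (minor <= 0) next
    # moment axes of a uniform bar overestimate its edge-to-edge dims by
    # 2/sqrt(3); undo that to report physical length/width
    len_um <- major * sp * sqrt(3) / 2
    wid_um <- minor * sp * sqrt(3) / 2
    elong <- len_um / wid_um
    if (elong < min_elongation || len_um < min_length_um) next
    if (wid_um < expected_width_um[1] || wid_um > expected_width_um[2]) next
    sel <- EBImage::imageData(lab) == i
    bright <- mean(EBImage::imageData(ref)[sel])
    conf <- max(0, min(1, bright / stats::quantile(img_s, 0.999))) *
      (1 - 1 / elong)
    # EBImage: cx along x (frame dim 1), cy along y; theta from +x toward +y
    cand[[length(cand) + 1L]] <- fiducial_mark(
      centroid_um = c((mom[i, "m.cx"] - 1) * plane$spacing_x_um,
                      (mom[i, "m.cy"] - 1) * plane$spacing_y_um),
      axis_deg = mom[i, "m.theta"] * 180 / pi,
      length_um = len_um, width_um = wid_um, confidence = conf)
  }
  if (!length(cand)) return(NULL)
  best <- cand[[which.max(vapply(cand, `[[`, 0, "confidence"))]]
  best$multiplicity <- length(cand) > 1
  best
}
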