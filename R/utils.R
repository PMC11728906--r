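# Shared numeric helpers: bilinear resampling, plane rotation, separable
# smoothing. All image matrices are indexed [y, x] (row = y, col = x) with
# 1-based voxel-center indices; physical position of index i is (i - 1) * spacing.

#' Bilinear sampling of a matrix at fractional indices
#'
#' @param mat numeric matrix indexed `[y, x]`.
#' @param x,y fractional 1-based column/row indices (same length).
#' @return numeric vector of sampled values; `NA` outside the matrix or where a
#'   contributing pixel is `NA`.
#' @keywords internal
bilinear_sample <- function(mat, x, y) {
  nr <- nrow(mat); nc <- ncol(mat)
  out <- rep(NA_real_, length(x))
  ok <- x >= 1 & x <= nc & y >= 1 & y <= nr & is.finite(x) & is.finite(y)
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  v <- (1 - fy) * ((1 - fx) * mat[i00] + fx * mat[i01]) +
    fy * ((1 - fx) * mat[i10] + fx * mat[i11])
  out[ok] <- v
  out
}

#' Rotate an image about its center
#'
#' Rotation is by `theta_deg` degrees in the (x, y) plane using the matrix
#' `[[cos, -sin], [sin, cos]]` acting on (x, y) column vectors, i.e. a point on
#' the +x axis moves toward +y for positive angles. The output canvas is
#' enlarged to contain the full rotated image; pixels with no source are `NA`.
#'
#' @param img numeric matrix `[y, x]`.
#' @param theta_deg rotation angle in degrees.
#' @return list with `image` (rotated matrix) and `center` (c(row, col) of the
#'   original image center in the output).
#' @keywords internal
rotate_plane <- function(img, theta_deg) {
  th <- theta_deg * pi / 180
  nr <- nrow(img); nc <- ncol(img)
  if (abs(theta_deg) < 1e-9) {
    return(list(image = img, center = c((nr + 1) / 2, (nc + 1) / 2)))
  }
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  # output extent: rotated bounding box
  hw <- (nc - 1) / 2; hh <- (nr - 1) / 2
  hw2 <- abs(hw * cos(th)) + abs(hh * sin(th))
  hh2 <- abs(hw * sin(th)) + abs(hh * cos(th))
  nc2 <- 2 * ceiling(hw2) + 1
  nr2 <- 2 * ceiling(hh2) + 1
  cx2 <- (nc2 + 1) / 2; cy2 <- (nr2 + 1) / 2
  xg <- rep(seq_len(nc2), each = nr2) - cx2
  yg <- rep(seq_len(nr2), times = nc2) - cy2
  # inverse map: source = R(-theta) * dest
  xs <- cos(th) * xg + sin(th) * yg + cx
  ys <- -sin(th) * xg + cos(th) * yg + cy
  out <- matrix(bilinear_sample(img, xs, ys), nr2, nc2)
  list(image = out, center = c(cy2, cx2))
}

#' Separable Gaussian smoothing with edge replication
#'
#' `NA` pixels are handled by mask-normalized convolution (smoothing the mask
#' alongside the data), so valid pixels near `NA` regions are not darkened.
#'
#' @param mat numeric matrix.
#' @param sigma_px Gaussian sigma in pixels; 0 returns the input.
#' @keywords internal
smooth_gauss <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  k <- max(1L, ceiling(3 * sigma_px))
  kern <- stats::dnorm(seq(-k, k), sd = sigma_px)
  kern <- kern / sum(kern)
  na <- is.na(mat)
  if (any(na)) {
    w <- 1 - na
    m0 <- mat; m0[na] <- 0
    num <- conv_sep(m0, kern)
    den <- conv_sep(w, kern)
    out <- num / pmax(den, 1e-12)
    out[na] <- NA_real_
    return(out)
  }
  conv_sep(mat, kern)
}

# separable convolution with replicated edges
conv_sep <- function(mat, kern) {
  k <- (length(kern) - 1L) / 2L
  conv1 <- function(m) {
    nr <- nrow(m)
    padded <- rbind(m[rep(1L, k), , drop = FALSE], m,
                    m[rep(nr, k), , drop = FALSE])
    f <- stats::filter(padded, kern, sides = 2)
    matrix(f[(k + 1L):(k + nr), ], nr, ncol(m))
  }
  t(conv1(t(conv1(mat))))
}

#' Median smoothing of a matrix (separable approximation)
#' @keywords internal
smooth_median <- function(mat, k) {
  k <- as.integer(k)
  if (k < 3L) return(mat)
  if (k %% 2L == 0L) k <- k + 1L
  row_pass <- function(m, k) {
    if (ncol(m) <= k) return(m)
    t(apply(m, 1, function(v) stats::runmed(v, k, endrule = "median")))
  }
  m <- row_pass(mat, k)
  t(row_pass(t(m), k))
}

#' Smooth unit-variance Gaussian random field
#' @keywords internal
smooth_noise_field <- function(nr, nc, sigma_px) {
  f <- smooth_gauss(matrix(stats::rnorm(nr * nc), nr, nc), sigma_px)
  (f - mean(f)) / stats::sd(f)
}

# quadratic sub-grid peak interpolation from three samples around a maximum;
# returns offset in (-0.5, 0.5) relative to the center sample
parabolic_offset <- function(ym1, y0, yp1) {
  den <- ym1 - 2 * y0 + yp1
  if (!is.finite(den) || den >= 0) return(0)
  off <- 0.5 * (ym1 - yp1) / den
  max(-0.5, min(0.5, off))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
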