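# Quantitative micro-elastography: axial displacement between compression
# states by windowed 1-D cross-correlation, axial strain by confidence-
# weighted least squares, layer stress from the characterized stress-strain
# curve, per-voxel elasticity as stress / strain, and validity masking
# (adipose artifacts and non-contact). Computation is in linear kPa; the
# logarithmic scale is a display convention only.

# windowed running sum along z of a (nz x N) matrix, window W (odd), edge-
# padded so every depth has a full window
run_sum_z <- function(m, W) {
  nz <- nrow(m); h <- (W - 1L) %/% 2L
  pad <- rbind(m[rep(1L, h), , drop = FALSE], m, m[rep(nz, h), , drop = FALSE])
  cs <- apply(pad, 2, cumsum)
  cs <- rbind(matrix(0, 1, ncol(m)), cs)
  cs[(W + 1L):(nz + W), , drop = FALSE] - cs[1L:nz, , drop = FALSE]
}

#' Estimate axial displacement between two compression states
#'
#' Per voxel, the axial shift (in the windowed neighborhood along z) that
#' maximizes normalized cross-correlation between the pre and post A-scans,
#' refined to sub-voxel by parabolic interpolation of the correlation peak.
#' Positive displacement means features move to larger depth; compression
#' toward the imaging window therefore yields negative values that grow in
#' magnitude with depth.
#'
#' @param pre,post [oct_volume()]s of identical shape and spacings.
#' @param window_um axial correlation window (um).
#' @param max_shift_um shift search half-range (um).
#' @param presmooth_z_voxels Gaussian sigma (voxels) of a light axial
#'   smoothing applied to both volumes before tracking; symmetrizes
#'   interpolation blur between the states and reduces integer-locking bias.
#' @return object of class `displacement_volume`: `uz_um` (z, y, x) and
#'   `confidence` (correlation peak value, 0 outside the trackable interior).
#' @export
estimate_displacement <- function(pre, post, window_um = 50,
                                  max_shift_um = NULL,
                                  presmooth_z_voxels = 1) {
  stopifnot(inherits(pre, "oct_volume"), inherits(post, "oct_volume"))
  d <- dim(pre$intensity)
  if (!identical(d, dim(post$intensity))) stop("volumes must share shape")
  dz <- pre$spacing_z_um
  W <- max(3L, 2L * floor(window_um / dz / 2) + 1L)
  if (W > d[1]) stop("correlation window larger than volume depth")
  S <- if (is.null(max_shift_um)) 8L else max(1L, round(max_shift_um / dz))
  nz <- d[1]; N <- d[2] * d[3]
  a <- matrix(pre$intensity, nz)
  b <- matrix(post$intensity, nz)
  if (presmooth_z_voxels > 0) {
    kk <- max(1L, ceiling(3 * presmooth_z_voxels))
    gk <- stats::dnorm(-kk:kk, sd = presmooth_z_voxels)
    gk <- gk / sum(gk)
    smz <- function(m) {
      p <- rbind(m[rep(1L, kk), , drop = FALSE], m,
                 m[rep(nz, kk), , drop = FALSE])
      f <- stats::filter(p, gk, sides = 2)
      matrix(f[(kk + 1L):(kk + nz), ], nz, ncol(m))
    }
    a <- smz(a); b <- smz(b)
  }
  sa <- run_sum_z(a, W); saa <- run_sum_z(a * a, W)
  ncc_s <- vector("list", 2L * S + 1L)
  res_s <- vector("list", 2L * S + 1L)
  shifts <- -S:S
  for (k in seq_along(shifts)) {
    s <- shifts[k]
    bs <- if (s >= 0) rbind(b[(1 + s):nz, , drop = FALSE],
                            b[rep(nz, s), , drop = FALSE])
    else rbind(b[rep(1L, -s), , drop = FALSE], b[1:(nz + s), , drop = FALSE])
    sb <- run_sum_z(bs, W); sbb <- run_sum_z(bs * bs, W)
    sab <- run_sum_z(a * bs, W)
    num <- sab - sa * sb / W
    den <- sqrt(pmax(saa - sa^2 / W, 0) * pmax(sbb - sb^2 / W, 0))
    v <- num / den
    v[!is.finite(v)] <- -1
    ncc_s[[k]] <- v
    # gradient (optical-flow) residual: bs(z) ~ pre(z - r) for small r
    g <- (rbind(bs[-1, , drop = FALSE], bs[nz, , drop = FALSE]) -
            rbind(bs[1, , drop = FALSE], bs[-nz, , drop = FALSE])) / 2
    rnum <- run_sum_z((a - bs) * g, W)
    rden <- run_sum_z(g * g, W)
    r <- rnum / rden
    r[!is.finite(r)] <- 0
    res_s[[k]] <- pmax(-1, pmin(1, r))
  }
  K <- length(shifts)
  pk <- matrix(1L, nz, N)
  peak <- ncc_s[[1]]
  for (k in 2:K) {
    upd <- ncc_s[[k]] > peak
    pk[upd] <- k
    peak[upd] <- ncc_s[[k]][upd]
  }
  # neighbor correlation values at pk-1 / pk+1 (parabolic fallback) and
  # gradient residual at the peak
  ym1 <- matrix(-1, nz, N); yp1 <- matrix(-1, nz, N)
  rres <- matrix(0, nz, N)
  for (k in seq_len(K)) {
    sel <- pk == k
    if (!any(sel)) next
    if (k > 1) ym1[sel] <- ncc_s[[k - 1]][sel]
    if (k < K) yp1[sel] <- ncc_s[[k + 1]][sel]
    rres[sel] <- res_s[[k]][sel]
  }
  interior <- pk > 1 & pk < K
  den0 <- ym1 - 2 * peak + yp1
  o <- 0.5 * (ym1 - yp1) / den0
  o[!is.finite(o) | den0 >= 0] <- 0
  # prefer the gradient residual (low integer-locking bias); outside its
  # linear range fall back to the correlation parabola
  use_g <- interior & abs(rres) <= 0.75
  off <- matrix(0, nz, N)
  off[interior] <- pmax(-0.5, pmin(0.5, o[interior]))
  off[use_g] <- rres[use_g]
  uz <- (matrix(shifts[pk], nz, N) + off) * dz
  conf <- pmax(peak, 0)
  # margins where the window or the shift range runs off the volume
  marg <- (W - 1L) %/% 2L + S
  if (marg >= 1 && 2 * marg < nz) {
    conf[c(seq_len(marg), (nz - marg + 1L):nz), ] <- 0
  }
  structure(list(uz_um = array(uz, d), confidence = array(conf, d),
                 spacing_z_um = dz, spacing_y_um = pre$spacing_y_um,
                 spacing_x_um = pre$spacing_x_um),
            class = "displacement_volume")
}

#' Axial strain from a displacement volume
#'
#' The gradient `d uz / dz`, estimated per voxel as the slope of a
#' confidence-weighted least-squares line fit of displacement against depth
#' over a centered axial window. Under compression toward the window the
#' returned values are negative; negate for compressive strain.
#'
#' @param disp a [estimate_displacement()] result.
#' @param fit_window_um axial fit window (um); must span >= 3 voxels.
#' @return array (z, y, x) of strain; `NA` where the window holds no
#'   confidence.
#' @export
compute_strain <- function(disp, fit_window_um = 100) {
  stopifnot(inherits(disp, "displacement_volume"))
  dz <- disp$spacing_z_um
  W <- 2L * floor(fit_window_um / dz / 2) + 1L
  if (W < 3L) stop("fit window must span at least 3 axial voxels")
  d <- dim(disp$uz_um)
  nz <- d[1]; N <- d[2] * d[3]
  u <- matrix(disp$uz_um, nz)
  w <- matrix(disp$confidence, nz)
  z <- (seq_len(nz) - 1) * dz
  zm <- matrix(z, nz, N)
  sw <- run_sum_z(w, W)
  swz <- run_sum_z(w * zm, W)
  swu <- run_sum_z(w * u, W)
  swzu <- run_sum_z(w * zm * u, W)
  swzz <- run_sum_z(w * zm * zm, W)
  den <- swzz - swz^2 / sw
  slope <- (swzu - swz * swu / sw) / den
  slope[!is.finite(slope) | sw < 1e-9] <- NA_real_
  array(slope, d)
}

#' Layer stress from measured layer strain
#'
#' Converts the (compressive, positive) strain measured in the compliant
#' layer to local axial stress by monotone interpolation of the layer's
#' characterized stress-strain curve.
#'
#' @param layer_strain (y, x) matrix of layer strains.
#' @param curve a [stress_strain_curve()].
#' @param extrapolate if FALSE (default), strains outside the characterized
#'   range raise an error; if TRUE they are linearly extrapolated from the
#'   nearest curve segment and flagged in the `extrapolated` attribute.
#' @return (y, x) matrix of stresses (kPa).
#' @export
layer_stress <- function(layer_strain, curve, extrapolate = FALSE) {
  stopifnot(inherits(curve, "stress_strain_curve"))
  s <- curve$strain_points; k <- curve$stress_points_kPa
  x <- as.numeric(layer_strain)
  out_of_range <- x < min(s) | x > max(s)
  out_of_range[is.na(x)] <- FALSE
  if (any(out_of_range) && !extrapolate)
    stop("layer strain outside the characterized range ",
         "(set extrapolate = TRUE to allow)")
  n <- length(s)
  slope_lo <- (k[2] - k[1]) / (s[2] - s[1])
  slope_hi <- (k[n] - k[n - 1]) / (s[n] - s[n - 1])
  y <- stats::approx(s, k, xout = pmin(pmax(x, min(s)), max(s)))$y
  y[x < min(s)] <- k[1] + slope_lo * (x[x < min(s)] - s[1])
  y[x > max(s)] <- k[n] + slope_hi * (x[x > max(s)] - s[n])
  res <- matrix(y, nrow(layer_strain), ncol(layer_strain))
  attr(res, "extrapolated") <- matrix(out_of_range, nrow(layer_strain))
  res
}

#' Per-voxel elasticity from stress and strain
#'
#' The uniaxial model: one axial stress per lateral position (broadcast along
#' depth) divided by the local axial strain. Voxels whose |strain| falls
#' below the noise floor are invalid rather than infinite.
#'
#' @param stress_kpa (y, x) stress map.
#' @param strain (z, y, x) compressive strain volume (positive under
#'   compression).
#' @param strain_floor strain noise floor.
#' @return object of class `elasticity_volume`: `E_kPa` (z, y, x), logical
#'   `valid`, and `log_display` flag (rendering convention).
#' @export
elasticity <- function(stress_kpa, strain, strain_floor = 1e-4) {
  d <- dim(strain)
  if (!all(dim(stress_kpa) == d[2:3]))
    stop("stress map must match the lateral shape of the strain volume")
  sig <- aperm(array(stress_kpa, c(d[2], d[3], d[1])), c(3, 1, 2))
  valid <- !is.na(strain) & abs(strain) >= strain_floor
  E <- array(NA_real_, d)
  E[valid] <- sig[valid] / strain[valid]
  valid <- valid & is.finite(E) & E > 0
  E[!valid] <- NA_real_
  structure(list(E_kPa = E, valid = valid, log_display = TRUE),
            class = "elasticity_volume")
}

#' Mask elasticity artifacts: adipose tissue and non-contact
#'
#' Voxels are invalidated where the co-registered OCT intensity indicates
#' adipose tissue (locally averaged intensity below an adipose dB threshold
#' -- low OCT signal there produces elasticity artifacts) and at lateral
#' positions without mechanical contact (layer strain at the noise floor).
#' The mask is monotone in its thresholds: loosening them never unmasks
#' voxels.
#'
#' @param E an [elasticity()] result.
#' @param oct co-registered [oct_volume()] (same shape).
#' @param adipose_threshold_db dB threshold on locally averaged intensity.
#' @param smooth_um lateral averaging scale.
#' @param layer_strain optional (y, x) layer-strain map for the non-contact
#'   rule.
#' @param contact_strain_floor layer strains at or below this are non-contact.
#' @return the elasticity volume with `valid` restricted and a `mask_reason`
#'   field ("adipose" / "non_contact" / "").
#' @export
mask_invalid <- function(E, oct, adipose_threshold_db = -5, smooth_um = 300,
                         layer_strain = NULL, contact_strain_floor = 1e-4) {
  stopifnot(inherits(E, "elasticity_volume"), inherits(oct, "oct_volume"))
  d <- dim(E$E_kPa)
  if (!identical(dim(oct$intensity), d))
    stop("OCT volume must match the elasticity volume")
  sp <- (oct$spacing_x_um + oct$spacing_y_um) / 2
  # adipose rule on the mean-intensity en face projection of the shallow
  # third of the tissue, where class contrast is not confounded by depth
  # attenuation
  zsel <- seq.int(1L, max(1L, ceiling(d[1] / 3)))
  mean_lat <- apply(oct$intensity[zsel, , , drop = FALSE], c(2, 3), mean)
  db <- to_decibels(smooth_gauss(mean_lat, max(0.8, smooth_um / sp / 2)))
  adipose <- db < adipose_threshold_db
  reason <- array("", d)
  adip3 <- aperm(array(adipose, c(d[2], d[3], d[1])), c(3, 1, 2))
  reason[adip3 & E$valid] <- "adipose"
  E$valid <- E$valid & !adip3
  if (!is.null(layer_strain)) {
    nc <- abs(layer_strain) <= contact_strain_floor
    nc3 <- aperm(array(nc, c(d[2], d[3], d[1])), c(3, 1, 2))
    reason[nc3 & E$valid] <- "non_contact"
    E$valid <- E$valid & !nc3
  }
  E$E_kPa[!E$valid] <- NA_real_
  E$mask_reason <- reason
  E
}

#' Full QME chain on a compression pair
#'
#' Displacement, strain, layer strain/stress from the top `layer_thickness_um`
#' of the volume, elasticity over the tissue region, and masking.
#'
#' @param pre,post compression pair [oct_volume()]s (layer slab on top, as
#'   produced by [simulate_compression_pair()]).
#' @param curve the layer [stress_strain_curve()].
#' @param layer_thickness_um layer thickness (um).
#' @param window_um,max_shift_um displacement-estimation parameters.
#' @param fit_window_um strain fit window.
#' @param strain_floor elasticity strain noise floor.
#' @param mask if TRUE apply [mask_invalid()].
#' @return list: `displacement`, `strain` (compressive, positive), `layer_strain`,
#'   `stress_kpa`, `elasticity` (tissue depths only), `tissue_z` (z indices of
#'   the tissue region in the input volumes).
#' @export
qme_pipeline <- function(pre, post, curve, layer_thickness_um = 500,
                         window_um = 50, max_shift_um = NULL,
                         fit_window_um = 100, strain_floor = 1e-4,
                         mask = TRUE) {
  dz <- pre$spacing_z_um
  L_px <- round(layer_thickness_um / dz)
  d <- dim(pre$intensity)
  disp <- estimate_displacement(pre, post, window_um, max_shift_um)
  slope <- compute_strain(disp, fit_window_um)
  strain <- -slope                       # compressive positive
  # layer strain: one confidence-weighted LS line per column over the layer
  # interior (the strain there is constant, so the fit may span the band
  # without crossing the layer/tissue boundary)
  lsel <- seq.int(max(1L, floor(L_px * 0.15) + 1L), ceiling(L_px * 0.85))
  nlz <- length(lsel)
  zl <- (lsel - 1) * dz
  ncol_lat <- prod(d[2:3])
  ul <- matrix(disp$uz_um[lsel, , ], nlz, ncol_lat)
  wl <- matrix(disp$confidence[lsel, , ], nlz, ncol_lat)
  sw <- colSums(wl); swz <- colSums(wl * zl); swu <- colSums(wl * ul)
  swzz <- colSums(wl * zl * zl); swzu <- colSums(wl * zl * ul)
  sl <- (swzu - swz * swu / sw) / (swzz - swz^2 / sw)
  sl[!is.finite(sl)] <- 0
  layer_strain <- matrix(-sl, d[2], d[3])
  stress <- layer_stress(layer_strain, curve, extrapolate = TRUE)
  tissue_z <- seq.int(L_px + 1L, d[1])
  E <- elasticity(stress, strain[tissue_z, , , drop = FALSE], strain_floor)
  if (mask) {
    oct_t <- oct_volume(pre$intensity[tissue_z, , , drop = FALSE], dz,
                        pre$spacing_y_um, pre$spacing_x_um,
                        role = pre$role)
    E <- mask_invalid(E, oct_t, layer_strain = layer_strain,
                      contact_strain_floor = strain_floor)
  }
  list(displacement = disp, strain = strain, layer_strain = layer_strain,
       stress_kpa = stress, elasticity = E, tissue_z = tissue_z)
}
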