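# Synthetic shaving phantom: wide-field OCT volumes with ground truth, tile
# extraction with acquisition degradations, compression pairs for QME, and
# warped histology sections. The generator emulates the image appearance the
# pipeline relies on -- bright dense stroma with depth attenuation, honeycomb
# adipose (bright septa, dark cell interiors), a bright protruding suture
# ridge, tubular vessel/nerve inclusions, surface topography and fully
# developed multiplicative speckle -- not OCT physics.

#' Specify a synthetic shaving phantom
#'
#' Defaults mirror the acquisition geometry of the clinical protocol
#' (20 x 20 x 3.5 mm specimen sampled at 12.7 um laterally / 3.4 um axially);
#' tests and examples pass coarser spacings to scale the problem down.
#'
#' @param extent_um physical extent c(x, y, z) in um.
#' @param spacing_lateral_um,spacing_axial_um voxel spacings (um).
#' @param adipose_fraction target areal fraction of adipose tissue in `[0,1]`.
#' @param features list of tubular inclusions; each a list with `center_um`
#'   c(x, y), `axis_deg`, `length_um`, `radius_um`, `depth_um`.
#' @param suture list(`present`, `centroid_um` c(x, y), `axis_deg`,
#'   `length_um`, `width_um`, `protrusion_um`): the cavity-suture fiducial,
#'   rendered as a bright elongated ridge protruding above the tissue surface.
#' @param attenuation_db_per_mm dense-tissue intensity decay with depth
#'   (dB/mm); adipose attenuates at one third of this.
#' @param speckle_contrast multiplicative speckle contrast in `[0,1]`
#'   (1 = fully developed exponential speckle, 0 = noiseless).
#' @param surface_topography_amplitude_um amplitude of the smooth surface
#'   height field.
#' @param cell_diameter_um adipose honeycomb cell diameter.
#' @param dense_reflectivity,dense_variation backscatter level of dense stroma
#'   and log-amplitude of its smooth spatial variation (the subtle intensity
#'   texture that makes dense regions registrable).
#' @param duct_fraction,duct_contrast areal fraction and intensity multiplier
#'   of hypo-reflective duct/lobule inclusions scattered through dense
#'   stroma; kept below 10 % so pure dense fields still satisfy the 90 %
#'   dominance rule.
#' @param damaged_fraction areal fraction of dense tissue marked as thermally
#'   damaged in the ground-truth elasticity map.
#' @param specimen_margin_um air border between specimen and volume edge.
#' @param seed integer; the same seed yields a bit-identical phantom.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(extent_um = c(20000, 20000, 3500),
                         spacing_lateral_um = 12.7,
                         spacing_axial_um = 3.4,
                         adipose_fraction = 0.35,
                         features = NULL,
                         suture = list(present = TRUE),
                         attenuation_db_per_mm = 6,
                         speckle_contrast = 0.9,
                         surface_topography_amplitude_um = 100,
                         cell_diameter_um = 90,
                         dense_reflectivity = 0.7,
                         dense_variation = 0.4,
                         duct_fraction = 0.07,
                         duct_contrast = 0.2,
                         damaged_fraction = 0.08,
                         specimen_margin_um = 600,
                         seed = 1L) {
  stopifnot(length(extent_um) == 3, all(extent_um > 0),
            spacing_lateral_um > 0, spacing_axial_um > 0)
  if (adipose_fraction < 0 || adipose_fraction > 1)
    stop("adipose_fraction must be in [0, 1]")
  if (damaged_fraction < 0 || damaged_fraction > 1)
    stop("damaged_fraction must be in [0, 1]")
  if (speckle_contrast < 0 || speckle_contrast > 1)
    stop("speckle_contrast must be in [0, 1]")
  su <- utils::modifyList(list(
    present = TRUE,
    centroid_um = c(extent_um[1] / 2, extent_um[2] / 2),
    axis_deg = 25, length_um = min(3000, extent_um[1] / 3),
    width_um = 280, protrusion_um = 150), suture %||% list(present = FALSE))
  if (su$present) {
    if (any(su$centroid_um < 0) || su$centroid_um[1] > extent_um[1] ||
        su$centroid_um[2] > extent_um[2])
      stop("suture centroid outside phantom extent")
  }
  if (is.null(features)) {
    features <- list(
      list(center_um = c(0.30, 0.62) * extent_um[1:2], axis_deg = -35,
           length_um = 0.18 * extent_um[1], radius_um = 150, depth_um = 300),
      list(center_um = c(0.70, 0.30) * extent_um[1:2], axis_deg = 60,
           length_um = 0.12 * extent_um[1], radius_um = 100, depth_um = 250))
  }
  for (f in features) {
    if (any(f$center_um < 0) || f$center_um[1] > extent_um[1] ||
        f$center_um[2] > extent_um[2] || f$radius_um <= 0)
      stop("feature outside phantom extent")
  }
  structure(list(
    extent_um = as.numeric(extent_um),
    spacing_lateral_um = spacing_lateral_um,
    spacing_axial_um = spacing_axial_um,
    adipose_fraction = adipose_fraction,
    features = features, suture = su,
    attenuation_db_per_mm = attenuation_db_per_mm,
    speckle_contrast = speckle_contrast,
    surface_topography_amplitude_um = surface_topography_amplitude_um,
    cell_diameter_um = cell_diameter_um,
    dense_reflectivity = dense_reflectivity,
    dense_variation = dense_variation,
    duct_fraction = duct_fraction,
    duct_contrast = duct_contrast,
    damaged_fraction = damaged_fraction,
    specimen_margin_um = specimen_margin_um,
    seed = as.integer(seed)), class = "phantom_spec")
}

# lateral mask of a rotated rectangle (suture footprint, vessel segment band)
rect_mask <- function(ny, nx, sp, center_um, axis_deg, length_um, halfwidth_um) {
  th <- axis_deg * pi / 180
  x <- (rep(seq_len(nx), each = ny) - 1) * sp - center_um[1]
  y <- (rep(seq_len(ny), times = nx) - 1) * sp - center_um[2]
  along <- x * cos(th) + y * sin(th)
  perp <- -x * sin(th) + y * cos(th)
  matrix(abs(along) <= length_um / 2 & abs(perp) <= halfwidth_um, ny, nx)
}

#' Generate a synthetic wide-field shaving volume with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `volume` (an [oct_volume()], role `wide_field`) and
#'   `truth` (class `phantom_truth`): `tissue_class` (y, x; 1 = dense,
#'   2 = adipose, 0 = background), `specimen` mask, `surface_um` depth of the
#'   tissue surface below the window, `elasticity_kpa` lateral map (dense
#'   15 kPa, adipose 3 kPa, thermally damaged patches 25 kPa),
#'   `feature_masks`, and `suture` (centroid, axis, mask).
#' @export
generate_shaving_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  sp <- spec$spacing_lateral_um; dz <- spec$spacing_axial_um
  nx <- round(spec$extent_um[1] / sp); ny <- round(spec$extent_um[2] / sp)
  nz <- round(spec$extent_um[3] / dz)

  # tissue classes: thresholded smooth field gives the target areal fraction
  cls <- matrix(1L, ny, nx)
  if (spec$adipose_fraction >= 1) {
    cls[] <- 2L
  } else if (spec$adipose_fraction > 0) {
    f <- smooth_noise_field(ny, nx, sigma_px = max(2, 1200 / sp))
    cls[f > stats::quantile(f, 1 - spec$adipose_fraction)] <- 2L
  }
  mpx <- round(spec$specimen_margin_um / sp)
  specimen <- matrix(FALSE, ny, nx)
  specimen[(mpx + 1):(ny - mpx), (mpx + 1):(nx - mpx)] <- TRUE
  cls[!specimen] <- 0L

  # reflectivity: dense stroma with two-scale smooth variation (the subtle
  # but registrable intensity structure of dense tissue); adipose honeycomb
  # via jittered-grid Voronoi (bright septa, dark interiors)
  dense_map <- spec$dense_reflectivity *
    exp(spec$dense_variation *
          (smooth_noise_field(ny, nx, sigma_px = max(2, 1500 / sp)) +
             smooth_noise_field(ny, nx, sigma_px = max(1.5, 500 / sp))) /
          sqrt(2))
  if (spec$duct_fraction > 0) {
    # hypo-reflective ducts / lobules scattered through the stroma
    df <- smooth_noise_field(ny, nx, sigma_px = max(1.5, 300 / sp))
    ducts <- df > stats::quantile(df, 1 - spec$duct_fraction)
    dense_map[ducts] <- dense_map[ducts] * spec$duct_contrast
  }
  refl <- dense_map
  if (any(cls == 2L)) {
    s_px <- spec$cell_diameter_um / sp
    gx <- (rep(seq_len(nx), each = ny) - 1)
    gy <- (rep(seq_len(ny), times = nx) - 1)
    ci <- floor(gx / s_px); cj <- floor(gy / s_px)
    ncell_x <- floor((nx - 1) / s_px) + 2L; ncell_y <- floor((ny - 1) / s_px) + 2L
    jx <- matrix(stats::runif((ncell_x + 2) * (ncell_y + 2), 0.15, 0.85),
                 ncell_y + 2, ncell_x + 2)
    jy <- matrix(stats::runif((ncell_x + 2) * (ncell_y + 2), 0.15, 0.85),
                 ncell_y + 2, ncell_x + 2)
    d1 <- rep(Inf, ny * nx); d2 <- rep(Inf, ny * nx)
    for (di in -1:1) for (dj in -1:1) {
      ii <- ci + di; jj <- cj + dj
      idx <- cbind(jj + 2L, ii + 2L)
      cxp <- (ii + jx[idx]) * s_px; cyp <- (jj + jy[idx]) * s_px
      d <- sqrt((gx - cxp)^2 + (gy - cyp)^2)
      closer <- d < d1
      d2 <- ifelse(closer, d1, pmin(d2, d))
      d1 <- pmin(d1, d)
    }
    septa <- matrix((d2 - d1) * sp < 18, ny, nx)  # ~18 um septal half-gap
    adip <- ifelse(septa, 0.4, 0.04)
    refl[cls == 2L] <- adip[cls == 2L]
  }

  # tubular inclusions: dark lumen with bright wall at a depth band
  feature_masks <- list()
  for (k in seq_along(spec$features)) {
    f <- spec$features[[k]]
    core <- rect_mask(ny, nx, sp, f$center_um, f$axis_deg, f$length_um,
                      f$radius_um)
    wall <- rect_mask(ny, nx, sp, f$center_um, f$axis_deg,
                      f$length_um + 60, f$radius_um + 40) & !core
    feature_masks[[k]] <- list(core = core & specimen, wall = wall & specimen,
                               depth_um = f$depth_um, radius_um = f$radius_um)
  }

  # surface topography; the suture ridge protrudes above the surface
  base_depth <- 250
  surf <- base_depth + spec$surface_topography_amplitude_um *
    smooth_noise_field(ny, nx, sigma_px = max(2, 2500 / sp))
  suture_mask <- matrix(FALSE, ny, nx)
  if (spec$suture$present) {
    su <- spec$suture
    suture_mask <- rect_mask(ny, nx, sp, su$centroid_um, su$axis_deg,
                             su$length_um, su$width_um / 2)
    surf[suture_mask] <- pmax(dz, surf[suture_mask] - su$protrusion_um)
  }
  surf <- pmax(surf, dz)
  surf[!specimen] <- NA_real_

  # attenuation (dB per um of depth below surface), per lateral class
  att <- matrix(spec$attenuation_db_per_mm / 1000, ny, nx)
  att[cls == 2L] <- att[cls == 2L] / 3

  arr <- array(0, c(nz, ny, nx))
  air_level <- 2e-4
  c_sp <- spec$speckle_contrast
  surf0 <- surf; surf0[is.na(surf0)] <- Inf
  su_thick <- if (spec$suture$present) spec$suture$width_um else 0
  for (z in seq_len(nz)) {
    depth <- (z - 1) * dz - surf0         # um below local surface
    inside <- depth >= 0
    r <- refl
    for (fm in feature_masks) {
      lum <- fm$core & abs(depth - fm$depth_um) < fm$radius_um
      wl <- fm$wall & abs(depth - fm$depth_um) < fm$radius_um + 40
      r[wl] <- 0.95; r[lum] <- 0.03
    }
    fac <- 10^(-att * pmax(depth, 0) / 10)
    if (any(suture_mask)) {
      in_su <- suture_mask & inside & depth < su_thick
      below_su <- suture_mask & depth >= su_thick
      r[in_su] <- 1.6
      fac[in_su] <- 1
      fac[below_su] <- fac[below_su] * 10^(-1.5)  # 15 dB suture shadow
    }
    slice <- ifelse(inside, r * fac, air_level)
    spk <- (1 - c_sp) + c_sp * stats::rexp(ny * nx)
    arr[z, , ] <- slice * spk
  }

  elast <- matrix(15, ny, nx)
  elast[cls == 2L] <- 3
  if (spec$damaged_fraction > 0 && any(cls == 1L)) {
    g <- smooth_noise_field(ny, nx, sigma_px = max(2, 1800 / sp))
    dmg <- cls == 1L & g > stats::quantile(g[cls == 1L],
                                           1 - spec$damaged_fraction)
    elast[dmg] <- 25
  } else {
    dmg <- matrix(FALSE, ny, nx)
  }

  vol <- oct_volume(arr, dz, sp, sp, role = "wide_field",
                    tile_id = "phantom_wide_field")
  truth <- structure(list(
    tissue_class = cls, specimen = specimen, surface_um = surf,
    elasticity_kpa = elast, damaged = dmg,
    feature_masks = feature_masks,
    suture = list(present = spec$suture$present,
                  centroid_um = spec$suture$centroid_um,
                  axis_deg = spec$suture$axis_deg,
                  length_um = spec$suture$length_um,
                  width_um = spec$suture$width_um, mask = suture_mask),
    spec = spec), class = "phantom_truth")
  list(volume = vol, truth = truth)
}

#' Extract an in vivo tile from a wide-field phantom
#'
#' Samples a rotated tile footprint from the wide-field volume and applies the
#' acquisition differences between the handheld and benchtop systems: additive
#' noise, lateral blur (resolution mismatch), a blood film attenuating the
#' signal, and probe tilt (a linear ramp of the sampled depth across the
#' tile). With zero degradation, zero rotation and matched spacings the result
#' is a voxel-exact crop.
#'
#' @param wide_field wide-field [oct_volume()].
#' @param pose a [rigid_pose2d()]: lateral position of the tile center in
#'   wide-field coordinates and in-plane rotation.
#' @param tile_fov_um lateral tile field of view (um).
#' @param degrade list(`noise_sigma`, `blur_sigma_um`, `blood_opacity`,
#'   `tilt_deg`, `respeckle_contrast`), all default 0. `respeckle_contrast`
#'   replaces the speckle realization after blurring (multiplicative
#'   exponential noise of the given contrast): the handheld and benchtop
#'   systems have different point-spread functions, so they observe
#'   independent speckle over the same tissue; leaving it 0 keeps the
#'   voxel-exact crop contract.
#' @param tile_id identifier for the returned tile.
#' @return an [oct_volume()] with role `in_vivo_tile`.
#' @export
extract_tile <- function(wide_field, pose, tile_fov_um = 6000,
                         degrade = list(), tile_id = NULL) {
  stopifnot(inherits(wide_field, "oct_volume"), inherits(pose, "rigid_pose2d"))
  dg <- utils::modifyList(list(noise_sigma = 0, blur_sigma_um = 0,
                               blood_opacity = 0, tilt_deg = 0,
                               respeckle_contrast = 0), degrade)
  d <- dim(wide_field$intensity)
  spx <- wide_field$spacing_x_um; spy <- wide_field$spacing_y_um
  dz <- wide_field$spacing_z_um
  nt_x <- round(tile_fov_um / spx); nt_y <- round(tile_fov_um / spy)
  th <- pose$theta_deg * pi / 180
  # tile center = pixel floor(n/2)+1, so voxel-multiple translations at
  # theta = 0 sample the wide-field lattice exactly
  u <- (seq_len(nt_x) - (floor(nt_x / 2) + 1)) * spx
  v <- (seq_len(nt_y) - (floor(nt_y / 2) + 1)) * spy
  ug <- rep(u, each = nt_y); vg <- rep(v, times = nt_x)
  px <- cos(th) * ug - sin(th) * vg + pose$tx_um
  py <- sin(th) * ug + cos(th) * vg + pose$ty_um
  ix <- px / spx + 1; iy <- py / spy + 1
  if (min(ix) < 1 || max(ix) > d[3] || min(iy) < 1 || max(iy) > d[2])
    stop("tile footprint out of wide-field bounds")

  exact <- abs(pose$theta_deg) < 1e-9 &&
    max(abs(ix - round(ix))) < 1e-6 && max(abs(iy - round(iy))) < 1e-6
  arr <- array(0, c(d[1], nt_y, nt_x))
  if (exact) {
    arr[] <- wide_field$intensity[, round(iy[seq_len(nt_y)]),
                                  round(ix[seq(1, length(ix), by = nt_y)])]
  } else {
    for (z in seq_len(d[1])) {
      s <- bilinear_sample(wide_field$intensity[z, , ], ix, iy)
      s[is.na(s)] <- 0
      arr[z, , ] <- s
    }
  }

  if (dg$tilt_deg != 0) {
    # probe tilt: the sampled depth ramps linearly across the tile's x axis
    shift_vox <- tan(dg$tilt_deg * pi / 180) * u / dz
    zi <- seq_len(d[1])
    for (j in seq_len(nt_x)) {
      zq <- zi + shift_vox[j]
      m <- arr[, , j]
      arr[, , j] <- apply(m, 2, function(col)
        stats::approx(zi, col, xout = zq, rule = 2)$y)
    }
  }
  if (dg$blur_sigma_um > 0) {
    sg <- dg$blur_sigma_um / spx
    for (z in seq_len(d[1])) arr[z, , ] <- smooth_gauss(arr[z, , ], sg)
  }
  if (dg$respeckle_contrast > 0) {
    cc <- dg$respeckle_contrast
    arr <- arr * ((1 - cc) + cc * stats::rexp(length(arr)))
  }
  if (dg$blood_opacity > 0) arr <- arr * (1 - dg$blood_opacity)
  if (dg$noise_sigma > 0)
    arr <- pmax(arr + stats::rnorm(length(arr), sd = dg$noise_sigma), 0)

  oct_volume(arr, dz, spy, spx, role = "in_vivo_tile", tile_id = tile_id)
}

#' Simulate a QME compression pair on a phantom
#'
#' Forward model matching the uniaxial series-spring assumption of the QME
#' inversion: the compliant layer (known stress-strain curve) and the tissue
#' column under each lateral position share one axial stress; actuation is the
#' total displacement at the actuator face. The pre volume is the tissue
#' resampled surface-relative (flat against the imaging window, as under
#' pre-strain) with the layer slab on top; the post volume is the pre volume
#' axially warped by the resulting displacement field.
#'
#' @param wide_field wide-field [oct_volume()].
#' @param truth matching `phantom_truth` (for surface and elasticity maps);
#'   `truth$elasticity_kpa` may be a lateral map or a 3-D array over tissue
#'   depths for depth-structured phantoms.
#' @param layer a [stress_strain_curve()].
#' @param layer_thickness_um silicone layer thickness.
#' @param actuation_um actuator-face displacement (um).
#' @param layer_reflectivity OCT backscatter level of the silicone layer.
#' @return list(`pre`, `post` [oct_volume()]s, `true_displacement_um` array
#'   (z, y, x; negative toward the window), `stress_kpa` and
#'   `layer_strain` lateral maps, `layer_px` layer thickness in voxels).
#' @export
simulate_compression_pair <- function(wide_field, truth, layer,
                                      layer_thickness_um = 500, actuation_um,
                                      layer_reflectivity = 0.25) {
  stopifnot(inherits(wide_field, "oct_volume"),
            inherits(layer, "stress_strain_curve"))
  d <- dim(wide_field$intensity)
  dz <- wide_field$spacing_z_um
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  L_px <- round(layer_thickness_um / dz)
  if (L_px < 2 || L_px >= nz - 2) stop("layer thickness incompatible with depth")
  L_um <- L_px * dz
  nz_t <- nz - L_px
  ts_um <- nz_t * dz

  # pre: layer slab + tissue sampled surface-relative (flat under the window)
  surf_idx <- round((truth$surface_um %||% matrix(0, ny, nx)) / dz)
  surf_idx[is.na(surf_idx)] <- 0L
  pre <- array(2e-4, c(nz, ny, nx))
  spk <- matrix((1 - 0.6) + 0.6 * stats::rexp(L_px * ny * nx), L_px)
  pre[seq_len(L_px), , ] <- layer_reflectivity *
    array(spk, c(L_px, ny, nx))
  zsrc <- outer(seq_len(nz_t), as.vector(surf_idx), `+`)  # nz_t x (ny*nx)
  zsrc[zsrc > nz] <- nz
  wfm <- matrix(wide_field$intensity, nz)
  tis <- matrix(wfm[cbind(as.vector(zsrc),
                          rep(seq_len(ny * nx), each = nz_t))], nz_t)
  pre[(L_px + 1):nz, , ] <- array(tis, c(nz_t, ny, nx))

  # per-column stress from the series-spring balance
  E <- truth$elasticity_kpa
  if (length(dim(E)) == 3L) {
    if (dim(E)[1] != nz_t) stop("3-D elasticity must cover tissue depths")
    Cmap <- matrix(colSums(dz / matrix(E, nz_t)), ny, nx)   # um / kPa
  } else {
    Cmap <- ts_um / E
  }
  eps_of_sigma <- function(s)
    stats::approx(layer$stress_points_kPa, layer$strain_points, xout = s,
                  rule = 2)$y
  s_hi <- max(layer$stress_points_kPa)
  if (any(L_um * max(layer$strain_points) + s_hi * Cmap < actuation_um))
    stop("actuation drives layer strain outside its characterized range")
  lo <- matrix(0, ny, nx); hi <- matrix(s_hi, ny, nx)
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    f <- L_um * eps_of_sigma(mid) + mid * Cmap - actuation_um
    hi[f >= 0] <- mid[f >= 0]
    lo[f < 0] <- mid[f < 0]
  }
  sigma <- (lo + hi) / 2
  eps_layer <- matrix(eps_of_sigma(sigma), ny, nx)

  # strain profile and displacement (window frame; negative = toward window)
  zc <- (seq_len(nz) - 1) * dz
  strain <- array(0, c(nz, ny, nx))
  strain[seq_len(L_px), , ] <- rep(eps_layer, each = L_px)
  if (length(dim(E)) == 3L) {
    strain[(L_px + 1):nz, , ] <- rep(sigma, each = nz_t) / E
  } else {
    strain[(L_px + 1):nz, , ] <- rep(sigma / E, each = nz_t)
  }
  sm <- matrix(strain, nz)
  cum <- apply(sm, 2, cumsum) * dz
  # trapezoid integral of strain between voxel centers: u(center 1) = 0
  u <- -(cum - sm * dz / 2 - rep(sm[1, ], each = nz) * dz / 2)
  disp <- array(u, c(nz, ny, nx))

  post <- array(2e-4, c(nz, ny, nx))
  prem <- matrix(pre, nz)
  postm <- matrix(post, nz)
  for (cidx in seq_len(ny * nx)) {
    z1 <- zc + u[, cidx]
    postm[, cidx] <- stats::approx(z1, prem[, cidx], xout = zc, rule = 2)$y
  }
  post <- array(pmax(postm, 0), c(nz, ny, nx))

  mk <- function(a) oct_volume(a, dz, wide_field$spacing_y_um,
                               wide_field$spacing_x_um, role = "ex_vivo_tile")
  list(pre = mk(pre), post = mk(post), true_displacement_um = disp,
       stress_kpa = sigma, layer_strain = eps_layer, layer_px = L_px)
}

#' Generate warped histology sections from a phantom
#'
#' Sections follow the bread-loaf protocol: cross-sectional (z, x) planes at
#' equally spaced section lines (first line at half-spacing from the specimen
#' edge), laterally contracted by the per-section shrink factor and smoothly
#' warped, with the fresh-tissue width recorded before scaling.
#'
#' @param wide_field wide-field [oct_volume()].
#' @param truth matching `phantom_truth`.
#' @param section_spacing_um bread-loaf slab thickness (~4000-5000 um).
#' @param shrink_factors per-section fresh/section width ratios; recycled.
#' @param warp_amplitude_um amplitude of the smooth lateral warp.
#' @return list of [histology_section()] objects; each carries an attribute
#'   `truth` with the generating line position and B-scan index.
#' @export
generate_histology_sections <- function(wide_field, truth,
                                        section_spacing_um = 4500,
                                        shrink_factors = 1.18,
                                        warp_amplitude_um = 0) {
  stopifnot(inherits(wide_field, "oct_volume"))
  spy <- wide_field$spacing_y_um; spx <- wide_field$spacing_x_um
  rows <- which(apply(truth$specimen, 1, any))
  y0 <- (min(rows) - 1) * spy; y1 <- (max(rows) - 1) * spy
  if (section_spacing_um > (y1 - y0))
    stop("section spacing exceeds specimen extent")
  pos <- section_line_positions(y0, y1, section_spacing_um)
  nsec <- length(pos)
  shrink <- rep_len(shrink_factors, nsec)
  out <- vector("list", nsec)
  for (k in seq_len(nsec)) {
    yi <- round(pos[k] / spy) + 1L
    colsk <- which(truth$specimen[yi, ])
    img <- wide_field$intensity[, yi, colsk]
    fresh_um <- length(colsk) * spx
    if (warp_amplitude_um > 0) {
      nzr <- nrow(img)
      ph <- 2 * pi * (k %% 7) / 7
      shift_px <- warp_amplitude_um / spx *
        sin(2 * pi * (seq_len(nzr) - 1) / nzr + ph)
      xi <- seq_len(ncol(img))
      for (z in seq_len(nzr))
        img[z, ] <- stats::approx(xi, img[z, ], xout = xi + shift_px[z],
                                  rule = 2)$y
    }
    n_new <- max(2L, round(length(colsk) / shrink[k]))
    xi_new <- seq(1, length(colsk), length.out = n_new)
    img_s <- t(apply(img, 1, function(r)
      stats::approx(seq_along(r), r, xout = xi_new)$y))
    sec <- histology_section(img_s, section_index = k,
                             fresh_width_um = fresh_um,
                             section_width_um = n_new * spx,
                             spacing_z_um = wide_field$spacing_z_um,
                             spacing_x_um = spx)
    attr(sec, "truth") <- list(line_y_um = pos[k], b_index = yi,
                               shrink = shrink[k])
    out[[k]] <- sec
  }
  out
}

# bread-loaf line placement rule shared by the generator and overlay_grid
section_line_positions <- function(edge0_um, edge1_um, spacing_um) {
  p <- edge0_um + spacing_um / 2
  pos <- c()
  while (p < edge1_um) {
    pos <- c(pos, p)
    p <- p + spacing_um
  }
  pos
}
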