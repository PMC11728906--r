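test_that("the generator is deterministic and hits the target adipose fraction", {
  sp <- phantom_spec(extent_um = c(6000, 6000, 600), spacing_lateral_um = 60,
                     spacing_axial_um = 20, adipose_fraction = 0.3, seed = 7)
  a <- generate_shaving_phantom(sp)
  b <- generate_shaving_phantom(sp)
  expect_identical(a$volume$intensity, b$volume$intensity)
  expect_identical(a$truth$tissue_class, b$truth$tissue_class)

  # adipose_fraction 0 leaves the specimen entirely dense
  sp0 <- phantom_spec(extent_um = c(4000, 4000, 400), spacing_lateral_um = 80,
                      spacing_axial_um = 20, adipose_fraction = 0, seed = 1)
  t0 <- generate_shaving_phantom(sp0)$truth
  expect_true(all(t0$tissue_class[t0$specimen] == 1L))

  # realized areal fraction near the target
  ph <- mosaic_phantom(seed = 3, adipose = 0.3)
  tc <- ph$truth$tissue_class
  expect_lt(abs(mean(tc[tc > 0] == 2L) - 0.3), 0.05)

  # dense regions are brighter than adipose cell interiors in the volume
  surf <- detect_surface(ph$volume)
  pl <- extract_enface(ph$volume, surf, 100)
  expect_gt(mean(pl$image[tc == 1L], na.rm = TRUE),
            2 * mean(pl$image[tc == 2L], na.rm = TRUE))
})

test_that("phantom geometry is validated", {
  expect_error(phantom_spec(adipose_fraction = 1.2), "adipose_fraction")
  expect_error(phantom_spec(suture = list(present = TRUE,
                                          centroid_um = c(-5, 100))),
               "suture")
  expect_error(phantom_spec(features = list(
    list(center_um = c(50000, 100), axis_deg = 0, length_um = 100,
         radius_um = 50, depth_um = 100))), "feature")
})

test_that("extract_tile with zero degradation is an exact crop; rotation is a symmetry", {
  ph <- mosaic_phantom()
  wf <- ph$volume
  tile <- extract_tile(wf, rigid_pose2d(6000, 6000, 0), tile_fov_um = 6000)
  i0 <- 6000 / 60 + 1 - 50           # tile center voxel = floor(n/2)+1
  expect_identical(tile$intensity, wf$intensity[, i0:(i0 + 99), i0:(i0 + 99)])
  expect_identical(tile$role, "in_vivo_tile")

  # 90 degree rotation permutes the sampling lattice
  t90 <- extract_tile(wf, rigid_pose2d(6000, 6000, 90), tile_fov_um = 6000)
  n <- dim(tile)[2]; cc <- floor(n / 2) + 1
  for (z in c(10, 30)) {
    got <- t90$intensity[z, 2:n, 1:n]
    expected <- matrix(0, n - 1, n)
    for (iy in 2:n) expected[iy - 1, ] <- tile$intensity[z, , 2 * cc - iy]
    expect_equal(got, expected, tolerance = 1e-9)
  }

  expect_error(extract_tile(wf, rigid_pose2d(500, 500, 0), 6000), "bounds")
})

test_that("added noise monotonically decorrelates the tile from its source", {
  ph <- mosaic_phantom()
  crop <- extract_tile(ph$volume, rigid_pose2d(6000, 6000, 0), 6000)
  sig <- stats::sd(crop$intensity)
  cors <- sapply(seq_along(lv <- c(0, 0.3, 0.7, 1.5, 3)), function(i) {
    set.seed(40 + i)
    tl <- extract_tile(ph$volume, rigid_pose2d(6000, 6000, 0), 6000,
                       degrade = list(noise_sigma = lv[i] * sig))
    stats::cor(as.vector(tl$intensity), as.vector(crop$intensity))
  })
  expect_equal(cors[1], 1)
  expect_true(all(diff(cors) < 0))
})

test_that("compression pairs obey the uniaxial series-spring model", {
  ph <- qme_phantom(seed = 5, elasticity_kpa = 20)
  nz <- dim(ph$volume)[1]; dz <- ph$volume$spacing_z_um
  L <- 300; L_px <- L / dz; ts_um <- (nz - L_px) * dz

  # layer with the same modulus as the tissue: strain is uniform and equals
  # actuation / total thickness
  curve_same <- stress_strain_curve(c(0, 0.25), c(0, 0.25 * 20))
  act <- 20
  pair <- simulate_compression_pair(ph$volume, ph$truth, curve_same, L, act)
  eps_expect <- act / (L + ts_um)
  expect_equal(unname(pair$layer_strain[1, 1]), eps_expect, tolerance = 1e-6)
  expect_equal(max(pair$layer_strain) - min(pair$layer_strain), 0,
               tolerance = 1e-9)
  # stress equals E * strain everywhere (series springs share the stress)
  expect_equal(as.vector(pair$stress_kpa), rep(20 * eps_expect, length(pair$stress_kpa)),
               tolerance = 1e-6)

  # displacement at the far face equals the actuation within 1 %
  u_bottom <- abs(pair$true_displacement_um[nz, , ])
  expect_lt(max(abs(u_bottom - act)) / act, 0.01)

  # re-integrating the strain profile reproduces the displacement field
  eps <- act / (L + ts_um)
  zc <- (seq_len(nz) - 1) * dz
  u_analytic <- -eps * zc
  expect_lt(max(abs(pair$true_displacement_um[, 3, 3] - u_analytic)) / dz, 0.1)

  # two stacked tissue layers with E1 = 2 E2 strain in ratio 1:2
  nt <- nz - L_px
  E3 <- array(10, c(nt, dim(ph$volume)[2], dim(ph$volume)[3]))
  E3[seq_len(nt / 2), , ] <- 20
  tr2 <- ph$truth; tr2$elasticity_kpa <- E3
  curve <- stress_strain_curve(c(0, 0.3), c(0, 3))
  p2 <- simulate_compression_pair(ph$volume, tr2, curve, L, 25)
  u <- p2$true_displacement_um[, 2, 2]
  i1 <- L_px + seq_len(nt / 2); i2 <- L_px + nt / 2 + seq_len(nt / 2)
  s1 <- -stats::coef(stats::lm(u[i1] ~ zc[i1]))[2]
  s2 <- -stats::coef(stats::lm(u[i2] ~ zc[i2]))[2]
  expect_equal(unname(s2 / s1), 2, tolerance = 0.02)

  # actuation beyond the layer characterization is rejected
  expect_error(simulate_compression_pair(ph$volume, ph$truth,
                                         stress_strain_curve(c(0, 0.01),
                                                             c(0, 0.2)),
                                         L, 500), "range")
})

test_that("histology sections follow the bread-loaf geometry and record widths", {
  ph <- hist_phantom()
  wf <- ph$volume
  secs <- generate_histology_sections(wf, ph$truth, 3000,
                                      shrink_factors = 1.0,
                                      warp_amplitude_um = 0)
  # identity section equals the B-plane crop over the specimen
  s1 <- secs[[1]]
  tr <- attr(s1, "truth")
  cols <- which(ph$truth$specimen[tr$b_index, ])
  expect_equal(s1$image, wf$intensity[, tr$b_index, cols], tolerance = 1e-9)
  expect_equal(s1$correction_factor, 1, tolerance = 0.01)

  # section count matches the placement rule (first line at half spacing)
  rows <- which(apply(ph$truth$specimen, 1, any))
  extent <- (max(rows) - min(rows)) * wf$spacing_y_um
  n_expect <- 0; p <- 3000 / 2
  while (p < extent) { n_expect <- n_expect + 1; p <- p + 3000 }
  expect_length(secs, n_expect)

  # recorded widths define the correction factor exactly
  secs2 <- generate_histology_sections(wf, ph$truth, 3000,
                                       shrink_factors = 1.18)
  for (s in secs2) {
    expect_equal(s$fresh_width_um / s$section_width_um, s$correction_factor)
    expect_equal(s$correction_factor, 1.18, tolerance = 0.02)
  }

  expect_error(generate_histology_sections(wf, ph$truth, 20000), "extent")
})
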