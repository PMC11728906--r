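test_that("displacement tracking recovers integer, sub-voxel and zero shifts", {
  pre <- bandlimited_volume(nz = 200, seed = 1)
  nz <- dim(pre)[1]; dz <- pre$spacing_z_um

  # features moved 2 voxels deeper: post(z) = pre(z - 2)
  post_arr <- pre$intensity
  post_arr[3:nz, , ] <- pre$intensity[1:(nz - 2), , ]
  post <- oct_volume(post_arr, dz, 60, 60, role = "ex_vivo_tile")
  d <- estimate_displacement(pre, post, window_um = 50)
  core <- d$confidence > 0
  expect_lt(stats::median(abs(d$uz_um[core] - 2 * dz)), 0.05 * dz)

  # half-voxel shift via linear interpolation
  zi <- seq_len(nz)
  m <- matrix(pre$intensity, nz)
  m05 <- apply(m, 2, function(col) stats::approx(zi, col, xout = zi - 0.5,
                                                 rule = 2)$y)
  post05 <- oct_volume(array(m05, dim(pre$intensity)), dz, 60, 60,
                       role = "ex_vivo_tile")
  d05 <- estimate_displacement(pre, post05, window_um = 50)
  expect_lt(stats::median(abs(d05$uz_um[core] - 0.5 * dz)), 0.1 * dz)

  # identical states: zero displacement
  d0 <- estimate_displacement(pre, pre, window_um = 50)
  expect_lt(max(abs(d0$uz_um[core])), 1e-6)

  expect_error(estimate_displacement(pre, post, window_um = 10 * nz * dz),
               "window")
})

test_that("displacement is invariant to global intensity rescaling", {
  pre <- bandlimited_volume(nz = 150, seed = 2)
  nz <- dim(pre)[1]
  post_arr <- pre$intensity
  post_arr[2:nz, , ] <- pre$intensity[1:(nz - 1), , ]
  post <- oct_volume(post_arr, pre$spacing_z_um, 60, 60, role = "ex_vivo_tile")
  d1 <- estimate_displacement(pre, post, 50)
  pre2 <- oct_volume(pre$intensity * 37.5, pre$spacing_z_um, 60, 60,
                     role = "ex_vivo_tile")
  post2 <- oct_volume(post$intensity * 37.5, pre$spacing_z_um, 60, 60,
                      role = "ex_vivo_tile")
  d2 <- estimate_displacement(pre2, post2, 50)
  # invariant up to floating-point ties in the integer peak selection
  expect_gt(mean(abs(d1$uz_um - d2$uz_um) < 1e-6), 0.995)
  expect_lt(stats::median(abs(d1$uz_um - d2$uz_um)), 1e-9)
})

make_disp <- function(uz_fun, nz = 100, dz = 5, ny = 4, nx = 4, conf = 1) {
  z <- (seq_len(nz) - 1) * dz
  uz <- array(rep(uz_fun(z), ny * nx), c(nz, ny, nx))
  structure(list(uz_um = uz,
                 confidence = array(conf, c(nz, ny, nx)),
                 spacing_z_um = dz, spacing_y_um = 60, spacing_x_um = 60),
            class = "displacement_volume")
}

test_that("strain is the local slope of displacement versus depth", {
  # exact linear case
  d <- make_disp(function(z) 0.01 * z)
  s <- compute_strain(d, fit_window_um = 100)
  expect_equal(s[20:80, 2, 2], rep(0.01, 61), tolerance = 1e-9)

  # constant displacement: zero strain
  s0 <- compute_strain(make_disp(function(z) 7), 100)
  expect_lt(max(abs(s0)), 1e-12)

  # piecewise slopes 0.01 / 0.02 transition within one window of the break
  nz <- 100; dz <- 5; brk <- 250
  d2 <- make_disp(function(z) ifelse(z < brk, 0.01 * z,
                                     0.01 * brk + 0.02 * (z - brk)))
  s2 <- compute_strain(d2, fit_window_um = 100)
  prof <- s2[, 2, 2]
  zc <- (seq_len(nz) - 1) * dz
  expect_equal(prof[zc < brk - 60][15], 0.01, tolerance = 1e-6)
  expect_equal(prof[zc > brk + 60][10], 0.02, tolerance = 1e-6)
  trans <- which(prof > 0.011 & prof < 0.019)
  expect_lte(diff(range(zc[trans])), 110)

  # zero confidence voids the estimate
  dz3 <- make_disp(function(z) 0.01 * z, conf = 0)
  expect_true(all(is.na(compute_strain(dz3, 100))))

  expect_error(compute_strain(make_disp(function(z) z, dz = 100), 100),
               "3 axial voxels")
})

test_that("layer stress interpolates the characterized curve", {
  lin <- stress_strain_curve(c(0, 0.2), c(0, 10))   # sigma = 50 * eps
  expect_equal(layer_stress(matrix(0.10, 2, 2), lin)[1, 1], 5)
  expect_equal(layer_stress(matrix(0, 2, 2), lin)[1, 1], 0)

  # three-point curve against hand-computed piecewise interpolation
  cv <- stress_strain_curve(c(0, 0.1, 0.3), c(0, 1, 5))
  # eps = 0.2: between knots 2 and 3 -> 1 + (0.2 - 0.1)/(0.3 - 0.1) * 4 = 3
  expect_equal(layer_stress(matrix(0.2, 1, 1), cv)[1, 1], 3)
  expect_equal(layer_stress(matrix(0.05, 1, 1), cv)[1, 1], 0.5)

  expect_error(layer_stress(matrix(0.5, 1, 1), cv), "range")
  ex <- layer_stress(matrix(c(0.5, 0.2), 1, 2), cv, extrapolate = TRUE)
  expect_equal(ex[1, 1], 5 + (0.5 - 0.3) * 20)      # end-segment slope
  expect_identical(attr(ex, "extrapolated")[1, ], c(TRUE, FALSE))
})

test_that("elasticity is stress over strain with a noise-floor mask", {
  strain <- array(0.1, c(5, 3, 3))
  E <- elasticity(matrix(1, 3, 3), strain)
  expect_true(all(E$E_kPa == 10))
  expect_true(all(E$valid))

  strain[2, , ] <- 0
  strain[3, 1, 1] <- NA
  E2 <- elasticity(matrix(1, 3, 3), strain, strain_floor = 1e-4)
  expect_false(any(E2$valid[2, , ]))
  expect_false(E2$valid[3, 1, 1])
  expect_true(all(is.na(E2$E_kPa[2, , ])))

  # chain conservation: E * strain returns the broadcast stress wherever valid
  set.seed(4)
  sig <- matrix(stats::rexp(9) + 0.5, 3, 3)
  eps <- array(stats::runif(45, 0.01, 0.2), c(5, 3, 3))
  E3 <- elasticity(sig, eps)
  sig3 <- aperm(array(sig, c(3, 3, 5)), c(3, 1, 2))
  expect_equal(E3$E_kPa * eps, sig3, tolerance = 1e-9)
})

test_that("masking removes adipose artifacts and non-contact regions", {
  ph <- mosaic_phantom(seed = 6, adipose = 0.5, duct_fraction = 0)
  curve <- stress_strain_curve(c(0, 0.3), c(0, 3))
  pair <- simulate_compression_pair(ph$volume, ph$truth, curve,
                                    layer_thickness_um = 300,
                                    actuation_um = 15)
  tissue_z <- (pair$layer_px + 1):dim(pair$pre)[1]
  nzt <- length(tissue_z)
  oct_t <- oct_volume(pair$pre$intensity[tissue_z, , , drop = FALSE],
                      ph$volume$spacing_z_um, 60, 60, role = "wide_field")
  E <- elasticity(matrix(1, dim(oct_t)[2], dim(oct_t)[3]),
                  array(0.01, dim(oct_t$intensity)))
  masked <- mask_invalid(E, oct_t)
  cls <- ph$truth$tissue_class
  vm <- matrix(masked$valid, nzt)
  expect_gte(mean(!vm[, cls == 2L]), 0.9)   # adipose removed
  expect_lte(mean(!vm[, cls == 1L]), 0.05)  # dense kept

  # zero layer strain marks non-contact columns entirely
  ls <- matrix(0.02, dim(oct_t)[2], dim(oct_t)[3])
  ls[10:20, 10:20] <- 0
  m2 <- mask_invalid(E, oct_t, layer_strain = ls)
  v2 <- m2$valid
  expect_false(any(v2[, 10:20, 10:20]))
})
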