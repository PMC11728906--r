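test_that("masked NCC agrees with direct correlation over all shifts", {
  set.seed(1)
  f <- matrix(stats::rnorm(7 * 9), 7, 9); f[2, 3] <- NA
  m <- matrix(stats::rnorm(4 * 5), 4, 5); m[1, 1] <- NA
  r <- masked_ncc(f, m, min_overlap_px = 4)
  direct <- function(sy, sx) {
    av <- c(); bv <- c()
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      fi <- i + sy; fj <- j + sx
      if (fi >= 1 && fi <= nrow(f) && fj >= 1 && fj <= ncol(f) &&
          !is.na(m[i, j]) && !is.na(f[fi, fj])) {
        av <- c(av, f[fi, fj]); bv <- c(bv, m[i, j])
      }
    }
    list(n = length(av),
         v = if (length(av) >= 4) suppressWarnings(stats::cor(av, bv))
         else NA_real_)
  }
  for (sy in r$shift_y) for (sx in r$shift_x) {
    d <- direct(sy, sx)
    iy <- which(r$shift_y == sy); ix <- which(r$shift_x == sx)
    expect_equal(r$n[iy, ix], d$n)
    if (d$n >= 4 && !is.na(d$v)) {
      expect_equal(r$ncc[iy, ix], d$v, tolerance = 1e-9)
    }
  }
})

test_that("NCC is invariant to affine intensity rescaling", {
  set.seed(2)
  f <- matrix(stats::rnorm(30 * 30), 30, 30)
  m <- f[6:20, 8:22] + 0
  r1 <- masked_ncc(f, m)
  r2 <- masked_ncc(2.7 * f + 13, m)
  r3 <- masked_ncc(f, 0.4 * m - 2)
  keep <- !is.na(r1$ncc)
  expect_equal(r1$ncc[keep], r2$ncc[keep], tolerance = 1e-7)
  expect_equal(r1$ncc[keep], r3$ncc[keep], tolerance = 1e-7)
})

make_session <- function(n = 9) {
  g <- expand.grid(grid_row = 0:2, grid_col = 0:2)[seq_len(n), ]
  scan_session(data.frame(grid_row = g$grid_row, grid_col = g$grid_col,
                          volume = sprintf("t%d", seq_len(n)), flags = "",
                          stringsAsFactors = FALSE),
               nominal_step_um = 5000,
               anchor_index = which(g$grid_row == 1 & g$grid_col == 1),
               tile_fov_um = 6000)
}

test_that("coarse placement anchors the grid on the suture", {
  session <- make_session()
  # in vivo mark at the tile center: the anchor tile center lands on the
  # ex vivo centroid
  mk_in <- fiducial_mark(c(3000, 3000), 40, 2000, 300, 0.9)
  mk_ex <- fiducial_mark(c(8000, 7000), 40, 2000, 300, 0.9)
  poses <- coarse_place(session, mk_in, mk_ex)
  expect_length(poses, 9)
  anchor <- poses[["t5"]]
  expect_equal(c(anchor$tx_um, anchor$ty_um), c(8000, 7000))
  expect_equal(anchor$theta_deg, 0)
  expect_equal(anchor$dz_um, 0)
  # tile at grid (1, 2) sits one step to the right of the anchor (1, 1)
  right <- poses[[which(session$tiles$grid_row == 1 &
                          session$tiles$grid_col == 2)]]
  expect_equal(c(right$tx_um - anchor$tx_um, right$ty_um - anchor$ty_um),
               c(5000, 0))

  # a 30-degree axis difference rotates the grid offsets
  mk_ex30 <- fiducial_mark(c(8000, 7000), 70, 2000, 300, 0.9)
  p30 <- coarse_place(session, mk_in, mk_ex30)
  th <- 30 * pi / 180
  for (i in seq_len(9)) {
    dg <- c(session$tiles$grid_col[i] - 1, session$tiles$grid_row[i] - 1) * 5000
    expected <- c(8000, 7000) +
      c(cos(th) * dg[1] - sin(th) * dg[2], sin(th) * dg[1] + cos(th) * dg[2])
    expect_equal(c(p30[[i]]$tx_um, p30[[i]]$ty_um), expected,
                 tolerance = 1e-6)
    expect_equal(p30[[i]]$theta_deg, 30)
  }

  expect_error(coarse_place(session, NULL, mk_ex), "anchor")
})

test_that("identity registration recovers an exact crop almost perfectly", {
  ph <- mosaic_phantom()
  tile <- extract_tile(ph$volume, rigid_pose2d(6000, 6000, 0), 6000)
  r <- refine_tile(tile, ph$volume, init = rigid_pose2d(5800, 6300, 0),
                   search = list(trans_um = 1000, theta_deg = 2,
                                 theta_step_deg = 0.5, dz_um = 0))
  expect_gte(r$score, 0.99)
  expect_lte(abs(r$pose$tx_um - 6000), 60)
  expect_lte(abs(r$pose$ty_um - 6000), 60)
  expect_lte(abs(r$pose$theta_deg), 0.5)
})

test_that("a tile of pure speckle scores below the success threshold", {
  set.seed(8)
  arr <- array(1e-4, c(60, 100, 100))
  arr[31:60, , ] <- stats::rexp(30 * 100 * 100)
  noise_tile <- oct_volume(arr, 20, 60, 60, role = "in_vivo_tile")
  ph <- mosaic_phantom()
  r <- refine_tile(noise_tile, ph$volume, init = rigid_pose2d(6000, 6000, 0),
                   search = list(trans_um = 800, theta_deg = 0, dz_um = 0))
  expect_lt(r$score, 0.3)
})

test_that("the 90 percent rule labels planes by dominant tissue type", {
  mk_map <- function(frac_dense) {
    m <- matrix(2L, 100, 100)
    m[seq_len(round(frac_dense * 100)), ] <- 1L
    m
  }
  expect_equal(classify_tissue(NULL, class_map = mk_map(0.95))$label, "dense")
  expect_equal(classify_tissue(NULL, class_map = mk_map(0.05))$label, "adipose")
  expect_equal(classify_tissue(NULL, class_map = mk_map(0.60))$label, "mixed")

  # intensity rule on phantom planes
  ph <- mosaic_phantom()
  surf <- detect_surface(ph$volume)
  pl <- extract_enface(ph$volume, surf, 100)
  cl <- classify_tissue(pl)
  expect_equal(cl$label, "mixed")
  expect_lt(abs(cl$adipose_fraction - 0.3), 0.12)
})

test_that("success needs both a high score and grid consistency", {
  expect_true(assess_success(0.95, 200))
  expect_false(assess_success(-1, 100))
  expect_false(assess_success(0.5, 4000))
  expect_true(assess_success(0.5, NA))    # no placed neighbor: score decides
  expect_false(assess_success(0.29, 100))

  # a decoy placement far from its grid-implied position is rejected by the
  # consistency gate even with a plausible score
  session <- scan_session(
    data.frame(grid_row = c(0, 0), grid_col = c(0, 1),
               volume = c("t1", "t2"), flags = "", stringsAsFactors = FALSE),
    nominal_step_um = 5000, anchor_index = 1, tile_fov_um = 6000)
  poses <- list(t1 = rigid_pose2d(10000, 10000, 0),
                t2 = rigid_pose2d(19000, 10000, 0))  # expected at 15000
  cons <- grid_consistency(poses, session)
  expect_equal(unname(cons["t2"]), 4000)
  expect_false(assess_success(0.5, cons["t2"]))
  # and a placement matching the grid passes
  poses$t2 <- rigid_pose2d(15100, 10050, 0)
  cons2 <- grid_consistency(poses, session)
  expect_true(assess_success(0.5, cons2["t2"]))
})

test_that("the summary table reproduces per-class rates and conserves counts", {
  # worked example from the clinical co-registration accounting
  s <- coregistration_summary(c(dense = 11, adipose = 31, mixed = 97),
                              c(dense = 10, adipose = 15, mixed = 84))
  expect_equal(s$success_pct, c(91, 48, 87, 78))
  expect_equal(s$pct_of_total, c(8, 22, 70, 100))
  expect_equal(s$n_scanned[4], 139)
  expect_equal(s$n_coregistered[4], 109)

  one <- summarize_placements(list(list(tissue_class = "dense",
                                        success = TRUE)))
  expect_equal(one$success_pct[c(1, 4)], c(100, 100))
  expect_equal(one$n_scanned[4], 1)

  fails <- summarize_placements(list(
    list(tissue_class = "dense", success = FALSE),
    list(tissue_class = "mixed", success = FALSE)))
  expect_true(all(fails$success_pct == 0))

  # conservation under random counts
  set.seed(11)
  for (i in 1:10) {
    sc <- stats::setNames(sample(0:40, 3, TRUE), c("dense", "adipose", "mixed"))
    co <- pmin(sc, sample(0:40, 3, TRUE))
    names(co) <- names(sc)
    if (sum(sc) == 0) next
    tb <- coregistration_summary(sc, co)
    expect_equal(sum(tb$n_scanned[1:3]), tb$n_scanned[4])
    expect_equal(sum(tb$n_coregistered[1:3]), tb$n_coregistered[4])
  }

  expect_error(coregistration_summary(c(dense = 1, adipose = 0, mixed = 0),
                                      c(dense = 2, adipose = 0, mixed = 0)),
               "exceed")
})
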