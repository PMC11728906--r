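test_that("integer volumes round-trip bit-exactly with full metadata", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  set.seed(1)
  arr <- array(as.numeric(sample(0:65535, 8 * 8 * 8, TRUE)), c(8, 8, 8))
  vol <- oct_volume(arr, 3.4, 12.7, 12.7, role = "in_vivo_tile",
                    tile_id = "t1", origin_um = c(120, 240))
  p <- file.path(dir, "v.tif")
  write_volume(vol, p)
  v2 <- read_volume(p)
  expect_identical(v2$intensity, arr)
  expect_identical(v2$role, "in_vivo_tile")
  expect_identical(v2$tile_id, "t1")
  expect_equal(v2$origin_um, c(120, 240))
  expect_equal(c(v2$spacing_z_um, v2$spacing_y_um, v2$spacing_x_um),
               c(3.4, 12.7, 12.7))

  # an asymmetric shape survives the page layout
  arr2 <- array(as.numeric(sample(0:999, 11 * 7 * 5, TRUE)), c(11, 7, 5))
  p2 <- file.path(dir, "v2.tif")
  write_volume(oct_volume(arr2, 5, 10, 10, role = "wide_field"), p2)
  expect_identical(dim(read_volume(p2)$intensity), c(11L, 7L, 5L))
})

test_that("float volumes round-trip to storage precision", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  set.seed(2)
  arr <- array(stats::rexp(6 * 6 * 6) * 123.4, c(6, 6, 6))
  p <- file.path(dir, "f.tif")
  write_volume(oct_volume(arr, 3.4, 12.7, 12.7), p)
  v2 <- read_volume(p)
  expect_lt(max(abs(v2$intensity - arr)) / max(arr), 1e-6)
})

test_that("invalid volumes and sidecars are rejected", {
  expect_error(oct_volume(array(1, c(0, 4, 4)), 1, 1, 1), "empty")
  expect_error(oct_volume(array(-1, c(2, 2, 2)), 1, 1, 1), "non-negative")
  expect_error(oct_volume(array(1, c(2, 2, 2)), 0, 1, 1), "positive")
  expect_error(oct_volume(matrix(1, 2, 2), 1, 1, 1), "3-D")

  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  p <- file.path(dir, "v.tif")
  write_volume(oct_volume(array(1, c(2, 2, 2)), 1, 1, 1), p)
  # zero spacing in the sidecar fails validation on read
  meta <- jsonlite::read_json(file.path(dir, "v.json"), simplifyVector = TRUE)
  meta$spacing_z_um <- 0
  jsonlite::write_json(meta, file.path(dir, "v.json"), auto_unbox = TRUE)
  expect_error(read_volume(p), "positive")
  # missing sidecar is a metadata error
  file.remove(file.path(dir, "v.json"))
  expect_error(read_volume(p), "sidecar")
})

test_that("session logs validate grid structure, flags and anchor", {
  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  log9 <- file.path(dir, "s9.csv")
  g <- expand.grid(grid_row = 0:2, grid_col = 0:2)
  df <- data.frame(grid_row = g$grid_row, grid_col = g$grid_col,
                   volume = sprintf("t%d.tif", 1:9), flags = "",
                   is_anchor = c(rep(FALSE, 4), TRUE, rep(FALSE, 4)))
  write.csv(df, log9, row.names = FALSE)
  s <- read_session_log(log9)
  expect_s3_class(s, "scan_session")
  expect_equal(nrow(s$tiles), 9)
  expect_equal(s$anchor_index, 5L)

  # a 7-tile partial grid is representable (two scans unusable)
  df7 <- df[-c(1, 9), ]
  write.csv(df7, file.path(dir, "s7.csv"), row.names = FALSE)
  expect_equal(nrow(read_session_log(file.path(dir, "s7.csv"))$tiles), 7)

  # duplicate cell
  dfd <- df; dfd$grid_row[2] <- 1; dfd$grid_col[2] <- 1
  write.csv(dfd, file.path(dir, "dup.csv"), row.names = FALSE)
  expect_error(read_session_log(file.path(dir, "dup.csv")), "duplicate")

  # unknown flag and flag parsing
  dff <- df; dff$flags[3] <- "poor_contact;blood"; dff$flags[4] <- "wet"
  write.csv(dff, file.path(dir, "flag.csv"), row.names = FALSE)
  expect_error(read_session_log(file.path(dir, "flag.csv")), "unknown flag")

  # missing anchor
  dfa <- df; dfa$is_anchor <- FALSE
  write.csv(dfa, file.path(dir, "noanchor.csv"), row.names = FALSE)
  expect_error(read_session_log(file.path(dir, "noanchor.csv")), "anchor")

  # step must leave overlap
  expect_error(read_session_log(log9, nominal_step_um = 6000,
                                tile_fov_um = 6000), "overlap")
})

test_that("stress-strain curves enforce monotone characterization", {
  c1 <- stress_strain_curve(c(0, 0.1, 0.2), c(0, 2, 5))
  expect_s3_class(c1, "stress_strain_curve")
  expect_error(stress_strain_curve(c(0.01, 0.1), c(1, 2)), "anchored")
  expect_error(stress_strain_curve(c(0, 0.2, 0.1), c(0, 1, 2)), "increasing")
  expect_error(stress_strain_curve(c(0, 0.1, 0.2), c(0, 2, 2)), "increasing")

  dir <- tempfile(); dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE))
  write.csv(data.frame(strain = c(0, 0.1), stress_kPa = c(0, 1.5)),
            file.path(dir, "c.csv"), row.names = FALSE)
  c2 <- read_stress_strain(file.path(dir, "c.csv"))
  expect_equal(c2$stress_points_kPa, c(0, 1.5))
})

test_that("decibel conversion follows the display convention and inverts", {
  x <- array(c(1, 100, 10), c(3, 1, 1))
  db <- to_decibels(x)
  expect_equal(as.vector(db), c(0, 20, 10))
  # invertible above the floor
  expect_equal(10^(db / 10), x, ignore_attr = TRUE)
  # zeros are clamped, not -Inf
  y <- to_decibels(c(0, 1, 100))
  expect_true(all(is.finite(y)))
})
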