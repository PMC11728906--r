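# End-to-end orchestration: phantom -> stitch -> mosaic -> histology map ->
# QME -> report, with seeded reproducibility and a machine-readable summary.
# The default configuration runs entirely on a synthetic phantom at desk
# scale; supplying a wide-field TIFF and session log instead runs the mosaic
# stage on external data.

#' Default pipeline configuration
#'
#' Returns the full nested configuration with defaults; supplied values are
#' merged over them and unknown keys rejected. The phantom geometry defaults
#' here are desk-scale (20 x 20 x 1.5 mm at 60 um lateral / 20 um axial
#' sampling) so a full run completes in minutes; module parameter defaults
#' match their function signatures.
#'
#' @param ... named overrides, nested lists merged recursively
#'   (e.g. `phantom = list(adipose_fraction = 0.5)`).
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    input = list(widefield_tiff = NULL, session_csv = NULL),
    phantom = list(enabled = TRUE,
                   extent_um = c(20000, 20000, 1500),
                   spacing_lateral_um = 60, spacing_axial_um = 20,
                   adipose_fraction = 0.35),
    session = list(nominal_step_um = 5000, tile_fov_um = 6000,
                   jitter_um = 250, theta_jitter_deg = 2,
                   noise_snr_db = 15, blur_sigma_um = 80,
                   respeckle_contrast = 0.9),
    mosaic = list(search = list(trans_um = 1500, theta_deg = 5,
                                theta_step_deg = 0.5, dz_um = 40,
                                dz_step_voxels = 2),
                  depth_offset_um = 100, score_threshold = 0.3,
                  consistency_threshold_um = 1500),
    histology = list(enabled = TRUE, section_spacing_um = 4500,
                     shrink = 1.18, warp_amplitude_um = 60,
                     search_halfwidth_um = 1000),
    qme = list(enabled = TRUE, extent_um = c(4000, 4000, 1500),
               spacing_axial_um = 5, layer_thickness_um = 300,
               layer_modulus_kpa = 10, target_strain = 0.015,
               window_um = 60, fit_window_um = 150))
  merge_cfg <- function(base, upd, path = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base))
        stop("unknown configuration key: ", path, nm)
      if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
          !is.null(names(base[[nm]])))
        base[[nm]] <- merge_cfg(base[[nm]], upd[[nm]],
                                paste0(path, nm, "$"))
      else base[[nm]] <- upd[[nm]]
    }
    base
  }
  cfg <- merge_cfg(defaults, list(...))
  if (!isTRUE(cfg$phantom$enabled) && is.null(cfg$input$widefield_tiff))
    stop("configuration invalid: input$widefield_tiff is required when the ",
         "phantom stage is disabled")
  cfg
}

#' Read a pipeline configuration from YAML
#' @param path YAML file whose keys mirror [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# draw a rotated rectangle outline into an image matrix (QC overlay)
draw_box <- function(img, center_px, half_y, half_x, theta_deg, value) {
  th <- theta_deg * pi / 180
  tseq <- seq(0, 1, length.out = 200)
  edges <- rbind(cbind(-half_x + 2 * half_x * tseq, -half_y),
                 cbind(-half_x + 2 * half_x * tseq, half_y),
                 cbind(-half_x, -half_y + 2 * half_y * tseq),
                 cbind(half_x, -half_y + 2 * half_y * tseq))
  xr <- round(center_px[2] + cos(th) * edges[, 1] - sin(th) * edges[, 2])
  yr <- round(center_px[1] + sin(th) * edges[, 1] + cos(th) * edges[, 2])
  ok <- xr >= 1 & xr <= ncol(img) & yr >= 1 & yr <= nrow(img)
  img[cbind(yr[ok], xr[ok])] <- value
  img
}

#' Run the co-registration pipeline
#'
#' Stages: phantom generation (or external input), wide-field re-tile and
#' stitch check, suture-anchored mosaic of the 3 x 3 in vivo grid, histology
#' grid / shrinkage / B-scan matching, QME on a fine-axially-sampled
#' compression pair, and report emission. Deterministic for a fixed seed;
#' every stage's parameters are logged into the summary.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created); receives `placements.json`,
#'   `summary.csv` (per-tissue-type counts and rates), `histology.csv`, `elasticity.tif`,
#'   `composite.png` (when the png package is available) and `summary.json`.
#' @param seed overrides `config$seed`.
#' @return invisible list with all stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("coreg_"),
                         seed = NULL) {
  cfg <- config
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)
  report <- list(parameters = cfg)

  external <- !isTRUE(cfg$phantom$enabled)
  if (external) {
    log_stage("input: reading wide-field volume and session log")
    wf <- read_volume(cfg$input$widefield_tiff)
    session <- read_session_log(cfg$input$session_csv,
                                nominal_step_um = cfg$session$nominal_step_um,
                                tile_fov_um = cfg$session$tile_fov_um)
    base <- dirname(cfg$input$session_csv)
    tiles <- lapply(as.character(session$tiles$volume), function(p)
      read_volume(if (file.exists(p)) p else file.path(base, p)))
    names(tiles) <- as.character(session$tiles$volume)
    truth <- NULL
  } else {
    log_stage("phantom: generating wide-field shaving")
    spec <- phantom_spec(extent_um = cfg$phantom$extent_um,
                         spacing_lateral_um = cfg$phantom$spacing_lateral_um,
                         spacing_axial_um = cfg$phantom$spacing_axial_um,
                         adipose_fraction = cfg$phantom$adipose_fraction,
                         seed = cfg$seed)
    ph <- generate_shaving_phantom(spec)
    wf <- ph$volume; truth <- ph$truth

    log_stage("stitch: re-tiling the wide-field volume and stitching back")
    ext_xy <- dim(wf)[3] * wf$spacing_x_um
    plan <- plan_tiles(ext_xy, tile_fov_um = ext_xy * 0.6,
                       step_um = ext_xy * 0.4)
    crops <- lapply(seq_len(nrow(plan$positions_um)), function(i) {
      p <- plan$positions_um[i, ]
      x0 <- round(p$x / wf$spacing_x_um); y0 <- round(p$y / wf$spacing_y_um)
      nx <- min(round(plan$tile_fov_um / wf$spacing_x_um), dim(wf)[3] - x0)
      ny <- min(round(plan$tile_fov_um / wf$spacing_y_um), dim(wf)[2] - y0)
      oct_volume(wf$intensity[, y0 + seq_len(ny), x0 + seq_len(nx)],
                 wf$spacing_z_um, wf$spacing_y_um, wf$spacing_x_um,
                 role = "ex_vivo_tile",
                 origin_um = c(x0 * wf$spacing_x_um, y0 * wf$spacing_y_um))
    })
    stitched <- stitch_tiles(crops)
    report$stitch <- list(n_tiles = length(crops),
                          max_abs_error = max(abs(stitched$intensity -
                                                    wf$intensity)))

    log_stage("session: extracting 3 x 3 in vivo tiles")
    set.seed(cfg$seed + 101L)
    ctr <- cfg$phantom$extent_um[1:2] / 2
    step <- cfg$session$nominal_step_um
    grid <- expand.grid(grid_col = 0:2, grid_row = 0:2)
    tiles <- list(); true_poses <- list()
    sig_ref <- stats::sd(wf$intensity)
    noise_sd <- sig_ref / 10^(cfg$session$noise_snr_db / 20)
    for (i in seq_len(nrow(grid))) {
      nm <- sprintf("tile_r%d_c%d", grid$grid_row[i], grid$grid_col[i])
      pose <- rigid_pose2d(
        ctr[1] + (grid$grid_col[i] - 1) * step + stats::runif(1, -1, 1) *
          cfg$session$jitter_um,
        ctr[2] + (grid$grid_row[i] - 1) * step + stats::runif(1, -1, 1) *
          cfg$session$jitter_um,
        theta_deg = stats::runif(1, -1, 1) * cfg$session$theta_jitter_deg)
      tiles[[nm]] <- extract_tile(wf, pose,
                                  tile_fov_um = cfg$session$tile_fov_um,
                                  degrade = list(noise_sigma = noise_sd,
                                                 blur_sigma_um =
                                                   cfg$session$blur_sigma_um,
                                                 respeckle_contrast =
                                                   cfg$session$respeckle_contrast),
                                  tile_id = nm)
      true_poses[[nm]] <- pose
    }
    session <- scan_session(
      data.frame(grid_row = grid$grid_row, grid_col = grid$grid_col,
                 volume = names(tiles), flags = "",
                 stringsAsFactors = FALSE),
      nominal_step_um = step, anchor_index = which(grid$grid_row == 1 &
                                                     grid$grid_col == 1),
      tile_fov_um = cfg$session$tile_fov_um)
  }

  log_stage("mosaic: suture anchoring and tile refinement")
  mos <- build_mosaic(session, tiles, wf,
                      search = cfg$mosaic$search,
                      depth_offset_um = cfg$mosaic$depth_offset_um,
                      score_threshold = cfg$mosaic$score_threshold,
                      consistency_threshold_um =
                        cfg$mosaic$consistency_threshold_um)
  report$mosaic <- list(
    summary = mos$summary,
    placements = lapply(mos$placements, function(p)
      list(tile_id = p$tile_id, tx_um = p$pose$tx_um, ty_um = p$pose$ty_um,
           theta_deg = p$pose$theta_deg, dz_um = p$pose$dz_um,
           score = p$score, tissue_class = p$tissue_class,
           overlap_consistency_um = p$overlap_consistency_um,
           success = p$success, flags = p$flags)))
  if (!external) {
    errs <- vapply(names(true_poses), function(nm) {
      sqrt((mos$placements[[nm]]$pose$tx_um - true_poses[[nm]]$tx_um)^2 +
             (mos$placements[[nm]]$pose$ty_um - true_poses[[nm]]$ty_um)^2)
    }, 0)
    report$mosaic$mean_pose_error_um <- mean(errs)
  }

  if (!external && isTRUE(cfg$histology$enabled)) {
    log_stage("histology: sections, shrinkage factors, B-scan matching")
    secs <- generate_histology_sections(
      wf, truth, section_spacing_um = cfg$histology$section_spacing_um,
      shrink_factors = cfg$histology$shrink,
      warp_amplitude_um = cfg$histology$warp_amplitude_um)
    grid_h <- overlay_grid(mos$wf_plane, cfg$histology$section_spacing_um)
    hist_rows <- lapply(seq_along(secs), function(k) {
      s <- secs[[k]]
      line <- grid_h$line_positions_um[min(k, length(grid_h$line_positions_um))]
      m <- match_bscan(s, wf, line,
                       search_halfwidth_um = cfg$histology$search_halfwidth_um)
      data.frame(section_index = s$section_index,
                 fresh_width_um = s$fresh_width_um,
                 section_width_um = s$section_width_um,
                 c = s$correction_factor, line_y_um = line,
                 matched_b_index = m$index, dice = m$score)
    })
    report$histology <- do.call(rbind, hist_rows)
  }

  if (!external && isTRUE(cfg$qme$enabled)) {
    log_stage("qme: compression pair and elasticity inversion")
    qspec <- phantom_spec(extent_um = cfg$qme$extent_um,
                          spacing_lateral_um = cfg$phantom$spacing_lateral_um,
                          spacing_axial_um = cfg$qme$spacing_axial_um,
                          adipose_fraction = cfg$phantom$adipose_fraction,
                          suture = list(present = FALSE),
                          seed = cfg$seed + 202L)
    qph <- generate_shaving_phantom(qspec)
    curve <- stress_strain_curve(c(0, 0.25),
                                 c(0, 0.25 * cfg$qme$layer_modulus_kpa))
    L <- cfg$qme$layer_thickness_um
    ts_um <- dim(qph$volume)[1] * cfg$qme$spacing_axial_um - L
    sig_t <- cfg$qme$target_strain * stats::median(qph$truth$elasticity_kpa)
    act <- L * sig_t / cfg$qme$layer_modulus_kpa +
      cfg$qme$target_strain * ts_um
    pair <- simulate_compression_pair(qph$volume, qph$truth, curve,
                                      layer_thickness_um = L,
                                      actuation_um = act)
    q <- qme_pipeline(pair$pre, pair$post, curve, layer_thickness_um = L,
                      window_um = cfg$qme$window_um,
                      fit_window_um = cfg$qme$fit_window_um)
    Ev <- q$elasticity
    dense_sel <- as.vector(qph$truth$tissue_class == 1L)
    Em <- matrix(Ev$E_kPa, dim(Ev$E_kPa)[1])[, dense_sel]
    Vm <- matrix(Ev$valid, dim(Ev$valid)[1])[, dense_sel]
    med_dense <- stats::median(Em[Vm], na.rm = TRUE)
    report$qme <- list(actuation_um = act,
                       median_dense_kpa = med_dense,
                       valid_fraction = mean(Ev$valid),
                       true_dense_kpa = 15)
    write_volume(oct_volume(ifelse(is.na(Ev$E_kPa), 0, Ev$E_kPa),
                            cfg$qme$spacing_axial_um,
                            qph$volume$spacing_y_um, qph$volume$spacing_x_um,
                            role = "wide_field", tile_id = "elasticity_kpa"),
                 file.path(out_dir, "elasticity.tif"))
  }

  log_stage("report: writing artifacts")
  jsonlite::write_json(report$mosaic$placements,
                       file.path(out_dir, "placements.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(mos$summary, file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$histology))
    utils::write.csv(report$histology, file.path(out_dir, "histology.csv"),
                     row.names = FALSE)
  if (requireNamespace("png", quietly = TRUE)) {
    img <- mos$wf_plane$image
    db <- to_decibels(img); db[is.na(img)] <- min(db, na.rm = TRUE)
    rng <- range(db, na.rm = TRUE)
    comp <- (db - rng[1]) / max(rng[2] - rng[1], 1e-9)
    for (p in mos$placements) {
      comp <- draw_box(comp,
                       c(p$pose$ty_um / mos$wf_plane$spacing_y_um + 1,
                         p$pose$tx_um / mos$wf_plane$spacing_x_um + 1),
                       half_y = session$tile_fov_um / 2 /
                         mos$wf_plane$spacing_y_um,
                       half_x = session$tile_fov_um / 2 /
                         mos$wf_plane$spacing_x_um,
                       theta_deg = p$pose$theta_deg,
                       value = if (p$success) 1 else 0.5)
    }
    png::writePNG(comp, file.path(out_dir, "composite.png"))
  }
  report$summary_table <- mos$summary
  jsonlite::write_json(
    list(seed = cfg$seed, parameters = cfg, stitch = report$stitch,
         mosaic = list(summary = mos$summary,
                       placements = report$mosaic$placements,
                       mean_pose_error_um = report$mosaic$mean_pose_error_um),
         histology = report$histology, qme = report$qme),
    file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows",
    null = "null", na = "null")
  log_stage("done")
  invisible(c(report, list(out_dir = out_dir, session = session,
                           placements = mos$placements)))
}
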