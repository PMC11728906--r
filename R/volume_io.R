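# Data model and on-disk formats for OCT volumes, scan-session logs and layer
# stress-strain characterizations.
#
# Conventions: volumes are arrays indexed [z, y, x] with z increasing into the
# tissue; a B-scan is the (z, x) slice at fixed y and an en face plane the
# (y, x) slice at fixed (surface-relative) depth. All physical metadata is in
# micrometers. Intensities are stored linear and non-negative; decibels are a
# display/registration convention only (see to_decibels).

#' Construct an OCT volume
#'
#' The universal carrier for in vivo tiles, ex vivo tiles and the stitched
#' wide-field volume: a 3-D grid of linear backscatter intensities plus
#' physical voxel spacings and acquisition metadata.
#'
#' @param intensity 3-D numeric array indexed `[z, y, x]`, non-negative.
#' @param spacing_z_um,spacing_y_um,spacing_x_um positive voxel spacings (um).
#' @param role acquisition role, one of `"in_vivo_tile"`, `"ex_vivo_tile"`,
#'   `"wide_field"`.
#' @param tile_id optional identifier string.
#' @param origin_um physical (x, y) of voxel `[ , 1, 1]` in the parent frame
#'   (c(0, 0) for standalone volumes); used by [stitch_tiles()].
#' @return an object of class `oct_volume`.
#' @export
oct_volume <- function(intensity, spacing_z_um, spacing_y_um, spacing_x_um,
                       role = c("wide_field", "in_vivo_tile", "ex_vivo_tile"),
                       tile_id = NULL, origin_um = c(0, 0)) {
  role <- match.arg(role)
  if (!is.array(intensity) || length(dim(intensity)) != 3L)
    stop("intensity must be a 3-D array [z, y, x]")
  if (any(dim(intensity) == 0L))
    stop("empty volume: every dimension must be positive")
  if (anyNA(intensity) || any(intensity < 0))
    stop("intensities must be finite and non-negative")
  sp <- c(spacing_z_um, spacing_y_um, spacing_x_um)
  if (length(sp) != 3L || anyNA(sp) || any(sp <= 0))
    stop("voxel spacings must be positive")
  if (length(origin_um) != 2L || anyNA(origin_um))
    stop("origin_um must be numeric (x, y)")
  structure(list(
    intensity = intensity,
    spacing_z_um = as.numeric(spacing_z_um),
    spacing_y_um = as.numeric(spacing_y_um),
    spacing_x_um = as.numeric(spacing_x_um),
    role = role,
    tile_id = if (is.null(tile_id)) NULL else as.character(tile_id),
    origin_um = as.numeric(origin_um)
  ), class = "oct_volume")
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensity)
  cat(sprintf("<oct_volume> role=%s%s  %d x %d x %d voxels [z,y,x]\n",
              x$role,
              if (!is.null(x$tile_id)) paste0(" id=", x$tile_id) else "",
              d[1], d[2], d[3]))
  cat(sprintf("  spacing (z,y,x) um: %.3g, %.3g, %.3g;  extent %.3g x %.3g x %.3g mm\n",
              x$spacing_z_um, x$spacing_y_um, x$spacing_x_um,
              d[1] * x$spacing_z_um / 1000, d[2] * x$spacing_y_um / 1000,
              d[3] * x$spacing_x_um / 1000))
  invisible(x)
}

#' @export
dim.oct_volume <- function(x) dim(x$intensity)

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".json")

#' Write an OCT volume to a multi-page TIFF with JSON sidecar
#'
#' Pages are z-slices in ascending depth order. Integer-valued data up to
#' 65535 are stored as 16-bit pages (lossless round-trip); other data as
#' 32-bit float pages normalized by a max-intensity scale recorded in the
#' sidecar (round-trip to single precision). The sidecar (same stem, `.json`)
#' carries all metadata fields.
#'
#' @param vol an [oct_volume()].
#' @param path output TIFF path; the sidecar is written next to it.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "oct_volume"))
  d <- dim(vol$intensity)
  mx <- max(vol$intensity)
  is_int <- mx <= 65535 && all(vol$intensity == round(vol$intensity))
  pages <- lapply(seq_len(d[1]), function(z) vol$intensity[z, , ])
  if (is_int) {
    dtype <- "uint16"; scale <- 65535
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    dtype <- "float32"; scale <- if (mx > 0) mx else 1
    pages <- lapply(pages, function(p) p / scale)
    suppressWarnings(tiff::writeTIFF(pages, path, bits.per.sample = 32L))
  }
  meta <- list(
    spacing_z_um = vol$spacing_z_um, spacing_y_um = vol$spacing_y_um,
    spacing_x_um = vol$spacing_x_um, role = vol$role,
    tile_id = vol$tile_id, origin_um = vol$origin_um,
    shape_zyx = d, dtype = dtype, intensity_scale = scale)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read an OCT volume written by [write_volume()]
#'
#' @param path TIFF path with a JSON sidecar of identical stem.
#' @return an [oct_volume()].
#' @export
read_volume <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("metadata error: missing JSON sidecar ", sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  req <- c("spacing_z_um", "spacing_y_um", "spacing_x_um", "role", "dtype",
           "intensity_scale")
  if (!all(req %in% names(meta)))
    stop("metadata error: sidecar missing fields: ",
         paste(setdiff(req, names(meta)), collapse = ", "))
  as_is <- identical(meta$dtype, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = as_is)
  if (!is.list(pages)) pages <- list(pages)
  shp <- vapply(pages, dim, integer(2))
  if (any(shp[1, ] != shp[1, 1]) || any(shp[2, ] != shp[2, 1]))
    stop("format error: TIFF pages have inconsistent shapes")
  nz <- length(pages)
  arr <- array(0, c(nz, shp[1, 1], shp[2, 1]))
  for (z in seq_len(nz)) arr[z, , ] <- pages[[z]]
  if (!as_is) arr <- arr * meta$intensity_scale
  oct_volume(arr, meta$spacing_z_um, meta$spacing_y_um, meta$spacing_x_um,
             role = meta$role, tile_id = meta$tile_id,
             origin_um = unlist(meta$origin_um) %||% c(0, 0))
}

#' Construct a scan session
#'
#' Ordered record of the in vivo acquisition: grid position of each tile in
#' the 3 x 3 protocol, nominal center-to-center pitch, surgeon note flags and
#' which tile contains the cavity suture (the registration anchor).
#'
#' @param tiles data.frame with columns `grid_row`, `grid_col` (integers in
#'   0..2), `volume` (path or id), `flags` (character, `;`-separated subset of
#'   `poor_contact`, `blood`, may be empty).
#' @param nominal_step_um nominal tile pitch; the protocol's ~5 mm probe shift.
#' @param anchor_index 1-based row index of the anchor tile in `tiles`.
#' @param tile_fov_um lateral tile field of view, used to check that the step
#'   leaves a positive overlap.
#' @return object of class `scan_session`.
#' @export
scan_session <- function(tiles, nominal_step_um = 5000, anchor_index,
                         tile_fov_um = 6000) {
  need <- c("grid_row", "grid_col", "volume", "flags")
  if (!is.data.frame(tiles) || !all(need %in% names(tiles)))
    stop("tiles must be a data.frame with columns ",
         paste(need, collapse = ", "))
  if (nrow(tiles) < 1L) stop("session needs at least one tile")
  if (!all(tiles$grid_row %in% 0:2 & tiles$grid_col %in% 0:2))
    stop("grid_row/grid_col must be in 0..2")
  cell <- paste(tiles$grid_row, tiles$grid_col)
  if (anyDuplicated(cell))
    stop("duplicate grid cell: ", cell[duplicated(cell)][1])
  known <- c("poor_contact", "blood")
  fl <- strsplit(ifelse(is.na(tiles$flags), "", tiles$flags), ";", fixed = TRUE)
  bad <- setdiff(trimws(unlist(fl)), c(known, ""))
  if (length(bad)) stop("unknown flag(s): ", paste(bad, collapse = ", "))
  if (length(anchor_index) != 1L || is.na(anchor_index) ||
      anchor_index < 1 || anchor_index > nrow(tiles))
    stop("anchor_index must identify one tile row")
  if (nominal_step_um >= tile_fov_um)
    stop("nominal_step_um must be smaller than the tile field of view ",
         "(tiles must overlap)")
  structure(list(tiles = tiles, nominal_step_um = nominal_step_um,
                 anchor_index = as.integer(anchor_index),
                 tile_fov_um = tile_fov_um),
            class = "scan_session")
}

#' Read a scan-session log
#'
#' CSV columns: `grid_row`, `grid_col`, `volume`, `flags` (semicolon-separated,
#' may be empty), `is_anchor` (exactly one TRUE row). A JSON file with the same
#' fields is also accepted.
#'
#' @param path CSV or JSON log file.
#' @inheritParams scan_session
#' @export
read_session_log <- function(path, nominal_step_um = 5000, tile_fov_um = 6000) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::read_json(path, simplifyVector = TRUE)
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(flags = "character"))
  }
  if (!"is_anchor" %in% names(df)) stop("session log must mark the anchor tile")
  anchor <- which(as.logical(df$is_anchor))
  if (length(anchor) != 1L)
    stop("session log must flag exactly one anchor tile (found ",
         length(anchor), ")")
  scan_session(df[c("grid_row", "grid_col", "volume", "flags")],
               nominal_step_um = nominal_step_um, anchor_index = anchor,
               tile_fov_um = tile_fov_um)
}

#' Construct a layer stress-strain characterization
#'
#' Monotone characterization of the compliant silicone stress layer used for
#' quantitative micro-elastography: local layer strain is converted to local
#' axial stress by interpolating this curve.
#'
#' @param strain_points strictly increasing strains starting at 0.
#' @param stress_points_kPa matching strictly increasing stresses starting at 0.
#' @export
stress_strain_curve <- function(strain_points, stress_points_kPa) {
  s <- as.numeric(strain_points); k <- as.numeric(stress_points_kPa)
  if (length(s) != length(k) || length(s) < 2L)
    stop("curve needs >= 2 matching (strain, stress) points")
  if (s[1] != 0 || k[1] != 0) stop("curve must be anchored at (0, 0)")
  if (any(diff(s) <= 0) || any(diff(k) <= 0))
    stop("curve must be strictly increasing in strain and stress")
  structure(list(strain_points = s, stress_points_kPa = k),
            class = "stress_strain_curve")
}

#' Read a stress-strain curve from CSV (columns `strain`, `stress_kPa`)
#' @param path CSV file.
#' @export
read_stress_strain <- function(path) {
  df <- utils::read.csv(path)
  stress_strain_curve(df$strain, df$stress_kPa)
}

#' Convert linear OCT intensity to decibels
#'
#' `dB = 10 * log10(I / I_ref)` with `I_ref = 1`. Zeros (and any value below
#' the floor) are clamped to `floor_fraction` times the maximum intensity so
#' the log is defined; above the floor the mapping is invertible.
#'
#' @param x an [oct_volume()], or a numeric array/matrix of linear intensities.
#' @param floor_fraction clamp floor as a fraction of the maximum intensity.
#' @return array/matrix of dB values with the same shape.
#' @export
to_decibels <- function(x, floor_fraction = 1e-6) {
  v <- if (inherits(x, "oct_volume")) x$intensity else x
  mx <- max(v, na.rm = TRUE)
  fl <- if (mx > 0) floor_fraction * mx else floor_fraction
  10 * log10(pmax(v, fl))
}
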