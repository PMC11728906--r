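# Shared desk-scale phantoms, generated once per test run and cached.
# Geometry: 12 x 12 x 1.2 mm at 60 um lateral / 20 um axial sampling for the
# mosaic-scale phantom; 9 x 9 x 0.9 mm for histology; 3 x 3 x 1.5 mm with
# 5 um axial sampling for QME (displacement gradients need fine axial
# sampling).

phantom_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (is.null(phantom_cache[[key]])) phantom_cache[[key]] <- build()
  phantom_cache[[key]]
}

mosaic_phantom <- function(seed = 3, adipose = 0.3, ...) {
  cached(paste("mosaic", seed, adipose, sep = "_"), function()
    generate_shaving_phantom(phantom_spec(
      extent_um = c(12000, 12000, 1200), spacing_lateral_um = 60,
      spacing_axial_um = 20, adipose_fraction = adipose, seed = seed, ...)))
}

hist_phantom <- function(seed = 4, adipose = 0.3) {
  cached(paste("hist", seed, adipose, sep = "_"), function()
    generate_shaving_phantom(phantom_spec(
      extent_um = c(9000, 9000, 900), spacing_lateral_um = 60,
      spacing_axial_um = 30, adipose_fraction = adipose, seed = seed)))
}

qme_phantom <- function(seed = 5, adipose = 0, elasticity_kpa = 20) {
  key <- paste("qme", seed, adipose, elasticity_kpa, sep = "_")
  cached(key, function() {
    ph <- generate_shaving_phantom(phantom_spec(
      extent_um = c(3000, 3000, 1500), spacing_lateral_um = 60,
      spacing_axial_um = 5, adipose_fraction = adipose,
      suture = list(present = FALSE), features = list(),
      surface_topography_amplitude_um = 40, seed = seed))
    if (!is.null(elasticity_kpa))
      ph$truth$elasticity_kpa <- matrix(elasticity_kpa,
                                        dim(ph$volume)[2], dim(ph$volume)[3])
    ph
  })
}

# band-limited random volume for displacement-tracking tests
bandlimited_volume <- function(nz = 200, ny = 12, nx = 12, dz = 5, seed = 1) {
  set.seed(seed)
  arr <- array(stats::rexp(nz * ny * nx), c(nz, ny, nx))
  m <- matrix(arr, nz)
  k <- stats::dnorm(-3:3, sd = 1.2); k <- k / sum(k)
  p <- rbind(m[rep(1, 3), ], m, m[rep(nz, 3), ])
  f <- stats::filter(p, k, sides = 2)
  oct_volume(array(f[4:(3 + nz), ], c(nz, ny, nx)) + 0.01, dz, 60, 60,
             role = "ex_vivo_tile")
}

# en face plane wrapper for synthetic images
synthetic_plane <- function(image, spacing_um = 60, depth_offset_um = 100) {
  structure(list(image = image, depth_offset_um = depth_offset_um,
                 source_id = "synthetic", spacing_y_um = spacing_um,
                 spacing_x_um = spacing_um), class = "en_face_plane")
}

# surface map wrapper for synthetic tests
synthetic_surface <- function(depth_index, valid = NULL) {
  if (is.null(valid)) valid <- depth_index > 0
  structure(list(depth_index = depth_index, valid = valid),
            class = "surface_map")
}
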