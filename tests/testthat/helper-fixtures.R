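# Shared fixtures, built once per test run and cached. Everything is
# generated in code; no binary fixtures on disk.

.fx <- new.env(parent = emptyenv())

fx_get <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# digital sphere of radius 30 voxels, isotropic 0.1 um voxels; the odd grid
# centres the sphere on a voxel centre
fx_sphere30 <- function() fx_get("sphere30", function() {
  geom <- generate_geometry(1, c(67, 67, 67), c(0.1, 0.1, 0.1),
                            seed = 7, radii = c(3, 3, 3))
  list(geom = geom, field = distance_field(geom$labels, geom$voxel_size))
})

# coverslip-flattened cell (flat top/bottom via z_clip): every 10% distance
# shell holds ~9-11% of the volume, so 50k uniform molecules resolve each
# bin frequency to ~±0.015 - the geometry for baseline calibration
fx_flat_cell <- function() fx_get("flat_cell", function() {
  geom <- generate_geometry(1, c(46, 288, 288), c(0.05, 0.1, 0.1),
                            seed = 5, radii = c(3, 14, 14), z_clip = 1.0)
  list(geom = geom, field = distance_field(geom$labels, geom$voxel_size))
})

# small single-cell ellipsoid for quick render/detect tests
fx_small_cell <- function() fx_get("small_cell", function() {
  geom <- generate_geometry(1, c(30, 110, 110), c(0.2, 0.1, 0.1),
                            seed = 3, radii = c(2.6, 5, 5))
  list(geom = geom, field = distance_field(geom$labels, geom$voxel_size))
})

# large sparse cell: 200 molecules stay mostly resolvable at 0.6 um separation
fx_sparse_cell <- function() fx_get("sparse_cell", function() {
  geom <- generate_geometry(1, c(52, 376, 376), c(0.2, 0.1, 0.1),
                            seed = 3, radii = c(4.5, 18, 18))
  list(geom = geom, field = distance_field(geom$labels, geom$voxel_size))
})

# four-cell embryo at a mid resolution for profile/pipeline tests
fx_fourcell <- function() fx_get("fourcell", function() {
  geom <- generate_geometry(4, c(44, 288, 288), c(0.3, 0.15, 0.15), seed = 9)
  list(geom = geom, field = distance_field(geom$labels, geom$voxel_size))
})

fx_noise <- list(poisson = TRUE, gaussian_sd = 10)
fx_amp_snr <- function(snr) amplitude_for_snr(snr, 100, fx_noise)

pooled_freqs <- function(profile) {
  p <- profile[profile$cell_id == "pooled", ]
  p$norm_freq[order(p$bin)]
}
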