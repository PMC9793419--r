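# synthetic embryo generator: geometry, placement, rendering

test_that("generate_geometry produces the requested connected cells, deterministically", {
  g1 <- generate_geometry(4, c(40, 128, 128), c(0.2, 0.1, 0.1), seed = 7)
  expect_identical(sort(unique(as.integer(g1$labels[g1$labels > 0]))), 1:4)
  for (k in 1:4) {
    cc <- memfish:::label_components(g1$labels == k, 26L)
    expect_identical(max(cc), 1L)
  }
  # nuclei lie strictly inside their own cell
  idx <- memfish:::um_to_voxel(g1$nuclei_um, g1$voxel_size, dim(g1$labels))
  expect_identical(as.integer(g1$labels[memfish:::voxel_linear(idx, dim(g1$labels))]), 1:4)
  g2 <- generate_geometry(4, c(40, 128, 128), c(0.2, 0.1, 0.1), seed = 7)
  expect_identical(g1$labels, g2$labels)
  g3 <- generate_geometry(4, c(40, 128, 128), c(0.2, 0.1, 0.1), seed = 8)
  expect_false(identical(g1$labels, g3$labels))
})

test_that("a stage-1 geometry with equal radii is a digital sphere of the right volume", {
  fx <- fx_sphere30()
  count <- sum(fx$geom$labels == 1L)
  expect_lt(abs(count - 4 / 3 * pi * 30^3) / (4 / 3 * pi * 30^3), 0.01)
})

test_that("undersized grids are rejected with a sizing error", {
  expect_error(generate_geometry(8, c(8, 8, 8), c(0.2, 0.1, 0.1)), "too small")
  expect_error(generate_geometry(3, c(40, 128, 128), c(0.2, 0.1, 0.1)), "stage")
})

test_that("placement conserves molecule counts in every mode", {
  fx <- fx_small_cell()
  for (model in list(localization_model("uniform"),
                     localization_model("membrane", membrane_fraction = 0.5),
                     localization_model("clustered", n_clusters = 3,
                                        molecules_per_cluster = 10))) {
    gt <- place_spots(fx$geom, model, 120, seed = 5, field = fx$field)
    expect_identical(nrow(gt), 120L)
    expect_true(all(gt$cell_id == 1L))
    # every position lies inside its cell's label
    idx <- memfish:::um_to_voxel(as.matrix(gt[, c("z_um", "y_um", "x_um")]),
                                 fx$geom$voxel_size, dim(fx$geom$labels))
    labs <- fx$geom$labels[memfish:::voxel_linear(idx, dim(fx$geom$labels))]
    expect_true(all(labs == gt$cell_id))
  }
})

test_that("uniform placement matches the analytic sphere shell fraction", {
  fx <- fx_sphere30()
  gt <- place_spots(fx$geom, localization_model("uniform"), 50000, seed = 1,
                    field = fx$field)
  expect_equal(mean(gt$norm_dist < 0.1), 1 - 0.9^3, tolerance = 0.01 / 0.271)
})

test_that("full-membrane placement is strictly confined to the shell", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom,
                    localization_model("membrane", membrane_fraction = 1,
                                       membrane_shell = 0.1),
                    2000, seed = 2, field = fx$field)
  expect_true(all(gt$norm_dist < 0.1))
})

test_that("clustered placement is recovered by brute-force single linkage", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom,
                    localization_model("clustered", n_clusters = 5,
                                       molecules_per_cluster = 20,
                                       cluster_sigma = 0.15),
                    100, seed = 11, field = fx$field)
  expect_identical(nrow(gt), 100L)
  expect_identical(sort(unique(gt$cluster_id)), 1:5)
  # brute-force union-find single linkage at 3 sigma
  pos <- as.matrix(gt[, c("z_um", "y_um", "x_um")])
  n <- nrow(pos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((pos[i, ] - pos[j, ])^2)) <= 3 * 0.15) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  expect_identical(length(unique(roots)), 5L)
  # linkage groups coincide with the planted cluster ids
  expect_true(all(tapply(gt$cluster_id, roots, function(x) length(unique(x))) == 1))
})

test_that("rendering is deterministic and reproduces the discrete kernel sum", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom, localization_model("uniform"), 1, seed = 8,
                    field = fx$field)
  st <- render_stack(fx$geom, gt, spot_amplitude = 150,
                     noise = list(poisson = FALSE, gaussian_sd = 0),
                     background = 0, seed = 1)
  v <- st$channels$smfish
  # peak at the molecule's voxel
  peak <- arrayInd(which.max(v), dim(v)) - 1L
  mol <- memfish:::um_to_voxel(as.matrix(gt[, c("z_um", "y_um", "x_um")]),
                               fx$geom$voxel_size, dim(v))
  expect_true(all(abs(peak - mol) <= 1))
  # summed intensity = amplitude x brute-force discrete kernel sum
  vs <- fx$geom$voxel_size
  ctr <- as.numeric(gt[1, c("z_um", "y_um", "x_um")]) / vs - 0.5
  psf <- st$psf_sigma
  rad <- ceiling(4 * psf / vs)
  ks <- 0
  for (dz in -rad[1]:(rad[1] + 1)) for (dy in -rad[2]:(rad[2] + 1))
    for (dx in -rad[3]:(rad[3] + 1)) {
      iz <- floor(ctr[1]) + dz; iy <- floor(ctr[2]) + dy; ix <- floor(ctr[3]) + dx
      ks <- ks + exp(-0.5 * (((iz - ctr[1]) * vs[1] / psf[1])^2 +
                             ((iy - ctr[2]) * vs[2] / psf[2])^2 +
                             ((ix - ctr[3]) * vs[3] / psf[3])^2))
    }
  expect_equal(sum(v), 150 * ks, tolerance = 1e-3)
  # determinism with noise on
  s1 <- render_stack(fx$geom, gt, seed = 42)
  s2 <- render_stack(fx$geom, gt, seed = 42)
  expect_identical(s1$channels, s2$channels)
  s3 <- render_stack(fx$geom, gt, seed = 43)
  expect_false(identical(s1$channels$smfish, s3$channels$smfish))
})

test_that("self-consistency: uniform truths profile flat through the enrichment module", {
  fx <- fx_flat_cell()
  for (sd in 1:3) {
    gt <- place_spots(fx$geom, localization_model("uniform"), 50000, seed = sd,
                      field = fx$field)
    fr <- pooled_freqs(assign_and_profile(gt, fx$field, fx$geom$labels))
    expect_true(all(abs(fr - 1) < 0.05))
  }
})
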