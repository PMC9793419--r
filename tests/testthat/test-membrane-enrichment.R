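# annotation rasterization, distance fields, enrichment profiles

test_that("axis-aligned square polygons fill exactly s^2 pixels per slice", {
  ann <- list(cells = list(list(cell_id = 1L, slices = lapply(0:9, function(z)
    list(z = z, y = c(2, 2, 12, 12), x = c(3, 13, 13, 3))))))
  lab <- rasterize_annotation(ann, c(10, 20, 20), auto_exclude = FALSE)
  expect_identical(sum(lab == 1L), 10L * 10L * 10L)
  # excluded slices zeroed
  lab2 <- rasterize_annotation(ann, c(10, 20, 20), excluded_slices = c(0, 9))
  expect_identical(sum(lab2[1, , ]), 0L)
  expect_identical(sum(lab2[10, , ]), 0L)
  expect_identical(sum(lab2 == 1L), 10L * 10L * 8L)
})

test_that("label-mask annotations pass through with exclusions applied", {
  m <- array(0L, c(6, 8, 8)); m[2:5, 3:6, 3:6] <- 1L
  out <- rasterize_annotation(m, c(6, 8, 8), excluded_slices = 1L)
  expect_identical(sum(out[2, , ]), 0L)
  expect_identical(out[3, , ], m[3, , ])
})

test_that("edge-sharing cells rasterize deterministically; true overlap errors", {
  two <- list(cells = list(
    list(cell_id = 1L, slices = list(list(z = 0, y = c(2, 2, 10, 10), x = c(2, 8, 8, 2)))),
    list(cell_id = 2L, slices = list(list(z = 0, y = c(2, 2, 10, 10), x = c(8, 14, 14, 8))))))
  lab <- rasterize_annotation(two, c(1, 16, 16), auto_exclude = FALSE)
  expect_identical(sum(lab == 1L), 8L * 6L)
  expect_identical(sum(lab == 2L), 8L * 6L)
  # same polygons listed in the other order: the shared boundary stays with
  # the first-listed cell either way (pixel centres are strictly inside one)
  labr <- rasterize_annotation(list(cells = rev(two$cells)), c(1, 16, 16),
                               auto_exclude = FALSE)
  expect_identical(sum(labr == 1L), 8L * 6L)
  overlap <- list(cells = list(
    list(cell_id = 1L, slices = list(list(z = 0, y = c(2, 2, 10, 10), x = c(2, 9, 9, 2)))),
    list(cell_id = 2L, slices = list(list(z = 0, y = c(2, 2, 10, 10), x = c(5, 14, 14, 5))))))
  expect_error(rasterize_annotation(overlap, c(1, 16, 16), auto_exclude = FALSE),
               "conflict")
  bowtie <- list(cells = list(list(cell_id = 1L, slices = list(
    list(z = 0, y = c(2, 10, 2, 10), x = c(2, 10, 10, 2))))))
  expect_error(rasterize_annotation(bowtie, c(1, 16, 16)), "self-intersect")
})

test_that("the centers-method distance respects anisotropy at the boundary", {
  lab <- array(0L, c(8, 8, 8)); lab[3:6, 3:6, 3:6] <- 1L
  f <- distance_field(lab, c(0.3, 0.1, 0.1), method = "centers")
  # face-adjacent to background in y: one lateral step
  expect_equal(f$distance[4, 3, 4], 0.1)
  lab2 <- array(0L, c(8, 20, 20)); lab2[3:6, 3:18, 3:18] <- 1L
  f2 <- distance_field(lab2, c(0.3, 0.1, 0.1), method = "centers")
  expect_equal(f2$distance[3, 10, 10], 0.3)       # only the z face is near
})

test_that("distance transform matches brute force on a small cell", {
  set.seed(8)
  lab <- array(0L, c(14, 14, 14))
  lab[3:12, 3:12, 3:12] <- 1L
  lab[3:5, 3:5, 3:5] <- 0L  # notch for irregularity
  vs <- c(0.25, 0.12, 0.12)
  f <- distance_field(lab, vs, method = "centers")
  inside <- which(lab == 1L)
  bg <- which(lab == 0L)
  bgi <- arrayInd(bg, dim(lab))
  bg_um <- sweep(bgi, 2L, vs, "*")
  for (i in sample(inside, 40)) {
    p <- sweep(arrayInd(i, dim(lab)), 2L, vs, "*")
    brute <- min(sqrt(rowSums(sweep(bg_um, 2L, as.numeric(p))^2)))
    expect_equal(f$distance[i], brute, tolerance = 1e-6)
  }
})

test_that("sphere distances normalize to 1 at the centre and shells match analytics", {
  fx <- fx_sphere30()
  f <- fx$field
  expect_equal(max(f$norm_dist, na.rm = TRUE), 1)
  expect_equal(unname(f$max_dist["1"]), 3, tolerance = 0.04)  # within ~1 voxel
  # voxel-counted shell fractions vs analytic concentric shell volumes
  nd <- f$norm_dist[fx$geom$labels == 1L]
  for (b in 1:3) {
    frac <- mean(nd >= (b - 1) / 10 & nd < b / 10)
    analytic <- (1 - (b - 1) / 10)^3 - (1 - b / 10)^3
    expect_lt(abs(frac - analytic) / analytic, 0.02)
  }
})

test_that("profiles conserve mass and recover planted membrane fractions", {
  fx <- fx_sphere30()
  gt <- place_spots(fx$geom, localization_model("uniform"), 50000, seed = 3,
                    field = fx$field)
  pr <- assign_and_profile(gt, fx$field, fx$geom$labels)
  fr <- pooled_freqs(pr)
  # outer bins of a sphere hold enough volume to resolve the flat baseline;
  # the innermost shells are Poisson-limited and checked on the flat cell
  expect_true(all(abs(fr[1:5] - 1) < 0.05))
  p <- pr[pr$cell_id == "pooled", ]
  expect_equal(sum(p$norm_freq * p$volume_fraction), 1, tolerance = 1e-12)
  expect_equal(sum(p$shell_volume_um3),
               sum(fx$geom$labels == 1L) * prod(fx$geom$voxel_size))
  # all-membrane fixture: bin-1 frequency is 1 / shell volume fraction
  mem <- place_spots(fx$geom,
                     localization_model("membrane", membrane_fraction = 1),
                     5000, seed = 4, field = fx$field)
  pm <- assign_and_profile(mem, fx$field, fx$geom$labels)
  pmp <- pm[pm$cell_id == "pooled", ]
  expect_equal(pmp$norm_freq[1], 1 / (1 - 0.9^3), tolerance = 0.02)
  expect_true(all(pmp$count[-1] == 0))
  expect_equal(membrane_fraction(pm), 1)
  # partial membrane fractions are recovered on ground truth within 0.03
  for (p40 in c(0.2, 0.4, 0.8)) {
    g <- place_spots(fx$geom,
                     localization_model("membrane", membrane_fraction = p40),
                     20000, seed = 5, field = fx$field)
    pf <- assign_and_profile(g, fx$field, fx$geom$labels)
    expect_lt(abs(membrane_fraction(pf) - p40), 0.03)
  }
})

test_that("membrane_fraction counts bins below an aligned cutoff", {
  fx <- fx_sphere30()
  gt <- place_spots(fx$geom, localization_model("uniform"), 1000, seed = 9,
                    field = fx$field)
  pr <- assign_and_profile(gt, fx$field, fx$geom$labels)
  p <- pr[pr$cell_id == "pooled", ]
  expect_equal(membrane_fraction(pr, 0.3), sum(p$count[1:3]) / sum(p$count))
  expect_error(membrane_fraction(pr, 0.25), "bin edge")
  empty <- pr; empty$count <- 0
  attr(empty, "n_bins") <- 10L
  expect_error(membrane_fraction(empty), "zero spots")
})

test_that("normalized frequencies are invariant to uniform voxel rescaling", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom, localization_model("membrane", membrane_fraction = 0.6),
                    2000, seed = 6, field = fx$field)
  pr1 <- assign_and_profile(gt, fx$field, fx$geom$labels)
  f2 <- distance_field(fx$geom$labels, fx$geom$voxel_size * 2)
  gt2 <- gt
  gt2[, c("z_um", "y_um", "x_um")] <- gt2[, c("z_um", "y_um", "x_um")] * 2
  pr2 <- assign_and_profile(gt2, f2, fx$geom$labels)
  expect_equal(pooled_freqs(pr1), pooled_freqs(pr2), tolerance = 1e-12)
})

test_that("membrane-hugging spots are rescued and background spots are tallied", {
  lab <- array(0L, c(8, 12, 12)); lab[3:6, 3:10, 3:10] <- 1L
  vs <- c(0.2, 0.1, 0.1)
  f <- distance_field(lab, vs)
  spots <- data.frame(spot_id = 1:2,
                      z_um = c(0.5, 0.05), y_um = c(0.15, 0.05), x_um = c(0.5, 0.05),
                      molecule_count = c(1L, 1L))
  # spot 1 sits just outside the label (y voxel 1) -> rescued to cell 1;
  # spot 2 is far in the background -> discarded
  pr <- assign_and_profile(spots, f, lab)
  expect_identical(attr(pr, "n_discarded"), 1L)
  expect_equal(sum(pr[pr$cell_id == "pooled", "count"]), 1)
})
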