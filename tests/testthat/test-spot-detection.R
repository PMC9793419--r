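# band-pass filtering, local-maxima detection, Gaussian refinement, matching

test_that("difference-of-Gaussians response is zero on constant input", {
  v <- array(37, c(12, 16, 16))
  out <- bandpass_filter(v, c(0.2, 0.1, 0.1))
  expect_lt(max(abs(out)), 1e-9)
  expect_error(bandpass_filter(v, c(0.2, 0.1, 0.1), sigma_small = c(-1, 0.1, 0.1)),
               "positive")
  expect_error(bandpass_filter(v, c(0.2, 0.1, 0.1), sigma_small = c(0.4, 0.2, 0.2),
                               sigma_large = c(0.3, 0.3, 0.3)), "smaller")
})

test_that("separable Gaussian filtering matches brute-force direct convolution", {
  set.seed(5)
  v <- array(rnorm(20 * 20 * 20, 100, 10), c(20, 20, 20))
  vs <- c(0.2, 0.1, 0.1)
  sig <- c(0.35, 0.13, 0.13)
  sm <- array(memfish:::.gauss3d(as.numeric(v), dim(v), sig / vs), dim(v))
  # direct-space convolution at an interior voxel with the same normalized
  # kernel (support fully inside, so boundary handling is irrelevant)
  at <- c(10, 10, 10)
  svox <- sig / vs
  r <- ceiling(4 * svox)
  k1 <- function(s, r) { k <- exp(-0.5 * ((-r:r) / s)^2); k / sum(k) }
  kz <- k1(svox[1], r[1]); ky <- k1(svox[2], r[2]); kx <- k1(svox[3], r[3])
  acc <- 0
  for (a in -r[1]:r[1]) for (b in -r[2]:r[2]) for (cc in -r[3]:r[3])
    acc <- acc + kz[a + r[1] + 1] * ky[b + r[2] + 1] * kx[cc + r[3] + 1] *
      v[at[1] + a, at[2] + b, at[3] + cc]
  expect_equal(sm[at[1], at[2], at[3]], acc, tolerance = 1e-6)
})

test_that("a single rendered spot gives a response maximum at its voxel", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom, localization_model("uniform"), 1, seed = 13,
                    field = fx$field)
  st <- render_stack(fx$geom, gt, spot_amplitude = 200,
                     noise = list(poisson = FALSE, gaussian_sd = 0),
                     background = 0, seed = 1)
  dog <- bandpass_filter(st$channels$smfish, fx$geom$voxel_size)
  peak <- arrayInd(which.max(dog), dim(dog)) - 1L
  mol <- memfish:::um_to_voxel(as.matrix(gt[, c("z_um", "y_um", "x_um")]),
                               fx$geom$voxel_size, dim(dog))
  expect_true(all(abs(peak - mol) <= 1))
})

test_that("pure-noise stacks yield no spots and empty volumes are not an error", {
  set.seed(99)
  v <- array(rnorm(20 * 60 * 60, 100, 10), c(20, 60, 60))
  sp <- detect_spots(v, c(0.2, 0.1, 0.1), threshold = 5)
  expect_identical(nrow(sp), 0L)
  expect_identical(nrow(detect_spots(array(0, c(10, 10, 10)), c(0.2, 0.1, 0.1))), 0L)
})

test_that("one spot at SNR 10 is found within half a lateral voxel", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom, localization_model("uniform"), 1, seed = 21,
                    field = fx$field)
  st <- render_stack(fx$geom, gt, spot_amplitude = fx_amp_snr(10),
                     noise = fx_noise, background = 100, seed = 22)
  sp <- detect_spots(st$channels$smfish, fx$geom$voxel_size)
  expect_identical(nrow(sp), 1L)
  err <- sqrt(sum((as.numeric(sp[1, c("z_um", "y_um", "x_um")]) -
                   as.numeric(gt[1, c("z_um", "y_um", "x_um")]))^2))
  expect_lt(err, 0.5 * 0.1)
})

test_that("sub-voxel accuracy: noiseless localization error is under 0.1 voxel", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom, localization_model("uniform"), 25, seed = 31,
                    field = fx$field)
  st <- render_stack(fx$geom, gt, spot_amplitude = 200,
                     noise = list(poisson = FALSE, gaussian_sd = 0),
                     background = 0, seed = 1)
  sp <- detect_spots(st$channels$smfish, fx$geom$voxel_size, min_separation = 0.3)
  m <- match_to_truth(sp, gt, tolerance = 0.3)
  expect_gte(m$recall, 0.9)  # a few close pairs may merge
  expect_lt(m$mean_error_um, 0.1 * 0.1)
})

test_that("raising the threshold never increases the spot count", {
  fx <- fx_small_cell()
  gt <- place_spots(fx$geom, localization_model("uniform"), 40, seed = 41,
                    field = fx$field)
  st <- render_stack(fx$geom, gt, spot_amplitude = fx_amp_snr(5),
                     noise = fx_noise, background = 100, seed = 42)
  counts <- vapply(c(3, 4, 5, 7, 10, 20),
                   function(th) nrow(suppressWarnings(
                     detect_spots(st$channels$smfish, fx$geom$voxel_size,
                                  threshold = th))),
                   integer(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("a four-cell embryo at single-transcript scale is detected at SNR 5", {
  # ~2400 molecules per four-cell embryo at DeltaVision-like sampling
  geom <- generate_geometry(4, c(62, 396, 396), c(0.2, 0.11, 0.11), seed = 9)
  gt <- place_spots(geom, localization_model("uniform"), 2400, seed = 1)
  st <- render_stack(geom, gt, spot_amplitude = fx_amp_snr(5),
                     noise = fx_noise, background = 100, seed = 2)
  sp <- suppressWarnings(detect_spots(st$channels$smfish, geom$voxel_size,
                                      min_separation = 0.3))
  m <- match_to_truth(sp, gt, tolerance = 0.5)
  expect_gte(m$recall, 0.9)
  expect_gte(m$precision, 0.95)
})

test_that("match_to_truth handles identity, empty and spurious cases", {
  gt <- data.frame(mol_id = 1:5, z_um = 1:5, y_um = 1:5, x_um = 1:5)
  det <- data.frame(spot_id = 1:5, z_um = 1:5, y_um = 1:5, x_um = 1:5)
  m <- match_to_truth(det, gt, tolerance = 0.1)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  m0 <- match_to_truth(det[0, ], gt, tolerance = 0.1)
  expect_equal(m0$recall, 0)
  expect_equal(m0$precision, 0)
  expect_true(m0$undefined_precision)
  sp6 <- rbind(det, data.frame(spot_id = 6, z_um = 40, y_um = 40, x_um = 40))
  m6 <- match_to_truth(sp6, gt, tolerance = 0.1)
  expect_equal(m6$precision, 5 / 6)
  expect_equal(m6$recall, 1)
})

test_that("matching is one-to-one and prefers the closest pairs", {
  gt <- data.frame(mol_id = 1:2, z_um = c(0, 0), y_um = c(0, 0), x_um = c(0, 0.2))
  det <- data.frame(spot_id = 1L, z_um = 0, y_um = 0, x_um = 0.05)
  m <- match_to_truth(det, gt, tolerance = 0.3)
  expect_identical(m$n_matched, 1L)
  expect_identical(m$matches$mol_id, 1L)  # the closer truth
  expect_equal(m$recall, 0.5)
})
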