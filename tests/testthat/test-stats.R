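# Welch tests, localization classification, condition summaries, nuclear RFU

test_that("welch_test matches the reference implementation to 1e-10", {
  set.seed(123)
  for (i in 1:100) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    w <- welch_test(a, b)
    tt <- stats::t.test(a, b, var.equal = FALSE)
    expect_lt(abs(w$statistic - unname(tt$statistic)), 1e-10)
    expect_lt(abs(w$df - unname(tt$parameter)), 1e-8)
    expect_lt(abs(w$p_value - tt$p.value), 1e-10)
  }
})

test_that("welch_test handles identical groups, symmetry and the classical limit", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  w <- welch_test(a, a)
  expect_equal(w$statistic, 0)
  expect_equal(w$p_value, 1)
  b <- a + 2
  w1 <- welch_test(a, b); w2 <- welch_test(b, a)
  expect_equal(w1$statistic, -w2$statistic)
  expect_equal(w1$p_value, w2$p_value)
  # equal sample variances, equal n: Welch df reduces to 2n - 2
  x <- c(1, 2, 3); y <- c(5, 6, 7)
  expect_equal(welch_test(x, y)$df, 4)
  expect_error(welch_test(1, c(1, 2)), "at least 2")
  expect_error(welch_test(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("significance stars follow the legend convention", {
  expect_identical(significance_stars(c(0.04, 0.004, 4e-4, 4e-5, 0.2)),
                   c("*", "**", "***", "****", "n.s."))
})

test_that("localization calls threshold the outermost-bin frequency", {
  mk <- function(freq1, total = 100) {
    pr <- data.frame(cell_id = "pooled", bin = 1:10,
                     count = c(total / 2, rep(total / 18, 9)),
                     shell_volume_um3 = rep(10, 10),
                     volume_fraction = rep(0.1, 10),
                     norm_freq = c(freq1, rep(1, 9)))
    attr(pr, "n_bins") <- 10L
    class(pr) <- c("enrichment_profile", "data.frame")
    pr
  }
  expect_identical(as.character(classify_localization(mk(3.0))), "localized")
  expect_identical(as.character(classify_localization(mk(1.0))), "unlocalized")
  expect_identical(as.character(classify_localization(mk(1.5))), "localized")
  expect_identical(as.character(classify_localization(mk(3.0, total = 20))),
                   "indeterminate")
  # monotone in the bin-1 frequency at a fixed threshold
  calls <- vapply(seq(0.5, 3, 0.25),
                  function(f) as.character(classify_localization(mk(f))),
                  character(1))
  expect_true(!is.unsorted(match(calls, c("unlocalized", "localized"))))
})

test_that("condition summaries report proportions per group", {
  rec <- data.frame(stage = rep(4L, 20), condition = "ctrl",
                    call = rep(c("localized", "unlocalized"), c(16, 4)))
  s <- condition_summary(rec)
  expect_equal(s$frac_localized, 0.8)
  expect_equal(s$frac_localized + s$frac_unlocalized, 1)
  allind <- data.frame(stage = 4L, condition = "x", call = rep("indeterminate", 3))
  s2 <- condition_summary(allind)
  expect_identical(s2$n_effective, 0L)
  expect_true(is.na(s2$frac_localized))
})

test_that("nuclear RFU is the background-subtracted nuclear mean", {
  d <- c(16, 24, 24)
  emb <- array(FALSE, d); emb[5:12, 7:18, 7:18] <- TRUE
  nuc_true <- array(FALSE, d); nuc_true[7:10, 10:15, 10:15] <- TRUE
  dapi <- array(10, d); dapi[nuc_true] <- 200
  rep100 <- array(10, d); rep100[nuc_true] <- 100
  rfu <- nuclear_rfu(rep100, dapi, emb)
  expect_equal(as.numeric(rfu), 90)
  # null signal
  expect_equal(as.numeric(nuclear_rfu(array(10, d), dapi, emb)), 0)
  # masked means agree with brute-force voxel iteration
  set.seed(6)
  rnd <- array(runif(prod(d), 50, 150), d)
  rfu2 <- nuclear_rfu(rnd, dapi, emb)
  thr <- attr(rfu2, "dapi_threshold")
  nuc <- emb & (dapi > thr)
  dist_out <- memfish:::edt(!emb, c(1, 1, 1))
  bg <- !emb & dist_out >= 2
  acc_n <- 0; cnt_n <- 0; acc_b <- 0; cnt_b <- 0
  for (i in seq_along(rnd)) {
    if (nuc[i]) { acc_n <- acc_n + rnd[i]; cnt_n <- cnt_n + 1 }
    if (bg[i]) { acc_b <- acc_b + rnd[i]; cnt_b <- cnt_b + 1 }
  }
  expect_equal(as.numeric(rfu2), acc_n / cnt_n - acc_b / cnt_b, tolerance = 1e-9)
  expect_error(nuclear_rfu(rep100, array(10, d), emb), "no nuclear")
})
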