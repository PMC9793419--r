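#' Welch two-sample t-test with the reporting conventions used here
#'
#' Unequal-variance two-sample t-test:
#' `t = (mean(a) - mean(b)) / sqrt(s2a/na + s2b/nb)` with
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value from the t
#' distribution. Significance stars follow the figure-legend convention
#' `*P<0.05, **P<0.005, ***P<0.0005, ****P<0.00005`; no multiple-testing
#' correction is applied.
#'
#' @param a,b Numeric vectors, each with at least 2 values and nonzero
#'   variance.
#' @param labels Length-2 character vector naming the groups.
#' @return An object of class `condition_comparison`: list with `statistic`
#'   (t), `df`, `p_value`, `means`, `n`, `labels`, `stars`.
#' @examples
#' welch_test(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
#' @export
welch_test <- function(a, b, labels = c("a", "b")) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stopf("test error: each group needs at least 2 values")
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0 && mean(a) == mean(b)) {
    # identical-group degenerate case is well-defined: no difference
    out <- list(statistic = 0, df = length(a) + length(b) - 2,
                p_value = 1, means = c(mean(a), mean(b)),
                n = c(length(a), length(b)), labels = labels, stars = "n.s.")
    class(out) <- "condition_comparison"
    return(out)
  }
  if (va == 0 || vb == 0) stopf("test error: zero variance in a group")
  na <- length(a); nb <- length(b)
  se2a <- va / na; se2b <- vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  p <- 2 * pt(-abs(tstat), df)
  out <- list(statistic = tstat, df = df, p_value = p,
              means = c(mean(a), mean(b)), n = c(na, nb),
              labels = labels, stars = significance_stars(p))
  class(out) <- "condition_comparison"
  out
}

#' Significance stars per the smFISH figure-legend convention
#'
#' @param p P-value(s).
#' @return `"****"` for p < 0.00005, `"***"` for p < 0.0005, `"**"` for
#'   p < 0.005, `"*"` for p < 0.05, `"n.s."` otherwise.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < 0.00005) "****" else if (pi < 0.0005) "***"
    else if (pi < 0.005) "**" else if (pi < 0.05) "*" else "n.s."
  }, character(1))
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: %s vs %s\n", x$labels[1], x$labels[2]))
  cat(sprintf("  t = %.4g, df = %.3f, p = %.4g %s\n",
              x$statistic, x$df, x$p_value, x$stars))
  cat(sprintf("  means: %.4g (n=%d) vs %.4g (n=%d)\n",
              x$means[1], x$n[1], x$means[2], x$n[2]))
  invisible(x)
}

#' Classify an embryo as membrane-localized or unlocalized
#'
#' An embryo is called `"localized"` when the outermost distance bin of its
#' pooled enrichment profile reaches `threshold` (default 1.5, midway between
#' the random baseline of 1 and the weakest reported enrichment classes of
#' roughly 1.3–1.8-fold); otherwise `"unlocalized"`. Profiles built from
#' fewer than `min_spots` molecules give `"indeterminate"` with a flag rather
#' than an error.
#'
#' @param profile An `enrichment_profile`.
#' @param threshold Bin-1 normalized-frequency threshold (calls `>=` as
#'   localized).
#' @param min_spots Minimum molecules required for a confident call.
#' @param cell Profile to use (default `"pooled"`).
#' @return Character: `"localized"`, `"unlocalized"`, or `"indeterminate"`,
#'   with attributes `bin1_freq` and `n_spots`.
#' @export
classify_localization <- function(profile, threshold = 1.5, min_spots = 50L,
                                  cell = "pooled") {
  rows <- profile[profile$cell_id == as.character(cell), ]
  if (nrow(rows) == 0L) stopf("no profile rows for cell '%s'", cell)
  tot <- sum(rows$count)
  b1 <- rows$norm_freq[rows$bin == 1L]
  call <- if (tot < min_spots) "indeterminate"
          else if (!is.na(b1) && b1 >= threshold) "localized" else "unlocalized"
  structure(call, bin1_freq = b1, n_spots = tot)
}

#' Summarize localization calls by condition group
#'
#' @param records Data frame of per-embryo records with a `call` column
#'   (`"localized"`, `"unlocalized"`, `"indeterminate"`) and the grouping
#'   columns.
#' @param by Grouping column names (default `c("stage", "condition")`,
#'   silently reduced to those present).
#' @return Data frame with one row per group: `n`, `n_localized`,
#'   `n_unlocalized`, `n_indeterminate`, `frac_localized`,
#'   `frac_unlocalized` (fractions over the determinate embryos).
#' @export
condition_summary <- function(records, by = c("stage", "condition")) {
  by <- intersect(by, names(records))
  if (length(by) == 0L) stopf("no grouping columns found in records")
  if (nrow(records) == 0L) stopf("empty records")
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  out <- do.call(rbind, lapply(levels(key), function(k) {
    r <- records[key == k, , drop = FALSE]
    nl <- sum(r$call == "localized"); nu <- sum(r$call == "unlocalized")
    ni <- sum(r$call == "indeterminate")
    ne <- nl + nu
    cbind(r[1, by, drop = FALSE],
          data.frame(n = nrow(r), n_localized = nl, n_unlocalized = nu,
                     n_indeterminate = ni, n_effective = ne,
                     frac_localized = if (ne > 0) nl / ne else NA_real_,
                     frac_unlocalized = if (ne > 0) nu / ne else NA_real_))
  }))
  rownames(out) <- NULL
  out
}

#' Background-subtracted nuclear reporter fluorescence (RFU)
#'
#' Quantifies a fluorescent reporter as relative fluorescence units: the mean
#' reporter intensity within a nuclear mask minus the mean intensity of the
#' extra-embryonic background. The nuclear mask is an Otsu threshold of the
#' DAPI channel restricted to the embryo, with connected components below
#' `min_voxels` removed; the background region is everything outside the
#' embryo mask after a 2-voxel erosion of that complement (so edge bleed-over
#' next to the embryo is excluded).
#'
#' @param reporter,dapi Co-registered 3D arrays of the same shape.
#' @param embryo_mask Logical or label 3D array marking the embryo (> 0).
#' @param min_voxels Smallest nuclear component kept (default 27).
#' @return Numeric RFU value with attributes `n_nuclear_voxels` and
#'   `dapi_threshold`.
#' @export
nuclear_rfu <- function(reporter, dapi, embryo_mask, min_voxels = 27L) {
  if (!all(dim(reporter) == dim(dapi)) || !all(dim(reporter) == dim(embryo_mask)))
    stopf("reporter, dapi and embryo_mask must share a shape")
  emb <- embryo_mask > 0
  if (!any(emb)) stopf("masking error: empty embryo mask")
  vals <- dapi[emb]
  rng <- range(vals)
  thr <- if (rng[1] == rng[2]) rng[1] else {
    v01 <- (vals - rng[1]) / (rng[2] - rng[1])
    ot <- EBImage::otsu(EBImage::Image(matrix(v01, ncol = 1L)), range = c(0, 1))
    rng[1] + ot * (rng[2] - rng[1])
  }
  nuc <- emb & (dapi > thr)
  if (any(nuc)) {
    cc <- label_components(nuc, 6L)
    sizes <- tabulate(cc[cc > 0L])
    keep <- which(sizes >= min_voxels)
    nuc <- array(cc %in% keep & cc > 0L, dim(nuc))
  }
  if (!any(nuc)) stopf("masking error: no nuclear voxels found")
  # background: complement eroded by 2 voxels (stay >= 2 voxels off the embryo)
  d_out <- edt(!emb, c(1, 1, 1))
  bg <- !emb & (d_out >= 2)
  if (!any(bg)) bg <- !emb
  if (!any(bg)) stopf("masking error: no background voxels available")
  rfu <- mean(reporter[nuc]) - mean(reporter[bg])
  structure(rfu, n_nuclear_voxels = sum(nuc), dapi_threshold = thr)
}
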