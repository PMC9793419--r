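#' Estimate the reference single-molecule intensity
#'
#' Derives the "average single mRNA" used for cluster decomposition from a
#' detected spot population: the integrated-intensity median after iteratively
#' trimming values above twice the current median (which removes bright
#' multi-molecule clusters from the reference), the MAD of the retained spots
#' as the spread, and the median fit sigmas.
#'
#' @param spots A `spot_set` (needs `intensity`; uses `sigma_z`/`sigma_xy`
#'   when present), or a numeric vector of integrated intensities.
#' @return An object of class `reference_molecule`: list with `intensity`,
#'   `intensity_spread` (MAD, 1.4826 scaling), `sigma` (`c(z, xy)` µm or
#'   `NA`), `n_used`.
#' @examples
#' estimate_reference(c(98, 100, 102))$intensity
#' @export
estimate_reference <- function(spots) {
  ints <- if (is.numeric(spots)) spots else spots$intensity
  if (length(ints) == 0L) stopf("reference error: empty spot set")
  if (any(ints <= 0)) stopf("reference error: non-positive intensities")
  keep <- ints
  repeat {
    med <- median(keep)
    nxt <- keep[keep <= 2 * med]
    if (length(nxt) == length(keep)) break
    keep <- nxt
  }
  sig <- c(NA_real_, NA_real_)
  if (!is.numeric(spots) && all(c("sigma_z", "sigma_xy") %in% names(spots)) &&
      nrow(spots) > 0)
    sig <- c(median(spots$sigma_z), median(spots$sigma_xy))
  structure(list(intensity = median(keep),
                 intensity_spread = if (length(keep) > 1L) mad(keep) else 0,
                 sigma = sig, n_used = length(keep)),
            class = "reference_molecule")
}

#' @export
print.reference_molecule <- function(x, ...) {
  cat(sprintf("reference_molecule: intensity %.4g +/- %.3g (n=%d)\n",
              x$intensity, x$intensity_spread, x$n_used))
  invisible(x)
}

#' Decompose detections into integer molecule counts
#'
#' Assigns each detected spot an integer molecule count by maximizing, over
#' `k = 1..k_max`, the Gaussian likelihood of its integrated intensity under
#' mean `k * ref$intensity` and SD `sqrt(k) * spread` (spread floored at 5% of
#' the reference intensity so a tight reference population cannot collapse the
#' model). Ties resolve toward smaller `k`; counts never fall below 1, so dim
#' spots still count as one molecule. This is the intensity-only
#' formalization of GMM-style single-molecule counting: the total mRNA count
#' of an embryo is the sum of `molecule_count` over its spots.
#'
#' @param spots A `spot_set`.
#' @param ref A `reference_molecule` from [estimate_reference()].
#' @param k_max Largest molecule count considered per spot (default 20).
#' @return The input with columns `molecule_count` (integer >= 1) and
#'   `posterior_score` (log-likelihood margin of the chosen `k` over the
#'   runner-up), class `counted_spots`.
#' @export
decompose_spots <- function(spots, ref, k_max = 20L) {
  if (!inherits(ref, "reference_molecule") || !is.finite(ref$intensity) ||
      ref$intensity <= 0)
    stopf("decomposition error: invalid reference molecule")
  k_max <- as.integer(k_max)
  if (k_max < 1L) stopf("k_max must be >= 1")
  sp <- as.data.frame(spots)
  if (nrow(sp) == 0L) {
    sp$molecule_count <- integer(0)
    sp$posterior_score <- numeric(0)
  } else {
    spread <- max(ref$intensity_spread, 0.05 * ref$intensity)
    ks <- seq_len(k_max)
    # log-likelihood of each spot intensity under each k (spots x k matrix)
    ll <- vapply(ks, function(k)
      stats::dnorm(sp$intensity, mean = k * ref$intensity,
                   sd = sqrt(k) * spread, log = TRUE),
      numeric(nrow(sp)))
    ll <- matrix(ll, nrow = nrow(sp))
    best <- max.col(ll, ties.method = "first")  # first = smallest k on ties
    margin <- vapply(seq_len(nrow(sp)), function(i) {
      if (k_max == 1L) return(Inf)
      srt <- sort(ll[i, ], decreasing = TRUE)
      srt[1] - srt[2]
    }, numeric(1))
    sp$molecule_count <- as.integer(best)
    sp$posterior_score <- margin
  }
  attr(sp, "reference") <- ref
  attr(sp, "voxel_size") <- attr(spots, "voxel_size")
  class(sp) <- c("counted_spots", "data.frame")
  sp
}

#' Count mRNA clusters by single-linkage grouping
#'
#' Groups spot positions by single-linkage agglomeration cut at `link_radius`
#' and counts the groups whose summed molecule count reaches `min_molecules`
#' — the P-granule-scale aggregates reported per embryo.
#'
#' @param spots A `counted_spots` or `spot_set` data frame (a missing
#'   `molecule_count` column counts each spot as one molecule).
#' @param link_radius Single-linkage cut distance, µm (default 0.3).
#' @param min_molecules Minimum summed molecule count for a group to qualify
#'   as a cluster (default 3, >= 2 required).
#' @return Integer cluster count; the per-spot group ids are attached as
#'   attribute `"groups"`, with 0 marking spots in non-qualifying groups.
#' @export
count_clusters <- function(spots, link_radius = 0.3, min_molecules = 3L) {
  if (link_radius <= 0) stopf("link_radius must be > 0")
  if (min_molecules < 2L) stopf("min_molecules must be >= 2")
  n <- nrow(spots)
  if (is.null(n) || n == 0L) return(structure(0L, groups = integer(0)))
  counts <- if ("molecule_count" %in% names(spots)) spots$molecule_count else rep(1L, n)
  if (n == 1L) {
    qual <- counts[1] >= min_molecules
    return(structure(as.integer(qual), groups = as.integer(qual)))
  }
  pos <- as.matrix(spots[, c("z_um", "y_um", "x_um")])
  hc <- hclust(dist(pos), method = "single")
  # cutree(h = r) merges pairs with linkage <= h; "grouping at link_radius"
  grp <- cutree(hc, h = link_radius)
  sums <- tapply(counts, grp, sum)
  qual_ids <- as.integer(names(sums)[sums >= min_molecules])
  out_groups <- integer(n)
  if (length(qual_ids)) {
    remap <- setNames(seq_along(qual_ids), qual_ids)
    hit <- grp %in% qual_ids
    out_groups[hit] <- remap[as.character(grp[hit])]
  }
  structure(length(qual_ids), groups = as.integer(out_groups))
}
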