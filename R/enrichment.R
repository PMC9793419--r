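#' Volume-normalized membrane-proximity enrichment profile
#'
#' The core statistic: spots are assigned to cells, their normalized membrane
#' distances are binned in `1/n_bins` increments away from the nearest
#' membrane, and per-bin spot fractions are divided by the fraction of the
#' cell volume in the corresponding concentric shell. A value of 1 in a bin
#' means as many molecules as a randomly distributed sample would put there;
#' values above 1 mean enrichment. Profiles are computed per cell and pooled
#' by summing counts and shell volumes across cells before re-normalizing
#' (not by averaging per-cell frequencies), so the pooled profile is
#' well-defined even when individual cells hold few spots.
#'
#' Spot-to-cell assignment uses the containing voxel's label. Spots falling
#' on the membrane itself (label 0) are the signal of interest and must not
#' be dropped silently: they are assigned to the nearest labelled voxel
#' within one voxel of their position; spots further into the background (or
#' in excluded slices) are discarded and tallied in the `n_discarded`
#' attribute. `molecule_count` weights the counts when present, so
#' decomposed clusters contribute their full molecule number.
#'
#' @param spots A `counted_spots`, `spot_set`, or `ground_truth` data frame
#'   (µm positions; optional `molecule_count`).
#' @param field A [distance_field()] computed from `labels`.
#' @param labels 3D integer cell label array (excluded slices zeroed).
#' @param n_bins Number of distance bins (default 10, >= 2). Bin `b` covers
#'   normalized distance `[(b-1)/n, b/n)`, the last bin closed.
#' @return An `enrichment_profile` data frame with one row per (cell, bin)
#'   plus pooled rows (`cell_id = "pooled"`): columns `cell_id`, `bin`,
#'   `count`, `shell_volume_um3`, `volume_fraction`, `norm_freq`. Attributes:
#'   `n_bins`, `n_assigned`, `n_discarded`, `voxel_size`.
#' @examples
#' geom <- generate_geometry(1, c(24, 24, 24), c(0.1, 0.1, 0.1), seed = 1)
#' f <- distance_field(geom$labels, geom$voxel_size)
#' tr <- place_spots(geom, localization_model("uniform"), 500, seed = 2, field = f)
#' pr <- assign_and_profile(tr, f, geom$labels)
#' subset(pr, cell_id == "pooled")
#' @export
assign_and_profile <- function(spots, field, labels, n_bins = 10L) {
  stopifnot(inherits(field, "distance_field"))
  if (inherits(labels, "embryo_geometry")) labels <- labels$labels
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stopf("n_bins must be >= 2")
  if (!all(dim(labels) == dim(field$norm_dist)))
    stopf("input error: field and labels shapes differ")
  d <- dim(labels)
  vs <- field$voxel_size
  vol_vox <- prod(vs)

  pos <- as.matrix(as.data.frame(spots)[, c("z_um", "y_um", "x_um")])
  weights <- if ("molecule_count" %in% names(spots))
    as.numeric(spots$molecule_count) else rep(1, nrow(pos))

  idx <- um_to_voxel(pos, vs, d)
  lin <- voxel_linear(idx, d)
  cell <- labels[lin]

  # membrane-adjacent rescue: label-0 spots adopt the nearest labelled voxel
  # within the 3x3x3 neighbourhood (<= 1 voxel away)
  n_disc <- 0L
  if (any(cell == 0L) && nrow(pos) > 0) {
    for (i in which(cell == 0L)) {
      best_lab <- 0L; best_d <- Inf
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        v <- idx[i, ] + c(dz, dy, dx)
        if (any(v < 0L) || any(v >= d)) next
        l2 <- labels[v[1] + d[1] * (v[2] + d[2] * v[3]) + 1]
        if (l2 == 0L) next
        ctr <- (v + 0.5) * vs
        dd <- sqrt(sum((ctr - pos[i, ])^2))
        if (dd < best_d) { best_d <- dd; best_lab <- l2; lin[i] <- v[1] + d[1] * (v[2] + d[2] * v[3]) + 1 }
      }
      cell[i] <- best_lab
    }
    n_disc <- sum(cell == 0L)
  }

  use <- cell > 0L
  nd <- field$norm_dist[lin[use]]
  bin <- pmin(floor(nd * n_bins), n_bins - 1L) + 1L
  cells_used <- cell[use]
  w <- weights[use]

  ids <- sort(unique(as.integer(labels[labels > 0L])))
  # shell volumes from the voxel-centre normalized distances of each cell
  shell <- matrix(0, length(ids), n_bins, dimnames = list(ids, NULL))
  for (j in seq_along(ids)) {
    ndv <- field$norm_dist[labels == ids[j]]
    bv <- pmin(floor(ndv * n_bins), n_bins - 1L) + 1L
    shell[j, ] <- tabulate(bv, n_bins) * vol_vox
  }

  counts <- matrix(0, length(ids), n_bins, dimnames = list(ids, NULL))
  if (any(use)) {
    agg <- tapply(w, list(factor(cells_used, levels = ids), factor(bin, levels = 1:n_bins)), sum)
    agg[is.na(agg)] <- 0
    counts[, ] <- agg
  }

  prof_rows <- function(cid, cnt, shl) {
    tot <- sum(cnt); volsum <- sum(shl)
    vf <- shl / volsum
    nf <- if (tot > 0) (cnt / tot) / vf else rep(NA_real_, n_bins)
    data.frame(cell_id = cid, bin = seq_len(n_bins), count = cnt,
               shell_volume_um3 = shl, volume_fraction = vf, norm_freq = nf,
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(
    lapply(seq_along(ids), function(j) prof_rows(as.character(ids[j]), counts[j, ], shell[j, ])),
    list(prof_rows("pooled", colSums(counts), colSums(shell)))))
  rownames(out) <- NULL
  attr(out, "n_bins") <- n_bins
  attr(out, "n_assigned") <- sum(w)
  attr(out, "n_discarded") <- n_disc
  attr(out, "voxel_size") <- vs
  class(out) <- c("enrichment_profile", "data.frame")
  out
}

#' Fraction of molecules within a membrane-distance cutoff
#'
#' Sums the spot counts of all bins below the normalized-distance `cutoff`
#' and divides by the total. The default cutoff 0.1 reports the fraction of
#' molecules within 10% of the normalized radius from the plasma membrane.
#'
#' @param profile An `enrichment_profile`.
#' @param cutoff Normalized distance; must align with a bin edge.
#' @param cell Which profile to use: `"pooled"` (default) or a cell id.
#' @return Fraction in `[0, 1]`.
#' @export
membrane_fraction <- function(profile, cutoff = 0.1, cell = "pooled") {
  n_bins <- attr(profile, "n_bins") %||% max(profile$bin)
  kb <- cutoff * n_bins
  if (abs(kb - round(kb)) > 1e-9)
    stopf("cutoff %.3g does not align with a bin edge (n_bins = %d)", cutoff, n_bins)
  kb <- as.integer(round(kb))
  rows <- profile[profile$cell_id == as.character(cell), ]
  if (nrow(rows) == 0L) stopf("no profile rows for cell '%s'", cell)
  tot <- sum(rows$count)
  if (tot <= 0) stopf("undefined membrane fraction: profile has zero spots")
  sum(rows$count[rows$bin <= kb]) / tot
}

#' @export
print.enrichment_profile <- function(x, ...) {
  pooled <- x[x$cell_id == "pooled", ]
  cat(sprintf("enrichment_profile: %d bins, %s cells, %g molecules (%d discarded)\n",
              attr(x, "n_bins"), length(unique(x$cell_id)) - 1L,
              attr(x, "n_assigned"), attr(x, "n_discarded")))
  cat("pooled normalized frequency by bin:\n")
  print(setNames(signif(pooled$norm_freq, 4), paste0("b", pooled$bin)))
  invisible(x)
}

#' Plot an enrichment profile
#'
#' Bar plot of volume-normalized frequency against normalized membrane
#' distance, with the random-baseline level 1 marked.
#'
#' @param x An `enrichment_profile`.
#' @param cell Profile to draw (default `"pooled"`).
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.enrichment_profile <- function(x, cell = "pooled", ...) {
  rows <- x[x$cell_id == as.character(cell), ]
  n <- nrow(rows)
  graphics::barplot(rows$norm_freq,
                    names.arg = sprintf("%g-%g", (rows$bin - 1) / n, rows$bin / n),
                    xlab = "normalized distance from membrane",
                    ylab = "volume-normalized frequency", las = 2, ...)
  graphics::abline(h = 1, lty = 2)
  invisible(x)
}
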