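#' Specify a molecule localization model
#'
#' Describes how molecules distribute inside cells: enriched in a shell at the
#' plasma membrane (`"membrane"`), homogeneously distributed (`"uniform"`), or
#' aggregated into P-granule-like clusters (`"clustered"`).
#'
#' @param mode One of `"membrane"`, `"uniform"`, `"clustered"`.
#' @param membrane_shell Normalized-distance cutoff defining the membrane
#'   shell, as a fraction of the cell's maximum interior distance; in (0, 1].
#'   The default 0.1 matches the outermost 10% distance bin.
#' @param membrane_fraction Fraction of molecules placed inside the shell; the
#'   remainder is placed uniformly in the cell interior beyond the shell, so
#'   `membrane_fraction` is exactly the planted shell fraction that
#'   [membrane_fraction()] recovers (up to binomial noise).
#' @param n_clusters,molecules_per_cluster,cluster_sigma Clustered mode:
#'   number of clusters, molecules per cluster, and the isotropic Gaussian
#'   spread of each cluster in µm.
#' @return An object of class `localization_model`.
#' @export
localization_model <- function(mode = c("membrane", "uniform", "clustered"),
                               membrane_shell = 0.1, membrane_fraction = 1.0,
                               n_clusters = 5L, molecules_per_cluster = 20L,
                               cluster_sigma = 0.15) {
  mode <- match.arg(mode)
  if (membrane_shell <= 0 || membrane_shell > 1)
    stopf("membrane_shell must be in (0, 1]")
  if (membrane_fraction < 0 || membrane_fraction > 1)
    stopf("membrane_fraction must be in [0, 1]")
  if (mode == "clustered" && (n_clusters < 1L || molecules_per_cluster < 1L))
    stopf("clustered mode requires n_clusters >= 1 and molecules_per_cluster >= 1")
  structure(list(mode = mode, membrane_shell = membrane_shell,
                 membrane_fraction = membrane_fraction,
                 n_clusters = as.integer(n_clusters),
                 molecules_per_cluster = as.integer(molecules_per_cluster),
                 cluster_sigma = cluster_sigma),
            class = "localization_model")
}

#' Place ground-truth molecules inside a synthetic embryo
#'
#' Samples `n_molecules` molecule positions inside the cells of `geometry`
#' according to a [localization_model()]. Molecules are allotted to cells in
#' proportion to cell volume. Uniform placement samples cell voxels with equal
#' probability and jitters uniformly within the voxel, so placement is exactly
#' uniform over the voxelized cell volume. Membrane placement draws, per
#' molecule, a Bernoulli(`membrane_fraction`) choice between the membrane
#' shell (normalized distance < `membrane_shell`) and the interior complement.
#' Clustered placement puts `n_clusters * molecules_per_cluster` molecules
#' into Gaussian clusters around uniformly drawn cluster centres; any
#' remaining molecules are uniform singletons (`cluster_id = 0`).
#'
#' The reported `norm_dist` is the normalized membrane distance of each
#' molecule's containing voxel, read from the same [distance_field()] used by
#' the enrichment module, so ground truth and measurement are self-consistent
#' by construction.
#'
#' @param geometry An `embryo_geometry`.
#' @param model A `localization_model`.
#' @param n_molecules Total number of molecules (>= 1). In clustered mode this
#'   must be at least `n_clusters * molecules_per_cluster`.
#' @param seed Integer seed; placement is deterministic given all arguments.
#' @param field Optional precomputed [distance_field()] for `geometry` (saves
#'   recomputation); must use the default per-cell-max normalization.
#' @return A `ground_truth` data frame with columns `mol_id`, `z_um`, `y_um`,
#'   `x_um`, `cell_id`, `norm_dist`, `cluster_id`.
#' @export
place_spots <- function(geometry, model, n_molecules, seed = 1L, field = NULL) {
  stopifnot(inherits(geometry, "embryo_geometry"),
            inherits(model, "localization_model"))
  n_molecules <- as.integer(n_molecules)
  if (n_molecules < 1L) stopf("n_molecules must be >= 1")
  if (is.null(field)) field <- distance_field(geometry$labels, geometry$voxel_size)
  labels <- geometry$labels
  dimv <- dim(labels)
  vs <- geometry$voxel_size

  vox_by_cell <- lapply(seq_len(geometry$stage), function(k) which(labels == k))
  if (any(lengths(vox_by_cell) == 0L)) stopf("placement error: empty cell label")

  # sample voxels from a linear-index pool and jitter uniformly within each
  draw_from <- function(pool, n) {
    pick <- pool[sample.int(length(pool), n, replace = TRUE)]
    idx0 <- arrayInd(pick, dimv) - 1L
    jit <- matrix(runif(3 * n), n, 3)
    list(pos = sweep(idx0 + jit, 2L, vs, "*"), lin = pick)
  }

  with_seed(seed, {
    pos <- matrix(NA_real_, 0, 3); lin <- integer(0)
    cell <- integer(0); clid <- integer(0)

    if (model$mode == "clustered") {
      need <- model$n_clusters * model$molecules_per_cluster
      if (n_molecules < need)
        stopf("clustered mode needs n_molecules >= n_clusters * molecules_per_cluster (%d)",
              need)
      all_vox <- which(labels > 0L)
      # hard-core sampling: condensate centres keep >= 8 sigma apart so
      # distinct clusters stay resolvable; falls back to the best draw if the
      # cell cannot host that spacing
      min_sep <- 8 * model$cluster_sigma
      centres <- integer(0)
      for (ci in seq_len(model$n_clusters)) {
        pick <- NA_integer_
        for (try in 1:500) {
          cand <- all_vox[sample.int(length(all_vox), 1L)]
          if (length(centres) == 0L) { pick <- cand; break }
          cp <- sweep(arrayInd(c(centres, cand), dimv) - 1L + 0.5, 2L, vs, "*")
          dd <- sqrt(rowSums((cp[-nrow(cp), , drop = FALSE] -
                              matrix(cp[nrow(cp), ], nrow(cp) - 1L, 3, byrow = TRUE))^2))
          if (all(dd >= min_sep)) { pick <- cand; break }
          if (try == 500L) pick <- cand
        }
        centres <- c(centres, pick)
      }
      cpos <- sweep(arrayInd(centres, dimv) - 1L + 0.5, 2L, vs, "*")
      ccell <- labels[centres]
      pos <- matrix(NA_real_, need, 3); cell <- integer(need); clid <- integer(need)
      row <- 1L
      for (ci in seq_len(model$n_clusters)) {
        for (m in seq_len(model$molecules_per_cluster)) {
          p <- cpos[ci, ]  # fallback: cluster centre itself
          for (try in 1:200) {
            cand <- cpos[ci, ] + rnorm(3, 0, model$cluster_sigma)
            iv <- floor(cand / vs)
            if (all(iv >= 0) && all(iv < dimv) &&
                labels[iv[1] + dimv[1] * (iv[2] + dimv[2] * iv[3]) + 1] == ccell[ci]) {
              p <- cand; break
            }
          }
          pos[row, ] <- p; cell[row] <- ccell[ci]; clid[row] <- ci
          row <- row + 1L
        }
      }
      extra <- n_molecules - need
      if (extra > 0L) {
        d <- draw_from(all_vox, extra)
        pos <- rbind(pos, d$pos)
        cell <- c(cell, labels[d$lin]); clid <- c(clid, rep(0L, extra))
      }
      lin <- voxel_linear(um_to_voxel(pos, vs, dimv), dimv)
    } else {
      probs <- lengths(vox_by_cell) / sum(lengths(vox_by_cell))
      alloc <- as.vector(stats::rmultinom(1, n_molecules, probs))
      for (k in seq_along(vox_by_cell)) {
        nk <- alloc[k]
        if (nk == 0L) next
        vox <- vox_by_cell[[k]]
        if (model$mode == "uniform") {
          d <- draw_from(vox, nk)
          pk <- d$pos; lk <- d$lin
        } else { # membrane
          nd_vox <- field$norm_dist[vox]
          shell_vox <- vox[nd_vox < model$membrane_shell]
          rest_vox <- vox[nd_vox >= model$membrane_shell]
          if (length(shell_vox) == 0L)
            stopf("placement error: cell %d has no voxels below membrane_shell %.3g",
                  k, model$membrane_shell)
          in_shell <- runif(nk) < model$membrane_fraction
          if (length(rest_vox) == 0L) in_shell[] <- TRUE
          pk <- matrix(NA_real_, nk, 3); lk <- integer(nk)
          if (any(in_shell)) {
            d <- draw_from(shell_vox, sum(in_shell))
            pk[in_shell, ] <- d$pos; lk[in_shell] <- d$lin
          }
          if (any(!in_shell)) {
            d <- draw_from(rest_vox, sum(!in_shell))
            pk[!in_shell, ] <- d$pos; lk[!in_shell] <- d$lin
          }
        }
        pos <- rbind(pos, pk); lin <- c(lin, lk)
        cell <- c(cell, rep(k, nk)); clid <- c(clid, rep(0L, nk))
      }
    }

    gt <- data.frame(mol_id = seq_len(nrow(pos)),
                     z_um = pos[, 1], y_um = pos[, 2], x_um = pos[, 3],
                     cell_id = as.integer(cell),
                     norm_dist = field$norm_dist[lin],
                     cluster_id = as.integer(clid))
    class(gt) <- c("ground_truth", "data.frame")
    gt
  })
}
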