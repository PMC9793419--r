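# End-to-end pipeline: simulate -> detect -> decompose -> profile -> stats,
# driven by a YAML config.

log_msg <- function(level, fmt, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  level, sprintf(fmt, ...)))
}

#' Default pipeline run configuration
#'
#' Returns the configuration list driving [run_simulate()], [run_quantify()]
#' and [run_report()]; write it to YAML with [write_run_config()] and edit.
#' Blocks: `simulation` (embryo count, stage, localization model, molecule
#' count, grid, noise, seed, condition label), `detection` (threshold in
#' robust-noise SDs, minimum separation µm, fit window voxels, PSF prior µm),
#' `enrichment` (bins, membrane cutoff, normalization mode) and `stats`
#' (classification threshold, minimum spots).
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  list(
    simulation = list(
      n_embryos = 2L, stage = 4L, condition = "membrane",
      mode = "membrane", membrane_fraction = 0.9, membrane_shell = 0.1,
      n_clusters = 5L, molecules_per_cluster = 20L, cluster_sigma = 0.15,
      n_molecules = 300L,
      shape = c(32L, 192L, 192L), voxel_size = c(0.2, 0.1, 0.1),
      psf_sigma = c(0.35, 0.13, 0.13),
      snr = 8, background = 100, poisson = TRUE, gaussian_sd = 10,
      seed = 1L),
    detection = list(threshold = 5, min_separation = 0.3,
                     fit_window = c(7L, 7L, 7L), psf_sigma = c(0.35, 0.13, 0.13)),
    enrichment = list(n_bins = 10L, cutoff = 0.1,
                      normalization = "per_cell_max"),
    stats = list(threshold = 1.5, min_spots = 50L),
    decomposition = list(k_max = 20L, link_radius = 0.3, min_molecules = 3L))
}

#' Read and write pipeline configurations as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()`: validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(modifyList(default_run_config(), cfg))
}

#' @rdname read_run_config
#' @param config Configuration list.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
validate_run_config <- function(config) {
  sim <- config$simulation
  if (!sim$stage %in% c(1L, 2L, 4L, 8L))
    stopf("config error in simulation$stage: must be one of 1, 2, 4, 8 (got %s)", sim$stage)
  if (!sim$mode %in% c("membrane", "uniform", "clustered"))
    stopf("config error in simulation$mode: must be membrane, uniform or clustered")
  if (sim$n_embryos < 1L) stopf("config error in simulation$n_embryos: must be >= 1")
  if (sim$n_molecules < 1L) stopf("config error in simulation$n_molecules: must be >= 1")
  if (is.null(sim$seed)) stopf("config error: simulation$seed is required")
  if (config$detection$threshold <= 0)
    stopf("config error in detection$threshold: must be > 0")
  if (config$enrichment$n_bins < 2L)
    stopf("config error in enrichment$n_bins: must be >= 2")
  config
}

sim_model <- function(sim) {
  localization_model(sim$mode,
                     membrane_shell = sim$membrane_shell,
                     membrane_fraction = sim$membrane_fraction,
                     n_clusters = sim$n_clusters,
                     molecules_per_cluster = sim$molecules_per_cluster,
                     cluster_sigma = sim$cluster_sigma)
}

#' Simulate a cohort of synthetic embryos to disk
#'
#' Generates `n_embryos` ground-truthed embryos under the configured
#' geometry, localization model and noise, and writes per embryo: the
#' multi-channel OME-TIFF stack, the label-mask TIFF and the ground-truth
#' CSV, plus a `manifest.json` listing every output with its seed. Embryo `i`
#' uses seed `simulation$seed + i - 1`, so reruns are byte-identical.
#'
#' @param config Configuration list (see [default_run_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Optional override of `simulation$seed`.
#' @return The manifest list, invisibly.
#' @export
run_simulate <- function(config = default_run_config(), out_dir, seed = NULL) {
  config <- validate_run_config(config)
  sim <- config$simulation
  if (!is.null(seed)) sim$seed <- as.integer(seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory %s", out_dir)
  model <- sim_model(sim)
  amp <- amplitude_for_snr(sim$snr, sim$background,
                           list(poisson = sim$poisson, gaussian_sd = sim$gaussian_sd))
  entries <- list()
  for (i in seq_len(sim$n_embryos)) {
    sd_i <- sim$seed + i - 1L
    id <- sprintf("embryo%03d", i)
    log_msg("INFO", "simulating %s (seed %d)", id, sd_i)
    geom <- generate_geometry(sim$stage, sim$shape, sim$voxel_size, seed = sd_i)
    field <- distance_field(geom$labels, geom$voxel_size)
    truth <- place_spots(geom, model, sim$n_molecules, seed = sd_i, field = field)
    stack <- render_stack(geom, truth, psf_sigma = sim$psf_sigma,
                          spot_amplitude = amp,
                          noise = list(poisson = sim$poisson,
                                       gaussian_sd = sim$gaussian_sd),
                          background = sim$background, seed = sd_i)
    files <- list(stack = file.path(out_dir, paste0(id, "_stack.tif")),
                  labels = file.path(out_dir, paste0(id, "_labels.tif")),
                  truth = file.path(out_dir, paste0(id, "_truth.csv")))
    write_stack(stack, files$stack)
    write_labels(geom$labels, files$labels)
    write_ground_truth(truth, files$truth)
    entries[[i]] <- list(id = id, seed = sd_i, stage = sim$stage,
                         condition = sim$condition,
                         files = lapply(files, basename))
  }
  manifest <- list(created = format(Sys.time()), config = config,
                   embryos = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_msg("INFO", "wrote %d embryos + manifest to %s", length(entries), out_dir)
  invisible(manifest)
}

#' Quantify simulated or annotated stacks into spot tables and profiles
#'
#' For every embryo in the manifest: detects spots on the smFISH channel,
#' estimates the reference single molecule, decomposes intensities into
#' molecule counts, computes the membrane-distance enrichment profile against
#' the label mask, and writes `<id>_spots.csv` (detected spots with counts,
#' cell assignment, normalized distance and bin) and `<id>_profile.csv`
#' (`n_bins` rows per cell plus pooled). A records table
#' (`records.csv`) collects one row per embryo: molecule totals, cluster
#' count, pooled bin-1 frequency, membrane fraction and localization call.
#' Embryos with a missing label mask are skipped with a warning and counted
#' in the returned `n_skipped`.
#'
#' @param in_dir Directory holding `manifest.json` and the simulated files.
#' @param out_dir Output directory (default `in_dir`).
#' @param config Optional configuration override; defaults to the manifest's.
#' @return List with `records` (data frame) and `n_skipped`, invisibly.
#' @export
run_quantify <- function(in_dir, out_dir = in_dir, config = NULL) {
  mpath <- file.path(in_dir, "manifest.json")
  if (!file.exists(mpath)) stopf("no manifest.json in %s", in_dir)
  manifest <- jsonlite::fromJSON(mpath, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
  config <- validate_run_config(config %||% modifyList(default_run_config(),
                                                       manifest$config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  det <- config$detection; enr <- config$enrichment
  dec <- config$decomposition; stt <- config$stats
  records <- list(); n_skipped <- 0L
  for (e in manifest$embryos) {
    spath <- file.path(in_dir, e$files$stack)
    lpath <- file.path(in_dir, e$files$labels)
    if (!file.exists(lpath) || !file.exists(spath)) {
      log_msg("WARN", "skipping %s: missing stack or annotation", e$id)
      n_skipped <- n_skipped + 1L
      next
    }
    log_msg("INFO", "quantifying %s", e$id)
    stack <- read_stack(spath)
    labels <- read_labels(lpath)
    vs <- stack$voxel_size
    spots <- detect_spots(stack$channels$smfish, vs,
                          threshold = det$threshold,
                          min_separation = det$min_separation,
                          fit_window = det$fit_window,
                          psf_sigma = det$psf_sigma)
    counted <- if (nrow(spots) > 0) {
      decompose_spots(spots, estimate_reference(spots), k_max = dec$k_max)
    } else spots
    field <- distance_field(labels, vs, normalization = enr$normalization,
                            fixed_radius = enr$fixed_radius)
    prof <- assign_and_profile(counted, field, labels, n_bins = enr$n_bins)
    call <- classify_localization(prof, threshold = stt$threshold,
                                  min_spots = stt$min_spots)
    mfrac <- tryCatch(membrane_fraction(prof, cutoff = enr$cutoff),
                      error = function(e2) NA_real_)
    ncl <- count_clusters(counted, link_radius = dec$link_radius,
                          min_molecules = dec$min_molecules)
    # annotate spots with cell / distance / bin for the spot table
    d <- dim(labels)
    if (nrow(counted) > 0) {
      idx <- um_to_voxel(as.matrix(counted[, c("z_um", "y_um", "x_um")]), vs, d)
      lin <- voxel_linear(idx, d)
      counted$cell_id <- labels[lin]
      counted$norm_dist <- field$norm_dist[lin]
      counted$bin <- ifelse(is.na(counted$norm_dist), NA_integer_,
                            pmin(floor(counted$norm_dist * enr$n_bins),
                                 enr$n_bins - 1L) + 1L)
    }
    write_table_csv(as.data.frame(counted),
                    file.path(out_dir, paste0(e$id, "_spots.csv")))
    write_table_csv(as.data.frame(prof),
                    file.path(out_dir, paste0(e$id, "_profile.csv")))
    records[[length(records) + 1L]] <- data.frame(
      embryo_id = e$id, stage = e$stage, condition = e$condition,
      n_spots = nrow(counted),
      total_molecules = if (nrow(counted)) sum(counted$molecule_count) else 0L,
      cluster_count = as.integer(ncl),
      bin1_freq = attr(call, "bin1_freq") %||% NA_real_,
      membrane_fraction = mfrac,
      n_discarded = attr(prof, "n_discarded"),
      call = as.character(call))
  }
  if (length(records) == 0L) stopf("no embryos quantified")
  rec <- do.call(rbind, records)
  write_table_csv(rec, file.path(out_dir, "records.csv"))
  log_msg("INFO", "quantified %d embryos (%d skipped)", nrow(rec), n_skipped)
  invisible(list(records = rec, n_skipped = n_skipped))
}

#' Summarize records into condition proportions and Welch comparisons
#'
#' Groups per-embryo records by stage and condition, reports
#' localized/unlocalized proportions, and runs pairwise Welch two-sample
#' t-tests on the pooled bin-1 frequencies between conditions (with star
#' annotations). With a single condition the comparisons are skipped with a
#' notice.
#'
#' @param records A records data frame from [run_quantify()], or the path(s)
#'   of `records.csv` file(s) to combine.
#' @param out_dir Optional directory for `summary.csv` / `comparisons.csv`.
#' @return List with `summary` and `comparisons` data frames.
#' @export
run_report <- function(records, out_dir = NULL) {
  if (is.character(records))
    records <- do.call(rbind, lapply(records, read.csv))
  if (!is.data.frame(records) || nrow(records) == 0L)
    stopf("empty records")
  summ <- condition_summary(records, by = c("stage", "condition"))
  conds <- unique(records$condition)
  comps <- NULL
  if (length(conds) < 2L) {
    log_msg("INFO", "single condition: comparisons skipped")
  } else {
    rows <- list()
    for (i in seq_along(conds)) for (j in seq_along(conds)) {
      if (j <= i) next
      va <- records$bin1_freq[records$condition == conds[i]]
      vb <- records$bin1_freq[records$condition == conds[j]]
      va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
      if (length(va) < 2L || length(vb) < 2L) next
      wt <- welch_test(va, vb, labels = c(conds[i], conds[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        group_a = conds[i], group_b = conds[j],
        mean_a = wt$means[1], mean_b = wt$means[2],
        n_a = wt$n[1], n_b = wt$n[2],
        t = wt$statistic, df = wt$df, p_value = wt$p_value,
        stars = wt$stars)
    }
    comps <- if (length(rows)) do.call(rbind, rows) else NULL
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_table_csv(summ, file.path(out_dir, "summary.csv"))
    if (!is.null(comps)) write_table_csv(comps, file.path(out_dir, "comparisons.csv"))
  }
  list(summary = summ, comparisons = comps)
}
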