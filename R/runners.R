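# Config-driven entry points tying the stages together. Each runner
# accepts a config as a YAML/JSON file path or an R list, writes its
# outputs plus the fully resolved config into an output directory, and
# logs to stderr. A thin command-line wrapper over these functions ships
# in inst/cli/edukinetics.R.

.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file")
  config
}

.check_keys <- function(block, allowed, where) {
  bad <- setdiff(names(block), allowed)
  if (length(bad))
    stop(sprintf("unknown config key%s in %s: %s",
                 if (length(bad) > 1) "s" else "", where,
                 paste(bad, collapse = ", ")))
  block
}

.resolve_seed <- function(config) {
  if (is.null(config$seed)) {
    message("no seed in config; using deterministic default seed 1")
    config$seed <- 1L
  }
  config
}

.write_resolved <- function(config, out_dir, name) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(config, file.path(out_dir, name))
}

.params_from_config <- function(block) {
  .check_keys(block, c("tc_h", "ts_h", "gf_percent", "g1_fraction"),
              "population")
  cell_cycle_params(tc = block$tc_h, ts = block$ts_h,
                    gf = block$gf_percent,
                    g1_fraction = if (is.null(block$g1_fraction)) 0.5
                                  else block$g1_fraction)
}

.protocol_from_config <- function(block) {
  .check_keys(block, c("kind", "exposure_start_h", "exposure_duration_h",
                       "sampling_times_h", "detection_threshold"),
              "protocol")
  labeling_protocol(
    kind = block$kind,
    exposure_start = if (is.null(block$exposure_start_h)) 0
                     else block$exposure_start_h,
    exposure_duration = block$exposure_duration_h,
    sampling_times = as.numeric(block$sampling_times_h),
    detection_threshold = if (is.null(block$detection_threshold)) 1 / 16
                          else block$detection_threshold)
}

#' Run a labeling-experiment simulation from a config
#'
#' Config keys: `population` (`tc_h`, `ts_h`, `gf_percent`,
#' `g1_fraction`), `protocol` (`kind`, `exposure_start_h`,
#' `exposure_duration_h`, `sampling_times_h`, `detection_threshold`),
#' `n_cells`, `n_specimens`, `seed`, optional `age_distribution` and
#' `mode`. Writes `counts.tsv` and the resolved config to `out_dir`.
#'
#' @param config List, or path to a YAML/JSON config file.
#' @param out_dir Output directory.
#' @return The simulated specimen-count table, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  config <- .resolve_seed(.load_config(config))
  .check_keys(config, c("population", "protocol", "n_cells",
                        "n_specimens", "seed", "age_distribution",
                        "mode"), "simulate config")
  if (is.null(config$n_specimens) || config$n_specimens < 1)
    stop("config error: 'n_specimens' must be >= 1")
  params <- .params_from_config(config$population)
  protocol <- .protocol_from_config(config$protocol)
  tab <- simulate_experiment(
    params, protocol, n_cells = config$n_cells,
    n_specimens = config$n_specimens, seed = config$seed,
    age_distribution = if (is.null(config$age_distribution)) "uniform"
                       else config$age_distribution,
    mode = if (is.null(config$mode)) "renewal" else config$mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_specimen_counts(tab, file.path(out_dir, "counts.tsv"))
  .write_resolved(config, out_dir, "simulate_config_resolved.yaml")
  message(sprintf("wrote %d specimen counts to %s", nrow(tab),
                  file.path(out_dir, "counts.tsv")))
  invisible(tab)
}

#' Fit the cumulative-labeling model to a table on disk
#'
#' Reads a specimen-count table, fits [fit_cumulative], optionally
#' bootstraps confidence intervals, and writes `fit.json` (plus
#' `fit_plot.pdf` when `plot = TRUE`) to `out_dir`.
#'
#' @param table_path Path to a specimen-count table
#'   (see [read_specimen_counts]).
#' @param out_dir Output directory.
#' @param n_boot Bootstrap resamples for [bootstrap_ci]; 0 disables.
#' @param level Confidence level for the bootstrap intervals.
#' @param seed Seed for the bootstrap.
#' @param plot Also write a curve plot as PDF.
#' @return The `cumulative_fit`, invisibly.
#' @export
run_fit <- function(table_path, out_dir, n_boot = 0L, level = 0.95,
                    seed = 1L, plot = FALSE) {
  tab <- read_specimen_counts(table_path)
  fit <- fit_cumulative(tab)
  if (n_boot > 0L && fit$converged)
    fit <- bootstrap_ci(fit, n_boot = n_boot, level = level, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_fit_json(fit, file.path(out_dir, "fit.json"))
  if (plot) {
    grDevices::pdf(file.path(out_dir, "fit_plot.pdf"), width = 6,
                   height = 4.5)
    plot(fit)
    grDevices::dev.off()
  }
  message(sprintf("fit written to %s (converged: %s)",
                  file.path(out_dir, "fit.json"), fit$converged))
  invisible(fit)
}

#' Group statistics for a specimen-count table on disk
#'
#' Summarises labeling index and total nuclei count by group (default:
#' sampling time), runs the Kruskal-Wallis omnibus test on the labeling
#' index and pairwise Mann-Whitney post-hoc tests, and writes
#' `summary.tsv` plus `pairwise.json` to `out_dir`.
#'
#' @param table_path Path to a specimen-count table.
#' @param out_dir Output directory.
#' @param group_by Grouping column, default `"time_h"`.
#' @param alpha Pairwise significance threshold (default 0.005).
#' @param p_adjust Multiplicity adjustment, default `"none"`.
#' @return List with `summary`, `kruskal`, `pairwise`, invisibly.
#' @export
run_stats <- function(table_path, out_dir, group_by = "time_h",
                      alpha = 0.005, p_adjust = "none") {
  tab <- read_specimen_counts(table_path)
  if (!group_by %in% names(tab))
    stop("config error: grouping column '", group_by, "' not in table")
  g <- factor(tab[[group_by]], levels = unique(tab[[group_by]]))
  li_sum <- group_summary(tab$li_percent, g)
  cells_sum <- group_summary(tab$n_total, g)
  summ <- data.frame(stage = li_sum$group, n = li_sum$n,
                     mean_li = li_sum$mean, sem_li = li_sum$sem,
                     mean_cells = cells_sum$mean,
                     sem_cells = cells_sum$sem)
  groups <- split(tab$li_percent, g)
  kw <- if (length(groups) >= 2L) kruskal_wallis(groups) else NULL
  pw <- if (length(groups) >= 2L)
    mann_whitney_pairwise(groups, alpha = alpha, p_adjust = p_adjust)
    else NULL
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(summ, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(pw))
    jsonlite::write_json(
      list(kruskal_wallis = list(H = unname(kw$statistic),
                                 p_value = kw$p_value,
                                 method = kw$method),
           alpha = alpha, p_adjust = p_adjust,
           groups = rownames(pw$p_value),
           p_values = pw$p_value, significant = pw$significant),
      file.path(out_dir, "pairwise.json"), auto_unbox = TRUE,
      digits = NA, matrix = "rowmajor")
  message("statistics written to ", out_dir)
  invisible(list(summary = summ, kruskal = kw, pairwise = pw))
}

#' Synthesize nuclei stacks from a config
#'
#' Config keys: `n_nuclei`, `labeled_fraction`, `nucleus_diameter_um`,
#' `shape`, `voxel_size_um`, `noise_sd`, `min_separation_um`, `seed`.
#' Writes the stack under the prefix `out_dir/stack` and the resolved
#' config.
#'
#' @param config List or path to YAML/JSON.
#' @param out_dir Output directory.
#' @return The `nuclei_stack`, invisibly.
#' @export
run_imagesim <- function(config, out_dir) {
  config <- .resolve_seed(.load_config(config))
  .check_keys(config, c("n_nuclei", "labeled_fraction",
                        "nucleus_diameter_um", "shape", "voxel_size_um",
                        "noise_sd", "min_separation_um", "seed"),
              "imagesim config")
  args <- config
  args$seed <- as.integer(config$seed)
  stack <- do.call(synthesize_stack, args)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(stack, file.path(out_dir, "stack"))
  .write_resolved(config, out_dir, "imagesim_config_resolved.yaml")
  message("stack written under prefix ", file.path(out_dir, "stack"))
  invisible(stack)
}

#' Count a stack on disk and compute its labeling index
#'
#' Reads the stack written by [run_imagesim] (or [write_stack]), detects
#' nuclei in both channels, and writes per-channel detection tables plus
#' `li.json` with the matched counts.
#'
#' @param prefix Stack path prefix (as passed to [write_stack]).
#' @param out_dir Output directory.
#' @param expected_diameter_um Expected nuclear diameter in microns.
#' @param threshold_nuclear,threshold_label Relative thresholds.
#' @return The one-row labeling-index data frame, invisibly.
#' @export
run_count <- function(prefix, out_dir, expected_diameter_um,
                      threshold_nuclear = 0.2, threshold_label = 0.2) {
  stack <- read_stack(prefix)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in c("nuclear", "label")) {
    det <- count_nuclei(stack, ch, expected_diameter_um,
                        threshold = if (ch == "nuclear") threshold_nuclear
                                    else threshold_label)
    write_detections(det, file.path(out_dir,
                                    paste0("detections_", ch, ".tsv")))
  }
  li <- li_from_stack(stack, expected_diameter_um, threshold_nuclear,
                      threshold_label)
  jsonlite::write_json(as.list(li[1, ]), file.path(out_dir, "li.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  message("counts written to ", out_dir)
  invisible(li)
}
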