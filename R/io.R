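# Table, stack and result I/O. All tables are UTF-8 tab-delimited text
# with a header; units are fixed in the column names (time_h, li_percent,
# *_um) to prevent silent unit drift.

.specimen_cols <- c("specimen_id", "time_h", "n_total", "n_labeled",
                    "li_percent")

#' Read a specimen-count table
#'
#' Reads a tab-delimited table of per-specimen nuclei counts with columns
#' `specimen_id`, `time_h`, `n_total`, `n_labeled`, `li_percent`. Lines
#' starting with `#` are treated as comments. `li_percent` is recomputed
#' from the counts when both are present and checked for consistency;
#' tables carrying only `time_h` and `li_percent` (e.g. published
#' per-time-point means) are accepted with the count columns set to `NA`.
#'
#' @param path Path to the table.
#' @return A data frame with the five specimen-count columns.
#' @export
read_specimen_counts <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("time_h", "li_percent") %in% names(tab)) &&
      !all(c("time_h", "n_total", "n_labeled") %in% names(tab)))
    stop("malformed table ", path,
         ": need columns time_h plus li_percent or n_total/n_labeled")
  if (is.null(tab$specimen_id))
    tab$specimen_id <- paste0("row", seq_len(nrow(tab)))
  if (is.null(tab$n_total)) tab$n_total <- NA_integer_
  if (is.null(tab$n_labeled)) tab$n_labeled <- NA_integer_
  if (is.null(tab$li_percent))
    tab$li_percent <- labeling_index(tab$n_labeled, tab$n_total)
  ok <- !is.na(tab$n_total) & !is.na(tab$n_labeled)
  if (any(ok)) {
    li <- labeling_index(tab$n_labeled[ok], tab$n_total[ok])
    if (any(abs(li - tab$li_percent[ok]) > 1e-6))
      stop("inconsistent li_percent in ", path)
  }
  tab[, .specimen_cols]
}

#' Write a specimen-count table
#'
#' @param tab Data frame with the specimen-count columns.
#' @param path Output path (tab-delimited text).
#' @return `path`, invisibly.
#' @export
write_specimen_counts <- function(tab, path) {
  stopifnot(all(c("time_h", "li_percent") %in% names(tab)))
  for (col in .specimen_cols) if (is.null(tab[[col]])) tab[[col]] <- NA
  utils::write.table(tab[, .specimen_cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a cumulative fit as JSON
#'
#' Writes the fitted parameters (`gf_percent`, `ts_h`, `tc_h`,
#' `breakpoint_h`, `intercept_a`, `slope_b`), `sse`, `n_points`,
#' `converged` and any bootstrap intervals.
#'
#' @param fit A `cumulative_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "cumulative_fit"))
  cf <- as.list(coef(fit))
  out <- c(cf, list(sse = fit$sse, n_points = fit$n_points,
                    converged = fit$converged))
  if (!fit$converged) out$gf_lower_bound <- fit$gf_lower_bound
  if (!is.null(fit$ci) && nrow(fit$ci$intervals) > 0) {
    ints <- fit$ci$intervals
    out$ci <- list(level = fit$ci$level, n_boot = fit$ci$n_boot,
                   lower = as.list(stats::setNames(ints[, "lower"],
                                                   rownames(ints))),
                   upper = as.list(stats::setNames(ints[, "upper"],
                                                   rownames(ints))))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write / read a two-channel nuclei stack
#'
#' The two channels are written as separate multi-page 32-bit float TIFF
#' files (`<prefix>_nuclear.tif`, `<prefix>_label.tif`, one page per
#' optical plane), intensities scaled into \[0, 1\] by the recorded
#' `intensity_scale`. Voxel size, the scale factor and any ground truth
#' go into plain-text sidecars (`<prefix>_meta.yaml`,
#' `<prefix>_truth.tsv`).
#'
#' @param stack A `nuclei_stack`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_stack <- function(stack, prefix) {
  stopifnot(inherits(stack, "nuclei_stack"))
  scale <- max(1, max(stack$channels$nuclear), max(stack$channels$label))
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]] / scale
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
    tiff::writeTIFF(pages, paste0(prefix, "_", ch, ".tif"),
                    bits.per.sample = 32L)
  }
  yaml::write_yaml(list(voxel_size_um = as.numeric(stack$voxel_size_um),
                        intensity_scale = scale,
                        shape = dim(stack$channels$nuclear)),
                   paste0(prefix, "_meta.yaml"))
  if (!is.null(stack$ground_truth))
    utils::write.table(stack$ground_truth, paste0(prefix, "_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_stack
#' @export
read_stack <- function(prefix) {
  meta_path <- paste0(prefix, "_meta.yaml")
  if (!file.exists(meta_path)) stop("no stack metadata at ", meta_path)
  meta <- yaml::read_yaml(meta_path)
  channels <- lapply(c(nuclear = "nuclear", label = "label"), function(ch) {
    pages <- tiff::readTIFF(paste0(prefix, "_", ch, ".tif"), all = TRUE)
    a <- array(0, unlist(meta$shape))
    for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
    a * meta$intensity_scale
  })
  truth_path <- paste0(prefix, "_truth.tsv")
  gt <- if (file.exists(truth_path))
    utils::read.delim(truth_path, stringsAsFactors = FALSE) else NULL
  structure(list(channels = channels,
                 voxel_size_um = as.numeric(unlist(meta$voxel_size_um)),
                 ground_truth = gt),
            class = "nuclei_stack")
}

#' Write detected centers as a delimited table
#'
#' @param detection A `detection_result` from [count_nuclei].
#' @param path Output path; columns `x_um`, `y_um`, `z_um`, `channel`.
#' @return `path`, invisibly.
#' @export
write_detections <- function(detection, path) {
  stopifnot(inherits(detection, "detection_result"))
  cu <- detection$centers_um
  out <- data.frame(x_um = cu[, "x_um"], y_um = cu[, "y_um"],
                    z_um = cu[, "z_um"], channel = detection$channel)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
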