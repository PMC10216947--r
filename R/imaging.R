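# 3D helpers -----------------------------------------------------------

# shift a 3D array by k voxels along an axis, zero-filling
.shift3 <- function(a, k, axis) {
  if (k == 0L) return(a)
  d <- dim(a)
  out <- array(0, d)
  n <- d[axis]
  if (abs(k) >= n) return(out)
  src <- if (k > 0) 1:(n - k) else (1 - k):n
  dst <- if (k > 0) (1 + k):n else 1:(n + k)
  ix <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  src_ix <- dst_ix <- ix
  src_ix[[axis]] <- src
  dst_ix[[axis]] <- dst
  out[dst_ix[[1]], dst_ix[[2]], dst_ix[[3]]] <-
    a[src_ix[[1]], src_ix[[2]], src_ix[[3]]]
  out
}

# separable Gaussian smoothing; sigma_vox per axis, truncated at 3 sigma
.gauss3 <- function(a, sigma_vox) {
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(-r:r, sd = s)
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (j in seq_along(w))
      acc <- acc + w[j] * .shift3(a, j - r - 1L, axis)
    a <- acc
  }
  a
}

# separable box maximum filter with per-axis radius (voxels)
.boxmax3 <- function(a, r_vox) {
  for (axis in 1:3) {
    r <- r_vox[axis]
    if (r < 1L) next
    acc <- a
    for (k in seq_len(r)) {
      acc <- pmax(acc, .shift3(a, k, axis), .shift3(a, -k, axis))
    }
    a <- acc
  }
  a
}

#' Synthesize a two-channel 3D nuclei stack with known ground truth
#'
#' Renders `n_nuclei` nuclei as 3D Gaussian blobs
#' (`sigma = diameter / 2.355`, so the full width at half maximum equals
#' the nuclear diameter) into a nuclear-stain channel, and a stratified
#' subset of exactly `round(n_nuclei * labeled_fraction)` of them into a
#' label (EdU) channel, then adds Gaussian noise. Centers are placed by
#' rejection sampling with a minimum pairwise separation inside a margin
#' of one nucleus radius from the stack faces. The default geometry
#' mimics a confocal acquisition: 45 optical planes at 1.5 um axial
#' step with finer (0.5 um) lateral sampling.
#'
#' @param n_nuclei Number of nuclei to place.
#' @param labeled_fraction Fraction of nuclei also rendered in the label
#'   channel, in \[0, 1\]; the labeled subset is chosen at random but its
#'   size is exact.
#' @param nucleus_diameter_um Nuclear diameter in microns.
#' @param shape Grid size as (planes, rows, columns).
#' @param voxel_size_um Voxel edge lengths in microns, (plane, row,
#'   column) order.
#' @param noise_sd Standard deviation of additive Gaussian noise
#'   (blob peak amplitude is 1, so `noise_sd = 0.2` gives a peak SNR of
#'   5). Negative intensities are clipped to zero.
#' @param min_separation_um Minimum distance between nucleus centers in
#'   microns; default one nuclear diameter.
#' @param seed Optional integer seed.
#' @return An object of class `nuclei_stack`: `channels` (list of two 3D
#'   arrays `nuclear`, `label`), `voxel_size_um`, and `ground_truth`
#'   (data frame of voxel-centred 0-based center coordinates
#'   `z_vox`, `y_vox`, `x_vox`, micron coordinates, and a `labeled`
#'   flag).
#' @export
synthesize_stack <- function(n_nuclei, labeled_fraction,
                             nucleus_diameter_um = 4,
                             shape = c(45L, 128L, 128L),
                             voxel_size_um = c(1.5, 0.5, 0.5),
                             noise_sd = 0,
                             min_separation_um = nucleus_diameter_um,
                             seed = NULL) {
  stopifnot(n_nuclei >= 1, labeled_fraction >= 0, labeled_fraction <= 1,
            length(shape) == 3L, length(voxel_size_um) == 3L)
  if (!is.null(seed)) set.seed(seed)
  extent <- shape * voxel_size_um
  margin <- nucleus_diameter_um / 2
  if (any(extent <= 2 * margin))
    stop("stack too small for the requested nucleus diameter")

  centers <- matrix(NA_real_, n_nuclei, 3L)
  placed <- 0L
  budget <- 200L * n_nuclei
  while (placed < n_nuclei && budget > 0L) {
    budget <- budget - 1L
    cand <- margin + stats::runif(3) * (extent - 2 * margin)
    ok <- placed == 0L ||
      min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                          cand)^2))) >= min_separation_um
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- cand
    }
  }
  if (placed < n_nuclei)
    stop("density error: placement budget exhausted; reduce n_nuclei or min_separation_um")

  n_lab <- as.integer(round(n_nuclei * labeled_fraction))
  labeled <- rep(FALSE, n_nuclei)
  labeled[sample.int(n_nuclei, n_lab)] <- TRUE

  sigma_um <- nucleus_diameter_um / 2.355
  sigma_vox <- sigma_um / voxel_size_um
  render <- function(which_rows) {
    a <- array(0, shape)
    for (i in which_rows) {
      cv <- centers[i, ] / voxel_size_um   # 0-based voxel coordinates
      win <- lapply(1:3, function(ax) {
        r <- ceiling(3 * sigma_vox[ax])
        lo <- max(0L, floor(cv[ax] - r))
        hi <- min(shape[ax] - 1L, ceiling(cv[ax] + r))
        lo:hi
      })
      gz <- exp(-0.5 * ((win[[1]] - cv[1]) / sigma_vox[1])^2)
      gy <- exp(-0.5 * ((win[[2]] - cv[2]) / sigma_vox[2])^2)
      gx <- exp(-0.5 * ((win[[3]] - cv[3]) / sigma_vox[3])^2)
      blob <- outer(gz, outer(gy, gx))
      a[win[[1]] + 1L, win[[2]] + 1L, win[[3]] + 1L] <-
        a[win[[1]] + 1L, win[[2]] + 1L, win[[3]] + 1L] + blob
    }
    a
  }
  nuclear <- render(seq_len(n_nuclei))
  label <- if (n_lab > 0L) render(which(labeled)) else array(0, shape)
  if (noise_sd > 0) {
    nuclear <- nuclear + array(stats::rnorm(prod(shape), 0, noise_sd), shape)
    label <- label + array(stats::rnorm(prod(shape), 0, noise_sd), shape)
  }
  nuclear[nuclear < 0] <- 0
  label[label < 0] <- 0

  gt <- data.frame(z_vox = centers[, 1] / voxel_size_um[1],
                   y_vox = centers[, 2] / voxel_size_um[2],
                   x_vox = centers[, 3] / voxel_size_um[3],
                   z_um = centers[, 1], y_um = centers[, 2],
                   x_um = centers[, 3], labeled = labeled)
  structure(list(channels = list(nuclear = nuclear, label = label),
                 voxel_size_um = voxel_size_um, ground_truth = gt),
            class = "nuclei_stack")
}

#' @export
print.nuclei_stack <- function(x, ...) {
  d <- dim(x$channels$nuclear)
  cat(sprintf("Two-channel nuclei stack: %d x %d x %d voxels (%.2g x %.2g x %.2g um)\n",
              d[1], d[2], d[3], x$voxel_size_um[1], x$voxel_size_um[2],
              x$voxel_size_um[3]))
  if (!is.null(x$ground_truth))
    cat(sprintf("  ground truth: %d nuclei, %d labeled\n",
                nrow(x$ground_truth), sum(x$ground_truth$labeled)))
  invisible(x)
}

#' Count nuclei in one channel by diameter-parameterised blob detection
#'
#' Emulates a spot-detection workflow: the channel is band-pass filtered
#' at the expected nuclear scale (difference of Gaussians,
#' `sigma = diameter / 2.355` and `1.6 sigma`), local maxima are
#' extracted with a minimum separation of half the expected diameter, and
#' maxima below `threshold` times the strongest band-pass response are
#' discarded. Deterministic; a blank channel yields zero detections.
#'
#' @param stack A [synthesize_stack] result (or a `nuclei_stack` read
#'   from disk).
#' @param channel `"nuclear"` or `"label"`.
#' @param expected_diameter_um Expected nuclear diameter in microns;
#'   must span at least 2 voxels on every axis.
#' @param threshold Relative intensity threshold in (0, 1).
#' @return An object of class `detection_result`: `centers_vox`
#'   (0-based, (plane, row, column)), `centers_um`, `n_detected`,
#'   `channel`, `threshold_used`.
#' @export
count_nuclei <- function(stack, channel = c("nuclear", "label"),
                         expected_diameter_um, threshold = 0.2) {
  stopifnot(inherits(stack, "nuclei_stack"))
  channel <- match.arg(channel)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)")
  vox <- stack$voxel_size_um
  if (any(expected_diameter_um / vox < 2))
    stop("expected diameter must span at least 2 voxels on every axis")
  a <- stack$channels[[channel]]
  sigma_vox <- (expected_diameter_um / 2.355) / vox
  bp <- .gauss3(a, sigma_vox) - .gauss3(a, 1.6 * sigma_vox)
  peak <- max(bp)
  empty <- structure(list(centers_vox = matrix(numeric(0), 0, 3),
                          centers_um = matrix(numeric(0), 0, 3),
                          n_detected = 0L, channel = channel,
                          threshold_used = threshold),
                     class = "detection_result")
  if (peak <= 0) return(empty)
  r_vox <- pmax(1L, as.integer(round((expected_diameter_um / 2) / vox)))
  dil <- .boxmax3(bp, r_vox)
  keep <- which(bp >= dil & bp >= threshold * peak, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(empty)
  vals <- bp[keep]
  ord <- order(-vals, keep[, 1], keep[, 2], keep[, 3])
  keep <- keep[ord, , drop = FALSE]
  cen_um <- sweep(keep - 1, 2, vox, `*`)
  # greedy suppression: enforce pairwise separation >= half diameter
  acc <- logical(nrow(keep))
  for (i in seq_len(nrow(keep))) {
    if (!any(acc)) { acc[i] <- TRUE; next }
    dmin <- min(sqrt(colSums((t(cen_um[acc, , drop = FALSE]) -
                                cen_um[i, ])^2)))
    if (dmin >= expected_diameter_um / 2) acc[i] <- TRUE
  }
  centers_vox <- keep[acc, , drop = FALSE] - 1
  colnames(centers_vox) <- c("z_vox", "y_vox", "x_vox")
  centers_um <- cen_um[acc, , drop = FALSE]
  colnames(centers_um) <- c("z_um", "y_um", "x_um")
  structure(list(centers_vox = centers_vox, centers_um = centers_um,
                 n_detected = nrow(centers_vox), channel = channel,
                 threshold_used = threshold),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("%d nuclei detected in the %s channel (threshold %.2g)\n",
              x$n_detected, x$channel, x$threshold_used))
  invisible(x)
}

# greedy nearest-neighbour matching of two micron-coordinate sets within
# a radius; returns indices into `b` for each row of `a` (NA = unmatched)
.match_points <- function(a, b, radius_um) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(rep(NA_integer_, nrow(a)))
  d <- as.matrix(stats::dist(rbind(a, b)))[seq_len(nrow(a)),
                                           nrow(a) + seq_len(nrow(b)),
                                           drop = FALSE]
  match_b <- rep(NA_integer_, nrow(a))
  repeat {
    i <- which.min(d)
    if (!length(i) || d[i] > radius_um) break
    ri <- (i - 1) %% nrow(d) + 1
    ci <- (i - 1) %/% nrow(d) + 1
    match_b[ri] <- ci
    d[ri, ] <- Inf
    d[, ci] <- Inf
  }
  match_b
}

#' Labeling index from a two-channel stack
#'
#' Counts both channels with [count_nuclei], scores a label-channel
#' detection as EdU-positive when it matches a nuclear detection within
#' half the expected diameter (greedy nearest-neighbour matching), and
#' computes the labeling index from the matched counts.
#'
#' @param stack A `nuclei_stack`.
#' @param expected_diameter_um Expected nuclear diameter in microns.
#' @param threshold_nuclear,threshold_label Relative detection thresholds
#'   per channel.
#' @param specimen_id Identifier recorded in the output.
#' @return A one-row specimen-count data frame (`specimen_id`, `time_h` =
#'   `NA`, `n_total`, `n_labeled`, `li_percent`), with attribute
#'   `"mismatch"` set to `TRUE` (and a warning) when more label
#'   detections than nuclear detections were found.
#' @export
li_from_stack <- function(stack, expected_diameter_um,
                          threshold_nuclear = 0.2,
                          threshold_label = 0.2,
                          specimen_id = "stack1") {
  nuc <- count_nuclei(stack, "nuclear", expected_diameter_um,
                      threshold_nuclear)
  lab <- count_nuclei(stack, "label", expected_diameter_um,
                      threshold_label)
  mismatch <- lab$n_detected > nuc$n_detected
  if (mismatch)
    warning("more label detections than nuclear detections; counts clamped")
  m <- .match_points(lab$centers_um, nuc$centers_um,
                     radius_um = expected_diameter_um / 2)
  n_labeled <- min(sum(!is.na(m)), nuc$n_detected)
  out <- data.frame(specimen_id = specimen_id, time_h = NA_real_,
                    n_total = nuc$n_detected, n_labeled = n_labeled,
                    li_percent = if (nuc$n_detected > 0)
                      100 * n_labeled / nuc$n_detected else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "mismatch") <- mismatch
  out
}
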