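#' Fit the cumulative-labeling model to labeling-index data
#'
#' Least-squares fit of the linear-rise-with-plateau cumulative-labeling
#' curve \eqn{LI(t) = GF (t + Ts)/Tc} for \eqn{t \le Tc - Ts},
#' \eqn{LI(t) = GF} beyond, to labeling indices measured at several
#' exposure times. The fit is parameterised by the curve geometry
#' (intercept `a`, slope `b`, plateau `GF`), which maps bijectively to the
#' kinetic parameters via `Ts = a/b`, `Tc = GF/b`; the breakpoint falls at
#' `Tc - Ts`.
#'
#' @details
#' For a breakpoint lying strictly between two adjacent sampling times the
#' least-squares problem decouples exactly: the rising segment is the
#' (weighted) ordinary regression line through the earlier points and the
#' plateau is the (weighted) mean of the later points. The fitter
#' enumerates every such placement, keeps the geometrically
#' *self-consistent* (feasible) candidates — positive slope, non-negative
#' intercept, plateau above intercept, and implied breakpoint falling
#' inside the interval that defines the split — and among feasible
#' candidates selects the one with the smallest implied cycle length `Tc`
#' (equivalently, the earliest breakpoint / the largest plateau). This
#' rule recovers the generating parameters exactly on noiseless data
#' (splits that put rising points onto the plateau drag the plateau mean
#' down and push their implied breakpoint out of the interval, so they are
#' infeasible), and on noisy data prefers the conservative, shorter-cycle
#' reading of an ambiguous final rise. Candidate placements and their
#' residual sums of squares are retained in the returned object.
#'
#' If no placement is feasible the curve is indistinguishable from a
#' single rising line within the observation window; the fit is flagged
#' non-converged and only bounds are reported (the plateau, if any, lies
#' above the largest observed labeling index).
#'
#' @param x Either a numeric vector of exposure times in hours, a formula
#'   such as `li_percent ~ time_h`, or a data frame with `time_h` and
#'   `li_percent` columns (as written by [simulate_experiment] or
#'   [read_specimen_counts]).
#' @param li Labeling indices in percent (with the default method).
#' @param weights Optional non-negative observation weights.
#' @param specimen Optional specimen identifiers (one per observation),
#'   used by [bootstrap_ci] for case resampling over specimens.
#' @param data Data frame in which to evaluate a formula `x`.
#' @param ... Passed between methods.
#' @return An object of class `cumulative_fit` with components `params`
#'   (a [cell_cycle_params], when converged), `segment` (a
#'   [line_segment]), `sse`, `n_points`, `converged`, `candidates`, the
#'   model frame `data`, and `ci` (populated by [bootstrap_ci]).
#' @examples
#' tab <- read_specimen_counts(system.file("extdata",
#'   "cumulative_2dpa_means.tsv", package = "edukinetics"))
#' fit <- fit_cumulative(li_percent ~ time_h, data = tab)
#' coef(fit)
#' @export
fit_cumulative <- function(x, ...) UseMethod("fit_cumulative")

#' @rdname fit_cumulative
#' @export
fit_cumulative.formula <- function(x, data, weights = NULL,
                                   specimen = NULL, ...) {
  mf <- stats::model.frame(x, data = data, na.action = stats::na.omit)
  li <- stats::model.response(mf)
  if (ncol(mf) != 2L)
    stop("formula must have exactly one predictor (the exposure time)")
  times <- mf[[2L]]
  if (is.null(specimen) && !is.null(data$specimen_id))
    specimen <- data$specimen_id
  out <- fit_cumulative.default(times, li, weights = weights,
                                specimen = specimen, ...)
  out$call <- match.call()
  out
}

#' @rdname fit_cumulative
#' @export
fit_cumulative.data.frame <- function(x, weights = NULL, ...) {
  if (!all(c("time_h", "li_percent") %in% names(x)))
    stop("data frame must have 'time_h' and 'li_percent' columns")
  out <- fit_cumulative.default(x$time_h, x$li_percent, weights = weights,
                                specimen = x$specimen_id, ...)
  out$call <- match.call()
  out
}

#' @rdname fit_cumulative
#' @export
fit_cumulative.default <- function(x, li, weights = NULL,
                                   specimen = NULL, ...) {
  times <- as.numeric(x)
  li <- as.numeric(li)
  if (length(times) != length(li))
    stop("'times' and 'li' lengths differ")
  if (anyNA(times) || anyNA(li)) stop("missing values in input")
  if (any(li < 0 | li > 100))
    stop("labeling indices must lie in [0, 100] percent")
  if (is.null(weights)) weights <- rep(1, length(li))
  if (length(weights) != length(li) || any(weights < 0))
    stop("'weights' must be non-negative, one per observation")
  ut <- sort(unique(times))
  if (length(ut) < 4L)
    stop("insufficient data: need at least 4 distinct time points")

  fit <- .cumfit_core(times, li, weights, ut)
  fit$data <- data.frame(time_h = times, li_percent = li, weight = weights,
                         specimen_id = if (is.null(specimen))
                           NA_character_ else as.character(specimen),
                         stringsAsFactors = FALSE)
  fit$call <- match.call()
  fit$ci <- NULL
  class(fit) <- "cumulative_fit"
  fit
}

# weighted simple linear regression, closed form
.wls_line <- function(t, y, w) {
  sw <- sum(w)
  mt <- sum(w * t) / sw
  my <- sum(w * y) / sw
  sxx <- sum(w * (t - mt)^2)
  if (sxx <= 0) return(NULL)
  b <- sum(w * (t - mt) * (y - my)) / sxx
  a <- my - b * mt
  list(a = a, b = b, sse = sum(w * (y - a - b * t)^2))
}

# enumerate decoupled breakpoint placements between adjacent distinct
# sampling times; returns the fit skeleton (no data/call/class yet)
.cumfit_core <- function(times, li, w, ut) {
  m <- length(ut)
  tol <- 1e-8 * (ut[m] - ut[1])
  cand <- vector("list", m - 2L)
  for (k in 2:(m - 1L)) {
    left <- times <= ut[k]
    lf <- .wls_line(times[left], li[left], w[left])
    row <- data.frame(split_after = ut[k], intercept_a = NA_real_,
                      slope_b = NA_real_, plateau_gf = NA_real_,
                      breakpoint = NA_real_, tc = NA_real_,
                      sse = NA_real_, feasible = FALSE)
    if (!is.null(lf)) {
      gf <- sum(w[!left] * li[!left]) / sum(w[!left])
      bp <- (gf - lf$a) / lf$b
      sse <- lf$sse + sum(w[!left] * (li[!left] - gf)^2)
      upper_ok <- if (k + 1L < m) bp <= ut[k + 1L] + tol
                  else bp < ut[m] - tol
      feas <- lf$b > 0 && lf$a >= -tol && gf > lf$a &&
        bp > ut[k] + tol && upper_ok
      row <- data.frame(split_after = ut[k], intercept_a = lf$a,
                        slope_b = lf$b, plateau_gf = gf, breakpoint = bp,
                        tc = gf / lf$b, sse = sse, feasible = feas)
    }
    cand[[k - 1L]] <- row
  }
  cand <- do.call(rbind, cand)
  feas <- cand[cand$feasible, , drop = FALSE]

  if (nrow(feas) == 0L) {
    lf <- .wls_line(times, li, w)
    return(list(params = NULL, segment = NULL,
                sse = if (is.null(lf)) NA_real_ else lf$sse,
                n_points = length(li), n_times = m, converged = FALSE,
                candidates = cand,
                line_only = if (is.null(lf)) NULL else
                  list(intercept_a = lf$a, slope_b = lf$b),
                gf_lower_bound = max(li)))
  }

  best <- feas[which.min(feas$tc), , drop = FALSE]
  seg <- line_segment(intercept_a = max(best$intercept_a, 0),
                      slope_b = best$slope_b,
                      plateau_gf = best$plateau_gf)
  params <- params_from_line(seg)
  list(params = params, segment = seg, sse = best$sse,
       n_points = length(li), n_times = m, converged = TRUE,
       candidates = cand, line_only = NULL, gf_lower_bound = NULL)
}

#' @export
coef.cumulative_fit <- function(object, ...) {
  if (!object$converged)
    return(c(gf_percent = NA_real_, ts_h = NA_real_, tc_h = NA_real_,
             breakpoint_h = NA_real_, intercept_a = NA_real_,
             slope_b = NA_real_))
  c(gf_percent = object$params$gf, ts_h = object$params$ts,
    tc_h = object$params$tc, breakpoint_h = object$segment$breakpoint,
    intercept_a = object$segment$intercept_a,
    slope_b = object$segment$slope_b)
}

#' @export
predict.cumulative_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) object$data$time_h
        else if (is.data.frame(newdata)) newdata$time_h
        else as.numeric(newdata)
  if (!object$converged) {
    if (is.null(object$line_only)) stop("fit did not converge; no line fit")
    return(object$line_only$intercept_a + object$line_only$slope_b * tt)
  }
  expected_cumulative_li(object$params, tt)
}

#' @export
fitted.cumulative_fit <- function(object, ...) predict(object)

#' @export
residuals.cumulative_fit <- function(object, ...)
  object$data$li_percent - fitted(object)

#' @export
print.cumulative_fit <- function(x, digits = 4, ...) {
  cat("Cumulative-labeling fit (linear rise with plateau)\n")
  cat(sprintf("  %d observations at %d distinct exposure times\n",
              x$n_points, x$n_times))
  if (x$converged) {
    cf <- coef(x)
    cat(sprintf("  GF = %s %%   Ts = %s h   Tc = %s h   breakpoint = %s h\n",
                format(cf[["gf_percent"]], digits = digits),
                format(cf[["ts_h"]], digits = digits),
                format(cf[["tc_h"]], digits = digits),
                format(cf[["breakpoint_h"]], digits = digits)))
    cat(sprintf("  rising segment: li = %s + %s t;  SSE = %s\n",
                format(cf[["intercept_a"]], digits = digits),
                format(cf[["slope_b"]], digits = digits),
                format(x$sse, digits = digits)))
  } else {
    cat("  non-identifiable: no interior breakpoint is self-consistent;\n")
    cat(sprintf("  curve is a single rising line within the window; GF > %s %%\n",
                format(x$gf_lower_bound, digits = digits)))
  }
  invisible(x)
}

#' @export
summary.cumulative_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cumulative_fit")
}

#' @export
print.summary.cumulative_fit <- function(x, ...) {
  print(x$fit)
  cat("\nBreakpoint placements examined:\n")
  print(x$fit$candidates, row.names = FALSE, digits = 4)
  if (!is.null(x$fit$ci)) {
    cat(sprintf("\nBootstrap %d%% percentile intervals (%d resamples, %d converged):\n",
                round(100 * x$fit$ci$level), x$fit$ci$n_boot,
                x$fit$ci$n_converged))
    print(x$fit$ci$intervals, digits = 4)
  }
  invisible(x)
}

#' @export
plot.cumulative_fit <- function(x, xlab = "EdU exposure time (h)",
                                ylab = "Labeling index (%)", ...) {
  d <- x$data
  graphics::plot(d$time_h, d$li_percent, pch = 19, xlab = xlab,
                 ylab = ylab, ylim = c(0, 100), ...)
  tt <- seq(0, max(d$time_h), length.out = 256)
  graphics::lines(tt, predict(x, tt), col = "firebrick", lwd = 2)
  if (x$converged) {
    bp <- x$segment$breakpoint
    gf <- x$params$gf
    graphics::segments(bp, 0, bp, gf, lty = 3)
    graphics::segments(0, gf, bp, gf, lty = 3)
    graphics::mtext(sprintf("Tc - Ts = %.1f h", bp), side = 1, at = bp,
                    line = -1, cex = 0.8)
  }
  invisible(x)
}

#' Bootstrap confidence intervals for a cumulative-labeling fit
#'
#' Case-resampling bootstrap of [fit_cumulative]. When the fitted data
#' carry specimen identifiers with replicate specimens, whole specimens
#' are resampled with replacement (cluster bootstrap); otherwise
#' individual observations are resampled. Resamples with fewer than four
#' distinct times or a non-identifiable breakpoint are dropped from the
#' percentile computation.
#'
#' @param fit A converged `cumulative_fit`.
#' @param n_boot Number of bootstrap resamples; 0 returns empty intervals.
#' @param level Confidence level in (0, 1).
#' @param seed Integer seed for reproducibility.
#' @return The input fit with its `ci` component populated: a list with
#'   `intervals` (matrix, rows `gf_percent`, `ts_h`, `tc_h`,
#'   `breakpoint_h`), `level`, `n_boot`, `n_converged` and the bootstrap
#'   `replicates` matrix.
#' @export
bootstrap_ci <- function(fit, n_boot = 500L, level = 0.95, seed = NULL) {
  stopifnot(inherits(fit, "cumulative_fit"))
  if (!fit$converged)
    stop("bootstrap requires a converged fit")
  if (level <= 0 || level >= 1) stop("'level' must be in (0, 1)")
  parms <- c("gf_percent", "ts_h", "tc_h", "breakpoint_h")
  if (n_boot == 0L) {
    fit$ci <- list(intervals = matrix(NA_real_, 0, 2,
                                      dimnames = list(NULL, c("lower", "upper"))),
                   level = level, n_boot = 0L, n_converged = 0L,
                   replicates = NULL)
    return(fit)
  }
  if (!is.null(seed)) set.seed(seed)
  d <- fit$data
  by_specimen <- !all(is.na(d$specimen_id)) &&
    length(unique(d$specimen_id)) > 1L
  reps <- matrix(NA_real_, n_boot, 4L, dimnames = list(NULL, parms))
  for (i in seq_len(n_boot)) {
    if (by_specimen) {
      ids <- unique(d$specimen_id)
      take <- sample(ids, length(ids), replace = TRUE)
      rows <- unlist(lapply(take, function(s) which(d$specimen_id == s)))
    } else {
      rows <- sample.int(nrow(d), nrow(d), replace = TRUE)
    }
    db <- d[rows, ]
    if (length(unique(db$time_h)) < 4L) next
    fb <- tryCatch(
      fit_cumulative(db$time_h, db$li_percent, weights = db$weight),
      error = function(e) NULL)
    if (is.null(fb) || !fb$converged) next
    reps[i, ] <- coef(fb)[parms]
  }
  ok <- stats::complete.cases(reps)
  if (!any(ok))
    warning("degenerate bootstrap: no resample produced an identifiable fit")
  alpha <- (1 - level) / 2
  ints <- t(apply(reps[ok, , drop = FALSE], 2, function(v)
    if (length(v)) stats::quantile(v, c(alpha, 1 - alpha), names = FALSE)
    else c(NA_real_, NA_real_)))
  colnames(ints) <- c("lower", "upper")
  fit$ci <- list(intervals = ints, level = level, n_boot = n_boot,
                 n_converged = sum(ok), replicates = reps[ok, , drop = FALSE])
  fit
}

#' @export
confint.cumulative_fit <- function(object, parm, level = 0.95, ...) {
  if (is.null(object$ci))
    stop("no bootstrap intervals stored; run bootstrap_ci() first")
  ints <- object$ci$intervals
  if (!missing(parm)) ints <- ints[parm, , drop = FALSE]
  ints
}

#' @export
simulate.cumulative_fit <- function(object, nsim = 1, seed = NULL,
                                    n_cells = 2000L, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  if (is.null(seed)) seed <- 1L
  protocol <- labeling_protocol("cumulative", exposure_start = 0,
                                exposure_duration = max(object$data$time_h),
                                sampling_times = sort(unique(object$data$time_h)))
  simulate_experiment(object$params, protocol, n_cells = n_cells,
                      n_specimens = nsim, seed = seed)
}
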