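#' Cell-cycle parameter set
#'
#' Bundles the kinetic triple describing a proliferating cell population:
#' total cycle length `Tc`, S-phase length `Ts` and growth fraction `GF`
#' (the percentage of cells actively cycling), together with the position
#' of S within the cycle. Phase layout: G1 occupies
#' `[0, g1_fraction * (tc - ts))` of cycle age, S the following `ts` hours,
#' and G2/M the remainder, so the three phases sum to `tc` exactly.
#'
#' The position of S inside the cycle (`g1_fraction`) does not affect
#' cumulative or pulse labeling indices in a steady-state population; it
#' only shifts when labeled cells divide in pulse-wait designs.
#'
#' @param tc Total cell-cycle length in hours (> 0).
#' @param ts S-phase length in hours (0 < `ts` < `tc`).
#' @param gf Growth fraction in percent, in (0, 100]. `gf = 0` is accepted
#'   to describe a fully quiescent population in simulations.
#' @param g1_fraction Fraction of the non-S cycle time preceding S, in
#'   \[0, 1\]. Default 0.5 (S centred in the cycle).
#' @return An object of class `cell_cycle_params`.
#' @examples
#' cell_cycle_params(tc = 33.2, ts = 1.3, gf = 85.7)
#' @export
cell_cycle_params <- function(tc, ts, gf, g1_fraction = 0.5) {
  stopifnot(is.numeric(tc), length(tc) == 1L, is.finite(tc),
            is.numeric(ts), length(ts) == 1L, is.finite(ts),
            is.numeric(gf), length(gf) == 1L, is.finite(gf),
            is.numeric(g1_fraction), length(g1_fraction) == 1L)
  if (tc <= 0) stop("'tc' must be a positive cycle length in hours")
  if (ts <= 0 || ts >= tc) stop("'ts' must satisfy 0 < ts < tc")
  if (gf < 0 || gf > 100) stop("'gf' must be a percentage in [0, 100]")
  if (g1_fraction < 0 || g1_fraction > 1)
    stop("'g1_fraction' must lie in [0, 1]")
  structure(
    list(tc = tc, ts = ts, gf = gf, g1_fraction = g1_fraction),
    class = "cell_cycle_params"
  )
}

#' @export
print.cell_cycle_params <- function(x, ...) {
  ph <- phase_layout(x)
  cat("Cell-cycle parameters\n")
  cat(sprintf("  Tc (cycle length): %.3g h\n", x$tc))
  cat(sprintf("  Ts (S-phase):      %.3g h\n", x$ts))
  cat(sprintf("  GF (growth frac.): %.3g %%\n", x$gf))
  cat(sprintf("  phases G1/S/G2+M:  %.3g / %.3g / %.3g h\n",
              ph$g1, x$ts, ph$g2m))
  invisible(x)
}

# phase boundaries implied by g1_fraction; s_start is the cycle age at
# which S begins
phase_layout <- function(params) {
  g1 <- params$g1_fraction * (params$tc - params$ts)
  list(g1 = g1, s_start = g1, s_end = g1 + params$ts,
       g2m = params$tc - params$ts - g1)
}

#' Rising segment of a cumulative labeling curve
#'
#' Describes the pre-plateau geometry of a cumulative-labeling curve:
#' `li = intercept_a + slope_b * t` up to the breakpoint, after which the
#' curve sits at the plateau `plateau_gf`. The breakpoint is where the
#' rising line meets the plateau, `(plateau_gf - intercept_a) / slope_b`.
#'
#' @param intercept_a Intercept of the rising line, percent (>= 0).
#' @param slope_b Slope of the rising line, percent per hour (> 0).
#' @param plateau_gf Plateau value (the growth fraction), percent;
#'   must exceed `intercept_a`.
#' @return An object of class `line_segment` with fields `intercept_a`,
#'   `slope_b`, `plateau_gf` and the derived `breakpoint` (hours).
#' @export
line_segment <- function(intercept_a, slope_b, plateau_gf) {
  stopifnot(is.numeric(intercept_a), is.numeric(slope_b),
            is.numeric(plateau_gf))
  if (slope_b <= 0)
    stop("non-identifiable rise: 'slope_b' must be > 0")
  if (intercept_a < 0) stop("'intercept_a' must be >= 0")
  if (plateau_gf <= intercept_a)
    stop("degenerate geometry: plateau must exceed the intercept")
  structure(
    list(intercept_a = intercept_a, slope_b = slope_b,
         plateau_gf = plateau_gf,
         breakpoint = (plateau_gf - intercept_a) / slope_b),
    class = "line_segment"
  )
}

#' @export
print.line_segment <- function(x, ...) {
  cat(sprintf(
    "Cumulative-curve segment: li = %.4g + %.4g t, plateau %.4g %% at t = %.4g h\n",
    x$intercept_a, x$slope_b, x$plateau_gf, x$breakpoint))
  invisible(x)
}

#' Expected labeling index under continuous (cumulative) exposure
#'
#' Closed-form labeling index of a steady-state population continuously
#' exposed to a thymidine analog for `t` hours:
#' `LI(t) = GF * (t + Ts) / Tc` while `t <= Tc - Ts`, then `LI = GF`
#' once every cycling cell has traversed S. The curve is continuous,
#' piecewise linear, non-decreasing and bounded by `GF`; its intercept
#' `GF * Ts / Tc` is the steady-state S-phase fraction and its breakpoint
#' falls at `Tc - Ts`.
#'
#' @param params A [cell_cycle_params] object.
#' @param t Exposure time(s) in hours, >= 0; vectorised.
#' @return Expected labeling index in percent, same length as `t`.
#' @examples
#' p <- cell_cycle_params(tc = 25.7, ts = 7.3, gf = 76)
#' expected_cumulative_li(p, c(0, 10, 24, 48))
#' @export
expected_cumulative_li <- function(params, t) {
  stopifnot(inherits(params, "cell_cycle_params"), is.numeric(t))
  if (any(t < 0)) stop("exposure time 't' must be >= 0")
  pmin(params$gf * (t + params$ts) / params$tc, params$gf)
}

#' Expected labeling index after a brief (pulse) exposure
#'
#' A pulse of duration `pulse_duration` labels every cell that occupies
#' S-phase at any moment of the pulse; in a steady-state population this
#' equals the cumulative curve evaluated at the pulse duration. At
#' `pulse_duration = 0` it reduces to `GF * Ts / Tc`, the instantaneous
#' S-phase fraction among all cells.
#'
#' @param params A [cell_cycle_params] object.
#' @param pulse_duration Pulse length in hours, >= 0; vectorised.
#' @return Expected labeling index in percent.
#' @export
expected_pulse_li <- function(params, pulse_duration) {
  expected_cumulative_li(params, pulse_duration)
}

#' Recover cell-cycle parameters from cumulative-curve geometry
#'
#' Inverts the cumulative-labeling model: given the rising line
#' `li = a + b t` and the plateau `GF`, the S-phase length is the
#' x-axis distance `Ts = a / b` (extrapolating the regression line to
#' the y-axis), the cycle length is `Tc = GF / b`, and the identity
#' `Tc = breakpoint + Ts` holds exactly.
#'
#' @param segment A [line_segment] object.
#' @param g1_fraction Passed through to [cell_cycle_params].
#' @return A [cell_cycle_params] object reproducing the segment under
#'   [expected_cumulative_li].
#' @examples
#' seg <- line_segment(intercept_a = 21.564, slope_b = 2.9436, plateau_gf = 76)
#' params_from_line(seg)
#' @export
params_from_line <- function(segment, g1_fraction = 0.5) {
  stopifnot(inherits(segment, "line_segment"))
  ts <- segment$intercept_a / segment$slope_b
  tc <- segment$plateau_gf / segment$slope_b
  if (ts <= 0)
    stop("zero intercept implies zero S-phase length; outside the Ts > 0 domain")
  cell_cycle_params(tc = tc, ts = ts, gf = segment$plateau_gf,
                    g1_fraction = g1_fraction)
}

#' Cumulative-curve geometry implied by cell-cycle parameters
#'
#' Forward companion of [params_from_line]: intercept `GF * Ts / Tc`,
#' slope `GF / Tc`, plateau `GF`, breakpoint `Tc - Ts`.
#'
#' @param params A [cell_cycle_params] object.
#' @return A [line_segment] object.
#' @export
line_from_params <- function(params) {
  stopifnot(inherits(params, "cell_cycle_params"))
  line_segment(intercept_a = params$gf * params$ts / params$tc,
               slope_b = params$gf / params$tc,
               plateau_gf = params$gf)
}
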