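#' Labeling protocol description
#'
#' Describes one of the three thymidine-analog labeling designs used in
#' proliferation studies: a brief *pulse* (marks cells in S-phase during
#' the exposure), *cumulative* labeling (continuous exposure; the
#' labeling index climbs until every cycling cell has traversed S), and
#' *pulse-wait* (pulse followed by a chase during which the label is
#' diluted two-fold at every division).
#'
#' Time zero is the start of the experiment (amputation, for regeneration
#' studies); `exposure_start` may be negative to describe labeling that
#' began before time zero.
#'
#' @param kind One of `"pulse"`, `"cumulative"`, `"pulse_wait"`.
#' @param exposure_start Start of the labeling window in hours.
#' @param exposure_duration Length of the labeling window in hours (> 0).
#' @param sampling_times Strictly increasing vector of fixation times in
#'   hours, each >= `exposure_start`.
#' @param detection_threshold Minimum label intensity still scored as
#'   positive, as a fraction of the intensity at incorporation. The
#'   default 1/16 corresponds to a label surviving four divisions.
#' @return An object of class `labeling_protocol`.
#' @examples
#' labeling_protocol("cumulative", 0, 48, c(0.25, 5, 10, 24, 48))
#' @export
labeling_protocol <- function(kind = c("pulse", "cumulative", "pulse_wait"),
                              exposure_start = 0, exposure_duration,
                              sampling_times,
                              detection_threshold = 1 / 16) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(exposure_start), length(exposure_start) == 1L,
            is.numeric(exposure_duration), length(exposure_duration) == 1L,
            is.numeric(sampling_times), length(sampling_times) >= 1L)
  if (exposure_duration <= 0) stop("'exposure_duration' must be > 0")
  if (is.unsorted(sampling_times, strictly = TRUE))
    stop("'sampling_times' must be strictly increasing")
  if (any(sampling_times < exposure_start))
    stop("all 'sampling_times' must be >= 'exposure_start'")
  if (detection_threshold <= 0 || detection_threshold > 1)
    stop("'detection_threshold' must be in (0, 1]")
  structure(list(kind = kind, exposure_start = exposure_start,
                 exposure_duration = exposure_duration,
                 sampling_times = sampling_times,
                 detection_threshold = detection_threshold),
            class = "labeling_protocol")
}

#' @export
print.labeling_protocol <- function(x, ...) {
  cat(sprintf("%s labeling: exposure [%g, %g] h; sampling at %s h; detection threshold %.3g\n",
              x$kind, x$exposure_start,
              x$exposure_start + x$exposure_duration,
              paste(x$sampling_times, collapse = ", "),
              x$detection_threshold))
  invisible(x)
}

#' Initialise a simulated cell population
#'
#' Creates `n` cells of which exactly `round(n * gf / 100)` are cycling
#' (deterministic stratified assignment — the growth fraction is treated
#' as a population constant, not a per-cell Bernoulli draw). Under the
#' default `uniform` age distribution, cycling cells receive i.i.d.
#' Uniform\[0, Tc) cycle ages, the stationary distribution of a
#' constant-size renewing population and the regime in which the
#' closed-form cumulative-labeling model is exact. The
#' `exponential_growth` option draws ages from the age density of an
#' exponentially expanding population, `p(a) = (2 log 2 / Tc) 2^(-a/Tc)`.
#'
#' @param n Number of cells (>= 1).
#' @param params A [cell_cycle_params] object.
#' @param age_distribution `"uniform"` or `"exponential_growth"`.
#' @param seed Optional integer seed.
#' @return A data frame of class `cell_population` with one row per cell:
#'   `cycling`, `age` (hours), `label_intensity`,
#'   `divisions_since_label`, `multiplicity`; simulation time 0 stored as
#'   the `"time"` attribute.
#' @export
init_population <- function(n, params,
                            age_distribution = c("uniform",
                                                 "exponential_growth"),
                            seed = NULL) {
  stopifnot(inherits(params, "cell_cycle_params"))
  age_distribution <- match.arg(age_distribution)
  if (length(n) != 1L || n < 1) stop("empty population: 'n' must be >= 1")
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  n_cyc <- as.integer(round(n * params$gf / 100))
  u <- stats::runif(n)
  age <- if (age_distribution == "uniform") u * params$tc
         else -params$tc * log2(1 - u / 2)
  pop <- data.frame(
    cycling = seq_len(n) <= n_cyc,
    age = age,
    label_intensity = 0,
    divisions_since_label = 0L,
    multiplicity = 1
  )
  attr(pop, "time") <- 0
  attr(pop, "age0") <- age        # cycle age at experiment time 0
  attr(pop, "params") <- params
  class(pop) <- c("cell_population", "data.frame")
  pop
}

#' Advance a population through a labeling experiment
#'
#' Propagates every cell from experiment start to time `until` under the
#' given protocol, in closed form (cell trajectories are deterministic
#' given their initial cycle age, so no time stepping is needed). A
#' cycling cell acquires full label intensity whenever its S-phase
#' overlaps the exposure window; at every cycle wrap-around it divides,
#' which halves the label intensity of the daughters. In `renewal` mode
#' (default) one daughter replaces the parent, keeping the population
#' size constant and the uniform age distribution stationary; in
#' `growth` mode both daughters are kept, tracked as a per-row
#' `multiplicity` (daughters of one founder divide in synchrony and share
#' identical state). Non-cycling cells never age, label or divide.
#'
#' @param population A `cell_population` from [init_population].
#' @param params The [cell_cycle_params] used to create it.
#' @param protocol A [labeling_protocol].
#' @param until Sampling (fixation) time in hours, >= the exposure start.
#' @param mode `"renewal"` (constant size) or `"growth"` (exponential).
#' @return The population at time `until`, with updated `age`,
#'   `label_intensity`, `divisions_since_label` and `multiplicity`.
#' @export
advance_and_label <- function(population, params, protocol, until,
                              mode = c("renewal", "growth")) {
  stopifnot(inherits(population, "cell_population"),
            inherits(params, "cell_cycle_params"),
            inherits(protocol, "labeling_protocol"))
  mode <- match.arg(mode)
  a0 <- attr(population, "age0")
  tc <- params$tc
  ph <- phase_layout(params)
  s0 <- ph$s_start
  ts <- params$ts
  t_start <- min(0, protocol$exposure_start)
  if (until < t_start) stop("'until' precedes the start of the experiment")

  w0 <- protocol$exposure_start
  w1 <- min(protocol$exposure_start + protocol$exposure_duration, until)

  cyc <- population$cycling
  lab <- rep(FALSE, nrow(population))
  dlab <- rep(0L, nrow(population))
  if (w1 > w0 && any(cyc)) {
    a <- a0[cyc]
    # S-phase visits are t in [k*tc + s0 - a, k*tc + s0 + ts - a); the
    # visit indices overlapping [w0, w1] are k_min..k_max
    k_max <- floor((w1 + a - s0) / tc)
    k_min <- floor((w0 + a - s0 - ts) / tc) + 1L
    hit <- k_max >= k_min
    lab[cyc] <- hit
    # divisions between the last labeled S visit and fixation
    d <- pmax(floor((until + a) / tc) - k_max, 0)
    dlab[cyc][hit] <- as.integer(d[hit])
  }
  population$label_intensity <- ifelse(lab, 2^(-dlab), 0)
  population$divisions_since_label <- dlab
  population$age <- ifelse(cyc, (a0 + until) %% tc, population$age)
  if (mode == "growth") {
    d_tot <- ifelse(cyc,
                    floor((until + a0) / tc) - floor((t_start + a0) / tc),
                    0)
    population$multiplicity <- 2^d_tot
  } else {
    population$multiplicity <- 1
  }
  attr(population, "time") <- until
  population
}

#' Score a population as one specimen count
#'
#' Counts nuclei whose label intensity is at or above the detection
#' threshold and computes the labeling index
#' `LI = 100 * n_labeled / n_total`. Labels diluted below the threshold
#' by successive divisions are scored negative, mimicking the loss of
#' finely dispersed label in pulse-wait experiments.
#'
#' @param population A `cell_population`.
#' @param detection_threshold Minimum intensity scored positive.
#' @param specimen_id Identifier recorded in the output row.
#' @return A one-row data frame: `specimen_id`, `time_h`, `n_total`,
#'   `n_labeled`, `li_percent`.
#' @export
measure_li <- function(population, detection_threshold = 1 / 16,
                       specimen_id = "s1") {
  stopifnot(inherits(population, "cell_population"))
  if (nrow(population) == 0L) stop("empty population")
  mult <- population$multiplicity
  n_total <- sum(mult)
  n_labeled <- sum(mult[population$label_intensity >= detection_threshold])
  data.frame(specimen_id = specimen_id,
             time_h = attr(population, "time"),
             n_total = n_total, n_labeled = n_labeled,
             li_percent = 100 * n_labeled / n_total,
             stringsAsFactors = FALSE)
}

#' Simulate a full labeling experiment
#'
#' Simulates `n_specimens` independent specimens, each a population of
#' `n_cells` cells, sampled (fixed) at every time in the protocol's
#' `sampling_times`. Each specimen uses its own random substream derived
#' from the master seed by a fixed counter scheme
#' (`seed + 104729 * specimen_index`), so per-specimen results do not
#' depend on the order in which specimens are generated.
#'
#' @param params A [cell_cycle_params] object.
#' @param protocol A [labeling_protocol].
#' @param n_cells Cells per specimen.
#' @param n_specimens Number of independent specimens (>= 1).
#' @param seed Master integer seed.
#' @param age_distribution,mode Passed to [init_population] and
#'   [advance_and_label].
#' @return A data frame with one row per specimen and sampling time
#'   (columns as in [measure_li]).
#' @examples
#' p <- cell_cycle_params(tc = 33.2, ts = 1.3, gf = 85.7)
#' pr <- labeling_protocol("cumulative", 0, 48, c(0.25, 5, 10, 24, 48))
#' tab <- simulate_experiment(p, pr, n_cells = 500, n_specimens = 3, seed = 1)
#' head(tab)
#' @export
simulate_experiment <- function(params, protocol, n_cells,
                                n_specimens, seed = 1L,
                                age_distribution = "uniform",
                                mode = "renewal") {
  if (length(n_specimens) != 1L || n_specimens < 1)
    stop("'n_specimens' must be >= 1")
  rows <- vector("list", n_specimens)
  for (i in seq_len(n_specimens)) {
    sub_seed <- (as.numeric(seed) + 104729 * i) %% 2147483647
    pop <- init_population(n_cells, params,
                           age_distribution = age_distribution,
                           seed = as.integer(sub_seed))
    per_time <- lapply(protocol$sampling_times, function(tt) {
      p_t <- advance_and_label(pop, params, protocol, until = tt,
                               mode = mode)
      measure_li(p_t, protocol$detection_threshold,
                 specimen_id = sprintf("s%02d", i))
    })
    rows[[i]] <- do.call(rbind, per_time)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
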