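# edukinetics

Quantitative cell-proliferation analysis from EdU
(5-ethynyl-2′-deoxyuridine) labeling experiments, built for regeneration
time-courses: the labeling index, the cumulative-labeling model of
cell-cycle kinetics, an agent-based simulator of the three classical
labeling designs, the nonparametric statistics used to compare stages,
and a synthetic 3D nuclei-counting pipeline to validate the upstream
counting step. It is aimed at developmental and regeneration biologists
who score EdU⁺/DAPI⁺ nuclei across stages and want the cell-cycle
parameters behind those counts, with reproducible fits and honest
uncertainty.

## The model

EdU marks cells in S-phase. Under continuous exposure of a steady-state
population, the labeling index (percentage of labeled nuclei) rises
linearly and then plateaus:

    LI(t) = GF · (t + Ts) / Tc   for t ≤ Tc − Ts
    LI(t) = GF                   for t ≥ Tc − Ts

where `GF` is the growth fraction (percent of cells cycling), `Ts` the
S-phase length and `Tc` the cycle length (hours). Writing the rising
segment as `li = a + b·t`, the geometry inverts to `Ts = a/b`,
`Tc = GF/b`, with the breakpoint at `Tc − Ts`. `fit_cumulative()` solves
the least-squares problem exactly by enumerating decoupled breakpoint
placements (regression line before, mean plateau after) and selecting
the earliest self-consistent placement — no nonlinear optimiser, no
starting values, fully deterministic. `bootstrap_ci()` adds
case-resampling percentile intervals. The agent-based simulator
(`simulate_experiment()`) generates per-specimen count tables under
pulse, cumulative or pulse-wait protocols, including two-fold label
dilution at each division. See the vignette
(`vignettes/cumulative-labeling-kinetics.Rmd`) for the assumptions and
design choices.

## Worked example

Fit the packaged mean labeling-index series from a cumulative-labeling
experiment started at 2 days post-amputation (exposure times 0.25, 10,
24, 48 h):

```r
library(edukinetics)
tab <- read_specimen_counts(system.file("extdata",
  "cumulative_2dpa_means.tsv", package = "edukinetics"))
fit <- fit_cumulative(li_percent ~ time_h, data = tab)
fit
#> Cumulative-labeling fit (linear rise with plateau)
#>   4 observations at 4 distinct exposure times
#>   GF = 76 %   Ts = 7.326 h   Tc = 25.82 h   breakpoint = 18.49 h
#>   rising segment: li = 21.56 + 2.944 t;  SSE = 426.3
```

76 % of the cells are cycling, S-phase lasts about 7.3 h, and the full
cycle about 25.8 h; the curve plateaus at 18.5 h of exposure, when every
cycling cell has passed through S. Simulating that population and
re-estimating shows the pipeline closing the loop, with bootstrap
intervals over specimens:

```r
p    <- cell_cycle_params(tc = 25.7, ts = 7.3, gf = 76)
prot <- labeling_protocol("cumulative", 0, 48, c(0.25, 5, 10, 24, 48))
sim  <- simulate_experiment(p, prot, n_cells = 2000, n_specimens = 6, seed = 1)
refit <- bootstrap_ci(fit_cumulative(sim), n_boot = 500, seed = 1)
coef(refit)[1:3]
#> gf_percent       ts_h       tc_h
#>  76.000000   7.501754  25.895164
confint(refit)
#>                  lower     upper
#> gf_percent   76.000000 76.000000
#> ts_h          7.284575  7.736668
#> tc_h         25.278509 26.541652
#> breakpoint_h 17.985985 18.839696
```

(The `GF` interval is degenerate here because the simulator treats the
growth fraction as a population constant and every plateau-side
observation hits it exactly.)

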