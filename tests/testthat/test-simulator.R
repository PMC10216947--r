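p_fast <- cell_cycle_params(tc = 20, ts = 5, gf = 80)

test_that("population initialisation is stratified and reproducible", {
  pop <- init_population(1000, p_fast, seed = 1)
  expect_equal(sum(pop$cycling), 800)        # exactly n * GF / 100
  expect_true(all(pop$age >= 0 & pop$age < 20))
  expect_identical(init_population(500, p_fast, seed = 3),
                   init_population(500, p_fast, seed = 3))
  expect_error(init_population(0, p_fast), "empty population")

  # a fully quiescent cell never labels
  pq <- init_population(1, cell_cycle_params(20, 5, 0), seed = 2)
  expect_false(pq$cycling[1])
  prot <- labeling_protocol("cumulative", 0, 100, c(100))
  adv <- advance_and_label(pq, cell_cycle_params(20, 5, 0), prot, 100)
  expect_equal(adv$label_intensity, 0)
  expect_equal(measure_li(adv)$li_percent, 0)
})

test_that("uniform-age S-phase occupancy matches Ts/Tc", {
  p <- cell_cycle_params(tc = 30, ts = 9, gf = 100)
  prot <- labeling_protocol("pulse", 0, 0.001, c(0.001))
  n <- 40000
  pop <- advance_and_label(init_population(n, p, seed = 5), p, prot, 0.001)
  occ <- mean(pop$label_intensity > 0)
  se <- sqrt(0.3 * 0.7 / n)
  expect_lt(abs(occ - 9 / 30), 3 * se)
})

test_that("cumulative labeling saturates and matches the closed form", {
  # GF = 100: every cycling cell traverses S within one cycle
  p <- cell_cycle_params(tc = 20, ts = 5, gf = 100)
  prot <- labeling_protocol("cumulative", 0, 30, c(15, 30))
  pop <- init_population(2000, p, seed = 8)
  adv <- advance_and_label(pop, p, prot, 15)   # t = Tc - Ts
  expect_equal(measure_li(adv)$li_percent, 100)

  # empirical curve vs closed form at n = 20000 (3 binomial SE)
  p2 <- cell_cycle_params(tc = 33.2, ts = 1.3, gf = 85.7)
  prot2 <- labeling_protocol("cumulative", 0, 48, c(5, 10, 24, 48))
  pop2 <- init_population(20000, p2, seed = 42)
  for (tt in prot2$sampling_times) {
    li <- measure_li(advance_and_label(pop2, p2, prot2, tt))$li_percent
    mu <- expected_cumulative_li(p2, tt)
    expect_lt(abs(li - mu), 3 * binom_se_pct(mu, 20000) + 1e-9)
  }
})

test_that("labeled fraction is monotone in exposure duration", {
  p <- cell_cycle_params(tc = 25, ts = 4, gf = 70)
  pop <- init_population(3000, p, seed = 13)
  li <- sapply(c(0.5, 2, 8, 16, 25, 40), function(dur) {
    prot <- labeling_protocol("cumulative", 0, dur, c(dur))
    measure_li(advance_and_label(pop, p, prot, dur))$li_percent
  })
  expect_true(all(diff(li) >= 0))
})

test_that("division halves the label and the threshold drops diluted labels", {
  # pulse then wait k full cycles -> intensities 2^-k
  p <- cell_cycle_params(tc = 20, ts = 5, gf = 100)
  prot <- labeling_protocol("pulse_wait", 0, 0.25, c(0.25, 20.25, 40.25,
                                                     60.25, 80.25, 100.25))
  pop <- init_population(500, p, seed = 21)
  for (k in 0:5) {
    adv <- advance_and_label(pop, p, prot, 0.25 + 20 * k)
    ints <- unique(adv$label_intensity[adv$label_intensity > 0])
    expect_equal(ints, 2^(-k))
    # after 5 divisions (2^-5 < 1/16) nothing is scored positive
    m <- measure_li(adv, detection_threshold = 1 / 16)
    if (k <= 4) expect_gt(m$n_labeled, 0) else expect_equal(m$n_labeled, 0)
  }
})

test_that("renewal conserves population size; growth doubles per cycle", {
  p <- cell_cycle_params(tc = 10, ts = 3, gf = 100)
  prot <- labeling_protocol("pulse", 0, 0.1, c(30))
  pop <- init_population(400, p, seed = 31)
  ren <- advance_and_label(pop, p, prot, 30, mode = "renewal")
  expect_equal(measure_li(ren)$n_total, 400)
  gro <- advance_and_label(pop, p, prot, 30, mode = "growth")
  expect_equal(measure_li(gro)$n_total, 400 * 2^3)   # t = 3 Tc exactly
})

test_that("simulated experiments have the expected table layout and determinism", {
  p <- cell_cycle_params(tc = 33.2, ts = 1.3, gf = 85.7)
  prot <- labeling_protocol("cumulative", 0, 48, c(0.25, 5, 10, 24, 48))
  tab <- simulate_experiment(p, prot, n_cells = 400, n_specimens = 4,
                             seed = 99)
  expect_equal(nrow(tab), 20)                  # specimens x times
  expect_equal(tab$li_percent,
               100 * tab$n_labeled / tab$n_total)
  expect_identical(tab, simulate_experiment(p, prot, n_cells = 400,
                                            n_specimens = 4, seed = 99))

  # per-time means track the closed form within 3 SEM (Monte Carlo)
  p2 <- cell_cycle_params(tc = 33.2, ts = 1.3, gf = 85.7)
  tab2 <- simulate_experiment(p2, prot, n_cells = 2000, n_specimens = 6,
                              seed = 7)
  for (tt in prot$sampling_times) {
    v <- tab2$li_percent[tab2$time_h == tt]
    mu <- expected_cumulative_li(p2, tt)
    sem <- max(sd(v) / sqrt(length(v)), binom_se_pct(mu, 2000 * 6))
    expect_lt(abs(mean(v) - mu), 3 * sem + 1e-9)
  }
})
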