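test_that("labeling index and group summaries follow their definitions", {
  expect_equal(labeling_index(0, 500), 0)
  expect_equal(labeling_index(50, 200), 25)
  expect_equal(labeling_index(7, 7), 100)
  expect_error(labeling_index(1, 0), "undefined")
  expect_error(labeling_index(5, 3), "n_labeled")

  s <- group_summary(c(10, 12, 14, 30), c("a", "a", "a", "b"))
  expect_equal(s$n, c(3L, 1L))
  expect_equal(s$mean, c(12, 30))
  expect_equal(s$sem[1], sd(c(10, 12, 14)) / sqrt(3))
  expect_true(is.na(s$sem[2]))      # SEM undefined for n = 1
})

test_that("Kruskal-Wallis handles degenerate and tied data", {
  expect_equal(unname(kruskal_wallis(list(c(1, 1), c(1, 1)))$statistic), 0)
  expect_equal(kruskal_wallis(list(c(1, 1), c(1, 1)))$p_value, 1)
  # tie correction divides by a factor <= 1, so corrected H >= uncorrected
  g <- list(c(1, 2, 2, 7), c(2, 5, 5), c(3, 5, 9, 9))
  values <- unlist(g); labels <- rep(1:3, lengths(g))
  r <- rank(values); n <- length(values)
  h_raw <- 12 / (n * (n + 1)) *
    sum(tapply(r, labels, sum)^2 / lengths(g)) - 3 * (n + 1)
  expect_gte(unname(kruskal_wallis(g)$statistic), h_raw)
  expect_true(kruskal_wallis(g)$tie_corrected)
})

test_that("Kruskal-Wallis agrees with kruskal.test and the exact oracle", {
  set.seed(61)
  sizes_list <- list(c(2, 2, 2), c(3, 3, 3), c(2, 3, 4), c(2, 2, 3, 3))
  for (sizes in sizes_list) {
    g <- split(rnorm(sum(sizes)), rep(seq_along(sizes), sizes))
    res <- kruskal_wallis(g)
    ref <- kruskal.test(unlist(g), factor(rep(seq_along(sizes), sizes)))
    expect_equal(unname(res$statistic), unname(ref$statistic),
                 tolerance = 1e-10)
    expect_equal(res$method, "exact_permutation")
    expect_equal(res$p_value, oracle_kw_exact_p(g), tolerance = 1e-12)
  }
  # beyond the exact limit the chi-square approximation is used
  big <- split(rnorm(15), rep(1:3, each = 5))
  res <- kruskal_wallis(big)
  expect_equal(res$method, "chi_square_approx")
  expect_equal(res$p_value,
               kruskal.test(unlist(big), factor(rep(1:3, each = 5)))$p.value,
               tolerance = 1e-10)
})

test_that("Mann-Whitney exact p-values match full enumeration", {
  # perfectly separated ranks: two-sided p = 2 / C(8,4) = 2/70
  res <- mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))
  expect_equal(unname(res$statistic), 0)
  expect_equal(res$p_value, 2 / 70, tolerance = 1e-12)
  expect_equal(res$method, "exact_permutation")

  set.seed(62)
  for (sizes in list(c(3, 3), c(4, 4), c(5, 5), c(4, 6), c(2, 8))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2], 0.8)
    for (alt in c("two_sided", "greater", "less")) {
      expect_equal(mann_whitney(x, y, alternative = alt)$p_value,
                   oracle_mw_exact_p(x, y, alt), tolerance = 1e-12)
    }
    # agreement with wilcox.test's exact route
    expect_equal(mann_whitney(x, y)$p_value,
                 wilcox.test(x, y, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("U complementarity and identical-sample degeneracy hold", {
  set.seed(63)
  x <- rnorm(6); y <- rnorm(9)
  u_xy <- unname(mann_whitney(x, y)$statistic)
  u_yx <- unname(mann_whitney(y, x)$statistic)
  expect_equal(u_xy + u_yx, length(x) * length(y))
  expect_equal(mann_whitney(5, 5)$p_value, 1)
})

test_that("normal approximation tracks the exact p for moderate samples", {
  set.seed(64)
  for (r in 1:5) {
    x <- rnorm(8); y <- rnorm(8, 0.5)
    p_exact <- mann_whitney(x, y, exact_limit = 16L)$p_value
    p_approx <- mann_whitney(x, y, exact_limit = 0L)$p_value
    expect_lt(abs(p_exact - p_approx), 0.02)
  }
})

test_that("two-group Kruskal-Wallis decides like the two-sided Mann-Whitney", {
  set.seed(65)
  for (r in 1:10) {
    x <- rnorm(4); y <- rnorm(4, sample(c(0, 2), 1))
    p_kw <- kruskal_wallis(list(x, y))$p_value
    p_mw <- mann_whitney(x, y)$p_value
    # both exact; they induce the same decision at any alpha
    expect_equal(p_kw, p_mw, tolerance = 1e-10)
  }
})

test_that("pairwise testing flags large stage effects at alpha = 0.005", {
  set.seed(66)
  # rising-then-falling LI means across stages, small SEM
  stages <- list(dpa1 = rnorm(8, 2, 0.7), dpa2 = rnorm(8, 22, 2),
                 dpa4 = rnorm(8, 37, 2), dpa6 = rnorm(8, 22, 2))
  pw <- mann_whitney_pairwise(stages)
  expect_true(pw$significant["dpa1", "dpa2"])
  expect_true(pw$significant["dpa2", "dpa4"])
  expect_true(pw$significant["dpa4", "dpa6"])
  expect_false(pw$significant["dpa2", "dpa6"])   # same mean, no effect
  # p matrix is symmetric with NA diagonal; U antisymmetric around n1*n2
  expect_equal(pw$p_value, t(pw$p_value))
  expect_true(all(is.na(diag(pw$p_value))))
  # optional multiplicity adjustment never decreases p
  pw_b <- mann_whitney_pairwise(stages, p_adjust = "bonferroni")
  up <- upper.tri(pw$p_value)
  expect_true(all(pw_b$p_value[up] >= pw$p_value[up]))
})
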