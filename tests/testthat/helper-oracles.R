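# Independent oracles used across the suite. These deliberately take
# different computational routes than the package internals.

# all distinct permutations of a label multiset (recursive, unique
# first-element branching) -- used to enumerate group-label assignments
multiset_perms <- function(labels) {
  if (length(labels) <= 1L) return(list(labels))
  out <- list()
  for (u in unique(labels)) {
    rest <- labels[-match(u, labels)]
    out <- c(out, lapply(multiset_perms(rest), function(p) c(u, p)))
  }
  out
}

# raw (uncorrected-formula, mid-rank, tie-corrected) Kruskal-Wallis H,
# written independently of the package internals
oracle_kw_h <- function(values, labels) {
  r <- rank(values)
  n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, labels, sum)^2 / tabulate(factor(labels))) -
    3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) 0 else h / corr
}

# exact Kruskal-Wallis p by full enumeration of label permutations
oracle_kw_exact_p <- function(groups) {
  values <- unlist(groups)
  labels <- rep(seq_along(groups), lengths(groups))
  h_obs <- oracle_kw_h(values, labels)
  perms <- multiset_perms(labels)
  hs <- vapply(perms, function(l) oracle_kw_h(values, l), numeric(1))
  mean(hs >= h_obs - 1e-12)
}

# exact two-sided Mann-Whitney p by full enumeration over combn
oracle_mw_exact_p <- function(x, y,
                              alternative = c("two_sided", "greater",
                                              "less")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  n1 <- length(x)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  us <- combn(length(pooled), n1, u_of)
  p_le <- mean(us <= u_obs + 1e-12)
  p_ge <- mean(us >= u_obs - 1e-12)
  switch(alternative,
         two_sided = min(2 * min(p_le, p_ge), 1),
         greater = p_ge,
         less = p_le)
}

# decoupled broken-line solution for a given split, via lm()/mean() --
# independent route for the within-interval optimality check
oracle_decoupled <- function(times, li, split_time) {
  left <- times <= split_time
  f <- lm(li[left] ~ times[left])
  gf <- mean(li[!left])
  a <- unname(coef(f)[1]); b <- unname(coef(f)[2])
  list(a = a, b = b, gf = gf, bp = (gf - a) / b,
       ts = a / b, tc = gf / b)
}

# binomial standard error of a percentage
binom_se_pct <- function(p_pct, n) 100 * sqrt(p_pct / 100 * (1 - p_pct / 100) / n)

# greedy matched precision/recall of detections against ground truth
match_precision_recall <- function(det_um, truth_um, radius_um) {
  if (nrow(det_um) == 0L) return(c(precision = NA, recall = 0))
  d <- as.matrix(dist(rbind(det_um, truth_um)))
  d <- d[seq_len(nrow(det_um)), nrow(det_um) + seq_len(nrow(truth_um)),
         drop = FALSE]
  tp <- 0L
  repeat {
    i <- which.min(d)
    if (!length(i) || d[i] > radius_um) break
    ri <- (i - 1) %% nrow(d) + 1
    ci <- (i - 1) %/% nrow(d) + 1
    tp <- tp + 1L
    d[ri, ] <- Inf
    d[, ci] <- Inf
  }
  c(precision = tp / nrow(det_um), recall = tp / nrow(truth_um))
}

fixture_path <- function(name) system.file("extdata", name,
                                           package = "edukinetics")
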