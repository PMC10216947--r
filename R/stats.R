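#' Labeling index
#'
#' Percentage of labeled (S-phase) nuclei among all nuclei:
#' `LI = 100 * n_labeled / n_total`.
#'
#' @param n_labeled Count(s) of label-positive nuclei.
#' @param n_total Count(s) of all nuclei (> 0).
#' @return Labeling index in percent; vectorised.
#' @examples
#' labeling_index(50, 200)
#' @export
labeling_index <- function(n_labeled, n_total) {
  if (any(n_total <= 0)) stop("undefined LI: 'n_total' must be > 0")
  if (any(n_labeled < 0 | n_labeled > n_total))
    stop("'n_labeled' must lie in [0, n_total]")
  100 * n_labeled / n_total
}

#' Per-group mean and standard error
#'
#' Summarises a measurement (labeling index, nuclei count, ...) by group
#' (typically regeneration stage): group size, mean and standard error of
#' the mean. The SEM of a single observation is undefined and returned as
#' `NA`.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, one per value.
#' @return A data frame with columns `group`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  g <- factor(groups, levels = unique(groups))
  n <- tapply(values, g, length)
  m <- tapply(values, g, mean)
  s <- tapply(values, g, function(v)
    if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  data.frame(group = levels(g), n = as.integer(n), mean = as.numeric(m),
             sem = as.numeric(s), row.names = NULL,
             stringsAsFactors = FALSE)
}

# midranks of pooled values plus the tie-correction sum t^3 - t
.pooled_ranks <- function(values) {
  r <- rank(values)
  tie <- table(values)
  list(r = r, tie_sum = sum(tie^3 - tie), tied = any(tie > 1L))
}

# tie-corrected Kruskal-Wallis H for pooled ranks r split by sizes
.kw_h <- function(r, grp_index, n_tot, tie_sum) {
  rs <- tapply(r, grp_index, sum)
  ns <- tapply(r, grp_index, length)
  h <- 12 / (n_tot * (n_tot + 1)) * sum(rs^2 / ns) - 3 * (n_tot + 1)
  corr <- 1 - tie_sum / (n_tot^3 - n_tot)
  if (corr <= 0) return(0)
  h / corr
}

#' Kruskal-Wallis rank-sum test
#'
#' Omnibus nonparametric comparison of two or more groups, with the
#' standard mid-rank tie correction. For small samples (total n <= 10 by
#' default) the p-value is computed by complete enumeration of all
#' distinct assignments of the pooled observations to the group sizes;
#' otherwise the usual chi-square approximation with k - 1 degrees of
#' freedom is used.
#'
#' @param groups A list of numeric vectors, one per group (each
#'   non-empty).
#' @param exact_limit Largest total sample size for which the exact
#'   permutation p-value is computed. The default 10 keeps enumeration
#'   (at most a few thousand assignments) essentially instantaneous.
#' @return A list of class `edu_test`: `statistic` (tie-corrected H),
#'   `p_value`, `df`, `method` (`"exact_permutation"` or
#'   `"chi_square_approx"`), `tie_corrected`.
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
#' @export
kruskal_wallis <- function(groups, exact_limit = 10L) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  sizes <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  n_tot <- length(values)
  gi <- rep(seq_along(groups), sizes)
  pr <- .pooled_ranks(values)
  h <- .kw_h(pr$r, gi, n_tot, pr$tie_sum)
  k <- length(groups)
  if (n_tot <= exact_limit) {
    perms <- .group_assignments(n_tot, sizes)
    hs <- vapply(perms, function(idx) {
      gperm <- integer(n_tot)
      gperm[unlist(idx)] <- rep(seq_len(k), sizes)
      .kw_h(pr$r, gperm, n_tot, pr$tie_sum)
    }, numeric(1))
    p <- mean(hs >= h - 1e-12)
    method <- "exact_permutation"
  } else {
    p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
    method <- "chi_square_approx"
  }
  structure(list(statistic = c(H = h), p_value = min(p, 1), df = k - 1,
                 method = method, tie_corrected = pr$tied),
            class = "edu_test")
}

# all distinct ordered partitions of 1..n into blocks of the given sizes,
# as lists of index vectors (recursive over combn)
.group_assignments <- function(n, sizes) {
  rec <- function(avail, sizes) {
    if (length(sizes) == 1L) return(list(list(avail)))
    first <- utils::combn(avail, sizes[1L], simplify = FALSE)
    out <- list()
    for (f in first) {
      rest <- rec(setdiff(avail, f), sizes[-1L])
      out <- c(out, lapply(rest, function(r) c(list(f), r)))
    }
    out
  }
  rec(seq_len(n), sizes)
}

#' @export
print.edu_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, p = %.4g (%s%s)\n",
              names(x$statistic), x$statistic, x$p_value, x$method,
              if (isTRUE(x$tie_corrected)) ", tie-corrected" else ""))
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test. The U statistic is computed from mid-ranks. For
#' tie-free samples with `n1 + n2 <= exact_limit` the p-value is exact
#' (from the null distribution of U); otherwise the normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @param alternative `"two_sided"`, `"greater"` (x stochastically
#'   larger) or `"less"`.
#' @param exact_limit Largest `n1 + n2` for which the exact tie-free
#'   p-value is used (default 12).
#' @return A list of class `edu_test` with `statistic` (U of `x` over
#'   `y`), `p_value`, `method` (`"exact_permutation"` or
#'   `"normal_approx"`), `tie_corrected`.
#' @examples
#' mann_whitney(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' @export
mann_whitney <- function(x, y,
                         alternative = c("two_sided", "greater", "less"),
                         exact_limit = 12L) {
  alternative <- match.arg(alternative)
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y)
  pr <- .pooled_ranks(c(x, y))
  r1 <- sum(pr$r[seq_len(n1)])
  u <- r1 - n1 * (n1 + 1) / 2           # U of x over y
  if (!pr$tied && n1 + n2 <= exact_limit) {
    # exact null distribution of U (tie-free)
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
    p <- switch(alternative,
                two_sided = min(2 * min(p_le, p_ge), 1),
                greater = p_ge,
                less = p_le)
    method <- "exact_permutation"
  } else {
    mu <- n1 * n2 / 2
    n <- n1 + n2
    sigma <- sqrt((n1 * n2 / 12) *
                    ((n + 1) - pr$tie_sum / (n * (n - 1))))
    z <- u - mu
    cc <- switch(alternative, two_sided = sign(z) * 0.5,
                 greater = 0.5, less = -0.5)
    z <- if (sigma > 0) (z - cc) / sigma else 0
    p <- switch(alternative,
                two_sided = 2 * min(stats::pnorm(z),
                                    stats::pnorm(z, lower.tail = FALSE)),
                greater = stats::pnorm(z, lower.tail = FALSE),
                less = stats::pnorm(z))
    p <- min(p, 1)
    method <- "normal_approx"
  }
  structure(list(statistic = c(U = u), p_value = p,
                 method = method, tie_corrected = pr$tied),
            class = "edu_test")
}

#' Pairwise Mann-Whitney post-hoc comparisons
#'
#' Runs [mann_whitney] on every pair of groups and flags pairs at the
#' configured significance level. Following common practice in labeling
#' studies, raw pairwise p-values are compared against a stringent
#' threshold (default 0.005) with no multiplicity adjustment; Bonferroni
#' or Holm adjustment can be switched on via `p_adjust`.
#'
#' @param groups A named list of numeric vectors.
#' @param alternative Passed to [mann_whitney].
#' @param alpha Significance threshold applied to the (possibly
#'   adjusted) p-values.
#' @param p_adjust Method for [stats::p.adjust] (default `"none"`).
#' @return A list of class `pairwise_mw` with matrices `u`, `p_value`,
#'   `significant`, plus `alpha` and `p_adjust`.
#' @export
mann_whitney_pairwise <- function(groups,
                                  alternative = "two_sided",
                                  alpha = 0.005, p_adjust = "none") {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) == 0L)) stop("all groups must be non-empty")
  k <- length(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  u <- p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tst <- mann_whitney(groups[[i]], groups[[j]],
                        alternative = alternative)
    u[i, j] <- tst$statistic
    u[j, i] <- lengths(groups)[i] * lengths(groups)[j] - tst$statistic
    p[i, j] <- p[j, i] <- tst$p_value
  }
  padj <- p
  up <- upper.tri(p)
  padj[up] <- stats::p.adjust(p[up], method = p_adjust)
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  structure(list(u = u, p_value = padj, significant = padj <= alpha,
                 alpha = alpha, p_adjust = p_adjust),
            class = "pairwise_mw")
}

#' @export
print.pairwise_mw <- function(x, ...) {
  cat(sprintf("Pairwise Mann-Whitney (alpha = %g, adjust = %s)\np-values:\n",
              x$alpha, x$p_adjust))
  print(signif(x$p_value, 3))
  invisible(x)
}
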