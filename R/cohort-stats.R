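# Cohort statistics implemented from their defining formulas. Distribution
# functions (pt, pf, ptukey, dhyper) are used as numerical primitives; the
# procedures themselves -- Welch's t, one-way ANOVA with Tukey HSD, the
# Benjamini-Hochberg step-up, the Benjamini-Krieger-Yekutieli two-stage
# step-up, and the hypergeometric upper tail -- are written out here so their
# behaviour is fully specified and testable against independent oracles.

#' Welch's two-tailed t test
#'
#' t = (mean(x) - mean(y)) / sqrt(s_x^2/n_x + s_y^2/n_y), with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value. If both
#' samples have zero variance and equal means the comparison is degenerate
#' and p is set to 1 with a warning, keeping pipelines total.
#'
#' @param x,y Numeric samples, each of length >= 2.
#' @return A `cohort_test` object; use [generics::tidy()] / `glance()` or
#'   access `$statistic`, `$df`, `$p`.
#' @examples
#' welch_t(c(1, 2, 3, 4), c(2, 3, 4, 5))$p
#' @export
welch_t <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2) abort("welch_t needs n >= 2 per sample")
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  if (vx + vy == 0) {
    if (mean(x) == mean(y)) {
      warn("zero variance in both samples with equal means; p set to 1")
      return(.cohort_test(0, Inf, 1, "welch_t"))
    }
    return(.cohort_test(sign(mean(x) - mean(y)) * Inf, Inf, 0, "welch_t"))
  }
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  .cohort_test(tstat, df, p, "welch_t")
}

#' One-way ANOVA with Tukey HSD post-hoc tests
#'
#' F = MS_between / MS_within from the standard sums-of-squares
#' decomposition; pairwise comparisons use Tukey's honestly significant
#' difference with p-values from the studentized range distribution.
#'
#' @param groups A named list of >= 3 numeric samples (>= 2 values each), or
#'   exactly 2 samples for the consistency case F = t^2.
#' @return A `cohort_test` object with `$statistic` (F), `$df` (c(between,
#'   within)), `$p`, and `$pairwise` (tibble of contrasts with Tukey-adjusted
#'   p-values).
#' @examples
#' anova_tukey(list(a = rnorm(4), b = rnorm(4), c = rnorm(4) + 2))$p
#' @export
anova_tukey <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  n_i <- lengths(groups)
  if (any(n_i < 2)) abort("every group needs n >= 2")
  k <- length(groups)
  n <- sum(n_i)
  means <- vapply(groups, mean, 0)
  grand <- sum(n_i * means) / n
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- k - 1
  df2 <- n - k
  ms_within <- ss_within / df2
  if (ms_within == 0 && ss_between == 0) {
    warn("all groups identical and constant; p set to 1")
    fstat <- 0; p <- 1
  } else if (ms_within == 0) {
    fstat <- Inf; p <- 0
  } else {
    fstat <- (ss_between / df1) / ms_within
    p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  }
  pairs <- combn(names(groups), 2)
  pw <- tibble(
    contrast = paste(pairs[2, ], "-", pairs[1, ]),
    diff = means[pairs[2, ]] - means[pairs[1, ]],
    p_adj = vapply(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      se <- sqrt(ms_within / 2 * (1 / n_i[[a]] + 1 / n_i[[b]]))
      if (se == 0) return(if (means[[a]] == means[[b]]) 1 else 0)
      q <- abs(means[[b]] - means[[a]]) / se
      stats::ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    }, 0)
  )
  .cohort_test(fstat, c(df1, df2), p, "anova_tukey", pairwise = pw)
}

.cohort_test <- function(statistic, df, p, method, pairwise = NULL) {
  structure(
    list(statistic = statistic, df = df, p = p, method = method,
         pairwise = pairwise),
    class = "cohort_test"
  )
}

#' @export
print.cohort_test <- function(x, ...) {
  cat("<cohort_test> ", x$method, ": statistic = ",
      format(x$statistic, digits = 5),
      ", df = ", paste(format(x$df, digits = 5), collapse = ", "),
      ", p = ", format(x$p, digits = 4), "\n", sep = "")
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cohort test
#'
#' @param x A `cohort_test`.
#' @param ... Unused.
#' @return For `tidy()`, one row per contrast (pairwise rows for ANOVA);
#'   for `glance()`, a one-row summary.
#' @export
tidy.cohort_test <- function(x, ...) {
  if (!is.null(x$pairwise)) {
    return(mutate(x$pairwise, method = x$method))
  }
  tibble(statistic = x$statistic, df = x$df, p.value = x$p, method = x$method)
}

#' @rdname tidy.cohort_test
#' @export
glance.cohort_test <- function(x, ...) {
  tibble(
    statistic = x$statistic,
    df1 = x$df[1],
    df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
    p.value = x$p,
    method = x$method
  )
}

#' Benjamini-Hochberg step-up adjustment
#'
#' q_(i) = min over j >= i of p_(j) * m / j, capped at 1, returned in the
#' original order of `pvals`.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0) return(numeric())
  ord <- order(pvals)
  q_sorted <- pvals[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Benjamini-Krieger-Yekutieli two-stage step-up procedure
#'
#' Stage 1 applies the linear step-up at level q' = q / (1 + q); the number
#' of rejections r1 estimates the number of true nulls as m0 = m - r1. Stage
#' 2 re-runs the step-up at level q' * m / m0. This adaptive procedure
#' controls the false discovery rate at level q and is more powerful than
#' plain Benjamini-Hochberg when some hypotheses are false.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @param q Target FDR level in (0, 1); defaults to 0.05.
#' @return Logical vector of per-test discovery flags.
#' @export
bky_two_stage <- function(pvals, q = 0.05) {
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m == 0) return(logical())
  q1 <- q / (1 + q)
  step_up <- function(p, level) {
    ord <- order(p)
    thresh <- level * seq_len(m) / m
    below <- which(p[ord] <= thresh)
    r <- if (length(below)) max(below) else 0L
    flags <- logical(m)
    if (r > 0) flags[ord[seq_len(r)]] <- TRUE
    flags
  }
  stage1 <- step_up(pvals, q1)
  r1 <- sum(stage1)
  if (r1 == 0) return(stage1)
  if (r1 == m) return(stage1)
  m0 <- m - r1
  step_up(pvals, q1 * m / m0)
}

#' Hypergeometric enrichment (upper tail) with odds ratio
#'
#' For an overlap of `k` between a drawn set of size `n` and a marked set of
#' size `K` in a universe of size `N`, computes p = P(X >= k) under
#' Hypergeometric(N, K, n), together with the odds ratio of the 2x2 overlap
#' table (with a Haldane 0.5 correction if any cell is zero).
#'
#' @param k Observed overlap.
#' @param K Number of marked elements in the universe.
#' @param n Number drawn.
#' @param N Universe size.
#' @return One-row tibble: `k`, `K`, `n`, `N`, `p`, `odds_ratio`.
#' @examples
#' hypergeom_enrichment(2, 5, 4, 20)
#' @export
hypergeom_enrichment <- function(k, K, n, N) {
  k <- as.integer(k); K <- as.integer(K); n <- as.integer(n); N <- as.integer(N)
  if (K > N || n > N || k > min(K, n) || k < 0 || min(K, n, N) < 0) {
    abort("inconsistent counts: need 0 <= k <= min(K, n) <= N")
  }
  upper <- min(K, n)
  p <- sum(stats::dhyper(k:upper, m = K, n = N - K, k = n))
  p <- min(p, 1)
  a <- k; b <- n - k; cc <- K - k; d <- N - K - n + k
  if (min(a, b, cc, d) == 0) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  tibble(k = k, K = K, n = n, N = N, p = p, odds_ratio = (a * d) / (b * cc))
}
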