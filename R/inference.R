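#' Normality gate for a set of group samples
#'
#' Shapiro–Wilk on every group; the comparison is routed to the parametric
#' branch only if every group passes at `alpha`. A constant-valued sample
#' (for which the test statistic is undefined) fails the gate.
#'
#' @param samples list of numeric vectors, one per group, each `n >= 3`.
#' @param alpha test level (default 0.05).
#' @return logical: `TRUE` if every group is compatible with normality.
#' @export
normality_gate <- function(samples, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 1)
  if (any(vapply(samples, length, 1L) < 3)) {
    stop_hc("each group needs n >= 3 for the Shapiro-Wilk test",
            "hemiconn_too_small")
  }
  ok <- vapply(samples, function(x) {
    p <- tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0)
    p > alpha
  }, logical(1))
  all(ok)
}

#' Omnibus group comparison
#'
#' One-way ANOVA (classical, equal-variance F test) when `parametric`,
#' otherwise Kruskal–Wallis. ANOVA degrees of freedom are `(k - 1, N - k)`;
#' the Kruskal–Wallis statistic has `k - 1` degrees of freedom (the
#' `H_(2, N-3)` notation seen in some software reports the error df
#' alongside, so `n_total` is returned separately). If all values are
#' identical across all groups the statistic is 0 and p = 1.
#'
#' @param samples list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @param parametric logical, typically from [normality_gate()].
#' @return data.frame with `test`, `statistic`, `df1`, `df2` (`NA` for
#'   Kruskal–Wallis), `n_total`, `p`.
#' @export
omnibus_group_test <- function(samples, parametric) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (any(vapply(samples, length, 1L) == 0)) {
    stop_hc("empty group in omnibus test", "hemiconn_too_small")
  }
  x <- unlist(samples, use.names = FALSE)
  g <- factor(rep(seq_along(samples), vapply(samples, length, 1L)))
  k <- length(samples)
  N <- length(x)
  if (stats::var(x) == 0) {
    return(data.frame(test = if (parametric) "anova" else "kruskal",
                      statistic = 0, df1 = k - 1,
                      df2 = if (parametric) N - k else NA_real_,
                      n_total = N, p = 1))
  }
  if (parametric) {
    ht <- stats::oneway.test(x ~ g, var.equal = TRUE)
    data.frame(test = "anova", statistic = unname(ht$statistic),
               df1 = unname(ht$parameter[1]), df2 = unname(ht$parameter[2]),
               n_total = N, p = ht$p.value)
  } else {
    ht <- stats::kruskal.test(x, g)
    data.frame(test = "kruskal", statistic = unname(ht$statistic),
               df1 = unname(ht$parameter), df2 = NA_real_,
               n_total = N, p = ht$p.value)
  }
}

#' Pairwise post-hoc tests with Bonferroni correction
#'
#' All pairwise two-sample comparisons between groups: pooled-variance t
#' tests on the parametric branch, Wilcoxon rank-sum otherwise. Raw p-values
#' are multiplied by the family size and capped at 1.
#'
#' @param samples named list of numeric vectors, one per group.
#' @param parametric logical branch flag.
#' @param family Bonferroni family size; defaults to the number of pairs.
#' @return data.frame with `group1`, `group2`, `statistic`, `p_raw`,
#'   `p_corrected`.
#' @export
pairwise_posthoc <- function(samples, parametric, family = NULL) {
  stopifnot(is.list(samples), length(samples) >= 2)
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_along(samples))
  pairs <- utils::combn(names(samples), 2, simplify = FALSE)
  if (is.null(family)) family <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    x <- samples[[pr[1]]]; y <- samples[[pr[2]]]
    if (stats::var(c(x, y)) == 0) {
      stat <- 0; p <- 1
    } else if (parametric) {
      ht <- stats::t.test(x, y, var.equal = TRUE)
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    data.frame(group1 = pr[1], group2 = pr[2], statistic = stat,
               p_raw = p, p_corrected = min(1, p * family))
  })
  do.call(rbind, rows)
}

#' Pearson chi-squared test on a contingency table
#'
#' Group-by-category counts (e.g. sex by group); Pearson's statistic without
#' continuity correction, df = (rows - 1)(cols - 1).
#'
#' @param counts matrix of non-negative counts.
#' @return data.frame with `statistic`, `df`, `p`.
#' @export
proportions_test <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop_hc("negative counts", "hemiconn_bad_counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop_hc("zero marginal in contingency table", "hemiconn_bad_counts")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  data.frame(statistic = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value)
}

#' Brain–behaviour correlation
#'
#' Pearson on the parametric branch, Spearman otherwise; pairs with missing
#' values are dropped (pairwise deletion, so each correlation carries its
#' own n).
#'
#' @param x,y numeric vectors of equal length.
#' @param parametric logical branch flag.
#' @return data.frame with `method` ("pearson" or "spearman"), `estimate`,
#'   `p`, `n`.
#' @export
correlate <- function(x, y, parametric) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) {
    stop_hc("fewer than 3 complete pairs", "hemiconn_too_small")
  }
  method <- if (parametric) "pearson" else "spearman"
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE))
  data.frame(method = method, estimate = unname(ht$estimate), p = ht$p.value,
             n = length(x))
}

#' Cohen's d from summary statistics
#'
#' `d = |m1 - m2| / sqrt((sd1^2 + sd2^2) / 2)` — the absolute standardised
#' mean difference with the root-mean-square of the two standard deviations
#' as denominator.
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations
#'   (`sd > 0`).
#' @return d, a non-negative scalar.
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (sd1 <= 0 || sd2 <= 0) {
    stop_hc("standard deviations must be positive", "hemiconn_bad_sd")
  }
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Post-hoc power of a two-sample t test
#'
#' Exact power via the noncentral t distribution with
#' `df = n1 + n2 - 2` and noncentrality `d * sqrt(n1 n2 / (n1 + n2))`.
#' At `d = 0` the power equals `alpha`.
#'
#' @param alpha test level in (0, 1).
#' @param d effect size (Cohen's d, >= 0).
#' @param n1,n2 group sizes (>= 2).
#' @param two_sided logical (default TRUE).
#' @return power in (0, 1).
#' @export
posthoc_power <- function(alpha = 0.05, d, n1, n2, two_sided = TRUE) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_hc("alpha must lie in (0, 1)", "hemiconn_bad_alpha")
  }
  if (d < 0 || n1 < 2 || n2 < 2) {
    stop_hc("need d >= 0 and group sizes >= 2", "hemiconn_too_small")
  }
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  if (two_sided) {
    tc <- stats::qt(1 - alpha / 2, df)
    (1 - stats::pt(tc, df, ncp)) + stats::pt(-tc, df, ncp)
  } else {
    tc <- stats::qt(1 - alpha, df)
    1 - stats::pt(tc, df, ncp)
  }
}
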