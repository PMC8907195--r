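#' Null-ensemble size rule
#'
#' The ensemble size is the rounded mean of the group sample sizes; with the
#' study's 27/26/32 split this gives 28 null graphs.
#'
#' @param group_sizes integer vector of per-group sample sizes.
#' @return integer ensemble size.
#' @export
null_ensemble_size <- function(group_sizes) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 1))
  as.integer(round(mean(group_sizes)))
}

#' Generate one Erdős–Rényi random graph
#'
#' Each unordered node pair receives an edge independently with probability
#' `p_edge`. Weights are unit by default (ER is a binary model); with
#' `weight_rule = "empirical"` weights are resampled with replacement from a
#' supplied pool of observed non-zero weights, making weighted metrics
#' comparable to empirical matrices.
#'
#' @param n node count (>= 2).
#' @param p_edge edge probability in `[0, 1]`.
#' @param weight_rule `"unit"` or `"empirical"`.
#' @param weight_pool numeric vector of positive weights, required for
#'   `"empirical"`.
#' @param seed integer seed; the draw is reproducible and leaves the global
#'   RNG state untouched.
#' @param labels optional node labels.
#' @return a `weighted_adjacency`.
#' @export
generate_er_graph <- function(n, p_edge, weight_rule = c("unit", "empirical"),
                              weight_pool = NULL, seed = 1, labels = NULL) {
  weight_rule <- match.arg(weight_rule)
  if (!is.numeric(p_edge) || length(p_edge) != 1 || is.na(p_edge) ||
      p_edge < 0 || p_edge > 1) {
    stop_hc("p_edge must be a probability in [0, 1]", "hemiconn_bad_probability")
  }
  stopifnot(n >= 2)
  if (weight_rule == "empirical" &&
      (is.null(weight_pool) || !length(weight_pool) || any(weight_pool <= 0))) {
    stop_hc("empirical weight rule needs a pool of positive weights",
            "hemiconn_bad_weight_pool")
  }
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(n))
  w <- withr::with_seed(seed, {
    m <- matrix(0, n, n)
    ut <- upper.tri(m)
    edges <- stats::rbinom(sum(ut), 1, p_edge)
    vals <- if (weight_rule == "unit") edges else
      edges * sample(weight_pool, sum(ut), replace = TRUE)
    m[ut] <- vals
    m + t(m)
  })
  rownames(w) <- colnames(w) <- labels
  weighted_adjacency(w)
}

#' Build an Erdős–Rényi null ensemble
#'
#' Generates `n_graphs` independent ER graphs; member seeds are derived
#' deterministically from the master seed so the whole ensemble is
#' reproducible.
#'
#' @param n_graphs ensemble size (default 28, the rounded mean of the study
#'   group sizes).
#' @param n nodes per graph (default 47).
#' @param p_edge edge probability.
#' @param weight_rule,weight_pool see [generate_er_graph()].
#' @param seed master seed.
#' @param labels optional node labels shared by all members.
#' @return object of class `null_ensemble`: list with `graphs`, `p_edge`,
#'   `weight_rule`, `seed`.
#' @export
build_null_ensemble <- function(n_graphs = 28, n = 47, p_edge,
                                weight_rule = c("unit", "empirical"),
                                weight_pool = NULL, seed = 1, labels = NULL) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(n_graphs >= 1)
  child_seeds <- derive_seeds(seed, n_graphs)
  graphs <- lapply(child_seeds, function(s) {
    generate_er_graph(n, p_edge, weight_rule, weight_pool, seed = s,
                      labels = labels)
  })
  structure(list(graphs = graphs, n = n, p_edge = p_edge,
                 weight_rule = weight_rule, seed = seed, size = n_graphs),
            class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d ER graphs, n = %d, p_edge = %.3f, seed = %d\n",
              x$size, x$n, x$p_edge, x$seed))
  invisible(x)
}

# deterministic child seeds below 2^31, derived under the master seed
derive_seeds <- function(seed, k) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

#' Compare empirical metric values against a null distribution
#'
#' Two-sample comparison of a per-subject empirical metric sample against
#' the per-graph null-model sample, normality-gated: Student's t when both
#' samples pass Shapiro–Wilk at `alpha`, Wilcoxon rank-sum otherwise.
#' Degenerate input (zero variance in both samples) is flagged and, when the
#' two constants are equal, reported as no evidence of difference (p = 1).
#'
#' @param empirical numeric vector of subject-level metric values.
#' @param null numeric vector of null-graph metric values.
#' @param alpha normality-gate level.
#' @return data.frame with `test`, `statistic`, `p`, `direction` (sign of
#'   empirical minus null location), `degenerate`.
#' @export
compare_to_null <- function(empirical, null, alpha = 0.05) {
  stopifnot(length(empirical) >= 1, length(null) >= 1)
  degenerate <- stats::var(empirical) == 0 && stats::var(null) == 0
  direction <- sign(stats::median(empirical) - stats::median(null))
  if (degenerate) {
    identical_vals <- empirical[1] == null[1]
    return(data.frame(test = "degenerate",
                      statistic = 0,
                      p = if (identical_vals) 1 else NA_real_,
                      direction = direction,
                      degenerate = TRUE))
  }
  parametric <- normality_gate(list(empirical, null), alpha = alpha)
  if (parametric) {
    ht <- stats::t.test(empirical, null)
    data.frame(test = "t", statistic = unname(ht$statistic), p = ht$p.value,
               direction = direction, degenerate = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(empirical, null, exact = FALSE))
    data.frame(test = "ranksum", statistic = unname(ht$statistic),
               p = ht$p.value, direction = direction, degenerate = FALSE)
  }
}
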