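#' Configuration for a full pipeline run
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"manifest"`
#'   (read matrices listed in a cohort manifest CSV).
#' @param cohort_config a [cohort_config()] for simulate mode.
#' @param manifest_path path to a manifest CSV for manifest mode; matrix
#'   paths are resolved relative to its directory.
#' @param atlas a `node_atlas`; matrices are subset/reordered to it.
#' @param threshold density-threshold fraction (default 0.25).
#' @param transform weight-to-length rule for betweenness.
#' @param null list of null-model settings: `n_graphs` (default: group-size
#'   rule), `p_edge` (`"auto"` = mean pre-threshold cohort density, or a
#'   number), `weight_rule` (`"unit"` or `"empirical"`).
#' @param stats list of settings: `alpha`, `bonferroni_family` (default 3,
#'   the pairwise comparisons within each metric/node).
#' @param out_dir output directory for report CSVs, summary and log; `NULL`
#'   to skip writing.
#' @param seed master seed for every stochastic stage.
#' @return an object of class `run_config`.
#' @export
run_config <- function(mode = c("simulate", "manifest"),
                       cohort_config = NULL, manifest_path = NULL,
                       atlas = default_atlas(), threshold = 0.25,
                       transform = c("inverse", "unit"),
                       null = list(), stats = list(),
                       out_dir = NULL, seed = 1) {
  mode <- match.arg(mode)
  transform <- match.arg(transform)
  if (threshold < 0 || threshold >= 1) {
    stop_hc("threshold must lie in [0, 1)", "hemiconn_bad_fraction")
  }
  if (mode == "manifest" && (is.null(manifest_path) || !file.exists(manifest_path))) {
    stop_hc("manifest mode needs an existing manifest_path", "hemiconn_manifest")
  }
  null_cfg <- list(n_graphs = NULL, p_edge = "auto", weight_rule = "unit")
  null_cfg[names(null)] <- null
  stats_cfg <- list(alpha = 0.05, bonferroni_family = 3)
  stats_cfg[names(stats)] <- stats
  structure(list(mode = mode, cohort_config = cohort_config,
                 manifest_path = manifest_path, atlas = atlas,
                 threshold = threshold, transform = transform,
                 null = null_cfg, stats = stats_cfg, out_dir = out_dir,
                 seed = seed),
            class = "run_config")
}

#' Per-subject metric tables for a whole cohort
#'
#' Applies the processing chain (atlas subsetting, diagonal zeroing,
#' density thresholding) to every subject matrix and computes the nodal and
#' hemispheric metric tables.
#'
#' @param manifest cohort manifest data.frame (needs `id`, `group`).
#' @param matrices named list of `weighted_adjacency`, keyed by subject id.
#' @param atlas a `node_atlas`.
#' @param threshold density-threshold fraction.
#' @param transform weight-to-length rule.
#' @return list with `nodal` (row-bound nodal tables with a `group`
#'   column), `hemispheric` (one row per subject), and
#'   `mean_density` (mean pre-threshold edge density, used for the ER null
#'   parameter).
#' @export
cohort_metrics <- function(manifest, matrices, atlas, threshold = 0.25,
                           transform = c("inverse", "unit")) {
  transform <- match.arg(transform)
  nodal <- vector("list", nrow(manifest))
  hemi <- vector("list", nrow(manifest))
  dens <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$id[i]
    A <- matrices[[id]]
    if (!identical(node_labels(A), atlas$all_labels)) {
      A <- subset_hemisphere(A, atlas)
    }
    A <- zero_diagonal(A)
    n <- nrow(A)
    dens[i] <- sum(as_weights(A)[upper.tri(A)] > 0) / choose(n, 2)
    At <- density_threshold(A, threshold)
    tab <- nodal_metric_table(At, id, transform = transform)
    tab$group <- manifest$group[i]
    nodal[[i]] <- tab
    h <- hemispheric_summary(tab[, setdiff(names(tab), "group")],
                             hierarchical_complexity(At))
    h$group <- manifest$group[i]
    hemi[[i]] <- h
  }
  list(nodal = do.call(rbind, nodal), hemispheric = do.call(rbind, hemi),
       mean_density = mean(dens))
}

# split metric values by group in fixed AIS/PVI/TDC order
split_groups <- function(values, groups) {
  lv <- intersect(c("AIS", "PVI", "TDC"), unique(groups))
  stats::setNames(lapply(lv, function(g) values[groups == g]), lv)
}

# full normality-gated battery for one metric: omnibus + Bonferroni
# pairwise + group summaries + Cohen's d per pair
group_battery <- function(values, groups, alpha = 0.05, family = 3) {
  samples <- split_groups(values, groups)
  # fixed report layout regardless of which groups are present/testable
  out <- data.frame(test = "insufficient", parametric = NA,
                    statistic = NA_real_, df1 = NA_real_, df2 = NA_real_,
                    n_total = length(unlist(samples)), p = NA_real_)
  for (g in c("AIS", "PVI", "TDC")) {
    s <- samples[[g]]
    out[[paste0("mean_", g)]] <- if (length(s)) mean(s) else NA_real_
    out[[paste0("sd_", g)]] <- if (length(s) > 1) stats::sd(s) else NA_real_
  }
  for (key in c("AIS_PVI", "AIS_TDC", "PVI_TDC")) {
    out[[paste0("p_", key)]] <- NA_real_
    out[[paste0("d_", key)]] <- NA_real_
  }
  # a metric can be undefined for most subjects at a node (e.g.
  # neighbourhood complexity at unique-degree nodes); too-small groups
  # leave the comparison marked untestable
  if (length(samples) < 2 || any(vapply(samples, length, 1L) < 3)) {
    return(out)
  }
  parametric <- normality_gate(samples, alpha = alpha)
  omni <- omnibus_group_test(samples, parametric)
  post <- pairwise_posthoc(samples, parametric, family = family)
  out$test <- omni$test
  out$parametric <- parametric
  out$statistic <- omni$statistic
  out$df1 <- omni$df1
  out$df2 <- omni$df2
  out$p <- omni$p
  for (r in seq_len(nrow(post))) {
    key <- paste0(post$group1[r], "_", post$group2[r])
    out[[paste0("p_", key)]] <- post$p_corrected[r]
    s1 <- samples[[post$group1[r]]]; s2 <- samples[[post$group2[r]]]
    out[[paste0("d_", key)]] <-
      if (stats::sd(s1) > 0 && stats::sd(s2) > 0) {
        cohens_d(mean(s1), stats::sd(s1), mean(s2), stats::sd(s2))
      } else NA_real_
  }
  out
}

nodal_metric_names <- c("betweenness_raw", "clustering",
                        "neighbourhood_complexity")
hemi_metric_names <- c("betweenness", "clustering",
                       "neighbourhood_complexity", "hierarchical_complexity")

# group comparisons for the 8 sensorimotor/control nodes x 3 nodal metrics
nodal_comparison_report <- function(nodal, atlas, alpha, family) {
  slice <- sensorimotor_slice(nodal, atlas)
  rows <- list()
  for (nd in unique(slice$node)) {
    sub <- slice[slice$node == nd, ]
    for (met in nodal_metric_names) {
      v <- sub[[met]]
      ok <- is.finite(v)
      bat <- group_battery(v[ok], sub$group[ok], alpha, family)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(node = nd, node_label = sub$node_label[1], metric = met),
        bat)
    }
  }
  do.call(rbind, rows)
}

hemispheric_comparison_report <- function(hemi, alpha, family) {
  rows <- lapply(hemi_metric_names, function(met) {
    cbind(data.frame(metric = met),
          group_battery(hemi[[met]], hemi$group, alpha, family))
  })
  do.call(rbind, rows)
}

# normality-gated correlation between a metric column and a clinical score
gated_correlation <- function(x, y, alpha) {
  keep <- is.finite(x) & is.finite(y)
  if (sum(keep) < 3) return(NULL)
  parametric <- sum(keep) >= 3 &&
    normality_gate(list(x[keep]), alpha) && normality_gate(list(y[keep]), alpha)
  correlate(x, y, parametric)
}

correlation_report <- function(nodal, hemi, manifest, atlas, alpha) {
  scores <- c("AHA", "MA", "BBTA", "BBTU")
  rows <- list()
  add_row <- function(level, node, metric, score, pooling, res) {
    if (is.null(res)) return()
    rows[[length(rows) + 1]] <<- cbind(
      data.frame(level = level, node = node, metric = metric, score = score,
                 pooling = pooling), res)
  }
  hemi_m <- merge(hemi, manifest[, c("id", scores)],
                  by.x = "subject_id", by.y = "id")
  poolings <- list(pooled = c("AIS", "PVI"), AIS = "AIS", PVI = "PVI")
  for (met in hemi_metric_names) {
    for (sc in scores) {
      for (pl in names(poolings)) {
        sub <- hemi_m[hemi_m$group %in% poolings[[pl]], ]
        add_row("hemispheric", NA_character_, met, sc, pl,
                gated_correlation(sub[[met]], sub[[sc]], alpha))
      }
    }
  }
  slice <- sensorimotor_slice(nodal, atlas)
  slice_m <- merge(slice, manifest[, c("id", scores)],
                   by.x = "subject_id", by.y = "id")
  for (nd in unique(slice_m$node)) {
    sub_all <- slice_m[slice_m$node == nd & slice_m$group %in% c("AIS", "PVI"), ]
    for (met in nodal_metric_names) {
      for (sc in scores) {
        add_row("nodal", nd, met, sc, "pooled",
                gated_correlation(sub_all[[met]], sub_all[[sc]], alpha))
      }
    }
  }
  do.call(rbind, rows)
}

null_comparison_report <- function(hemi, ensemble, threshold, transform,
                                   alpha) {
  null_hemi <- lapply(ensemble$graphs, function(g) {
    gt <- density_threshold(g, threshold)
    tab <- nodal_metric_table(gt, "null", transform = transform)
    hemispheric_summary(tab, hierarchical_complexity(gt))
  })
  null_hemi <- do.call(rbind, null_hemi)
  rows <- list()
  for (met in hemi_metric_names) {
    for (g in unique(hemi$group)) {
      res <- compare_to_null(hemi[[met]][hemi$group == g], null_hemi[[met]],
                             alpha)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(metric = met, group = g,
                   empirical_mean = mean(hemi[[met]][hemi$group == g]),
                   null_mean = mean(null_hemi[[met]])), res)
    }
  }
  do.call(rbind, rows)
}

#' Run the full analysis pipeline
#'
#' Loads or simulates a cohort, applies density thresholding, computes nodal
#' and hemispheric metrics, compares groups node-by-node and
#' hemisphere-wide with the normality-gated battery, correlates metrics with
#' clinical motor scores (pooled and per stroke group), and compares every
#' hemispheric metric against an Erdős–Rényi null ensemble processed through
#' the identical thresholding path. Deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a `report_bundle`: list with `nodal_comparisons`,
#'   `hemispheric_comparisons`, `correlations`, `null_comparisons`,
#'   `manifest`, `nodal_metrics`, `hemispheric_metrics`, `log`. Written as
#'   CSVs plus `summary.txt` and `run_log.txt` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c("hemiconn pipeline run",
                 sprintf("package version: %s",
                         as.character(utils::packageVersion("hemiconn"))),
                 sprintf("mode: %s | seed: %d | threshold: %g | transform: %s",
                         config$mode, config$seed, config$threshold,
                         config$transform))
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))
  if (config$mode == "simulate") {
    say("stage: simulate cohort")
    cc <- if (is.null(config$cohort_config)) cohort_config() else config$cohort_config
    cohort <- generate_cohort(cc, seed = config$seed)
    manifest <- cohort$manifest
    matrices <- cohort$matrices
  } else {
    say("stage: load cohort from %s", config$manifest_path)
    manifest <- read_manifest(config$manifest_path)
    base <- dirname(config$manifest_path)
    matrices <- lapply(manifest$matrix_path, function(p) {
      read_adjacency(file.path(base, p))
    })
    names(matrices) <- manifest$id
  }
  say("subjects: %d (%s)", nrow(manifest),
      paste(sprintf("%s=%d", names(table(manifest$group)),
                    table(manifest$group)), collapse = ", "))
  say("stage: threshold + metrics")
  met <- cohort_metrics(manifest, matrices, config$atlas, config$threshold,
                        config$transform)
  alpha <- config$stats$alpha
  family <- config$stats$bonferroni_family
  say("stage: nodal group comparisons (alpha = %g, Bonferroni family = %d)",
      alpha, family)
  nodal_cmp <- nodal_comparison_report(met$nodal, config$atlas, alpha, family)
  say("gate decisions (nodal): %s",
      paste(sprintf("%s/%s=%s", nodal_cmp$node, nodal_cmp$metric,
                    nodal_cmp$test), collapse = " "))
  say("stage: hemispheric group comparisons")
  hemi_cmp <- hemispheric_comparison_report(met$hemispheric, alpha, family)
  say("gate decisions (hemispheric): %s",
      paste(sprintf("%s=%s", hemi_cmp$metric, hemi_cmp$test), collapse = " "))
  say("stage: brain-behaviour correlations")
  corr <- correlation_report(met$nodal, met$hemispheric, manifest,
                             config$atlas, alpha)
  say("stage: null-model comparison")
  n_graphs <- config$null$n_graphs
  if (is.null(n_graphs)) {
    n_graphs <- null_ensemble_size(as.integer(table(manifest$group)))
  }
  p_edge <- config$null$p_edge
  if (identical(p_edge, "auto")) p_edge <- met$mean_density
  pool <- NULL
  if (config$null$weight_rule == "empirical") {
    pool <- unlist(lapply(matrices, function(m) {
      w <- as_weights(m); w[upper.tri(w) & w > 0]
    }), use.names = FALSE)
  }
  ensemble <- build_null_ensemble(
    n_graphs = n_graphs, n = length(config$atlas$all_labels),
    p_edge = p_edge, weight_rule = config$null$weight_rule,
    weight_pool = pool, seed = derive_seeds(config$seed, 1),
    labels = config$atlas$all_labels)
  say("null ensemble: %d ER graphs, p_edge = %.4f, weights = %s",
      n_graphs, p_edge, config$null$weight_rule)
  null_cmp <- null_comparison_report(met$hemispheric, ensemble,
                                     config$threshold, config$transform,
                                     alpha)
  bundle <- structure(list(
    nodal_comparisons = nodal_cmp,
    hemispheric_comparisons = hemi_cmp,
    correlations = corr,
    null_comparisons = null_cmp,
    manifest = manifest,
    nodal_metrics = met$nodal,
    hemispheric_metrics = met$hemispheric,
    log = log_lines), class = "report_bundle")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, f) utils::write.csv(df, file.path(config$out_dir, f),
                                           row.names = FALSE, na = "")
    wr(nodal_cmp, "nodal_comparisons.csv")
    wr(hemi_cmp, "hemispheric_comparisons.csv")
    wr(corr, "correlations.csv")
    wr(null_cmp, "null_comparisons.csv")
    wr(met$nodal, "nodal_metrics.csv")
    wr(met$hemispheric, "hemispheric_metrics.csv")
    writeLines(summarize_run(bundle), file.path(config$out_dir, "summary.txt"))
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  }
  invisible(bundle)
}

#' Human-readable summary of a report bundle
#'
#' One text block per report, with group values in `mean ± SD` style.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @return character vector of lines.
#' @export
summarize_run <- function(bundle) {
  stopifnot(inherits(bundle, "report_bundle"))
  fmt_ms <- function(m, s) sprintf("%.3g ± %.3g", m, s)
  out <- c("== Nodal group comparisons ==")
  nc <- bundle$nodal_comparisons
  for (r in seq_len(nrow(nc))) {
    out <- c(out, sprintf(
      "%-4s %-26s %s: AIS %s | PVI %s | TDC %s | %s p = %.4g",
      nc$node[r], nc$metric[r], nc$test[r],
      fmt_ms(nc$mean_AIS[r], nc$sd_AIS[r]),
      fmt_ms(nc$mean_PVI[r], nc$sd_PVI[r]),
      fmt_ms(nc$mean_TDC[r], nc$sd_TDC[r]),
      nc$test[r], nc$p[r]))
  }
  out <- c(out, "", "== Hemispheric group comparisons ==")
  hc <- bundle$hemispheric_comparisons
  for (r in seq_len(nrow(hc))) {
    out <- c(out, sprintf(
      "%-26s %s: AIS %s | PVI %s | TDC %s | p = %.4g",
      hc$metric[r], hc$test[r],
      fmt_ms(hc$mean_AIS[r], hc$sd_AIS[r]),
      fmt_ms(hc$mean_PVI[r], hc$sd_PVI[r]),
      fmt_ms(hc$mean_TDC[r], hc$sd_TDC[r]), hc$p[r]))
  }
  out <- c(out, "", "== Brain-behaviour correlations ==")
  cr <- bundle$correlations
  if (is.null(cr) || nrow(cr) == 0) {
    out <- c(out, "(no clinical scores supplied)")
  } else {
    for (r in seq_len(nrow(cr))) {
      out <- c(out, sprintf(
        "%-11s %-4s %-26s ~ %-4s [%s] %s = %.3f (p = %.4g, n = %d)",
        cr$level[r], ifelse(is.na(cr$node[r]), "", cr$node[r]), cr$metric[r],
        cr$score[r], cr$pooling[r],
        ifelse(cr$method[r] == "pearson", "r", "r_s"),
        cr$estimate[r], cr$p[r], cr$n[r]))
    }
  }
  out <- c(out, "", "== Null-model comparisons ==")
  nl <- bundle$null_comparisons
  for (r in seq_len(nrow(nl))) {
    out <- c(out, sprintf(
      "%-26s %s: empirical mean %.4g vs null mean %.4g | %s p = %.4g",
      nl$metric[r], nl$group[r], nl$empirical_mean[r], nl$null_mean[r],
      nl$test[r], nl$p[r]))
  }
  out
}
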