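#' Configuration for the synthetic three-group cohort generator
#'
#' Defaults reproduce the study conditions the analysis assumes: group sizes
#' 26 AIS / 27 PVI / 32 TDC, 47 regions per hemisphere, heavy-tailed
#' (log-normal) streamline-count weights, stroke-group topology effects
#' (M1/S1 hub displacement, sensorimotor clique densification, thalamic
#' detachment, background degree homogenisation), clinical motor scores with
#' the published group means and SDs, and a configurable negative rank
#' correlation between realised M1/S1/SMA clustering and AHA/MA.
#'
#' @param n_ais,n_pvi,n_tdc group sizes (each >= 2).
#' @param atlas a `node_atlas` (default [default_atlas()]).
#' @param density baseline scaffold edge probability, in (0, 1).
#' @param weight_meanlog,weight_sdlog log-normal weight parameters
#'   (streamline counts).
#' @param hub_frac fraction of eligible nodes a hub connects to.
#' @param hub_weight_mult weight multiplier on hub edges.
#' @param clique_p edge probability inside the densified sensorimotor
#'   community of stroke subjects.
#' @param clique_weight_mult weight multiplier on community and subcortical
#'   edges.
#' @param stroke_bg_keep fraction of background edges M1/S1 retain under hub
#'   suppression.
#' @param thalamus_detach_mult weight multiplier applied to thalamic
#'   sensorimotor edges in stroke groups.
#' @param order_strength strength of the stroke-group degree homogenisation
#'   (0 disables).
#' @param edge_jitter per-subject probability of removing an existing
#'   scaffold edge (absent pairs are added at the density-matched rate).
#' @param weight_noise_sdlog sd (log scale) of subject-level multiplicative
#'   weight noise; sized so nodal metric dispersions approach the large
#'   between-subject SDs seen in streamline-count connectomes.
#' @param clique_scale_sdlog sd (log scale) of the shared subject-level
#'   multiplier on sensorimotor-community weights in stroke subjects — the
#'   latent "local hyperconnectivity" severity that M1/S1/SMA clustering
#'   (and through it the motor scores) all load on.
#' @param rho_clinical Gaussian-copula correlation linking M1/S1/SMA
#'   clustering to AHA and MA across stroke subjects; in (-1, 0].
#' @param effects named logical list of stroke-effect toggles:
#'   `hub_suppression`, `local_clustering_boost`, `thalamus_clustering_drop`,
#'   `hemispheric_order_increase`, `control_neutral`.
#' @param threshold density-threshold fraction used when realising the
#'   clustering values that drive the clinical scores.
#' @param seed master seed; recorded in all outputs.
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_ais = 26, n_pvi = 27, n_tdc = 32,
                          atlas = default_atlas(),
                          density = 0.45,
                          weight_meanlog = log(150), weight_sdlog = 0.8,
                          hub_frac = 0.85, hub_weight_mult = 1.5,
                          clique_p = 0.95, clique_weight_mult = 2.5,
                          stroke_bg_keep = 0.6,
                          thalamus_detach_mult = 0.25,
                          order_strength = 0.3,
                          edge_jitter = 0.1,
                          weight_noise_sdlog = 0.5,
                          clique_scale_sdlog = 0.3,
                          rho_clinical = -0.5,
                          effects = list(),
                          threshold = 0.25,
                          seed = 1) {
  stopifnot(n_ais >= 2, n_pvi >= 2, n_tdc >= 2,
            inherits(atlas, "node_atlas"))
  if (density <= 0 || density >= 1) {
    stop_hc("density must lie in (0, 1)", "hemiconn_bad_probability")
  }
  if (rho_clinical > 0 || rho_clinical <= -1) {
    stop_hc("rho_clinical must lie in (-1, 0]", "hemiconn_bad_probability")
  }
  eff <- list(hub_suppression = TRUE, local_clustering_boost = TRUE,
              thalamus_clustering_drop = TRUE,
              hemispheric_order_increase = TRUE, control_neutral = TRUE)
  eff[names(effects)] <- effects
  clinical <- list(
    # mean, sd per group; observed counts emulate the study's completion rates
    AHA  = list(AIS = c(56.1, 18.7), PVI = c(68.4, 15.7),
                n_obs = c(AIS = 26, PVI = 23)),
    MA   = list(AIS = c(68.8, 22.4), PVI = c(88.0, 10.6),
                n_obs = c(AIS = 20, PVI = 14)),
    BBTA = list(AIS = c(23.0, 16.6), PVI = c(36.3, 13.4),
                n_obs = c(AIS = 26, PVI = 23)),
    BBTU = list(AIS = c(44.0, 14.5), PVI = c(49.0, 16.8),
                n_obs = c(AIS = 26, PVI = 23)))
  demographics <- list(
    age = list(AIS = c(12.7, 4.0), PVI = c(11.5, 3.7), TDC = c(13.3, 3.6)),
    age_range = c(6.4, 19.7),
    male_prop = c(AIS = 0.58, PVI = 0.63, TDC = 0.53),
    lesion_meanlog = log(15), lesion_sdlog = 1)
  structure(list(
    n_ais = n_ais, n_pvi = n_pvi, n_tdc = n_tdc, atlas = atlas,
    density = density, weight_meanlog = weight_meanlog,
    weight_sdlog = weight_sdlog, hub_frac = hub_frac,
    hub_weight_mult = hub_weight_mult, clique_p = clique_p,
    clique_weight_mult = clique_weight_mult,
    stroke_bg_keep = stroke_bg_keep,
    thalamus_detach_mult = thalamus_detach_mult,
    order_strength = order_strength, edge_jitter = edge_jitter,
    weight_noise_sdlog = weight_noise_sdlog,
    clique_scale_sdlog = clique_scale_sdlog,
    rho_clinical = rho_clinical, effects = eff,
    clinical = clinical, demographics = demographics,
    threshold = threshold, seed = seed),
    class = "cohort_config")
}

# structural roles within the atlas: the sensorimotor community, the two
# surrogate hub nodes that absorb the hub role in stroke groups, and the
# subcortical motor set
atlas_blocks <- function(atlas) {
  sm_extra <- intersect(c("Rolandic_Oper_L", "Paracentral_Lobule_L",
                          "Insula_L", "Parietal_Sup_L", "Cingulate_Mid_L"),
                        atlas$all_labels)
  sm_block <- unique(c(unname(atlas$sensorimotor), sm_extra))
  candidates <- setdiff(atlas$all_labels, c(sm_block, atlas$control))
  list(sm_block = sm_block,
       hubs_tdc = unname(atlas$sensorimotor[c("M1", "S1")]),
       hubs_stroke = candidates[seq_len(2)],
       subcortical = unname(atlas$sensorimotor[c("thalamus", "caudate",
                                                 "putamen", "pallidum")]),
       thalamus = unname(atlas$sensorimotor[["thalamus"]]),
       control = atlas$control)
}

# symmetric assignment helper: set both triangles from an index matrix
set_sym <- function(w, idx, values) {
  w[idx] <- values
  w[idx[, c(2, 1), drop = FALSE]] <- values
  w
}

# upper-triangle index pairs within a label set / between two sets
pairs_within <- function(labels, all) {
  i <- match(labels, all)
  if (length(i) < 2) return(matrix(integer(0), 0, 2))
  cmb <- t(utils::combn(sort(i), 2))
  cmb
}
pairs_between <- function(a, b, all) {
  ia <- match(a, all); ib <- match(b, all)
  g <- expand.grid(ia, ib)
  g <- g[g[, 1] != g[, 2], ]
  cbind(pmin(g[, 1], g[, 2]), pmax(g[, 1], g[, 2]))
}

rlnorm_w <- function(k, config) {
  stats::rlnorm(k, config$weight_meanlog, config$weight_sdlog)
}

# shared cohort scaffold drawn once under its own seed
build_scaffold <- function(config, seed) {
  atlas <- config$atlas
  n <- length(atlas$all_labels)
  blocks <- atlas_blocks(atlas)
  withr::with_seed(seed, {
    w <- matrix(0, n, n, dimnames = list(atlas$all_labels, atlas$all_labels))
    ut <- which(upper.tri(w))
    present <- stats::rbinom(length(ut), 1, config$density) == 1
    w[ut[present]] <- rlnorm_w(sum(present), config)
    w <- w + t(w) - diag(diag(w))
    # subcortical motor loop: fully wired with strongly boosted weights in
    # every group, so control thalami carry heavy closed triplets that the
    # stroke-group thalamic detachment can remove
    sub_idx <- pairs_within(blocks$subcortical, atlas$all_labels)
    w <- set_sym(w, sub_idx,
                 4 * config$clique_weight_mult * rlnorm_w(nrow(sub_idx), config))
    if (config$effects$control_neutral) {
      # the negative-control node never touches group-modulated nodes
      prot <- pairs_between(blocks$control,
                            c(blocks$sm_block, blocks$hubs_stroke),
                            atlas$all_labels)
      w <- set_sym(w, prot, 0)
    }
    diag(w) <- 0
    w
  })
}

# one subject's matrix: scaffold + jitter + group effects + weight noise
build_subject_matrix <- function(scaffold, group, config, blocks, seed) {
  atlas <- config$atlas
  all <- atlas$all_labels
  n <- length(all)
  eff <- config$effects
  stroke <- group %in% c("AIS", "PVI")
  withr::with_seed(seed, {
    w <- scaffold
    ut <- which(upper.tri(w))
    # topological jitter, identical in distribution for every group
    on_e <- ut[w[ut] > 0]
    off_e <- ut[w[ut] == 0]
    drop <- on_e[stats::runif(length(on_e)) < config$edge_jitter]
    p_add <- config$edge_jitter * config$density / (1 - config$density)
    add <- off_e[stats::runif(length(off_e)) < p_add]
    w[drop] <- 0
    w[add] <- rlnorm_w(length(add), config)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    if (eff$control_neutral) {
      prot <- pairs_between(blocks$control,
                            c(blocks$sm_block, blocks$hubs_stroke), all)
      w <- set_sym(w, prot, 0)
    }
    # hub wiring: M1/S1 act as inter-community hubs in controls; under hub
    # suppression the hub role is displaced onto two fixed background nodes
    hubs <- if (stroke && eff$hub_suppression) blocks$hubs_stroke else blocks$hubs_tdc
    for (h in hubs) {
      eligible <- setdiff(all, c(h, blocks$control))
      idx <- pairs_between(h, eligible, all)
      on <- stats::runif(nrow(idx)) < config$hub_frac
      vals <- numeric(nrow(idx))
      vals[on] <- config$hub_weight_mult * rlnorm_w(sum(on), config)
      w <- set_sym(w, idx, vals)
    }
    if (stroke && eff$hub_suppression) {
      # former hubs lose most long-range background edges
      for (h in blocks$hubs_tdc) {
        bg <- setdiff(all, c(blocks$sm_block, blocks$control, h))
        idx <- pairs_between(h, bg, all)
        cur <- w[idx]
        keep <- stats::runif(nrow(idx)) < config$stroke_bg_keep
        w <- set_sym(w, idx, cur * keep)
      }
    }
    if (stroke && eff$local_clustering_boost) {
      # densely intra-connected sensorimotor neighbourhood around M1/S1/SMA:
      # the three cortical motor nodes are wired into the community at high
      # density, while edges among the supporting community members keep
      # their scaffold presence and only gain weight. Keeping support-edge
      # presence unchanged confines the binary-degree footprint to the three
      # manipulated nodes, so degree-class metrics elsewhere stay clean.
      # A shared subject-level severity factor scales the whole community so
      # M1, S1 and SMA clustering co-vary across subjects.
      clique <- blocks$sm_block
      if (eff$thalamus_clustering_drop) clique <- setdiff(clique, blocks$thalamus)
      cortical <- intersect(clique, unname(
        config$atlas$sensorimotor[c("M1", "S1", "SMA")]))
      severity <- exp(stats::rnorm(1, 0, config$clique_scale_sdlog))
      idx <- pairs_within(clique, all)
      cort_idx <- match(cortical, all)
      involves_cortical <- (idx[, 1] %in% cort_idx) | (idx[, 2] %in% cort_idx)
      present <- w[idx] > 0
      present[involves_cortical] <-
        stats::runif(sum(involves_cortical)) < config$clique_p
      vals <- numeric(nrow(idx))
      vals[present] <- severity * config$clique_weight_mult *
        rlnorm_w(sum(present), config)
      w <- set_sym(w, idx, vals)
    }
    if (stroke && eff$thalamus_clustering_drop) {
      idx <- pairs_between(blocks$thalamus,
                           setdiff(blocks$sm_block, blocks$thalamus), all)
      w <- set_sym(w, idx, w[idx] * config$thalamus_detach_mult)
    }
    if (stroke && eff$hemispheric_order_increase && config$order_strength > 0) {
      # compress the background degree distribution: high-degree deep
      # background nodes shed edges, lowering degree diversity
      deep <- setdiff(all, c(blocks$sm_block, blocks$hubs_stroke,
                             blocks$control))
      if (eff$control_neutral) {
        iog_nb <- all[scaffold[match(blocks$control, all), ] > 0]
        deep <- setdiff(deep, iog_nb)
      }
      k <- rowSums(w > 0)
      kbar <- mean(k[match(deep, all)])
      idx <- pairs_within(deep, all)
      idx <- idx[w[idx] > 0, , drop = FALSE]
      if (nrow(idx)) {
        excess <- pmax(0, (k[idx[, 1]] + k[idx[, 2]]) / 2 - kbar) / kbar
        p_rm <- pmin(0.8, config$order_strength * excess)
        gone <- stats::runif(nrow(idx)) < p_rm
        w <- set_sym(w, idx[gone, , drop = FALSE], 0)
      }
    }
    # subject-level multiplicative weight noise
    noisy <- which(upper.tri(w) & w > 0)
    w[noisy] <- w[noisy] * exp(stats::rnorm(length(noisy), 0,
                                            config$weight_noise_sdlog))
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    diag(w) <- 0
    weighted_adjacency(w)
  })
}

#' Generate clinical motor scores coupled to realised clustering
#'
#' AHA and MA are drawn through a Gaussian copula on the ranks of the
#' supplied sensorimotor clustering values, giving the configured negative
#' rank correlation (plus independent noise); BBT scores are drawn
#' independently of all metrics. AHA/MA are clipped to \[0, 100\]; BBT
#' scores are non-negative integers. Per-score missingness reproduces the
#' configured observation counts.
#'
#' @param clustering numeric vector of realised mean M1/S1/SMA clustering,
#'   one value per stroke subject.
#' @param groups character vector (`"AIS"`/`"PVI"`) aligned with
#'   `clustering`.
#' @param config a `cohort_config`.
#' @param seed integer seed.
#' @return data.frame with columns `AHA, MA, BBTA, BBTU` aligned with the
#'   input (`NA` = not observed).
#' @export
generate_clinical_scores <- function(clustering, groups, config, seed) {
  stopifnot(all(is.finite(clustering)), length(clustering) == length(groups))
  n <- length(clustering)
  rho <- config$rho_clinical
  withr::with_seed(seed, {
    z_c <- stats::qnorm((rank(clustering, ties.method = "average") - 0.5) / n)
    draw_coupled <- function(score) {
      z <- rho * z_c + sqrt(1 - rho^2) * stats::rnorm(n)
      mu <- vapply(groups, function(g) config$clinical[[score]][[g]][1], 1)
      sd <- vapply(groups, function(g) config$clinical[[score]][[g]][2], 1)
      pmin(100, pmax(0, mu + sd * z))
    }
    draw_free <- function(score) {
      mu <- vapply(groups, function(g) config$clinical[[score]][[g]][1], 1)
      sd <- vapply(groups, function(g) config$clinical[[score]][[g]][2], 1)
      round(pmax(0, mu + sd * stats::rnorm(n)))
    }
    out <- data.frame(AHA = draw_coupled("AHA"), MA = draw_coupled("MA"),
                      BBTA = draw_free("BBTA"), BBTU = draw_free("BBTU"))
    for (score in names(config$clinical)) {
      for (g in c("AIS", "PVI")) {
        members <- which(groups == g)
        n_obs <- min(config$clinical[[score]]$n_obs[[g]], length(members))
        unobserved <- setdiff(members, sample(members, n_obs))
        out[unobserved, score] <- NA_real_
      }
    }
    out
  })
}

#' Generate a synthetic three-group cohort
#'
#' Builds one weighted 47 x 47 hemispheric matrix per subject from a shared
#' scaffold graph, group-specific topology effects and subject-level noise,
#' then attaches demographics and clinical scores. Byte-identical output for
#' a fixed config and seed. See `cohort_config()` for the effect structure.
#'
#' @param config a `cohort_config`.
#' @param seed master seed; defaults to `config$seed`.
#' @return an object of class `synthetic_cohort`: list with `manifest`
#'   (data.frame), `matrices` (named list of `weighted_adjacency`),
#'   `config`, `seed`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  atlas <- config$atlas
  blocks <- atlas_blocks(atlas)
  groups <- c(rep("AIS", config$n_ais), rep("PVI", config$n_pvi),
              rep("TDC", config$n_tdc))
  n_sub <- length(groups)
  ids <- sprintf("%s%02d", groups,
                 stats::ave(seq_len(n_sub), groups, FUN = seq_along))
  seeds <- derive_seeds(seed, n_sub + 3)
  scaffold <- build_scaffold(config, seeds[n_sub + 1])
  m1 <- unname(atlas$sensorimotor[["M1"]])
  if (sum(scaffold[m1, ] > 0) == 0) {
    stop_hc("scaffold disconnected at M1; increase density", "hemiconn_scaffold")
  }
  matrices <- stats::setNames(vector("list", n_sub), ids)
  for (i in seq_len(n_sub)) {
    matrices[[i]] <- build_subject_matrix(scaffold, groups[i], config, blocks,
                                          seeds[i])
    if (sum(as_weights(matrices[[i]])[m1, ] > 0) == 0) {
      stop_hc("subject matrix disconnected at M1", "hemiconn_scaffold")
    }
  }
  # realised sensorimotor clustering (post-threshold) drives the scores
  stroke_idx <- which(groups != "TDC")
  sm3 <- unname(atlas$sensorimotor[c("M1", "S1", "SMA")])
  clust_sm <- vapply(stroke_idx, function(i) {
    cc <- clustering_coefficients(
      density_threshold(matrices[[i]], config$threshold))$nodal
    mean(cc[sm3])
  }, 1)
  scores <- generate_clinical_scores(clust_sm, groups[stroke_idx], config,
                                     seeds[n_sub + 2])
  full_scores <- data.frame(AHA = rep(NA_real_, n_sub), MA = NA_real_,
                            BBTA = NA_real_, BBTU = NA_real_)
  full_scores[stroke_idx, ] <- scores
  demo <- withr::with_seed(seeds[n_sub + 3], {
    d <- config$demographics
    age <- vapply(groups, function(g) {
      stats::rnorm(1, d$age[[g]][1], d$age[[g]][2])
    }, 1)
    age <- round(pmin(d$age_range[2], pmax(d$age_range[1], age)), 1)
    sex <- ifelse(stats::runif(n_sub) < d$male_prop[groups], "M", "F")
    lesion <- ifelse(groups == "TDC", NA_real_,
                     round(stats::rlnorm(n_sub, d$lesion_meanlog,
                                         d$lesion_sdlog), 2))
    data.frame(age = age, sex = sex, lesion_volume = lesion)
  })
  manifest <- data.frame(id = ids, group = groups, age = demo$age,
                         sex = demo$sex, lesion_volume = demo$lesion_volume,
                         full_scores,
                         matrix_path = paste0(ids, ".csv"),
                         stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  structure(list(manifest = manifest, matrices = matrices, config = config,
                 seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%s), %d nodes, seed = %d\n",
              nrow(x$manifest),
              paste(sprintf("%d %s", table(x$manifest$group),
                            names(table(x$manifest$group))), collapse = ", "),
              nrow(x$matrices[[1]]), x$seed))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Emits one adjacency CSV per subject, the manifest CSV, and a metadata
#' YAML recording the generator configuration and seed. Matrices round-trip
#' through [read_adjacency()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$matrices)) {
    write_adjacency(cohort$matrices[[id]], file.path(dir, paste0(id, ".csv")))
  }
  utils::write.csv(cohort$manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE, na = "")
  cfg <- cohort$config
  meta <- list(seed = cohort$seed,
               n_subjects = nrow(cohort$manifest),
               n_nodes = length(cfg$atlas$all_labels),
               config = cfg[setdiff(names(cfg), "atlas")],
               atlas_labels = cfg$atlas$all_labels,
               sensorimotor = as.list(cfg$atlas$sensorimotor),
               control = cfg$atlas$control)
  yaml::write_yaml(meta, file.path(dir, "metadata.yaml"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir cohort directory containing `manifest.csv` and per-subject
#'   adjacency CSVs.
#' @return list with `manifest` and `matrices`.
#' @export
read_cohort <- function(dir) {
  manifest <- read_manifest(file.path(dir, "manifest.csv"))
  matrices <- lapply(manifest$matrix_path, function(p) {
    read_adjacency(file.path(dir, p))
  })
  names(matrices) <- manifest$id
  list(manifest = manifest, matrices = matrices)
}
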