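#' Node degrees
#'
#' Degree is the number of non-zero edges incident to a node; weights are
#' ignored.
#'
#' @param A a `weighted_adjacency`.
#' @return named integer vector of degrees.
#' @export
node_degrees <- function(A) {
  stopifnot(is_weighted_adjacency(A))
  w <- as_weights(A)
  diag(w) <- 0
  stats::setNames(as.integer(rowSums(w > 0)), node_labels(A))
}

# weight -> edge length for shortest paths. Streamline count is a strength:
# stronger connections are "shorter". Absent edges map to Inf.
weight_to_length <- function(w, transform = c("inverse", "unit")) {
  transform <- match.arg(transform)
  L <- switch(transform, inverse = 1 / w, unit = (w > 0) * 1)
  L[w <= 0] <- Inf
  diag(L) <- Inf
  L
}

# single-source Dijkstra keeping shortest-path counts.
# L: length matrix (Inf = no edge). Ties in path length are detected with an
# absolute tolerance; exact for unit lengths, conservative for 1/w lengths.
dijkstra_counts <- function(L, s, tol = 1e-10) {
  n <- nrow(L)
  dist <- rep(Inf, n); dist[s] <- 0
  sigma <- numeric(n); sigma[s] <- 1
  done <- logical(n)
  repeat {
    open <- which(!done & is.finite(dist))
    if (!length(open)) break
    u <- open[which.min(dist[open])]
    done[u] <- TRUE
    alt <- dist[u] + L[u, ]
    relax <- !done & (alt < dist - tol)
    tie <- !done & !relax & is.finite(alt) & (abs(alt - dist) <= tol)
    if (any(relax)) {
      dist[relax] <- alt[relax]
      sigma[relax] <- sigma[u]
    }
    if (any(tie)) sigma[tie] <- sigma[tie] + sigma[u]
  }
  list(dist = dist, sigma = sigma)
}

#' All-pairs shortest-path tallies
#'
#' For every ordered node pair `(h, j)` computes the shortest-path length,
#' the number of distinct shortest paths `rho_hj`, and the number of those
#' passing through each intermediate node `i` (`rho_hj(i)`). Edge lengths
#' are obtained from weights by the `transform` rule (default `1/w`, the
#' standard strength-to-length map for streamline-count connectomes).
#' Unreachable pairs contribute zero tallies.
#'
#' @param A a `weighted_adjacency`.
#' @param transform `"inverse"` (length `1/w`) or `"unit"` (all edges
#'   length 1).
#' @param tol absolute tolerance for detecting equal path lengths.
#' @return an object of class `sp_tally`: list with `lengths` (n x n
#'   distance matrix), `counts` (n x n matrix, `rho_hj`), and `via`
#'   (n x n x n array, `via[h, j, i] = rho_hj(i)`).
#' @export
shortest_path_tallies <- function(A, transform = c("inverse", "unit"),
                                  tol = 1e-10) {
  stopifnot(is_weighted_adjacency(A))
  transform <- match.arg(transform)
  w <- as_weights(A)
  L <- weight_to_length(w, transform)
  n <- nrow(w)
  dist <- matrix(Inf, n, n)
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- dijkstra_counts(L, s, tol)
    dist[s, ] <- d$dist
    nsp[s, ] <- d$sigma
  }
  via <- array(0, c(n, n, n), dimnames = rep(list(node_labels(A)), 3))
  for (i in seq_len(n)) {
    # i lies on a shortest h -> j path iff d(h,i) + d(i,j) = d(h,j);
    # the count of such paths is rho_hi * rho_ij
    through <- abs(outer(dist[, i], dist[i, ], "+") - dist) <= tol
    through[is.na(through)] <- FALSE
    cnt <- outer(nsp[, i], nsp[i, ]) * through
    cnt[i, ] <- 0; cnt[, i] <- 0; diag(cnt) <- 0
    via[, , i] <- cnt
  }
  dimnames(dist) <- dimnames(nsp) <- list(node_labels(A), node_labels(A))
  structure(list(lengths = dist, counts = nsp, via = via, transform = transform),
            class = "sp_tally")
}

#' Betweenness centrality
#'
#' For node `i`, the sum over ordered pairs `h != j` (both distinct from
#' `i`) of the fraction of shortest `h`-`j` paths passing through `i`. The
#' raw sum is the default output; the normalised variant divides by
#' `(n - 1)(n - 2)` so a star centre scores 1. Leaf (degree-1) nodes score
#' 0. Unreachable pairs contribute nothing.
#'
#' @param A a `weighted_adjacency` (`n >= 3` for the normalised variant).
#' @param normalized logical; divide by `(n - 1)(n - 2)`.
#' @param transform weight-to-length rule, see [shortest_path_tallies()].
#' @param tol shortest-path tie tolerance.
#' @return named numeric vector of centralities.
#' @export
betweenness_centrality <- function(A, normalized = FALSE,
                                   transform = c("inverse", "unit"),
                                   tol = 1e-10) {
  stopifnot(is_weighted_adjacency(A))
  transform <- match.arg(transform)
  n <- nrow(A)
  if (normalized && n < 3) {
    stop_hc("normalized betweenness requires n >= 3", "hemiconn_too_small")
  }
  w <- as_weights(A)
  L <- weight_to_length(w, transform)
  dist <- matrix(Inf, n, n)
  nsp <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- dijkstra_counts(L, s, tol)
    dist[s, ] <- d$dist
    nsp[s, ] <- d$sigma
  }
  b <- numeric(n)
  for (i in seq_len(n)) {
    through <- abs(outer(dist[, i], dist[i, ], "+") - dist) <= tol
    through[is.na(through)] <- FALSE
    num <- outer(nsp[, i], nsp[i, ])
    sel <- through & nsp > 0
    sel[i, ] <- FALSE; sel[, i] <- FALSE; diag(sel) <- FALSE
    b[i] <- sum(num[sel] / nsp[sel])
  }
  if (normalized) b <- b / ((n - 1) * (n - 2))
  stats::setNames(b, node_labels(A))
}

#' Weighted clustering coefficients
#'
#' Nodal coefficient `c_i = 2 t_i / (k_i (k_i - 1))`, where `t_i` is the
#' weighted closed-triplet mass around `i`: the sum over triangles at `i` of
#' the geometric mean of the three edge weights, computed on raw
#' (unrescaled) weights so the coefficient carries the scale of the
#' streamline counts. Nodes with degree below 2 have no possible triplets
#' and score 0. With all weights equal to 1 this is the classic binary local
#' clustering coefficient (closed / possible triplets). The hemispheric
#' summary `C^W` is the plain mean of the nodal values.
#'
#' @param A a `weighted_adjacency`.
#' @param rescale logical; divide weights by the maximum weight first, which
#'   bounds the coefficients by 1. Default `FALSE` (raw weights).
#' @return list with `nodal` (named numeric vector `c_i`) and `hemispheric`
#'   (`C^W`, mean over all nodes).
#' @export
clustering_coefficients <- function(A, rescale = FALSE) {
  stopifnot(is_weighted_adjacency(A))
  w <- as_weights(A)
  diag(w) <- 0
  if (rescale && max(w) > 0) w <- w / max(w)
  cw <- w^(1 / 3)
  t_i <- diag(cw %*% cw %*% cw) / 2
  k <- rowSums(w > 0)
  c_i <- ifelse(k >= 2, 2 * t_i / (k * (k - 1)), 0)
  list(nodal = stats::setNames(c_i, node_labels(A)),
       hemispheric = mean(c_i))
}

# ascending neighbourhood degree sequences and degree classes of the
# binarized graph; shared by the two complexity metrics
degree_classes <- function(A) {
  w <- as_weights(A)
  diag(w) <- 0
  B <- w > 0
  k <- rowSums(B)
  seqs <- lapply(seq_len(nrow(B)), function(i) sort(k[B[i, ]]))
  list(k = k, seqs = seqs, D = length(unique(k)))
}

#' Hierarchical complexity of the degree hierarchy
#'
#' For each degree class `K_p` (all nodes of degree `p`) with at least two
#' members, take every member's ascending neighbourhood degree sequence
#' `s_i^p` and the entrywise class mean `mu^p`; the class contributes the
#' entrywise squared deviations summed over members and entries, scaled by
#' `1 / (p (|K_p| - 1))`. `R` is the average of the class contributions over
#' the `D` distinct degrees present in the network. `R = 0` for regular
#' graphs (all neighbourhood sequences identical within each class); larger
#' `R` means nodes of equal degree attach to structurally more diverse
#' neighbourhoods. Computed on the binarized graph: the metric is a
#' function of integer degrees.
#'
#' @param A a `weighted_adjacency`; binarized internally.
#' @return `R`, a non-negative scalar.
#' @export
hierarchical_complexity <- function(A) {
  dc <- degree_classes(A)
  total <- 0
  for (p in unique(dc$k)) {
    if (p < 1) next
    Kp <- which(dc$k == p)
    if (length(Kp) < 2) next
    S <- do.call(rbind, dc$seqs[Kp])      # |Kp| x p
    dev <- sweep(S, 2, colMeans(S))
    total <- total + sum(dev^2) / (p * (length(Kp) - 1))
  }
  total / dc$D
}

#' Nodal neighbourhood complexity
#'
#' The nodal contribution to [hierarchical_complexity()]: for node `i` of
#' degree `p` in a class with `|K_p| > 1`,
#' `nc_i = sum_j (s_i^p(j) - mu^p(j))^2 / (p (|K_p| - 1))`. Nodes whose
#' degree is unique in the graph (or zero) have no within-class reference
#' and are undefined (`NA`); the hemispheric value is the mean over defined
#' nodes. Summing `nc_i` over all defined nodes recovers `R * D`.
#'
#' @param A a `weighted_adjacency`; binarized internally.
#' @return list with `nodal` (named numeric vector, `NA` where undefined)
#'   and `hemispheric` (mean over defined nodes, `NaN` if none).
#' @export
neighbourhood_complexity <- function(A) {
  dc <- degree_classes(A)
  n <- length(dc$k)
  nc <- rep(NA_real_, n)
  for (p in unique(dc$k)) {
    if (p < 1) next
    Kp <- which(dc$k == p)
    if (length(Kp) < 2) next
    S <- do.call(rbind, dc$seqs[Kp])
    dev <- sweep(S, 2, colMeans(S))
    nc[Kp] <- rowSums(dev^2) / (p * (length(Kp) - 1))
  }
  list(nodal = stats::setNames(nc, node_labels(A)),
       hemispheric = mean(nc, na.rm = TRUE))
}

#' Nodal metric table for one subject
#'
#' Computes degree, betweenness centrality (raw and normalised), weighted
#' clustering and neighbourhood complexity for every node of a (typically
#' already thresholded) matrix.
#'
#' @param A a `weighted_adjacency`.
#' @param subject_id identifier recorded in the table.
#' @param transform weight-to-length rule for betweenness.
#' @return data.frame with columns `subject_id, node_label, degree,
#'   betweenness_raw, betweenness_norm, clustering,
#'   neighbourhood_complexity`.
#' @export
nodal_metric_table <- function(A, subject_id, transform = c("inverse", "unit")) {
  transform <- match.arg(transform)
  n <- nrow(A)
  b_raw <- betweenness_centrality(A, normalized = FALSE, transform = transform)
  data.frame(
    subject_id = subject_id,
    node_label = node_labels(A),
    degree = as.integer(node_degrees(A)),
    betweenness_raw = unname(b_raw),
    betweenness_norm = unname(b_raw) / ((n - 1) * (n - 2)),
    clustering = unname(clustering_coefficients(A)$nodal),
    neighbourhood_complexity = unname(neighbourhood_complexity(A)$nodal),
    stringsAsFactors = FALSE)
}

#' Restrict a nodal metric table to the sensorimotor nodes
#'
#' Keeps the rows for the named sensorimotor regions plus the negative
#' control node, in atlas order.
#'
#' @param table a nodal metric table ([nodal_metric_table()], possibly
#'   row-bound over subjects).
#' @param atlas a `node_atlas`.
#' @return the reduced data.frame with an extra `node` column holding the
#'   short names (M1, S1, SMA, ..., IOG).
#' @export
sensorimotor_slice <- function(table, atlas) {
  stopifnot(inherits(atlas, "node_atlas"))
  keep <- c(atlas$sensorimotor, IOG = atlas$control)
  missing <- setdiff(unname(keep), unique(table$node_label))
  if (length(missing)) {
    stop_hc(paste("table lacks atlas nodes:", paste(missing, collapse = ", ")),
            "hemiconn_label_mismatch")
  }
  out <- table[table$node_label %in% keep, , drop = FALSE]
  short <- names(keep)[match(out$node_label, keep)]
  out <- cbind(node = short, out, stringsAsFactors = FALSE)
  ord <- order(match(out$node_label, keep), out$subject_id)
  rownames(out) <- NULL
  out[ord, , drop = FALSE]
}

#' Hemispheric summary for one subject
#'
#' Arithmetic means of the nodal betweenness, clustering and neighbourhood
#' complexity over all nodes of the hemisphere, together with the supplied
#' whole-network hierarchical complexity `R`.
#'
#' @param table nodal metric table for a single subject.
#' @param R hierarchical complexity of the same subject's graph.
#' @return one-row data.frame with columns `subject_id, betweenness,
#'   clustering, neighbourhood_complexity, hierarchical_complexity`.
#' @export
hemispheric_summary <- function(table, R) {
  if (length(unique(table$subject_id)) != 1) {
    stop_hc("table must contain exactly one subject", "hemiconn_manifest")
  }
  data.frame(
    subject_id = table$subject_id[1],
    betweenness = mean(table$betweenness_raw),
    clustering = mean(table$clustering),
    neighbourhood_complexity = mean(table$neighbourhood_complexity, na.rm = TRUE),
    hierarchical_complexity = R,
    stringsAsFactors = FALSE)
}
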