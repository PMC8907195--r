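# Independent brute-force oracles and fixture builders. Everything here is
# written from first principles (exhaustive enumeration, definition-level
# loops) and never calls the package's shortest-path machinery.

# random symmetric weighted adjacency fixture
rand_wadj <- function(n, p = 0.5, weights = c("random", "unit"), seed = 1,
                      labels = paste0("R", seq_len(n))) {
  weights <- match.arg(weights)
  withr::with_seed(seed, {
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w))
    on <- runif(length(ut)) < p
    w[ut[on]] <- if (weights == "unit") 1 else runif(sum(on), 0.5, 2)
    w <- w + t(w)
    rownames(w) <- colnames(w) <- labels
    weighted_adjacency(w)
  })
}

# small named fixtures
path_graph <- function(labels = c("A", "B", "C")) {
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) w[i, i + 1] <- w[i + 1, i] <- 1
  weighted_adjacency(w)
}
star_graph <- function(n_leaves = 4) {
  labels <- c("hub", paste0("leaf", seq_len(n_leaves)))
  w <- matrix(0, n_leaves + 1, n_leaves + 1, dimnames = list(labels, labels))
  w[1, -1] <- w[-1, 1] <- 1
  weighted_adjacency(w)
}
cycle_graph <- function(n) {
  labels <- paste0("c", seq_len(n))
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    j <- i %% n + 1
    w[i, j] <- w[j, i] <- 1
  }
  weighted_adjacency(w)
}

# exhaustive enumeration of all simple paths between every ordered pair;
# keeps the minimal-length ones and tallies pass-through nodes
bf_path_tallies <- function(A, transform = "inverse", tol = 1e-9) {
  w <- unclass(A)
  n <- nrow(w)
  L <- matrix(Inf, n, n)
  L[w > 0] <- if (transform == "inverse") 1 / w[w > 0] else 1
  diag(L) <- Inf
  lengths <- matrix(Inf, n, n); diag(lengths) <- 0
  counts <- matrix(0, n, n); diag(counts) <- 1
  via <- array(0, c(n, n, n))
  for (h in seq_len(n)) for (j in seq_len(n)) {
    if (h == j) next
    found <- list()
    rec <- function(path, len) {
      u <- path[length(path)]
      if (u == j) {
        found[[length(found) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (v in which(is.finite(L[u, ]))) {
        if (!(v %in% path)) rec(c(path, v), len + L[u, v])
      }
    }
    rec(h, 0)
    if (!length(found)) next
    lens <- vapply(found, `[[`, 1, "len")
    mn <- min(lens)
    sel <- which(lens <= mn + tol * max(1, mn))
    lengths[h, j] <- mn
    counts[h, j] <- length(sel)
    for (s in sel) {
      mids <- setdiff(found[[s]]$path, c(h, j))
      via[h, j, mids] <- via[h, j, mids] + 1
    }
  }
  list(lengths = lengths, counts = counts, via = via)
}

bf_betweenness <- function(A, normalized = FALSE, transform = "inverse") {
  bt <- bf_path_tallies(A, transform)
  n <- nrow(A)
  b <- numeric(n)
  for (i in seq_len(n)) {
    for (h in seq_len(n)) for (j in seq_len(n)) {
      if (h == j || h == i || j == i || bt$counts[h, j] == 0) next
      b[i] <- b[i] + bt$via[h, j, i] / bt$counts[h, j]
    }
  }
  if (normalized) b <- b / ((n - 1) * (n - 2))
  stats::setNames(b, rownames(A))
}

# definition-level triangle enumeration for the weighted clustering
bf_clustering <- function(A) {
  w <- unclass(A)
  n <- nrow(w)
  c_i <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(w[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    t_i <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      j <- nb[a]; h <- nb[b]
      if (w[j, h] > 0) t_i <- t_i + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
    }
    c_i[i] <- 2 * t_i / (k * (k - 1))
  }
  stats::setNames(c_i, rownames(A))
}

# definition-level hierarchical complexity: per-degree-class entrywise
# variance of ascending neighbourhood degree sequences
bf_hierarchical <- function(A) {
  w <- unclass(A)
  B <- w > 0; diag(B) <- FALSE
  k <- rowSums(B)
  D <- length(unique(k))
  total <- 0
  for (p in unique(k)) {
    if (p < 1) next
    members <- which(k == p)
    if (length(members) < 2) next
    seqs <- lapply(members, function(i) sort(k[B[i, ]]))
    class_sum <- 0
    for (j in seq_len(p)) {
      entries <- vapply(seqs, `[[`, 1, j)
      mu_j <- mean(entries)
      class_sum <- class_sum + sum((entries - mu_j)^2)
    }
    total <- total + class_sum / (p * (length(members) - 1))
  }
  total / D
}

bf_neighbourhood <- function(A) {
  w <- unclass(A)
  B <- w > 0; diag(B) <- FALSE
  k <- rowSums(B)
  nc <- rep(NA_real_, nrow(w))
  for (p in unique(k)) {
    if (p < 1) next
    members <- which(k == p)
    if (length(members) < 2) next
    seqs <- lapply(members, function(i) sort(k[B[i, ]]))
    mu <- sapply(seq_len(p), function(j) mean(vapply(seqs, `[[`, 1, j)))
    for (m in seq_along(members)) {
      nc[members[m]] <- sum((seqs[[m]] - mu)^2) / (p * (length(members) - 1))
    }
  }
  stats::setNames(nc, rownames(A))
}
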