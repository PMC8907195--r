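test_that("degrees count incident non-zero edges, ignoring weights", {
  st <- star_graph(4)
  expect_equal(unname(node_degrees(st)), c(4, 1, 1, 1, 1))
  empty <- weighted_adjacency(matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4])))
  expect_true(all(node_degrees(empty) == 0))
  for (seed in 1:5) {
    A <- rand_wadj(12, p = 0.4, seed = seed)
    w <- unclass(A); diag(w) <- 0
    expect_equal(unname(node_degrees(A)), unname(rowSums(w > 0)))
  }
})

test_that("shortest-path tallies match hand counts on canonical graphs", {
  # path A-B-C: one shortest A->C path, through B
  tp <- shortest_path_tallies(path_graph(c("A", "B", "C")))
  expect_equal(tp$counts["A", "C"], 1)
  expect_equal(tp$via["A", "C", "B"], 1)
  expect_equal(tp$via["A", "C", "A"], 0)

  # 4-cycle: two shortest paths between opposite corners
  tc <- shortest_path_tallies(cycle_graph(4))
  expect_equal(tc$counts["c1", "c3"], 2)
  expect_equal(tc$counts["c2", "c4"], 2)
  # undirected symmetry of counts
  expect_equal(tc$counts, t(tc$counts))
})

test_that("tallies equal exhaustive path enumeration on small graphs", {
  for (seed in 1:12) {
    A <- rand_wadj(6, p = 0.55, weights = "random", seed = seed)
    got <- shortest_path_tallies(A)
    want <- bf_path_tallies(A)
    expect_equal(unname(got$lengths), want$lengths, tolerance = 1e-9)
    expect_equal(unname(got$counts), want$counts)
    expect_equal(unname(got$via), want$via)
    # invariant: 0 <= rho_hj(i) <= rho_hj
    for (i in seq_len(6)) {
      expect_true(all(got$via[, , i] <= got$counts + 1e-12))
      expect_true(all(got$via[, , i] >= 0))
    }
  }
  # unit-weight transform on a unit-weight graph
  A <- rand_wadj(6, p = 0.5, weights = "unit", seed = 99)
  got <- shortest_path_tallies(A, transform = "unit")
  want <- bf_path_tallies(A, transform = "unit")
  expect_equal(unname(got$counts), want$counts)
})

test_that("betweenness is zero at leaves and 1 at a normalised star centre", {
  st <- star_graph(4)  # 5 nodes
  b <- betweenness_centrality(st, normalized = TRUE)
  expect_equal(unname(b["hub"]), 1)
  expect_true(all(b[paste0("leaf", 1:4)] == 0))
  # raw = normalized * (n-1)(n-2)
  braw <- betweenness_centrality(st, normalized = FALSE)
  expect_equal(unname(braw), unname(b) * 12)
  expect_error(betweenness_centrality(path_graph(c("A", "B")), normalized = TRUE),
               class = "hemiconn_too_small")
})

test_that("betweenness equals the brute-force oracle, both variants", {
  for (seed in 1:15) {
    A <- rand_wadj(6, p = 0.5, weights = "random", seed = 100 + seed)
    expect_equal(betweenness_centrality(A), bf_betweenness(A), tolerance = 1e-9)
    expect_equal(betweenness_centrality(A, normalized = TRUE),
                 bf_betweenness(A, normalized = TRUE), tolerance = 1e-9)
  }
  # leaves always score zero
  for (seed in 1:5) {
    A <- rand_wadj(7, p = 0.4, seed = 200 + seed)
    k <- node_degrees(A)
    b <- betweenness_centrality(A)
    expect_true(all(b[k == 1] == 0))
  }
})

test_that("betweenness is equivariant under node relabelling", {
  A <- rand_wadj(8, p = 0.5, weights = "random", seed = 7)
  perm <- withr::with_seed(8, sample(8))
  Ap <- weighted_adjacency(unclass(A)[perm, perm])
  expect_equal(unname(betweenness_centrality(Ap)),
               unname(betweenness_centrality(A))[perm], tolerance = 1e-9)
})

test_that("clustering handles triangles, stars, and matches the triangle oracle", {
  tri <- weighted_adjacency(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3, 3,
                                   dimnames = list(letters[1:3], letters[1:3])))
  cc <- clustering_coefficients(tri)
  expect_equal(unname(cc$nodal), rep(1, 3))
  expect_equal(cc$hemispheric, 1)

  st <- clustering_coefficients(star_graph(5))
  expect_true(all(st$nodal == 0))  # no closed triplets anywhere

  for (seed in 1:10) {
    A <- rand_wadj(7, p = 0.5, weights = "random", seed = 300 + seed)
    got <- clustering_coefficients(A)
    expect_equal(got$nodal, bf_clustering(A), tolerance = 1e-12)
    expect_equal(got$hemispheric, mean(bf_clustering(A)), tolerance = 1e-12)
    # homogeneity: scaling all weights by kappa scales every c_i by kappa
    kappa <- 3.7
    scaled <- clustering_coefficients(weighted_adjacency(unclass(A) * kappa))
    expect_equal(unname(scaled$nodal), unname(got$nodal) * kappa,
                 tolerance = 1e-12)
  }
})

test_that("binary clustering recovers the classic local coefficient", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    A <- rand_wadj(12, p = 0.4, weights = "unit", seed = 400 + seed)
    g <- igraph::graph_from_adjacency_matrix(unclass(A), mode = "undirected",
                                             weighted = NULL)
    ref <- unname(igraph::transitivity(g, type = "localundirected",
                                       isolates = "zero"))
    ref[node_degrees(A) < 2] <- 0
    expect_equal(unname(clustering_coefficients(A)$nodal), ref,
                 tolerance = 1e-12)
  }
})

test_that("weighted betweenness cross-checks against igraph", {
  skip_if_not_installed("igraph")
  for (seed in 1:5) {
    A <- rand_wadj(10, p = 0.5, weights = "random", seed = 500 + seed)
    w <- unclass(A)
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    # igraph sums over unordered pairs; the raw definition uses ordered pairs
    ref <- 2 * igraph::betweenness(g, weights = 1 / igraph::E(g)$weight)
    expect_equal(unname(betweenness_centrality(A)), unname(ref),
                 tolerance = 1e-9)
  }
})

test_that("regular graphs have zero hierarchical complexity", {
  expect_equal(hierarchical_complexity(cycle_graph(8)), 0)
  K5 <- weighted_adjacency(matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5])) -
                             diag(5))
  expect_equal(hierarchical_complexity(K5), 0)
})

test_that("mixing neighbour-degree sequences raises hierarchical complexity", {
  # ordered: every degree-2 node sees the same (3, 3) sequence
  # b1 - a1 - a2 - b2 with extra scaffolding to pin degrees
  mk <- function(edges, n) {
    w <- matrix(0, n, n, dimnames = list(paste0("v", 1:n), paste0("v", 1:n)))
    for (e in edges) {
      w[e[1], e[2]] <- w[e[2], e[1]] <- 1
    }
    weighted_adjacency(w)
  }
  # 4-path: both degree-2 nodes see the sequence (1, 2), both leaves see
  # (2) -> every class homogeneous, R = 0
  ordered <- mk(list(c(1, 2), c(2, 3), c(3, 4)), 4)
  # triangle 1-2-3 with a tail 3-4-5: the degree-2 class {1, 2, 4} mixes
  # sequences (2, 3), (2, 3) and (1, 3) -> R > 0
  mixed <- mk(list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 3)), 5)
  expect_equal(hierarchical_complexity(ordered), 0)
  expect_gt(hierarchical_complexity(mixed), 0)
  expect_lt(hierarchical_complexity(ordered), hierarchical_complexity(mixed))
})

test_that("hierarchical complexity equals the definition oracle", {
  for (seed in 1:20) {
    A <- rand_wadj(8, p = 0.5, weights = "unit", seed = 600 + seed)
    expect_equal(hierarchical_complexity(A), bf_hierarchical(A),
                 tolerance = 1e-12)
  }
})

test_that("nodal neighbourhood complexity: zeros on regular graphs, class sums give R", {
  expect_true(all(neighbourhood_complexity(cycle_graph(7))$nodal == 0))
  for (seed in 1:10) {
    A <- rand_wadj(8, p = 0.45, weights = "unit", seed = 700 + seed)
    nc <- neighbourhood_complexity(A)
    expect_equal(nc$nodal, bf_neighbourhood(A), tolerance = 1e-12)
    # algebraic consistency: defined nodal values sum to R * D
    k <- node_degrees(A)
    D <- length(unique(k))
    expect_equal(sum(nc$nodal, na.rm = TRUE),
                 hierarchical_complexity(A) * D, tolerance = 1e-12)
    # nodes whose degree is unique are undefined, hence excluded from the mean
    uniq <- k %in% as.integer(names(which(table(k) == 1)))
    expect_true(all(is.na(nc$nodal[uniq & k > 0])))
    expect_equal(nc$hemispheric, mean(nc$nodal, na.rm = TRUE))
  }
})

test_that("complexity metrics are isomorphism-invariant", {
  A <- rand_wadj(9, p = 0.45, weights = "unit", seed = 42)
  perm <- withr::with_seed(43, sample(9))
  Ap <- weighted_adjacency(unclass(A)[perm, perm])
  expect_equal(hierarchical_complexity(Ap), hierarchical_complexity(A))
  expect_equal(unname(neighbourhood_complexity(Ap)$nodal),
               unname(neighbourhood_complexity(A)$nodal)[perm])
})

test_that("sensorimotor slice extracts the 8 atlas nodes with intact values", {
  atlas <- default_atlas()
  A <- density_threshold(rand_wadj(47, p = 0.45, weights = "random", seed = 77,
                                   labels = atlas$all_labels))
  tab <- nodal_metric_table(A, "s01")
  sl <- sensorimotor_slice(tab, atlas)
  expect_equal(nrow(sl), 8)
  expect_setequal(sl$node, c("M1", "S1", "SMA", "thalamus", "caudate",
                             "putamen", "pallidum", "IOG"))
  for (r in seq_len(nrow(sl))) {
    expect_equal(sl$clustering[r],
                 tab$clustering[tab$node_label == sl$node_label[r]])
    expect_equal(sl$betweenness_raw[r],
                 tab$betweenness_raw[tab$node_label == sl$node_label[r]])
  }
  tiny <- tab[tab$node_label == "Heschl_L", ]
  expect_error(sensorimotor_slice(tiny, atlas), class = "hemiconn_label_mismatch")
})

test_that("hemispheric summary averages nodal values and carries R", {
  atlas <- default_atlas()
  A <- density_threshold(rand_wadj(47, p = 0.45, weights = "random", seed = 78,
                                   labels = atlas$all_labels))
  tab <- nodal_metric_table(A, "s01")
  R <- hierarchical_complexity(A)
  h <- hemispheric_summary(tab, R)
  expect_equal(h$betweenness, mean(tab$betweenness_raw))
  expect_equal(h$clustering, mean(tab$clustering))
  expect_equal(h$hierarchical_complexity, R)
  expect_gte(h$betweenness, min(tab$betweenness_raw))
  expect_lte(h$betweenness, max(tab$betweenness_raw))
  # constant nodal values average to themselves
  const <- tab
  const$betweenness_raw <- 5
  expect_equal(hemispheric_summary(const, R)$betweenness, 5)
})
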