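test_that("construction validates symmetry, sign, labels and squareness", {
  w <- matrix(c(0, 2, 0, 2, 0, 5, 0, 5, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  A <- weighted_adjacency(w)
  expect_s3_class(A, "weighted_adjacency")
  expect_identical(node_labels(A), c("A", "B", "C"))
  expect_equal(A["A", "B"], 2)

  asym <- w; asym[1, 2] <- asym[1, 2] + 0.5
  expect_error(weighted_adjacency(asym), class = "hemiconn_asymmetric")
  neg <- w; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(weighted_adjacency(neg), class = "hemiconn_negative")
  expect_error(weighted_adjacency(w[, 1:2]), class = "hemiconn_nonsquare")
  dup <- w; dimnames(dup) <- list(c("A", "A", "C"), c("A", "A", "C"))
  expect_error(weighted_adjacency(dup), class = "hemiconn_label_mismatch")
})

test_that("adjacency CSV round-trips exactly, preserving label order", {
  A <- rand_wadj(47, p = 0.4, weights = "random", seed = 101,
                 labels = default_atlas()$all_labels)
  f <- withr::local_tempfile(fileext = ".csv")
  write_adjacency(A, f)
  B <- read_adjacency(f)
  expect_identical(node_labels(B), node_labels(A))
  expect_lt(max(abs(unclass(B) - unclass(A))), 1e-12)

  # shuffled label order is preserved as-is
  shuffled <- withr::with_seed(5, sample(node_labels(A)))
  As <- weighted_adjacency(unclass(A)[shuffled, shuffled])
  write_adjacency(As, f)
  expect_identical(node_labels(read_adjacency(f)), shuffled)

  # label expectation is enforced
  expect_error(read_adjacency(f, expected_labels = node_labels(A)),
               class = "hemiconn_label_mismatch")

  # an asymmetric file is rejected at read time
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",A,B", "A,0,1", "B,2,0"), bad)
  expect_error(read_adjacency(bad), class = "hemiconn_asymmetric")

  # empty graph round-trips
  empty <- weighted_adjacency(matrix(0, 2, 2,
                                     dimnames = list(c("x", "y"), c("x", "y"))))
  write_adjacency(empty, f)
  expect_equal(unclass(read_adjacency(f)), unclass(empty))
})

test_that("zero_diagonal clears self-connections and nothing else", {
  w <- diag(7, 3)
  dimnames(w) <- list(letters[1:3], letters[1:3])
  A <- weighted_adjacency(w)
  Z <- zero_diagonal(A)
  expect_true(all(unclass(Z) == 0))

  B <- rand_wadj(10, seed = 3)
  Z2 <- zero_diagonal(B)
  expect_identical(unclass(zero_diagonal(Z2)), unclass(Z2))  # idempotent
  off <- upper.tri(unclass(B))
  expect_equal(sum(unclass(Z2)[off]), sum(unclass(B)[off]))  # off-diag conserved
})

test_that("hemisphere subsetting extracts the atlas principal submatrix", {
  atlas <- default_atlas()
  big_labels <- c(atlas$all_labels, paste0("X", 1:20))
  perm <- withr::with_seed(9, sample(big_labels))
  A <- rand_wadj(67, p = 0.4, seed = 9, labels = perm)
  S <- subset_hemisphere(A, atlas)
  expect_identical(node_labels(S), atlas$all_labels)
  expect_identical(dim(unclass(S)), c(47L, 47L))
  # entries equal parent lookups at random label pairs
  pairs <- withr::with_seed(2, replicate(20, sample(atlas$all_labels, 2)))
  for (k in seq_len(ncol(pairs))) {
    expect_identical(S[pairs[1, k], pairs[2, k]], A[pairs[1, k], pairs[2, k]])
  }
  # idempotent; identity when the atlas covers everything
  expect_identical(unclass(subset_hemisphere(S, atlas)), unclass(S))
  expect_error(subset_hemisphere(rand_wadj(5, seed = 1), atlas),
               class = "hemiconn_label_mismatch")
})

test_that("density thresholding removes exactly the weakest edge fraction", {
  # 47 nodes, exactly 100 distinct non-zero weights
  labels <- sprintf("n%02d", 1:47)
  w <- matrix(0, 47, 47, dimnames = list(labels, labels))
  ut <- which(upper.tri(w))
  picks <- withr::with_seed(12, sample(ut, 100))
  w[picks] <- withr::with_seed(13, sample(seq(1, 1000, length.out = 100)))
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  A <- weighted_adjacency(w)
  Th <- density_threshold(A, 0.25)
  expect_equal(sum(unclass(Th)[upper.tri(Th)] > 0), 75)
  # the 75 survivors are the 75 largest weights, unchanged
  kept <- sort(unclass(Th)[upper.tri(Th)][unclass(Th)[upper.tri(Th)] > 0])
  expect_equal(kept, sort(w[ut][w[ut] > 0], decreasing = TRUE)[75:1])

  expect_identical(unclass(density_threshold(A, 0)), unclass(A))
  expect_error(density_threshold(A, 1), class = "hemiconn_bad_fraction")
  expect_error(density_threshold(A, -0.1), class = "hemiconn_bad_fraction")
})

test_that("tied weights at the cut follow the documented deterministic rule", {
  A <- rand_wadj(12, p = 0.7, weights = "unit", seed = 21)  # all weights tied
  frac <- 0.4
  Th <- density_threshold(A, frac)
  # brute-force sort-and-cut oracle with the (weight, row, col) tie rule
  w <- unclass(A)
  ut <- which(upper.tri(w) & w > 0)
  rc <- arrayInd(ut, dim(w))
  ord <- order(w[ut], rc[, 1], rc[, 2])
  kill <- ord[seq_len(floor(frac * length(ut)))]
  expected <- w
  expected[ut[kill]] <- 0
  expected[cbind(rc[kill, 2], rc[kill, 1])] <- 0
  expect_equal(unname(unclass(Th)), unname(expected))
})

test_that("thresholding is monotone and never alters surviving weights", {
  for (seed in 1:5) {
    A <- rand_wadj(20, p = 0.5, seed = seed)
    w <- unclass(A)
    fr <- c(0.1, 0.25, 0.5, 0.8)
    survivors <- lapply(fr, function(f) {
      tw <- unclass(density_threshold(A, f))
      which(upper.tri(tw) & tw > 0)
    })
    for (k in seq_len(length(fr) - 1)) {
      expect_true(all(survivors[[k + 1]] %in% survivors[[k]]))
    }
    tw <- unclass(density_threshold(A, 0.5))
    kept <- which(tw > 0)
    expect_identical(tw[kept], w[kept])
    # invariants: symmetric, non-negative, zero-diagonal
    expect_true(all(tw == t(tw)) && min(tw) >= 0 && all(diag(tw) == 0))
  }
})

test_that("binarize maps non-zero weights to 1 and preserves edge count", {
  A <- weighted_adjacency(matrix(c(0, 2, 5, 2, 0, 0, 5, 0, 0), 3, 3,
                                 dimnames = list(letters[1:3], letters[1:3])))
  B <- binarize(A)
  expect_equal(sort(unique(as.vector(unclass(B)))), c(0, 1))
  expect_identical(unclass(binarize(B)), unclass(B))  # idempotent
  for (seed in 1:5) {
    R <- rand_wadj(15, p = 0.4, seed = seed)
    expect_equal(sum(unclass(binarize(R)) > 0), sum(unclass(R) > 0))
  }
})

test_that("manifest reading validates groups, ids and score ranges", {
  f <- withr::local_tempfile(fileext = ".csv")
  hdr <- "id,group,age,sex,lesion_volume,AHA,MA,BBTA,BBTU,matrix_path"
  writeLines(c(hdr,
               "s1,AIS,10,M,12.5,55,60,20,40,s1.csv",
               "s2,TDC,11,F,,,,,,s2.csv"), f)
  m <- read_manifest(f)
  expect_equal(nrow(m), 2)
  expect_true(is.na(m$AHA[2]))

  writeLines(c(hdr, "s1,BAD,10,M,,,,,,s1.csv"), f)
  expect_error(read_manifest(f), class = "hemiconn_manifest")
  writeLines(c(hdr, "s1,AIS,10,M,,130,,,,s1.csv"), f)
  expect_error(read_manifest(f), class = "hemiconn_manifest")
})
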