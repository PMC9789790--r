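test_that("mutual KNN equals a brute-force oracle on seeded points", {
  set.seed(21)
  pe <- matrix(runif(10 * 3), 10, 3)
  re <- matrix(runif(10 * 3), 10, 3)
  got <- mutual_knn_edges(pe, re, k = 3)

  # O(n^2) oracle: full distance matrix, rank both directions, intersect
  d <- as.matrix(dist(rbind(pe, re)))[1:10, 11:20]
  oracle <- list()
  for (p in 1:10) for (r in 1:10) {
    p_rank <- rank(d[p, ], ties.method = "first")[r]
    r_rank <- rank(d[, r], ties.method = "first")[p]
    if (p_rank <= 3 && r_rank <= 3) oracle[[length(oracle) + 1]] <- c(p, r)
  }
  oracle <- do.call(rbind, oracle)
  got_m <- as.matrix(got[order(got$pseudo_idx, got$real_idx), ])
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(unname(got_m), unname(oracle))
})

test_that("mutual KNN is complete when k covers both sets and monotone in k", {
  set.seed(8)
  pe <- matrix(rnorm(6 * 2), 6, 2)
  re <- matrix(rnorm(4 * 2), 4, 2)
  expect_warning(full <- mutual_knn_edges(pe, re, k = 10), "clamping")
  expect_equal(nrow(full), 6L * 4L)

  expect_equal(nrow(mutual_knn_edges(matrix(0, 1, 2), matrix(1, 1, 2),
                                     k = 1)), 1L)

  prev <- NULL
  for (k in 1:4) {
    e <- mutual_knn_edges(pe, re, k = k)
    key <- paste(e$pseudo_idx, e$real_idx)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
})

test_that("spatial edges follow the staggered-lattice diagonal offsets", {
  # single spot: nothing to link
  one <- spot_coordinates("a", 0, 0)
  expect_equal(nrow(spatial_edges(one, h = 1)), 0L)

  # two spots exactly at a diagonal offset
  two <- spot_coordinates(c("a", "b"), c(0, 0.5), c(0, 0.5))
  expect_equal(nrow(spatial_edges(two, h = 1)), 1L)

  # staggered two-row lattice of 6 spots vs brute-force offset scan
  h <- 2
  coords <- spot_coordinates(
    sprintf("s%d", 1:6),
    x = c(0, 2, 4, 1, 3, 5),
    y = c(0, 0, 0, 1, 1, 1)
  )
  got <- spatial_edges(coords, h = h, tol = 0.15)
  offs <- h / 2 * cbind(c(-1, -1, 1, 1), c(-1, 1, 1, -1))
  oracle <- NULL
  for (i in 1:6) for (o in 1:4) for (j in setdiff(1:6, i)) {
    tgt <- c(coords$x[i] + offs[o, 1], coords$y[i] + offs[o, 2])
    if (sqrt(sum((c(coords$x[j], coords$y[j]) - tgt)^2)) <= 0.15 * h) {
      oracle <- rbind(oracle, c(min(i, j), max(i, j)))
    }
  }
  oracle <- unique(oracle)
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  expect_equal(unname(as.matrix(got)), unname(oracle))
})

test_that("adjacency normalization matches the dense closed form", {
  # one isolated node
  expect_equal(as.matrix(normalize_adjacency(matrix(0, 1, 1))),
               matrix(1, 1, 1))
  # two nodes, one edge: both degree-2 after self-loops
  A2 <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(as.matrix(normalize_adjacency(A2)),
               matrix(0.5, 2, 2))
  # seeded random 8-node graph vs explicit D^-1/2 (A + I) D^-1/2
  set.seed(13)
  A <- matrix(0, 8, 8)
  A[upper.tri(A)] <- rbinom(28, 1, 0.4)
  A <- A + t(A)
  An <- as.matrix(normalize_adjacency(A))
  Ahat <- A + diag(8)
  Dm <- diag(1 / sqrt(rowSums(Ahat)))
  expect_equal(An, Dm %*% Ahat %*% Dm, tolerance = 1e-12)
  expect_true(all(An >= 0 & An <= 1))
  expect_equal(An, t(An))
})

test_that("normalized adjacency of a regular graph has unit row sums", {
  # 4-cycle: every node degree 2
  A <- matrix(0, 4, 4)
  for (i in 1:4) {
    A[i, i %% 4 + 1] <- 1
    A[i %% 4 + 1, i] <- 1
  }
  expect_equal(unname(Matrix::rowSums(normalize_adjacency(A))), rep(1, 4))
})

test_that("graph assembly stacks features, splits masks, keeps bipartite kinds", {
  set.seed(2)
  pe <- matrix(rnorm(10 * 3), 10, 3,
               dimnames = list(sprintf("p%d", 1:10), NULL))
  re <- matrix(rnorm(4 * 3), 4, 3,
               dimnames = list(sprintf("r%d", 1:4), NULL))
  lab <- proportion_matrix(matrix(0.5, 10, 2), sprintf("p%d", 1:10),
                           c("A", "B"))
  knn <- tibble::tibble(pseudo_idx = c(1L, 3L), real_idx = c(2L, 2L))
  sp <- tibble::tibble(from = 1L, to = 3L)
  g <- assemble_graph(pe, re, knn, sp, lab, split_seed = 4)
  expect_equal(dim(g$X), c(14L, 3L))
  expect_equal(Matrix::nnzero(g$A), 2L * 3L) # 3 undirected edges
  expect_equal(as.matrix(g$A), t(as.matrix(g$A)))
  expect_equal(unname(Matrix::diag(g$A)), rep(0, 14))
  # masks: 8/1/1 disjoint cover of the pseudo nodes
  expect_equal(lengths(g$masks[c("train", "val", "test")]),
               c(train = 8L, val = 1L, test = 1L))
  expect_equal(sort(unlist(g$masks[c("train", "val", "test")],
                           use.names = FALSE)), 1:10)
  # every knn edge joins a pseudo to a real node; spatial joins two reals
  ii <- which(as.matrix(g$A) != 0, arr.ind = TRUE)
  kinds <- ifelse(ii <= 10, "p", "r")
  pairs <- paste0(kinds[, 1], kinds[, 2])
  expect_true(all(pairs %in% c("pr", "rp", "rr")))

  # no edges at all: adjacency empty, propagation operator is the identity
  g0 <- assemble_graph(pe, re, knn[0, ], NULL, lab, split_seed = 4)
  expect_equal(Matrix::nnzero(g0$A), 0L)
  expect_equal(as.matrix(g0$A_norm), diag(14))

  # a 2+1 node graph with one knn edge has exactly one symmetric pair
  g1 <- assemble_graph(pe[1:2, ], re[1, , drop = FALSE],
                       tibble::tibble(pseudo_idx = 1L, real_idx = 1L),
                       NULL, lab[1:2, ], split_seed = 1)
  expect_equal(Matrix::nnzero(g1$A), 2L)
})
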