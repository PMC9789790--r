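test_that("dropout statistics are the zero fraction and column mean", {
  m <- expression_matrix(
    cbind(c(0, 0, 0, 0), c(2, 0, 0, 2), c(1, 2, 3, 4)),
    sprintf("s%d", 1:4), c("gA", "gB", "gC"), "st"
  )
  st <- compute_dropout_stats(m)
  expect_equal(st$P, c(1, 0.5, 0))
  expect_equal(st$E, c(0, 1, 2.5))
  expect_equal(attr(st, "n_obs"), 4L)
  expect_error(compute_dropout_stats(m[1, , drop = FALSE]), "2 observations")
})

test_that("gene-specific K inverts the Michaelis-Menten curve exactly", {
  expect_equal(estimate_gene_K(1, 0.5), 1)
  expect_equal(estimate_gene_K(3, 0.25), 1)
  expect_equal(estimate_gene_K(5, 0), 0)
  expect_true(is.na(estimate_gene_K(2, 1)))

  # plugging K back reproduces P to 1e-12 across the admissible range
  E <- rep(c(0.1, 1, 7, 120), times = 9)
  P <- rep(seq(0.1, 0.9, by = 0.1), each = 4)
  K <- estimate_gene_K(E, P)
  expect_equal(1 - E / (E + K), P, tolerance = 1e-12)
})

test_that("global K_M maximum likelihood matches a grid-search oracle", {
  n_obs <- 1000
  E <- c(0.5, 1, 2, 4, 8)
  # dropout rates on the K = 2 curve, rounded to achievable zero counts
  zeros <- round(n_obs * (1 - E / (E + 2)))
  stats <- tibble::tibble(gene_id = letters[1:5], E = E, P = zeros / n_obs)
  fit <- fit_global_KM(stats, n_obs = n_obs)

  oracle_grid <- exp(seq(log(0.01), log(100), length.out = 20001))
  oracle_ll <- vapply(oracle_grid, function(K) {
    sum(dbinom(zeros, n_obs, K / (E + K), log = TRUE))
  }, numeric(1))
  oracle_K <- oracle_grid[which.max(oracle_ll)]

  expect_equal(fit$K_M, oracle_K, tolerance = 1e-3)
  expect_lt(abs(fit$K_M - 2) / 2, 0.05)
  expect_equal(fit$n_genes_used, 5L)
})

test_that("K_M fit is exact for one gene and invariant to duplication/order", {
  one <- tibble::tibble(gene_id = "g", E = 1, P = 0.5)
  expect_equal(fit_global_KM(one, n_obs = 10)$K_M, 1, tolerance = 1e-6)

  two <- dplyr::bind_rows(one, one)
  expect_equal(fit_global_KM(two, n_obs = 10)$K_M, 1, tolerance = 1e-6)

  several <- tibble::tibble(gene_id = letters[1:4],
                            E = c(0.5, 2, 5, 1), P = c(0.8, 0.5, 0.3, 0.7))
  shuffled <- several[c(3, 1, 4, 2), ]
  expect_equal(fit_global_KM(several, n_obs = 50)$K_M,
               fit_global_KM(shuffled, n_obs = 50)$K_M)

  expect_error(fit_global_KM(tibble::tibble(gene_id = "g", E = 2, P = 0),
                             n_obs = 10),
               "not identifiable")
})

test_that("significance test is calibrated at the null and extreme off it", {
  fit <- structure(list(K_M = 1, log_likelihood = 0, n_genes_used = 1),
                   class = "mm_dropout_fit")
  st <- tibble::tibble(gene_id = c("null", "hot"),
                       E = c(1, 100), P = c(0.5, 0.5))
  out <- test_gene_significance(st, fit, n_obs = 100)
  # K_i = K_M: statistic 0, right-tailed p exactly 0.5
  expect_equal(out$statistic[1], 0)
  expect_equal(out$p_value[1], 0.5)
  # K_i = 100 K_M at se_logK = 0.4: enormous evidence
  expect_lt(out$p_value[2], 1e-10)
  expect_true(all(out$q_value >= out$p_value))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))
  expect_error(test_gene_significance(st, fit, n_obs = 2), "fewer than 3")
})

test_that("top-k selection intersects and orders by ST significance", {
  mk <- function(p, K) tibble::tibble(gene_id = names(p), E = 1,
                                      P = 0.5, K_i = K, p_value = p)
  st <- mk(c(a = 0.01, b = 0.02, c = 0.5), c(3, 2, 1))
  sc <- mk(c(a = 0.6, b = 0.01, c = 0.02), c(1, 3, 2))
  expect_equal(select_dropout_genes(st, sc, top_k = 2), "b")
  # identical stats: intersection is the top-k set itself, ST order
  expect_equal(select_dropout_genes(st, st, top_k = 2), c("a", "b"))
  expect_error(select_dropout_genes(st, sc, top_k = 1), "no genes shared")
})

test_that("selection recovers the planted dropout-inflated genes", {
  n_obs <- 200
  n_genes <- 100
  set.seed(7)
  E <- rlnorm(n_genes, log(2), 0.5)
  K <- rep(2, n_genes)
  hot <- 1:10
  K[hot] <- 40 # inflated 20x
  zeros <- round(n_obs * K / (E + K))
  ids <- sprintf("g%03d", seq_len(n_genes))
  stats <- tibble::tibble(gene_id = ids, E = E, P = zeros / n_obs)
  fit <- fit_global_KM(stats, n_obs = n_obs)
  tested <- test_gene_significance(stats, fit, n_obs = n_obs)
  got <- select_dropout_genes(tested, tested, top_k = 10)

  # oracle: rank genes by exact binomial right-tail probability of their
  # zero count under the global curve
  p0 <- fit$K_M / (E + fit$K_M)
  oracle_p <- pbinom(zeros - 1, n_obs, p0, lower.tail = FALSE)
  oracle_top <- ids[order(oracle_p)][1:10]
  expect_setequal(got, oracle_top)
  expect_setequal(got, ids[hot])
})
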