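test_that("reference markers carry their fold-change empirically", {
  cfg <- synthetic_config(n_cells = 3000, seed = 11)
  ref <- simulate_reference(cfg)
  expect_equal(dim(ref$expression), c(3000L, 500L))
  expect_equal(length(unlist(ref$marker_genes)), 75L)
  expect_equal(anyDuplicated(unlist(ref$marker_genes)), 0L)

  # pre-dropout NB means: each marker is exactly marker_fold up in its type
  for (t in seq_along(ref$marker_genes)) {
    mu <- ref$type_means[ref$marker_genes[[t]], ]
    expect_true(all(mu[, t] / rowMeans(mu[, -t, drop = FALSE]) >=
                      cfg$marker_fold - 1e-9))
  }
  # observed group means: fold survives dropout within sampling tolerance
  ann <- ref$annotation
  t1 <- unclass(ref$expression)[ann$cell_type == "type1",
                                ref$marker_genes[[1]]]
  rest <- unclass(ref$expression)[ann$cell_type != "type1",
                                  ref$marker_genes[[1]]]
  fold <- colMeans(t1) / pmax(colMeans(rest), 1e-9)
  expect_true(mean(fold >= 0.8 * cfg$marker_fold) > 0.8)
})

test_that("dropout in the reference follows the fitted curve and recovers K", {
  fx <- blocks_fixture()
  stats <- compute_dropout_stats(fx$ref$expression)
  fit <- fit_global_KM(stats)
  expect_gte(fit$K_M, 1.6)
  expect_lte(fit$K_M, 2.4)

  # non-marker genes sit on the curve: their observed dropout is close to
  # K_true / (E + K_true)
  nm <- setdiff(stats$gene_id, unlist(fx$ref$marker_genes))
  s <- stats[stats$gene_id %in% nm & stats$P > 0 & stats$P < 1, ]
  pred <- fx$cfg$K_true / (s$E + fx$cfg$K_true)
  expect_lt(median(abs(s$P - pred)), 0.03)
})

test_that("the generator is deterministic in its seed", {
  cfg <- synthetic_config(n_genes = 60, n_cells = 120,
                          markers_per_type = 5, seed = 9)
  a <- simulate_reference(cfg)
  b <- simulate_reference(cfg)
  expect_identical(unclass(a$expression), unclass(b$expression))
  ta <- simulate_spatial_tissue(cfg, a)
  tb <- simulate_spatial_tissue(cfg, b)
  expect_identical(ta$coords, tb$coords)
  expect_identical(ta$cell_types, tb$cell_types)
})

test_that("blocks layout clusters types into bands; random layout does not", {
  cfg2 <- synthetic_config(n_types = 2, markers_per_type = 10,
                           n_cells = 2000, seed = 5)
  ref2 <- simulate_reference(cfg2)
  tis <- simulate_spatial_tissue(cfg2, ref2)
  width <- cfg2$grid_cols * cfg2$pitch_h
  left <- tis$cell_types[tis$coords$x < width / 2]
  right <- tis$cell_types[tis$coords$x >= width / 2]
  expect_gte(mean(left == "type1"), 0.8)
  expect_gte(mean(right == "type2"), 0.8)
  expect_equal(length(tis$cell_types), 2000L)

  cfg_r <- synthetic_config(n_types = 2, markers_per_type = 10,
                            n_cells = 2000, spatial_layout = "random",
                            seed = 5)
  tis_r <- simulate_spatial_tissue(cfg_r, simulate_reference(cfg_r))
  quadrant <- paste(tis_r$coords$x < width / 2,
                    tis_r$coords$y < cfg_r$grid_rows * cfg_r$pitch_h / 4)
  chi <- suppressWarnings(chisq.test(table(quadrant, tis_r$cell_types)))
  expect_gt(chi$p.value, 0.01)
})

test_that("Visium-like spots live on a staggered lattice with 4 diagonal
           neighbours inside and fewer at corners", {
  fx <- blocks_fixture()
  vis <- fx$vis
  edges <- spatial_edges(vis$coords, h = fx$cfg$pitch_h)
  deg <- table(factor(c(edges$from, edges$to),
                      levels = seq_len(nrow(vis$coords))))
  # pick an interior spot: row 4 (0-based 3), col 4 of the 8x8 grid
  interior <- which(vis$coords$obs_id == "spot_028")
  xy <- vis$coords[interior, ]
  stopifnot(xy$x > fx$cfg$pitch_h, xy$y > fx$cfg$pitch_h / 2)
  expect_equal(unname(deg[interior]), 4L)
  corner <- which.min(vis$coords$x + vis$coords$y)
  expect_lte(unname(deg[corner]), 2L)
  expect_true(all(abs(rowSums(unclass(vis$truth)) - 1) < 1e-12))
  expect_true(all(fx$vis$expression >= 0))
})
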