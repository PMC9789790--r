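# Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Blocks-layout synthetic study: annotated reference, planar tissue and
# Visium-like spots with ground truth, under the generator defaults.
blocks_fixture <- function() {
  if (is.null(.fixture_cache$blocks)) {
    cfg <- synthetic_config(seed = 42)
    ref <- simulate_reference(cfg)
    tissue <- simulate_spatial_tissue(cfg, ref)
    vis <- make_visium_like(cfg, tissue)
    .fixture_cache$blocks <- list(cfg = cfg, ref = ref, tissue = tissue,
                                  vis = vis)
  }
  .fixture_cache$blocks
}

# One full pipeline run on the blocks fixture (reused across tests).
blocks_pipeline_result <- function() {
  if (is.null(.fixture_cache$pipeline)) {
    fx <- blocks_fixture()
    .fixture_cache$pipeline <- suppressWarnings(run_pipeline(
      fx$vis$expression, fx$vis$coords, fx$ref$expression,
      fx$ref$annotation, pipeline_config(seed = 1), truth = fx$vis$truth
    ))
  }
  .fixture_cache$pipeline
}

# Small deterministic expression matrix for unit tests.
toy_expression <- function(n_obs = 4, n_genes = 3, modality = "st") {
  m <- matrix(c(2, 0, 0, 2,
                1, 2, 3, 4,
                0, 0, 0, 0), n_obs, n_genes)
  expression_matrix(m, sprintf("s%d", seq_len(n_obs)),
                    sprintf("g%d", seq_len(n_genes)), modality)
}

# Tiny deconvolution graph built directly (bypasses assemble_graph) so GCN
# numerics can be tested against hand arithmetic.
manual_graph <- function(X, A, labels, n_pseudo, train = seq_len(n_pseudo)) {
  n <- nrow(X)
  structure(list(
    X = X, A = A, A_norm = normalize_adjacency(A),
    masks = list(train = train, val = integer(0), test = integer(0),
                 real = setdiff(seq_len(n), seq_len(n_pseudo))),
    labels = labels, n_pseudo = n_pseudo, n_real = n - n_pseudo,
    real_ids = sprintf("r%d", seq_len(n - n_pseudo))
  ), class = "deconvolution_graph")
}
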