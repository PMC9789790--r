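#' Pipeline configuration
#'
#' Collects every hyperparameter of the deconvolution pipeline with the
#' defaults used throughout: top-2000 dropout genes, 10-20 cells per
#' pseudo-spot, a 200-unit autoencoder bottleneck trained 5 epochs with
#' batch 300, mutual-KNN k = 100, a GCN trained with Adam at 0.005 for up
#' to 200 epochs with early-stopping patience 10, and a 5% proportion
#' filter.
#'
#' @param top_k_genes Top genes per dataset before intersecting.
#' @param m_range Cells mixed per pseudo-spot, `c(min, max)`.
#' @param n_pseudo Number of pseudo-spots; `NULL` means
#'   `max(3000, 5 * n_real_spots)`. Pseudo-spots are the only supervision,
#'   and mixtures reaching the corners of the composition simplex are rare
#'   under uniform mixing, so a generous floor keeps extreme real
#'   compositions inside the training support.
#' @param ae_hidden,ae_batch,ae_epochs Autoencoder bottleneck width, batch
#'   size and epochs.
#' @param knn_k Mutual-KNN neighbourhood size.
#' @param gcn_lr,gcn_epochs,gcn_patience,gcn_hidden GCN optimizer and
#'   architecture settings.
#' @param proportion_threshold Minimum reported per-spot fraction.
#' @param use_spatial_edges Ablation switch: include lattice edges.
#' @param feature_mode `"dropout"` (curve-based selection), `"hvg"`
#'   (variance ranking) or `"both"` (union).
#' @param embedding_mode `"autoencoder"` or `"svd"`.
#' @param normalize_for_stats Compute dropout statistics on library-size
#'   normalized values (the pipeline default) or raw counts.
#' @param seed Master seed; each random stage consumes a deterministic
#'   child of it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(top_k_genes = 2000, m_range = c(10, 20),
                            n_pseudo = NULL, ae_hidden = 200,
                            ae_batch = 300, ae_epochs = 5, knn_k = 100,
                            gcn_lr = 0.005, gcn_epochs = 200,
                            gcn_patience = 10, gcn_hidden = c(64, 32),
                            proportion_threshold = 0.05,
                            use_spatial_edges = TRUE,
                            feature_mode = c("dropout", "hvg", "both"),
                            embedding_mode = c("autoencoder", "svd"),
                            normalize_for_stats = TRUE, seed = 1) {
  feature_mode <- match.arg(feature_mode)
  embedding_mode <- match.arg(embedding_mode)
  stopifnot(top_k_genes >= 1, length(m_range) == 2, m_range[1] >= 1,
            m_range[1] <= m_range[2], ae_hidden >= 1, ae_batch >= 1,
            ae_epochs >= 0, knn_k >= 1, gcn_lr > 0, gcn_epochs >= 1,
            gcn_patience >= 1, length(gcn_hidden) == 2,
            proportion_threshold >= 0, proportion_threshold < 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full deconvolution pipeline
#'
#' Gene selection, pseudo-spot synthesis, shared library-size
#' normalization, embedding, graph assembly and GCN training, returning the
#' per-spot cell-type composition of the real ST data. When ground-truth
#' proportions are supplied, RMSE and JSD are computed.
#'
#' @param st_expr Real-ST [expression_matrix()] (spots x genes, counts).
#' @param st_coords [spot_coordinates()] for the real spots.
#' @param sc_expr Reference scRNA-seq [expression_matrix()] (cells x genes,
#'   counts).
#' @param sc_ann [cell_annotation()] for the reference cells.
#' @param cfg A [pipeline_config()].
#' @param truth Optional [proportion_matrix()] with ground-truth real-spot
#'   compositions.
#' @param out_dir Optional directory; when given, the proportions (raw and
#'   filtered), selected genes, edge list, training log and metrics are
#'   written there.
#' @return A list of class `deconvolution_result`: `proportions`,
#'   `proportions_filtered`, `genes`, `graph`, `model`, `embedder`,
#'   `metrics` (tibble, present when `truth` given), `config`.
#' @export
run_pipeline <- function(st_expr, st_coords, sc_expr, sc_ann,
                         cfg = pipeline_config(), truth = NULL,
                         out_dir = NULL) {
  stage <- "gene_selection"
  res <- tryCatch({
    shared <- intersect_gene_ids(colnames(st_expr), colnames(sc_expr))
    if (nrow(shared) == 0) stop("ST and reference share no gene ids")
    st <- st_expr[, shared$st, drop = FALSE]
    sc <- sc_expr[, shared$sc, drop = FALSE]
    colnames(sc) <- colnames(st)  # canonical ids from the ST side

    genes <- select_features(st, sc, cfg)

    stage <- "pseudo_spots"
    n_pseudo <- cfg$n_pseudo %||% max(3000, 5 * nrow(st))
    ps <- generate_pseudo_spots(sc[, genes, drop = FALSE], sc_ann, n_pseudo,
                                cfg$m_range[1], cfg$m_range[2],
                                seed = child_seed(cfg$seed, "pseudo"))

    stage <- "normalization"
    p_norm <- normalize_library(ps$expression)
    r_norm <- normalize_library(st[, genes, drop = FALSE])
    labels <- ps$labels[rownames(p_norm), , drop = FALSE]
    labels <- proportion_matrix(unclass(labels), rownames(p_norm),
                                colnames(ps$labels))

    stage <- "embedding"
    stacked <- rbind(r_norm, p_norm)
    if (cfg$embedding_mode == "autoencoder") {
      embedder <- train_autoencoder(stacked, hidden_dim = cfg$ae_hidden,
                                    batch_size = cfg$ae_batch,
                                    epochs = cfg$ae_epochs,
                                    seed = child_seed(cfg$seed, "ae"))
      p_emb <- embed(embedder, p_norm)
      r_emb <- embed(embedder, r_norm)
    } else {
      embedder <- fit_svd_embedder(stacked, hidden_dim = cfg$ae_hidden)
      p_emb <- embed_svd(embedder, p_norm)
      r_emb <- embed_svd(embedder, r_norm)
    }

    stage <- "graph"
    knn <- mutual_knn_edges(p_emb, r_emb, k = cfg$knn_k)
    sp <- NULL
    if (cfg$use_spatial_edges) {
      coords_used <- st_coords[match(rownames(r_norm), st_coords$obs_id), ]
      attr(coords_used, "pitch_h") <- attr(st_coords, "pitch_h")
      sp <- spatial_edges(coords_used)
    }
    graph <- assemble_graph(p_emb, r_emb, knn, sp, labels,
                            split_seed = child_seed(cfg$seed, "split"))

    stage <- "gcn"
    model <- train_gcn(graph, lr = cfg$gcn_lr, max_epochs = cfg$gcn_epochs,
                       patience = cfg$gcn_patience,
                       hidden_dims = cfg$gcn_hidden,
                       seed = child_seed(cfg$seed, "gcn"))
    props <- predict_real_proportions(model, graph)
    filtered <- filter_low_proportions(props, cfg$proportion_threshold)

    metrics <- NULL
    if (!is.null(truth)) {
      stage <- "metrics"
      metrics <- tibble::tibble(
        metric = c("rmse", "jsd", "rmse_uniform_baseline"),
        value = c(rmse(props, truth), jsd(props, truth),
                  uniform_baseline_rmse(truth))
      )
    }
    list(proportions = props, proportions_filtered = filtered,
         genes = genes, graph = graph, model = model, embedder = embedder,
         knn_edges = knn, spatial_edge_list = sp, metrics = metrics,
         config = cfg)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  class(res) <- "deconvolution_result"
  if (!is.null(out_dir)) write_result(res, out_dir)
  res
}

#' @export
print.deconvolution_result <- function(x, ...) {
  cat("<deconvolution_result> ", nrow(x$proportions), " spots x ",
      ncol(x$proportions), " cell types; ", length(x$genes),
      " genes used\n", sep = "")
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.deconvolution_result <- function(x, ...) tidy(x$proportions)

#' @exportS3Method generics::glance
glance.deconvolution_result <- function(x, ...) {
  out <- tibble::tibble(n_spots = nrow(x$proportions),
                        n_types = ncol(x$proportions),
                        n_genes = length(x$genes),
                        gcn_epochs = nrow(x$model$log),
                        best_epoch = x$model$best_epoch)
  if (!is.null(x$metrics)) {
    out <- dplyr::bind_cols(out, tidyr::pivot_wider(x$metrics,
                                                    names_from = "metric",
                                                    values_from = "value"))
  }
  out
}

write_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_proportions(res$proportions, file.path(out_dir, "proportions.csv"))
  write_proportions(res$proportions_filtered,
                    file.path(out_dir, "proportions_filtered.csv"))
  writeLines(res$genes, file.path(out_dir, "genes.txt"))
  edges <- dplyr::bind_rows(
    tibble::tibble(src = res$knn_edges$pseudo_idx,
                   dst = res$knn_edges$real_idx, kind = "knn"),
    if (!is.null(res$spatial_edge_list)) {
      tibble::tibble(src = res$spatial_edge_list$from,
                     dst = res$spatial_edge_list$to, kind = "spatial")
    }
  )
  utils::write.table(edges, file.path(out_dir, "edges.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(res$model$log, file.path(out_dir, "training_log.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(res$metrics)) {
    utils::write.table(res$metrics, file.path(out_dir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(out_dir)
}

# Case-fold/strip gene-id intersection preserving each side's own labels.
intersect_gene_ids <- function(st_genes, sc_genes) {
  idx <- match_gene_ids(st_genes, sc_genes)
  keep <- which(!is.na(idx))
  tibble::tibble(st = st_genes[keep], sc = sc_genes[idx[keep]])
}

# Feature selection honouring the configured mode.
select_features <- function(st, sc, cfg) {
  top_k <- min(cfg$top_k_genes, ncol(st))
  dropout_set <- function() {
    st_stats <- compute_dropout_stats(st, normalize = cfg$normalize_for_stats)
    sc_stats <- compute_dropout_stats(sc, normalize = cfg$normalize_for_stats)
    st_fit <- fit_global_KM(st_stats)
    sc_fit <- fit_global_KM(sc_stats)
    st_stats <- test_gene_significance(st_stats, st_fit)
    sc_stats <- test_gene_significance(sc_stats, sc_fit)
    select_dropout_genes(st_stats, sc_stats, top_k)
  }
  hvg_set <- function() {
    vs <- apply(normalize_library(st), 2, stats::var) +
      apply(normalize_library(sc), 2, stats::var)
    names(sort(vs, decreasing = TRUE))[seq_len(top_k)]
  }
  switch(cfg$feature_mode,
         dropout = dropout_set(),
         hvg = hvg_set(),
         both = union(dropout_set(), hvg_set()))
}

#' Run the ablation study
#'
#' Re-runs the pipeline once per named condition with only that switch
#' toggled, sharing the master seed across conditions, and scores each run
#' against the truth.
#'
#' @inheritParams run_pipeline
#' @param truth Ground-truth [proportion_matrix()] (required).
#' @param conditions Subset of `"original"`, `"no_spatial"`,
#'   `"no_dropout_genes"`, `"no_ae"`.
#' @return Tibble with columns `condition`, `rmse`, `jsd`.
#' @export
run_ablation <- function(st_expr, st_coords, sc_expr, sc_ann,
                         cfg = pipeline_config(), truth,
                         conditions = c("original", "no_spatial",
                                        "no_dropout_genes", "no_ae")) {
  known <- c("original", "no_spatial", "no_dropout_genes", "no_ae")
  bad <- setdiff(conditions, known)
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  if (is.null(truth)) stop("ablation requires ground-truth proportions")
  purrr::map_dfr(conditions, function(cond) {
    cfg_c <- cfg
    if (cond == "no_spatial") cfg_c$use_spatial_edges <- FALSE
    if (cond == "no_dropout_genes") cfg_c$feature_mode <- "hvg"
    if (cond == "no_ae") cfg_c$embedding_mode <- "svd"
    res <- run_pipeline(st_expr, st_coords, sc_expr, sc_ann, cfg_c,
                        truth = truth)
    tibble::tibble(condition = cond,
                   rmse = res$metrics$value[res$metrics$metric == "rmse"],
                   jsd = res$metrics$value[res$metrics$metric == "jsd"])
  })
}
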