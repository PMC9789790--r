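#' Configuration for the synthetic data generator
#'
#' Bundles the knobs for a fully synthetic scRNA-seq reference plus a
#' matching planar tissue: cell-type-specific marker structure, negative
#' binomial counts, Michaelis-Menten dropout with a known constant
#' `K_true`, and spatially clustered cell types.
#'
#' @param n_types Number of cell types (>= 2).
#' @param n_genes Total genes.
#' @param n_cells Reference cells (balanced across types).
#' @param markers_per_type Marker genes per type (disjoint sets).
#' @param marker_fold Expression fold-change of a marker in its own type.
#' @param K_true Michaelis-Menten dropout constant on the count scale.
#' @param base_mean Median of the lognormal per-gene base mean.
#' @param base_sdlog Log-sd of the per-gene base mean.
#' @param nb_size Negative binomial dispersion (size) of counts.
#' @param st_efficiency Capture efficiency of the spot platform relative to
#'   the scRNA-seq reference: summed spot counts are binomially thinned by
#'   this rate in [make_visium_like()]. Spot-based ST captures far fewer
#'   transcripts per cell than scRNA-seq, which is why real ST zero rates
#'   exceed 90%; the default reproduces that sparsity regime.
#' @param spatial_layout `"blocks"` (vertical bands, one dominant type
#'   each), `"gradient"` (type mixing drifts along x) or `"random"`.
#' @param grid_rows,grid_cols Staggered lattice dimensions for
#'   [make_visium_like()].
#' @param pitch_h Lattice pitch (horizontal spot-to-spot distance).
#' @param seed Master seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_types = 3, n_genes = 500, n_cells = 2000,
                             markers_per_type = 25, marker_fold = 8,
                             K_true = 2, base_mean = 1.5, base_sdlog = 0.8,
                             nb_size = 2, st_efficiency = 0.1,
                             spatial_layout = c("blocks", "gradient",
                                                "random"),
                             grid_rows = 8, grid_cols = 8, pitch_h = 2,
                             seed = 1) {
  spatial_layout <- match.arg(spatial_layout)
  stopifnot(n_types >= 2, n_genes >= 1, n_cells >= n_types,
            markers_per_type >= 1, marker_fold >= 1, K_true > 0,
            base_mean > 0, nb_size > 0, st_efficiency > 0,
            st_efficiency <= 1, grid_rows >= 1, grid_cols >= 1,
            pitch_h > 0)
  if (markers_per_type * n_types > n_genes) {
    stop("markers_per_type x n_types exceeds n_genes")
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Simulate an annotated scRNA-seq reference
#'
#' Per-gene base means are lognormal; each type's markers are multiplied by
#' `marker_fold` in that type. Counts are negative binomial, then every
#' entry is independently zeroed with a per-gene Bernoulli dropout rate
#' chosen so that a unimodal gene's total observed zero fraction lands
#' exactly on the Michaelis-Menten curve
#' `P = 1 - E / (E + K_true)` at its observed mean `E` (the rate solves
#' that equation after accounting for the zeros the negative binomial
#' already produces). Fitting the curve on the output therefore recovers
#' `K_true`, while marker genes — bimodal across types, hence with more
#' sampling zeros than a unimodal gene of the same grand mean — sit above
#' the curve. That excess dropout of cell-type-specific genes is exactly
#' the signal the dropout-based feature selection exploits.
#'
#' @param cfg A [synthetic_config()].
#' @return List: `expression` ([expression_matrix()], modality `"scrna"`),
#'   `annotation` ([cell_annotation()]), `marker_genes` (list per type),
#'   `type_means` (genes x types matrix of NB means).
#' @export
simulate_reference <- function(cfg) {
  type_names <- sprintf("type%d", seq_len(cfg$n_types))
  withr::with_seed(child_seed(cfg$seed, "reference"), {
    base <- stats::rlnorm(cfg$n_genes, meanlog = log(cfg$base_mean),
                          sdlog = cfg$base_sdlog)
    marker_ids <- split(seq_len(cfg$markers_per_type * cfg$n_types),
                        rep(seq_len(cfg$n_types),
                            each = cfg$markers_per_type))
    mu <- matrix(base, cfg$n_genes, cfg$n_types)
    for (t in seq_len(cfg$n_types)) {
      mu[marker_ids[[t]], t] <- mu[marker_ids[[t]], t] * cfg$marker_fold
    }
    type_of_cell <- rep(seq_len(cfg$n_types), length.out = cfg$n_cells)
    counts <- matrix(0, cfg$n_cells, cfg$n_genes)
    for (t in seq_len(cfg$n_types)) {
      cells_t <- which(type_of_cell == t)
      counts[cells_t, ] <- matrix(
        stats::rnbinom(length(cells_t) * cfg$n_genes, mu = rep(mu[, t],
                       each = length(cells_t)), size = cfg$nb_size),
        length(cells_t), cfg$n_genes
      )
    }
    grand_mean <- as.numeric(mu %*% (tabulate(type_of_cell) / cfg$n_cells))
    p_drop <- vapply(grand_mean, dropout_rate_on_curve,
                     numeric(1), K = cfg$K_true, size = cfg$nb_size)
    keep <- matrix(stats::rbinom(length(counts), 1,
                                 rep(1 - p_drop, each = cfg$n_cells)),
                   cfg$n_cells, cfg$n_genes)
    counts <- counts * keep
  })
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  cell_ids <- sprintf("cell%05d", seq_len(cfg$n_cells))
  list(
    expression = expression_matrix(counts, cell_ids, gene_ids, "scrna"),
    annotation = cell_annotation(cell_ids, type_names[type_of_cell],
                                 type_names),
    marker_genes = lapply(marker_ids, function(ix) gene_ids[ix]),
    type_means = `dimnames<-`(mu, list(gene_ids, type_names))
  )
}

# Bernoulli dropout rate p such that the total zero fraction of a unimodal
# NB(mu, size) gene thinned by p lands on the Michaelis-Menten curve at its
# observed mean (1 - p) * mu:
#   p + (1 - p) z  =  K / ((1 - p) mu + K),   z = (size/(size + mu))^size.
# Genes too shallow to reach the curve fall back to the plain curve value.
dropout_rate_on_curve <- function(mu, K, size) {
  if (mu <= 0) return(0)
  z <- (size / (size + mu))^size
  f <- function(p) p + (1 - p) * z - K / ((1 - p) * mu + K)
  if (f(0) >= 0) return(0)
  grid <- seq(0, 1 - 1e-6, length.out = 512)
  fg <- vapply(grid, f, numeric(1))
  hit <- which(fg > 0)[1]
  if (is.na(hit)) return(K / (mu + K))
  stats::uniroot(f, c(grid[hit - 1], grid[hit]), tol = 1e-12)$root
}

#' Simulate a planar tissue at single-cell resolution
#'
#' Places `n_cells` cells uniformly in a rectangle spanning the staggered
#' lattice of the config and assigns each a type according to the layout:
#' `"blocks"` partitions the rectangle into `n_types` vertical bands, each
#' drawing 80% of its cells from one type (spatially clustered types, as in
#' layered cortex); `"gradient"` drifts the type mix linearly along x;
#' `"random"` mixes types homogeneously. Expression vectors are resampled
#' from reference cells of the assigned type.
#'
#' @param cfg A [synthetic_config()].
#' @param ref Output of [simulate_reference()].
#' @return List: `coords` (tibble `x`, `y` per cell), `cell_types`
#'   (factor), `expression` ([expression_matrix()] of cells x genes).
#' @export
simulate_spatial_tissue <- function(cfg, ref) {
  type_names <- levels(ref$annotation$cell_type)
  width <- cfg$grid_cols * cfg$pitch_h
  height <- cfg$grid_rows * cfg$pitch_h / 2
  withr::with_seed(child_seed(cfg$seed, "tissue"), {
    x <- stats::runif(cfg$n_cells, 0, width)
    y <- stats::runif(cfg$n_cells, 0, height)
    types <- switch(
      cfg$spatial_layout,
      blocks = {
        band <- pmin(floor(x / (width / cfg$n_types)) + 1, cfg$n_types)
        dominant <- stats::rbinom(cfg$n_cells, 1, 0.8) == 1
        other <- sample.int(cfg$n_types, cfg$n_cells, replace = TRUE)
        ifelse(dominant, band, other)
      },
      gradient = {
        w <- x / width
        probs <- vapply(seq_len(cfg$n_types), function(t) {
          stats::dnorm(w, mean = (t - 0.5) / cfg$n_types, sd = 0.25)
        }, numeric(cfg$n_cells))
        apply(probs, 1, function(p) sample.int(cfg$n_types, 1, prob = p))
      },
      random = sample.int(cfg$n_types, cfg$n_cells, replace = TRUE)
    )
    by_type <- split(seq_len(nrow(ref$expression)),
                     as.integer(ref$annotation$cell_type))
    donor <- vapply(types, function(t) {
      by_type[[t]][sample.int(length(by_type[[t]]), 1)]
    }, integer(1))
  })
  expr <- ref$expression[donor, , drop = FALSE]
  ids <- sprintf("tcell%05d", seq_len(cfg$n_cells))
  list(
    coords = tibble::tibble(x = x, y = y),
    cell_types = factor(type_names[types], levels = type_names),
    expression = expression_matrix(unname(expr), ids,
                                   colnames(ref$expression), "scrna")
  )
}

#' Aggregate a simulated tissue into Visium-like spots
#'
#' Lays a staggered lattice with horizontal pitch `h` (consecutive rows are
#' offset by `h/2` horizontally and spaced `h/2` vertically), so that each
#' interior spot has exactly four nearest neighbours at the diagonal
#' offsets (± h/2, ± h/2). Each spot aggregates its 10-20 nearest cells
#' (count drawn per spot), expression summed on the count scale, and the
#' ground-truth composition of the aggregated cells is recorded.
#'
#' @param cfg A [synthetic_config()] (grid at least 2 x 2).
#' @param tissue Output of [simulate_spatial_tissue()].
#' @param m_min,m_max Range of cells aggregated per spot.
#' @return List: `expression` ([expression_matrix()], modality `"st"`),
#'   `coords` ([spot_coordinates()] with `pitch_h` set), `truth`
#'   ([proportion_matrix()]).
#' @export
make_visium_like <- function(cfg, tissue, m_min = 10, m_max = 20) {
  if (cfg$grid_rows < 2 || cfg$grid_cols < 2) {
    stop("grid must be at least 2 x 2")
  }
  h <- cfg$pitch_h
  lattice <- expand.grid(col = seq_len(cfg$grid_cols) - 1,
                         row = seq_len(cfg$grid_rows) - 1)
  sx <- lattice$col * h + (lattice$row %% 2) * h / 2
  sy <- lattice$row * h / 2
  n_s <- nrow(lattice)
  ids <- sprintf("spot_%03d", seq_len(n_s))
  cell_xy <- cbind(tissue$coords$x, tissue$coords$y)
  type_names <- levels(tissue$cell_types)
  expr <- matrix(0, n_s, ncol(tissue$expression))
  truth <- matrix(0, n_s, length(type_names))
  withr::with_seed(child_seed(cfg$seed, "visium"), {
    m_vals <- seq.int(m_min, m_max)
    m_spot <- m_vals[sample.int(length(m_vals), n_s, replace = TRUE)]
    for (s in seq_len(n_s)) {
      dd <- (cell_xy[, 1] - sx[s])^2 + (cell_xy[, 2] - sy[s])^2
      members <- order(dd, seq_along(dd))[seq_len(min(m_spot[s],
                                                      nrow(cell_xy)))]
      pooled <- colSums(tissue$expression[members, , drop = FALSE])
      # spot platforms capture a small fraction of the pooled transcripts
      expr[s, ] <- stats::rbinom(length(pooled), size = round(pooled),
                                 prob = cfg$st_efficiency)
      truth[s, ] <- tabulate(tissue$cell_types[members],
                             nbins = length(type_names)) / length(members)
    }
  })
  list(
    expression = expression_matrix(expr, ids,
                                   colnames(tissue$expression), "st"),
    coords = spot_coordinates(ids, sx, sy, pitch_h = h),
    truth = proportion_matrix(truth, ids, type_names)
  )
}
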