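#' Mutual K-nearest-neighbour edges between pseudo- and real spots
#'
#' An edge (p, r) is created iff real spot r is among the k nearest real
#' spots to pseudo-spot p AND p is among the k nearest pseudo-spots to r,
#' under Euclidean distance in the embedded space. Mutuality keeps the
#' bipartite graph sparse and symmetric in information: k controls sparsity.
#' Ties at the k-th rank are broken by node index for determinism.
#'
#' @param pseudo_emb Matrix `n_p x g_a` of embedded pseudo-spots.
#' @param real_emb Matrix `n_r x g_a` of embedded real spots.
#' @param k Neighbourhood size; values above the relevant set size are
#'   clamped with a warning.
#' @return Tibble with columns `pseudo_idx`, `real_idx` (1-based).
#' @export
mutual_knn_edges <- function(pseudo_emb, real_emb, k = 100) {
  if (ncol(pseudo_emb) != ncol(real_emb)) {
    stop("embeddings must share dimensionality")
  }
  if (k < 1) stop("k must be at least 1")
  n_p <- nrow(pseudo_emb); n_r <- nrow(real_emb)
  if (k > max(n_p, n_r)) {
    warning("k = ", k, " exceeds both set sizes; clamping")
  }
  k_r <- min(k, n_r)  # neighbours of a pseudo node among reals
  k_p <- min(k, n_p)  # neighbours of a real node among pseudos
  d2 <- cross_dist2(pseudo_emb, real_emb)  # n_p x n_r
  # p -> its k_r nearest reals
  p_near <- apply(d2, 1, function(row) {
    order(row, seq_along(row))[seq_len(k_r)]
  }, simplify = FALSE)
  # r -> its k_p nearest pseudos
  r_near <- apply(d2, 2, function(col) {
    order(col, seq_along(col))[seq_len(k_p)]
  }, simplify = FALSE)
  edges <- lapply(seq_len(n_p), function(p) {
    cand <- p_near[[p]]
    keep <- cand[vapply(cand, function(r) p %in% r_near[[r]], logical(1))]
    if (length(keep)) cbind(p, keep) else NULL
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges)) {
    return(tibble::tibble(pseudo_idx = integer(0), real_idx = integer(0)))
  }
  tibble::tibble(pseudo_idx = as.integer(edges[, 1]),
                 real_idx = as.integer(edges[, 2])) |>
    dplyr::distinct()
}

# Squared Euclidean cross-distances, clamped at 0 against rounding.
cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Spatial lattice edges among real spots
#'
#' On a staggered lattice with horizontal pitch `h`, the four nearest
#' neighbours of a spot at (x, y) sit at the diagonal offsets
#' (x ± h/2, y ± h/2). For each spot and each of the four target positions,
#' the spot lying within `tol * h` of that target (nearest if several) is
#' linked; the edge set is symmetrized and deduplicated. If fewer than half
#' of the spots find any diagonal neighbour the layout evidently does not
#' follow that lattice, and the function falls back (with a message) to
#' linking each spot to its 4 nearest spatial neighbours, preserving the
#' intent of four adjacency edges per spot.
#'
#' @param coords A [spot_coordinates()] tibble.
#' @param h Positive lattice pitch; if `NULL`, estimated as the modal
#'   nearest-neighbour distance times sqrt(2) (so diagonal neighbours sit at
#'   the stated offsets) and reported via a message.
#' @param tol Matching tolerance as a fraction of `h`.
#' @return Tibble with columns `from`, `to` (1-based row indices into
#'   `coords`, `from < to`).
#' @export
spatial_edges <- function(coords, h = NULL, tol = 0.15) {
  n <- nrow(coords)
  if (n < 2) return(tibble::tibble(from = integer(0), to = integer(0)))
  xy <- cbind(coords$x, coords$y)
  if (is.null(h)) h <- attr(coords, "pitch_h")
  if (is.null(h)) {
    h <- estimate_pitch(xy)
    message("estimated lattice pitch h = ", format(h, digits = 6))
  }
  if (!is.finite(h) || h <= 0) stop("h must be positive")
  d2 <- cross_dist2(xy, xy)
  diag(d2) <- Inf
  offs <- h / 2 * cbind(c(-1, -1, 1, 1), c(-1, 1, 1, -1))
  tol2 <- (tol * h)^2
  pairs <- matrix(integer(0), 0, 2)
  for (i in seq_len(n)) {
    for (o in 1:4) {
      target <- xy[i, ] + offs[o, ]
      dd <- (xy[, 1] - target[1])^2 + (xy[, 2] - target[2])^2
      dd[i] <- Inf
      j <- which.min(dd)
      if (dd[j] <= tol2) pairs <- rbind(pairs, c(i, j))
    }
  }
  touched <- unique(as.vector(pairs))
  if (length(touched) < n / 2) {
    message("coordinates do not follow the staggered lattice; ",
            "falling back to 4 nearest spatial neighbours per spot")
    kk <- min(4, n - 1)
    pairs <- do.call(rbind, lapply(seq_len(n), function(i) {
      cbind(i, order(d2[i, ], seq_len(n))[seq_len(kk)])
    }))
  }
  tibble::tibble(from = pmin(pairs[, 1], pairs[, 2]),
                 to = pmax(pairs[, 1], pairs[, 2])) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)
}

# Modal nearest-neighbour distance (rounded to 6 signif digits) * sqrt(2):
# on a staggered lattice the nearest neighbours are the diagonal ones at
# distance h / sqrt(2).
estimate_pitch <- function(xy) {
  d2 <- cross_dist2(xy, xy)
  diag(d2) <- Inf
  nn <- sqrt(apply(d2, 1, min))
  tab <- table(signif(nn, 6))
  as.numeric(names(tab)[which.max(tab)]) * sqrt(2)
}

#' Assemble the deconvolution graph
#'
#' Stacks embedded pseudo- and real-spot features into one node matrix
#' (pseudo first), converts the two edge lists into a binary symmetric
#' adjacency, normalizes it, and splits the pseudo nodes into
#' train/validation/test masks by a seeded shuffle. Feature columns are
#' z-standardized across all nodes (constant columns set to 0) so the
#' downstream graph convolutions operate at unit scale regardless of the
#' embedding's magnitude; without this a softmax head saturates on
#' library-size-scaled features.
#'
#' @param pseudo_emb,real_emb Embedded features (shared column count).
#' @param knn_edges Tibble from [mutual_knn_edges()].
#' @param sp_edges Tibble from [spatial_edges()] (indices into real spots),
#'   or `NULL` to omit spatial structure.
#' @param labels [proportion_matrix()] over the pseudo-spots, row order
#'   matching `pseudo_emb`.
#' @param split Train/validation/test fractions over pseudo nodes.
#' @param split_seed Seed for the mask shuffle.
#' @return Object of class `deconvolution_graph`: `X`, sparse `A`, `A_norm`,
#'   `masks` (list `train`, `val`, `test`, `real` of node indices), `labels`,
#'   `n_pseudo`, `n_real`, `real_ids`.
#' @export
assemble_graph <- function(pseudo_emb, real_emb, knn_edges, sp_edges = NULL,
                           labels, split = c(0.8, 0.1, 0.1), split_seed = 1) {
  n_p <- nrow(pseudo_emb); n_r <- nrow(real_emb)
  if (nrow(labels) != n_p) stop("labels must cover every pseudo node")
  if (abs(sum(split) - 1) > 1e-8) stop("split fractions must sum to 1")
  X <- rbind(unname(as.matrix(pseudo_emb)), unname(as.matrix(real_emb)))
  X <- scale(X)
  X[, attr(X, "scaled:scale") == 0] <- 0
  attr(X, "scaled:center") <- NULL
  attr(X, "scaled:scale") <- NULL
  N <- n_p + n_r
  ii <- integer(0); jj <- integer(0)
  if (nrow(knn_edges)) {
    if (any(knn_edges$pseudo_idx > n_p) || any(knn_edges$real_idx > n_r)) {
      stop("knn edge endpoints out of range")
    }
    ii <- c(ii, knn_edges$pseudo_idx)
    jj <- c(jj, n_p + knn_edges$real_idx)
  }
  if (!is.null(sp_edges) && nrow(sp_edges)) {
    if (any(sp_edges$from > n_r) || any(sp_edges$to > n_r)) {
      stop("spatial edge endpoints out of range")
    }
    ii <- c(ii, n_p + sp_edges$from)
    jj <- c(jj, n_p + sp_edges$to)
  }
  A <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = 1,
                            dims = c(N, N))
  A@x[] <- 1  # duplicated triplets must not stack
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)

  masks <- withr::with_seed(split_seed, {
    ord <- sample.int(n_p)
    n_train <- floor(split[1] * n_p)
    n_val <- floor(split[2] * n_p)
    list(train = sort(ord[seq_len(n_train)]),
         val = sort(ord[n_train + seq_len(n_val)]),
         test = sort(ord[setdiff(seq_len(n_p),
                                 seq_len(n_train + n_val))]),
         real = n_p + seq_len(n_r))
  })

  structure(
    list(X = X, A = A, A_norm = normalize_adjacency(A), masks = masks,
         labels = labels, n_pseudo = n_p, n_real = n_r,
         real_ids = rownames(real_emb) %||% sprintf("spot_%d", seq_len(n_r))),
    class = "deconvolution_graph"
  )
}

#' @export
print.deconvolution_graph <- function(x, ...) {
  cat("<deconvolution_graph> ", x$n_pseudo, " pseudo + ", x$n_real,
      " real nodes; ", Matrix::nnzero(x$A) / 2, " undirected edges; ",
      ncol(x$X), "-dim features\n", sep = "")
  invisible(x)
}

#' Symmetrically normalized adjacency with self-loops
#'
#' Computes the graph-convolution propagation operator
#' \eqn{\tilde A = \hat D^{-1/2} (A + I) \hat D^{-1/2}} where \eqn{\hat D}
#' is the degree matrix of \eqn{A + I}. Isolated nodes keep a self-loop of
#' weight 1.
#'
#' @param A Binary symmetric adjacency (sparse or dense), zero diagonal.
#' @return Sparse symmetric matrix with entries in `[0, 1]`.
#' @export
normalize_adjacency <- function(A) {
  A <- Matrix::Matrix(A, sparse = TRUE)
  Ahat <- A + Matrix::Diagonal(nrow(A))
  dinv <- 1 / sqrt(Matrix::rowSums(Ahat))
  Matrix::Diagonal(x = dinv) %*% Ahat %*% Matrix::Diagonal(x = dinv)
}
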