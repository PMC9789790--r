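#' Bin single-cell-resolution spatial data into square simulated spots
#'
#' Lays a square grid of side `side` anchored at the bounding-box minimum of
#' the cell coordinates, assigns each cell to a square by half-open intervals
#' `[lo, lo + side)`, and aggregates: spot expression is the sum of member
#' cells' counts, ground-truth proportions are the member type counts over
#' the spot's cell count. Empty squares are dropped. This converts
#' single-cell-resolution technologies (seqFISH+/MERFISH-like) into
#' ST-resolution spots with exact composition labels for benchmarking.
#'
#' @param cell_coords Tibble/data frame with columns `x`, `y` (one row per
#'   cell) — or a [spot_coordinates()] tibble.
#' @param cell_types Character/factor vector of per-cell types.
#' @param cell_expr [expression_matrix()] of cells x genes, rows aligned
#'   with `cell_coords`.
#' @param side Positive square side length, in the units of the coordinates.
#' @return Object of class `simulated_spot_set`: `expression`
#'   ([expression_matrix()]), `coords` (square centers), `truth`
#'   ([proportion_matrix()]), `cells_per_spot`.
#' @export
bin_cells_to_spots <- function(cell_coords, cell_types, cell_expr, side) {
  if (!is.numeric(side) || side <= 0) stop("side must be a positive length")
  n <- nrow(cell_coords)
  if (n == 0) stop("no cells to bin")
  if (length(cell_types) != n || nrow(cell_expr) != n) {
    stop("coordinates, types and expression must align one row per cell")
  }
  lo_x <- min(cell_coords$x); lo_y <- min(cell_coords$y)
  gx <- floor((cell_coords$x - lo_x) / side)
  gy <- floor((cell_coords$y - lo_y) / side)
  key <- paste(gx, gy, sep = "_")
  spots <- sort(unique(key))
  type_names <- if (is.factor(cell_types)) {
    levels(cell_types)
  } else {
    sort(unique(as.character(cell_types)))
  }
  types <- factor(as.character(cell_types), levels = type_names)
  groups <- split(seq_len(n), key)[spots]
  expr <- t(vapply(groups, function(ix) {
    colSums(cell_expr[ix, , drop = FALSE])
  }, numeric(ncol(cell_expr))))
  truth <- t(vapply(groups, function(ix) {
    tabulate(types[ix], nbins = length(type_names)) / length(ix)
  }, numeric(length(type_names))))
  cx <- lo_x + (as.numeric(sub("_.*", "", spots)) + 0.5) * side
  cy <- lo_y + (as.numeric(sub(".*_", "", spots)) + 0.5) * side
  ids <- sprintf("spot_%s", spots)
  structure(
    list(
      expression = expression_matrix(expr, ids, colnames(cell_expr), "st"),
      coords = spot_coordinates(ids, cx, cy),
      truth = proportion_matrix(truth, ids, type_names),
      cells_per_spot = stats::setNames(vapply(groups, length, integer(1)),
                                       ids)
    ),
    class = "simulated_spot_set"
  )
}

#' @export
print.simulated_spot_set <- function(x, ...) {
  cat("<simulated_spot_set> ", nrow(x$expression), " spots, ",
      ncol(x$truth), " cell types, mean ",
      format(mean(x$cells_per_spot), digits = 3), " cells/spot\n", sep = "")
  invisible(x)
}

# Align a prediction to a truth matrix by observation id and type name.
align_props <- function(pred, truth) {
  if (is.null(rownames(pred)) || is.null(rownames(truth))) {
    if (nrow(pred) != nrow(truth)) stop("row counts differ and ids missing")
    ridx <- seq_len(nrow(pred))
  } else {
    ridx <- match(rownames(truth), rownames(pred))
    if (anyNA(ridx)) stop("prediction is missing spots present in the truth")
  }
  cidx <- match(colnames(truth), colnames(pred))
  if (anyNA(cidx)) stop("prediction is missing cell types present in truth")
  list(pred = unclass(pred)[ridx, cidx, drop = FALSE],
       truth = unclass(truth))
}

#' Root-mean-square error between predicted and true proportions
#'
#' `mode = "overall"` takes the square root of the mean squared difference
#' over every spot x type entry; `mode = "per_type"` does the same per
#' column.
#'
#' @param pred,truth [proportion_matrix()] objects with matching spot ids
#'   and cell types.
#' @param mode `"overall"` or `"per_type"`.
#' @return A single number, or a named per-type vector.
#' @export
rmse <- function(pred, truth, mode = c("overall", "per_type")) {
  mode <- match.arg(mode)
  al <- align_props(pred, truth)
  sq <- (al$pred - al$truth)^2
  if (mode == "overall") sqrt(mean(sq)) else sqrt(colMeans(sq))
}

#' Mean Jensen-Shannon divergence between proportion rows
#'
#' Per spot, `JSD(p, q) = KL(p||m)/2 + KL(q||m)/2` with `m = (p + q)/2`,
#' logarithms base 2 and `0 log 0 := 0`, so each spot's divergence lies in
#' `[0, 1]`; the returned value is the mean over spots.
#'
#' @inheritParams rmse
#' @return A number in `[0, 1]`.
#' @export
jsd <- function(pred, truth) {
  al <- align_props(pred, truth)
  if (nrow(al$pred) &&
      (any(abs(rowSums(al$pred) - 1) > 1e-6) ||
       any(abs(rowSums(al$truth) - 1) > 1e-6))) {
    stop("rows must be proportion distributions summing to 1")
  }
  per_spot <- vapply(seq_len(nrow(al$pred)), function(i) {
    p <- al$pred[i, ]; q <- al$truth[i, ]
    m <- (p + q) / 2
    kl <- function(a, b) {
      nz <- a > 0
      sum(a[nz] * log2(a[nz] / b[nz]))
    }
    (kl(p, m) + kl(q, m)) / 2
  }, numeric(1))
  mean(per_spot)
}

#' RMSE of the uniform-proportion baseline
#'
#' Closed form for the error of predicting `1/T` everywhere — the floor any
#' informative deconvolution must beat.
#'
#' @param truth A [proportion_matrix()].
#' @return A single number.
#' @export
uniform_baseline_rmse <- function(truth) {
  v <- unclass(truth)
  sqrt(mean((v - 1 / ncol(v))^2))
}
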