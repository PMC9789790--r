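#' Construct a validated expression matrix
#'
#' An expression matrix holds non-negative expression values for a set of
#' observations (spots or cells) by genes. Observations are rows. The object
#' is a plain numeric matrix with row/column names plus a `modality`
#' attribute, so it drops straight into any linear-algebra code.
#'
#' @param values Numeric matrix, observations x genes, non-negative and finite.
#' @param obs_ids Character vector of unique observation identifiers
#'   (defaults to `rownames(values)`).
#' @param gene_ids Character vector of unique gene identifiers
#'   (defaults to `colnames(values)`).
#' @param modality One of `"st"`, `"scrna"`, `"pseudo"`.
#' @return A numeric matrix with dimnames set and attribute `modality`.
#' @export
#' @examples
#' m <- expression_matrix(matrix(0:3, 2, 2), c("s1", "s2"), c("g1", "g2"), "st")
expression_matrix <- function(values, obs_ids = rownames(values),
                              gene_ids = colnames(values),
                              modality = c("st", "scrna", "pseudo")) {
  modality <- match.arg(modality)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(obs_ids) || is.null(gene_ids)) {
    stop("obs_ids and gene_ids must be supplied when `values` lacks dimnames")
  }
  obs_ids <- as.character(obs_ids)
  gene_ids <- as.character(gene_ids)
  if (nrow(values) != length(obs_ids) || ncol(values) != length(gene_ids)) {
    stop("dimension mismatch: values is ", nrow(values), "x", ncol(values),
         " but ids imply ", length(obs_ids), "x", length(gene_ids))
  }
  if (anyDuplicated(obs_ids)) stop("duplicate observation ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (any(!is.finite(values))) stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  dimnames(values) <- list(obs_ids, gene_ids)
  attr(values, "modality") <- modality
  values
}

#' Construct a validated proportion matrix
#'
#' Per-observation cell-type composition: rows are observations, columns are
#' cell types, every row sums to 1.
#'
#' @param values Numeric matrix in \[0, 1\], observations x types.
#' @param obs_ids Unique observation identifiers.
#' @param type_names Cell-type names, one per column.
#' @param tol Tolerance on the row-sum-to-one invariant.
#' @return A matrix of class `proportion_matrix`.
#' @export
proportion_matrix <- function(values, obs_ids = rownames(values),
                              type_names = colnames(values), tol = 1e-6) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(obs_ids) || is.null(type_names)) {
    stop("obs_ids and type_names required")
  }
  obs_ids <- as.character(obs_ids)
  type_names <- as.character(type_names)
  if (nrow(values) != length(obs_ids) || ncol(values) != length(type_names)) {
    stop("dimension mismatch between values and ids")
  }
  if (anyDuplicated(obs_ids)) stop("duplicate observation ids")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1)) {
    stop("proportions must be finite and within [0, 1]")
  }
  if (nrow(values) > 0) {
    rs <- rowSums(values)
    bad <- which(abs(rs - 1) > tol)
    if (length(bad)) {
      stop("proportion rows must sum to 1 (worst offender: row ",
           bad[which.max(abs(rs[bad] - 1))], ", sum ",
           format(rs[bad[which.max(abs(rs[bad] - 1))]], digits = 10), ")")
    }
  }
  dimnames(values) <- list(obs_ids, type_names)
  class(values) <- c("proportion_matrix", class(values))
  values
}

#' @export
print.proportion_matrix <- function(x, ...) {
  cat("<proportion_matrix> ", nrow(x), " observations x ", ncol(x),
      " cell types\n", sep = "")
  print(utils::head(unclass(x), 5))
  if (nrow(x) > 5) cat("... and", nrow(x) - 5, "more rows\n")
  invisible(x)
}

#' Convert a proportion matrix to a long tibble
#'
#' @param x A `proportion_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `obs_id`, `cell_type`, `proportion`.
#' @exportS3Method generics::tidy
tidy.proportion_matrix <- function(x, ...) {
  tibble::as_tibble(unclass(x), rownames = "obs_id") |>
    tidyr::pivot_longer(-"obs_id", names_to = "cell_type",
                        values_to = "proportion")
}

#' Construct spot coordinates
#'
#' @param obs_id Character ids, one per spot.
#' @param x,y Planar coordinates in the same length unit as the lattice pitch.
#' @param pitch_h Optional positive spot-to-spot horizontal distance.
#' @return A tibble with columns `obs_id`, `x`, `y` and attribute `pitch_h`.
#' @export
spot_coordinates <- function(obs_id, x, y, pitch_h = NULL) {
  obs_id <- as.character(obs_id)
  if (anyDuplicated(obs_id)) stop("duplicate spot ids in coordinates")
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(obs_id) || length(y) != length(obs_id)) {
    stop("obs_id, x, y must have equal lengths")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("coordinates must be finite numbers")
  }
  if (!is.null(pitch_h) && (!is.finite(pitch_h) || pitch_h <= 0)) {
    stop("pitch_h must be a positive number")
  }
  out <- tibble::tibble(obs_id = obs_id, x = x, y = y)
  attr(out, "pitch_h") <- pitch_h
  out
}

#' Construct a cell annotation table
#'
#' @param cell_id Character ids, one per cell.
#' @param cell_type Cell-type label per cell.
#' @param type_names Optional ordered vector of distinct type labels; defaults
#'   to the sorted unique labels. At least two types are required.
#' @return A tibble with columns `cell_id`, `cell_type` (factor with levels
#'   `type_names`).
#' @export
cell_annotation <- function(cell_id, cell_type, type_names = NULL) {
  cell_id <- as.character(cell_id)
  if (anyDuplicated(cell_id)) stop("duplicate cell ids")
  cell_type <- as.character(cell_type)
  if (length(cell_type) != length(cell_id)) stop("one cell_type per cell_id")
  if (is.null(type_names)) type_names <- sort(unique(cell_type))
  type_names <- as.character(type_names)
  if (anyDuplicated(type_names)) stop("type_names must be distinct")
  if (!all(cell_type %in% type_names)) {
    stop("cell_type labels outside type_names: ",
         paste(setdiff(cell_type, type_names), collapse = ", "))
  }
  if (length(type_names) < 2) stop("need at least two cell types")
  tibble::tibble(cell_id = cell_id,
                 cell_type = factor(cell_type, levels = type_names))
}

# Deterministic per-stage child seed so that toggling one pipeline stage never
# reshuffles another. Kept well below 2^31.
child_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  code <- utf8ToInt(stage)
  h <- sum(code * seq_along(code)) %% 99991L
  (abs(as.integer(seed)) %% 1000003L) * 2039L + as.integer(h)
}
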