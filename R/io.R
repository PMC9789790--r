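#' Read an expression matrix from disk
#'
#' Supports a dense delimited table (first column = observation ids, header =
#' gene ids) and a Matrix Market triplet file with plain-text gene and barcode
#' sidecar files. Orientation is normalized to observations x genes: set
#' `genes_in_rows = TRUE` when the source stores genes as rows (the common
#' MTX dialect); with `genes_in_rows = NA` the MTX reader auto-detects by
#' matching sidecar lengths against the declared dimensions.
#'
#' @param path Path to the matrix file (`.csv`/`.tsv` dense, or `.mtx`).
#' @param format_hint `"auto"` (by extension), `"dense_csv"` or `"mtx_triplet"`.
#' @param modality Passed to [expression_matrix()].
#' @param genes_in_rows Logical or `NA` (auto-detect, MTX only).
#' @param genes_path,barcodes_path Sidecar paths for the MTX triplet; default
#'   to `genes.tsv` and `barcodes.tsv` next to the matrix file.
#' @return An [expression_matrix()].
#' @export
read_expression_matrix <- function(path,
                                   format_hint = c("auto", "dense_csv",
                                                   "mtx_triplet"),
                                   modality = "st",
                                   genes_in_rows = NA,
                                   genes_path = NULL,
                                   barcodes_path = NULL) {
  format_hint <- match.arg(format_hint)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format_hint == "auto") {
    format_hint <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
      "mtx_triplet"
    } else {
      "dense_csv"
    }
  }
  if (format_hint == "mtx_triplet") {
    if (is.null(genes_path)) genes_path <- file.path(dirname(path), "genes.tsv")
    if (is.null(barcodes_path)) {
      barcodes_path <- file.path(dirname(path), "barcodes.tsv")
    }
    if (!file.exists(genes_path)) stop("gene sidecar not found: ", genes_path)
    if (!file.exists(barcodes_path)) {
      stop("barcode sidecar not found: ", barcodes_path)
    }
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(genes_path)
    genes <- genes[nzchar(genes)]
    # 10x-style gene files may carry a second symbol column
    genes <- vapply(strsplit(genes, "\t"), `[[`, character(1), 1L)
    barcodes <- readLines(barcodes_path)
    barcodes <- barcodes[nzchar(barcodes)]
    if (is.na(genes_in_rows)) {
      genes_in_rows <- if (length(genes) == nrow(m) &&
                           length(barcodes) == ncol(m)) {
        TRUE
      } else if (length(barcodes) == nrow(m) && length(genes) == ncol(m)) {
        FALSE
      } else {
        stop("sidecar lengths (", length(genes), " genes, ", length(barcodes),
             " barcodes) match neither orientation of the ", nrow(m), "x",
             ncol(m), " matrix")
      }
    }
    if (genes_in_rows) m <- t(m)
    if (length(barcodes) != nrow(m) || length(genes) != ncol(m)) {
      stop("sidecar lengths do not match matrix dimensions")
    }
    expression_matrix(m, barcodes, genes, modality)
  } else {
    tab <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                             check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2) stop("dense matrix needs an id column plus gene columns")
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    if (isTRUE(genes_in_rows)) {
      m <- t(m)
      expression_matrix(m, colnames(tab)[-1], ids, modality)
    } else {
      expression_matrix(m, ids, colnames(tab)[-1], modality)
    }
  }
}

delim_for <- function(path) {
  if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read per-spot planar coordinates
#'
#' Expects a delimited table whose first three columns are id, x, y (a header
#' row with any names is accepted).
#'
#' @param path Path to a CSV/TSV file.
#' @param pitch_h Optional known lattice pitch to attach.
#' @return A [spot_coordinates()] tibble.
#' @export
read_coordinates <- function(path, pitch_h = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("coordinate file needs id, x and y columns")
  x <- suppressWarnings(as.numeric(tab[[2]]))
  y <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(x) || anyNA(y)) stop("non-numeric coordinates in ", path)
  spot_coordinates(tab[[1]], x, y, pitch_h = pitch_h)
}

#' Read per-cell type annotations
#'
#' @param path Delimited table whose first two columns are cell id and type.
#' @return A [cell_annotation()] tibble.
#' @export
read_cell_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("annotation file needs id and cell_type columns")
  cell_annotation(tab[[1]], tab[[2]])
}

#' Write a proportion matrix to a delimited file
#'
#' One row per observation, columns = cell types, numbers written with enough
#' significant digits that a read-back reproduces the input to 1e-9.
#'
#' @param props A valid [proportion_matrix()].
#' @param path Output path (`.csv` or `.tsv` decides the delimiter).
#' @return Invisibly, `path`.
#' @export
write_proportions <- function(props, path) {
  if (!inherits(props, "proportion_matrix")) {
    props <- proportion_matrix(props)  # validates (rows sum to 1)
  } else if (nrow(props) > 0 && any(abs(rowSums(props) - 1) > 1e-6)) {
    stop("proportion rows must sum to 1 before writing")
  }
  write_id_table(unclass(props), path)
  invisible(path)
}

#' Read a proportion matrix written by [write_proportions()]
#'
#' @param path Path to the delimited file.
#' @return A [proportion_matrix()].
#' @export
read_proportions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, sep = delim_for(path), header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  proportion_matrix(m, as.character(tab[[1]]), colnames(tab)[-1])
}

#' Write an expression matrix as a dense delimited table
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_matrix <- function(m, path) {
  write_id_table(m, path)
  invisible(path)
}

# Shared writer: first column obs_id, then numeric columns formatted with 12
# significant digits so read-back round-trips within 1e-9.
write_id_table <- function(m, path) {
  fm <- matrix(sprintf("%.12g", m), nrow(m), ncol(m))
  header <- paste(c("obs_id", colnames(m)), collapse = delim_for(path))
  body <- if (nrow(m) > 0) {
    paste(rownames(m), apply(fm, 1, paste, collapse = delim_for(path)),
          sep = delim_for(path))
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
}

#' Write spot coordinates
#'
#' @param coords A [spot_coordinates()] tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_coordinates <- function(coords, path) {
  utils::write.table(as.data.frame(coords), path, sep = delim_for(path),
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
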