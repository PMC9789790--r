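#' Synthesize pseudo-spots from annotated single cells
#'
#' Each pseudo-spot mixes `m` cells drawn uniformly without replacement
#' (with replacement across spots), with `m` uniform on
#' `[m_min, m_max]` — the typical number of cells under one low-resolution
#' ST spot. The spot's expression is the cellwise mean and its label is the
#' exact mixing fraction `m_c / m` per cell type, which is what makes
#' pseudo-spots usable as supervision for deconvolution.
#'
#' @param sc Reference [expression_matrix()] (cells x genes), already subset
#'   to the selected gene panel.
#' @param ann [cell_annotation()] covering every row of `sc`.
#' @param n_spots Number of pseudo-spots to synthesize.
#' @param m_min,m_max Range of cells mixed per spot.
#' @param seed Integer seed; the same seed reproduces the set exactly.
#' @return A list of class `pseudo_spot_set`: `expression`
#'   (an [expression_matrix()], modality `"pseudo"`), `labels`
#'   (a [proportion_matrix()]), `m_per_spot` (integer vector).
#' @export
generate_pseudo_spots <- function(sc, ann, n_spots, m_min = 10, m_max = 20,
                                  seed = 1) {
  if (n_spots < 1) stop("n_spots must be at least 1")
  if (m_min > m_max) stop("m_min must not exceed m_max")
  if (m_max > nrow(sc)) stop("m_max exceeds the number of reference cells")
  idx <- match(rownames(sc), ann$cell_id)
  if (anyNA(idx)) stop("annotation missing for some reference cells")
  types <- as.character(ann$cell_type)[idx]
  type_names <- levels(ann$cell_type)

  withr::with_seed(seed, {
    m_vals <- seq.int(m_min, m_max)
    m_per_spot <- m_vals[sample.int(length(m_vals), n_spots, replace = TRUE)]
    members <- lapply(m_per_spot, function(m) sample.int(nrow(sc), m))
  })
  expr <- t(vapply(members, function(ix) colMeans(sc[ix, , drop = FALSE]),
                   numeric(ncol(sc))))
  labels <- t(vapply(members, function(ix) {
    tabulate(factor(types[ix], levels = type_names),
             nbins = length(type_names)) / length(ix)
  }, numeric(length(type_names))))
  ids <- sprintf("pseudo_%d", seq_len(n_spots))
  structure(
    list(
      expression = expression_matrix(expr, ids, colnames(sc), "pseudo"),
      labels = proportion_matrix(labels, ids, type_names),
      m_per_spot = as.integer(m_per_spot)
    ),
    class = "pseudo_spot_set"
  )
}

#' @export
print.pseudo_spot_set <- function(x, ...) {
  cat("<pseudo_spot_set> ", nrow(x$expression), " pseudo-spots x ",
      ncol(x$expression), " genes; ", ncol(x$labels), " cell types; ",
      "m in [", min(x$m_per_spot), ", ", max(x$m_per_spot), "]\n", sep = "")
  invisible(x)
}

#' Library-size normalization
#'
#' Scales every observation (row) so its total equals `size_factor`
#' (counts / row-sum x 10 000 by default). Rows with zero total carry no
#' information and are dropped with a warning naming them.
#'
#' @param m An [expression_matrix()].
#' @param size_factor Target row total.
#' @return The normalized [expression_matrix()]; idempotent.
#' @export
normalize_library <- function(m, size_factor = 10000) {
  rs <- rowSums(m)
  zero <- rs == 0
  if (all(zero)) stop("all observations have zero total expression")
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-sum observation(s): ",
            paste(utils::head(rownames(m)[zero], 5), collapse = ", "),
            if (sum(zero) > 5) ", ..." else "")
    m <- m[!zero, , drop = FALSE]
    rs <- rs[!zero]
  }
  out <- m * (size_factor / rs)
  expression_matrix(out, rownames(m), colnames(m),
                    attr(m, "modality") %||% "st")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
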