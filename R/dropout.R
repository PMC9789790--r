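#' Per-gene dropout statistics
#'
#' Computes, for every gene, its mean expression `E` across observations and
#' its dropout rate `P` (the fraction of exactly-zero entries). These are the
#' two coordinates of the Michaelis-Menten dropout curve
#' \deqn{P = 1 - E / (E + K)}
#' that relates how often a transcript fails to be captured to how highly it
#' is expressed.
#'
#' @param m An [expression_matrix()], normally library-size normalized with
#'   [normalize_library()] first (set `normalize = TRUE` to do it here).
#'   Raw-count mode (`normalize = FALSE`, the default, on an already
#'   normalized matrix) keeps `E` in whatever units `m` carries.
#' @param normalize If `TRUE`, apply [normalize_library()] before computing.
#' @return A tibble with columns `gene_id`, `E`, `P` and attribute `n_obs`;
#'   `K_i`, `se_logK`, `p_value`, `q_value` are filled by
#'   [test_gene_significance()].
#' @export
compute_dropout_stats <- function(m, normalize = FALSE) {
  if (nrow(m) < 2) stop("need at least 2 observations for dropout statistics")
  if (normalize) m <- normalize_library(m)
  out <- tibble::tibble(
    gene_id = colnames(m),
    E = unname(colMeans(m)),
    P = unname(colMeans(m == 0))
  )
  attr(out, "n_obs") <- nrow(m)
  out
}

#' Invert the Michaelis-Menten dropout curve for one gene
#'
#' Given a gene's mean expression `E` and dropout rate `P`, returns the unique
#' gene-specific constant `K_i` with `P = 1 - E/(E + K_i)`, i.e.
#' `K_i = E * P / (1 - P)`.
#'
#' @param E Mean expression (non-negative); vectorized.
#' @param P Dropout rate in `[0, 1)`; vectorized.
#' @return `K_i` values; `NA` where `P == 1` (the curve cannot be inverted —
#'   such genes are excluded from fitting and testing).
#' @export
#' @examples
#' estimate_gene_K(E = 1, P = 0.5) # 1
estimate_gene_K <- function(E, P) {
  if (any(E < 0, na.rm = TRUE)) stop("E must be non-negative")
  if (any(P < 0 | P > 1, na.rm = TRUE)) stop("P must lie in [0, 1]")
  ifelse(P == 1, NA_real_, E * P / (1 - P))
}

#' Fit the global Michaelis-Menten dropout constant by maximum likelihood
#'
#' Models each gene's zero count among `n_obs` observations as
#' Binomial(`n_obs`, `K_M / (E + K_M)`) and maximizes the pooled
#' log-likelihood over `log K_M` by bounded 1-D search. Genes with `P = 0`
#' or `P = 1` contribute no information about a shared finite `K_M` relative
#' to their `E` and are excluded (a gene with `E = 0` likewise).
#'
#' @param stats Tibble from [compute_dropout_stats()].
#' @param n_obs Number of observations behind `stats`; defaults to the
#'   attribute recorded by [compute_dropout_stats()].
#' @param interval Search interval for `K_M` (log-spanned).
#' @return An object of class `mm_dropout_fit`: list with `K_M`,
#'   `log_likelihood`, `n_genes_used`.
#' @export
fit_global_KM <- function(stats, n_obs = attr(stats, "n_obs"),
                          interval = c(1e-4, 1e6)) {
  if (is.null(n_obs)) stop("n_obs must be supplied")
  usable <- stats$P > 0 & stats$P < 1 & stats$E > 0
  if (!any(usable)) {
    stop("no usable genes: every gene has P = 0, P = 1 or E = 0; ",
         "the global K_M is not identifiable")
  }
  E <- stats$E[usable]
  zeros <- round(stats$P[usable] * n_obs)
  ll <- function(logK) {
    K <- exp(logK)
    p <- K / (E + K)
    sum(stats::dbinom(zeros, n_obs, p, log = TRUE))
  }
  opt <- stats::optimize(ll, log(interval), maximum = TRUE, tol = 1e-10)
  structure(
    list(K_M = exp(opt$maximum),
         log_likelihood = opt$objective,
         n_genes_used = sum(usable)),
    class = "mm_dropout_fit"
  )
}

#' @export
print.mm_dropout_fit <- function(x, ...) {
  cat("<mm_dropout_fit> K_M =", format(x$K_M, digits = 6),
      " (log-likelihood", format(x$log_likelihood, digits = 6),
      "over", x$n_genes_used, "genes)\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mm_dropout_fit <- function(x, ...) {
  tibble::tibble(term = "K_M", estimate = x$K_M)
}

#' @exportS3Method generics::glance
glance.mm_dropout_fit <- function(x, ...) {
  tibble::tibble(K_M = x$K_M, log_likelihood = x$log_likelihood,
                 n_genes_used = x$n_genes_used)
}

#' Test each gene's dropout constant against the global fit
#'
#' Null hypothesis: the gene-specific `K_i` equals the global `K_M`. The test
#' statistic is `(log K_i - log K_M) / se_logK`, with `se_logK` obtained by
#' propagating the binomial standard error of `P` through
#' `K(P) = E * P / (1 - P)` on the log scale:
#' `se_logK = sqrt(P (1 - P) / n_obs) / (P (1 - P))`. By default the test is
#' right-tailed (excess dropout is the informative direction); p-values use
#' the t distribution with `n_obs - 1` degrees of freedom and q-values are
#' Benjamini-Hochberg adjusted.
#'
#' @param stats Tibble from [compute_dropout_stats()].
#' @param fit An `mm_dropout_fit`.
#' @param n_obs Observation count behind `stats`.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return `stats` with columns `K_i`, `se_logK`, `statistic`, `p_value`,
#'   `q_value` added; genes with `P` of exactly 0 or 1 get `NA` statistics.
#' @export
test_gene_significance <- function(stats, fit, n_obs = attr(stats, "n_obs"),
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (is.null(n_obs)) stop("n_obs must be supplied")
  if (n_obs < 3) stop("refusing to test with fewer than 3 observations")
  K_i <- estimate_gene_K(stats$E, stats$P)
  testable <- !is.na(K_i) & stats$P > 0 & stats$E > 0
  se <- ifelse(testable,
               sqrt(stats$P * (1 - stats$P) / n_obs) /
                 (stats$P * (1 - stats$P)),
               NA_real_)
  z <- ifelse(testable, (log(K_i) - log(fit$K_M)) / se, NA_real_)
  p <- if (alternative == "greater") {
    stats::pt(z, df = n_obs - 1, lower.tail = FALSE)
  } else {
    2 * stats::pt(abs(z), df = n_obs - 1, lower.tail = FALSE)
  }
  stats$K_i <- K_i
  stats$se_logK <- se
  stats$statistic <- z
  stats$p_value <- p
  stats$q_value <- stats::p.adjust(p, method = "BH")
  attr(stats, "n_obs") <- n_obs
  stats
}

#' Select dropout-informative genes shared by ST and scRNA-seq data
#'
#' Ranks genes in each dataset by ascending p-value (ties: descending `K_i`,
#' then gene id), keeps the top `top_k` in each, and intersects the two sets.
#' The result is ordered by the ST p-value; both matrices are subsequently
#' subset to it.
#'
#' @param st_stats,sc_stats Tested stats tibbles (see
#'   [test_gene_significance()]) for the ST and scRNA-seq data.
#' @param top_k Number of top genes taken per dataset before intersecting.
#' @return Character vector of selected gene ids.
#' @export
select_dropout_genes <- function(st_stats, sc_stats, top_k = 2000) {
  top_st <- rank_dropout_genes(st_stats, top_k)
  top_sc <- rank_dropout_genes(sc_stats, top_k)
  shared <- intersect(top_st, top_sc)
  if (length(shared) == 0) {
    stop("no genes shared by the two top-", top_k,
         " sets; raise top_k or check that gene ids match")
  }
  shared[order(match(shared, top_st))]
}

rank_dropout_genes <- function(stats, top_k) {
  ok <- !is.na(stats$p_value)
  s <- stats[ok, ]
  ord <- order(s$p_value, -s$K_i, s$gene_id)
  utils::head(s$gene_id[ord], top_k)
}

#' Match gene identifiers between two expression matrices
#'
#' Exact string matching after case-folding and whitespace stripping; no
#' symbol/alias resolution is attempted.
#'
#' @param a,b Character vectors of gene ids.
#' @return For each element of `a`, the index of its match in `b` (or `NA`).
#' @export
match_gene_ids <- function(a, b) {
  canon <- function(x) tolower(gsub("\\s+", "", x))
  match(canon(a), canon(b))
}
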