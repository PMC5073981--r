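## Log-entropy weighting of the raw frequency matrix. Each entry becomes
## the product of a log-damped local weight and a global weight derived
## from the entropy of the term's distribution across documents: common,
## evenly spread terms are driven toward 0, document-specific terms toward
## their local weight.

#' Local log weight of a term count
#'
#' \eqn{l = \log_2(1 + f)}.
#'
#' @param f Nonnegative count (vectorized).
#' @return Numeric local weight(s).
#' @export
local_weight <- function(f) {
  if (any(f < 0)) stop("counts must be nonnegative")
  log2(1 + f)
}

#' Global entropy weight of a term
#'
#' For a term with frequencies \eqn{f_j} over \eqn{n} documents,
#' \eqn{p_j = f_j / \sum_j f_j} and
#' \deqn{g = 1 + \frac{\sum_j p_j \log_2 p_j}{\log_2 n},}
#' with the convention \eqn{0 \log 0 = 0}. \eqn{g} is 1 for a term
#' confined to a single document and 0 for a term spread uniformly over
#' all documents. For a single-document corpus (\eqn{n = 1}) the formula
#' is undefined and \eqn{g} is defined as 1.
#'
#' @param row Nonnegative frequency vector of one term over all documents;
#'   must have at least one positive entry.
#' @return Global weight in [0, 1].
#' @export
global_weight <- function(row) {
  if (length(row) == 0L || all(row == 0)) {
    stop("term row must have at least one positive entry")
  }
  if (any(row < 0)) stop("counts must be nonnegative")
  n <- length(row)
  if (n == 1L) return(1)
  p <- row[row > 0] / sum(row)
  g <- 1 + sum(p * log2(p)) / log2(n)
  min(max(g, 0), 1)
}

#' Apply log-entropy weighting to a term-document matrix
#'
#' Produces \eqn{a_{ij} = l_{ij} \cdot g_i}: the sparsity pattern of the
#' input is preserved exactly (only nonzero entries are touched).
#'
#' @param tdm Sparse term-by-entity count matrix from
#'   \code{\link{build_term_document_matrix}}.
#' @return A \code{log_entropy_matrix}: list with \code{A} (the weighted
#'   sparse matrix), \code{g} (named global-weight vector) and \code{n}
#'   (number of documents).
#' @export
apply_log_entropy <- function(tdm) {
  stopifnot(nrow(tdm) > 0L, ncol(tdm) > 0L)
  if (any(tdm@x < 0)) stop("counts must be nonnegative")
  n <- ncol(tdm)
  rs <- Matrix::rowSums(tdm)
  if (any(rs == 0)) stop("every term must occur in at least one document")
  tsp <- methods::as(tdm, "TsparseMatrix")
  trip <- data.frame(i = tsp@i + 1L, j = tsp@j + 1L, x = tsp@x)
  p <- trip$x / rs[trip$i]
  if (n == 1L) {
    g <- rep(1, nrow(tdm))
  } else {
    ent <- rep(0, nrow(tdm))
    contrib <- p * log2(p)
    agg <- tapply(contrib, trip$i, sum)
    ent[as.integer(names(agg))] <- agg
    g <- pmin(pmax(1 + ent / log2(n), 0), 1)
  }
  names(g) <- rownames(tdm)
  a <- log2(1 + trip$x) * g[trip$i]
  A <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = a,
                            dims = dim(tdm), dimnames = dimnames(tdm))
  structure(list(A = A, g = g, n = n, local = "log2(1+f)"),
            class = "log_entropy_matrix")
}

#' @export
print.log_entropy_matrix <- function(x, ...) {
  cat(sprintf("log-entropy weighted matrix: %d terms x %d entity documents\n",
              nrow(x$A), ncol(x$A)))
  cat(sprintf("  global weights in [%.3f, %.3f]\n", min(x$g), max(x$g)))
  invisible(x)
}
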