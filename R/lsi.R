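## SVD factorization of the weighted matrix, entropy-based choice of the
## truncation rank k, and the scaled term / entity vector spaces.

#' Factorize a weighted term-by-entity matrix by SVD
#'
#' Computes \eqn{A = U S V'} with orthonormal \eqn{U} (terms) and \eqn{V}
#' (entities) and nonnegative, non-increasing singular values. The
#' transposed reading \eqn{A' = V S U'} is the same factorization with the
#' roles of terms and entities exchanged; no second decomposition is
#' performed. The sign of each singular triplet is fixed so that the
#' largest-magnitude component of every left singular vector is positive
#' (cosines are unaffected; serialization becomes reproducible).
#'
#' Singular values below \code{1e-10} times the largest are treated as
#' numerically zero and excluded from the retained spectrum, giving the
#' numerical rank \code{r}.
#'
#' @param W A \code{log_entropy_matrix}, or any numeric matrix (sparse or
#'   dense) with terms as rows and entities as columns.
#' @param rank Optional requested rank; must not exceed
#'   \code{min(dim(W))}. Defaults to \code{min(dim(W))} (full).
#' @return An \code{lsi_model} with factors truncated to the numerical
#'   rank \code{r} (and at most \code{rank}); \code{k} is unset until
#'   \code{\link{lsi_truncate}}.
#' @export
lsi_decompose <- function(W, rank = NULL) {
  A <- if (inherits(W, "log_entropy_matrix")) W$A else W
  A <- as.matrix(A)
  if (is.null(rownames(A))) rownames(A) <- sprintf("term%04d", seq_len(nrow(A)))
  if (is.null(colnames(A))) colnames(A) <- sprintf("doc%03d", seq_len(ncol(A)))
  full <- min(dim(A))
  if (is.null(rank)) rank <- full
  if (rank > full) {
    stop("requested rank ", rank, " exceeds min(dim) = ", full)
  }
  sv <- svd(A, nu = rank, nv = rank)
  d <- sv$d[seq_len(rank)]
  r <- sum(d >= 1e-10 * d[1L])
  U <- sv$u[, seq_len(r), drop = FALSE]
  V <- sv$v[, seq_len(r), drop = FALSE]
  d <- d[seq_len(r)]
  for (j in seq_len(r)) {
    if (U[which.max(abs(U[, j])), j] < 0) {
      U[, j] <- -U[, j]
      V[, j] <- -V[, j]
    }
  }
  rownames(U) <- rownames(A)
  rownames(V) <- colnames(A)
  structure(list(U = U, d = d, V = V, r = r, k = NULL,
                 E = NULL, C = NULL,
                 vocab = rownames(A), entities = colnames(A),
                 weighting = if (inherits(W, "log_entropy_matrix"))
                   "log-entropy" else "as-given",
                 stoplist = character()),
            class = "lsi_model")
}

#' @export
print.lsi_model <- function(x, ...) {
  cat(sprintf("LSI model: %d terms x %d entities, numerical rank r = %d\n",
              length(x$vocab), length(x$entities), x$r))
  if (!is.null(x$k)) {
    cat(sprintf("  truncated to k = %d (spectrum entropy E = %.4f)\n",
                x$k, x$E))
  } else {
    cat("  untruncated (run lsi_truncate)\n")
  }
  invisible(x)
}

#' Contribution of each singular value to the total variation
#'
#' \eqn{C_i = \sigma_i^2 / \sum_i \sigma_i^2}; the contributions sum to 1.
#'
#' @param singular_values Nonnegative vector with at least one positive
#'   value.
#' @return Contribution vector of the same length.
#' @export
contributions <- function(singular_values) {
  if (length(singular_values) == 0L || all(singular_values == 0)) {
    stop("spectrum must contain a positive singular value")
  }
  if (any(singular_values < 0)) stop("singular values must be nonnegative")
  singular_values^2 / sum(singular_values^2)
}

#' Normalized entropy of a contribution vector
#'
#' \deqn{E = \frac{-1}{\log r} \sum_{i=1}^{r} C_i \log C_i}
#' with \eqn{0 \log 0 = 0}. \eqn{E} ranges from 0 (all variation captured
#' by the first dimension) to 1 (all dimensions equally important) and is
#' independent of the logarithm base.
#'
#' @param C Contribution vector summing to 1.
#' @param r Number of dimensions; defaults to \code{length(C)}; must be
#'   at least 2 (for \eqn{r = 1} the normalizer \eqn{\log r} vanishes).
#' @return Entropy in [0, 1].
#' @export
spectrum_entropy <- function(C, r = length(C)) {
  if (r < 2L) stop("spectrum entropy requires r >= 2")
  if (any(C < 0) || abs(sum(C) - 1) > 1e-8) {
    stop("contributions must be nonnegative and sum to 1")
  }
  nz <- C[C > 0]
  e <- -sum(nz * log(nz)) / log(r)
  min(max(e, 0), 1) + 0  # + 0 normalizes IEEE negative zero
}

#' Choose the truncation rank k from the spectrum entropy
#'
#' \eqn{k = E \times r}, rounded to the nearest integer (round-half-even)
#' and clamped to \eqn{[1, r]}, where \eqn{E} is the normalized entropy of
#' the contributions of the \eqn{r} retained singular values.
#'
#' @param model An \code{lsi_model}.
#' @return A \code{spectrum_summary} list: \code{C}, \code{E}, \code{r},
#'   \code{k}.
#' @export
select_k <- function(model) {
  stopifnot(inherits(model, "lsi_model"))
  if (model$r < 2L) stop("rank-selection requires numerical rank >= 2")
  C <- contributions(model$d)
  E <- spectrum_entropy(C, model$r)
  k <- max(1L, min(model$r, as.integer(round(E * model$r))))
  structure(list(C = C, E = E, r = model$r, k = k),
            class = "spectrum_summary")
}

#' @export
print.spectrum_summary <- function(x, ...) {
  cat(sprintf("spectrum: r = %d, entropy E = %.4f, chosen k = %d\n",
              x$r, x$E, x$k))
  invisible(x)
}

#' Truncate an LSI model to k factors
#'
#' @param model An \code{lsi_model}.
#' @param k Number of leading singular triplets to keep; defaults to the
#'   entropy-based choice of \code{\link{select_k}}.
#' @return The truncated \code{lsi_model} with \code{k}, \code{E} and
#'   \code{C} recorded.
#' @export
lsi_truncate <- function(model, k = NULL) {
  stopifnot(inherits(model, "lsi_model"))
  summ <- if (model$r >= 2L) select_k(model) else
    list(C = contributions(model$d), E = NA_real_, k = 1L)
  if (is.null(k)) k <- summ$k
  k <- as.integer(k)
  if (k < 1L || k > model$r) stop("k must lie in [1, r = ", model$r, "]")
  model$U <- model$U[, seq_len(k), drop = FALSE]
  model$V <- model$V[, seq_len(k), drop = FALSE]
  model$d <- model$d[seq_len(k)]
  model$k <- k
  model$E <- summ$E
  model$C <- summ$C
  log_stage("lsi", "truncated to k = %d of r = %d (E = %.4f)",
            k, model$r, summ$E)
  model
}

## Row-wise unit normalization; zero rows are left at zero and flagged.
unit_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  out <- M / nrm
  attr(out, "zero_rows") <- rownames(M)[zero]
  out
}

#' Scaled (and optionally normalized) term vectors
#'
#' Row \eqn{i} of \eqn{U_k S_k}: the term's coordinates in the truncated
#' concept space, each axis scaled by its singular value. With
#' \code{normalize = TRUE} each nonzero vector is scaled to unit length
#' (zero vectors stay zero and are listed in the \code{"zero_rows"}
#' attribute); cosine comparisons are unaffected by normalization.
#'
#' @param model A truncated \code{lsi_model}.
#' @param normalize Unit-normalize rows?
#' @return Numeric matrix, terms x k.
#' @export
scaled_term_vectors <- function(model, normalize = FALSE) {
  stopifnot(inherits(model, "lsi_model"), !is.null(model$k))
  M <- model$U %*% diag(model$d, length(model$d))
  rownames(M) <- model$vocab
  if (normalize) M <- unit_rows(M)
  M
}

#' Scaled (and optionally normalized) entity vectors
#'
#' Row \eqn{j} of \eqn{V_k S_k}; see \code{\link{scaled_term_vectors}}.
#'
#' @param model A truncated \code{lsi_model}.
#' @param normalize Unit-normalize rows?
#' @return Numeric matrix, entities x k.
#' @export
scaled_entity_vectors <- function(model, normalize = FALSE) {
  stopifnot(inherits(model, "lsi_model"), !is.null(model$k))
  M <- model$V %*% diag(model$d, length(model$d))
  rownames(M) <- model$entities
  if (normalize) M <- unit_rows(M)
  M
}

#' Save an LSI model to a directory
#'
#' Plain-text serialization: factor matrices as TSV, singular values,
#' vocabulary / entity / stop-word lists as line files, and a JSON
#' metadata file recording \code{k}, \code{r}, \code{E}, the contribution
#' vector and the weighting scheme.
#'
#' @param model A truncated \code{lsi_model}.
#' @param dir Output directory (created if needed).
#' @export
save_lsi_model <- function(model, dir) {
  stopifnot(inherits(model, "lsi_model"), !is.null(model$k))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(model$U, file.path(dir, "U.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(model$V, file.path(dir, "V.tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  writeLines(format(model$d, digits = 17), file.path(dir, "singular_values.txt"))
  writeLines(model$vocab, file.path(dir, "vocabulary.txt"))
  writeLines(model$entities, file.path(dir, "entities.txt"))
  writeLines(model$stoplist, file.path(dir, "stoplist.txt"))
  meta <- list(k = model$k, r = model$r, E = model$E, C = model$C,
               n_terms = length(model$vocab),
               n_entities = length(model$entities),
               weighting = model$weighting)
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Load an LSI model saved by \code{save_lsi_model}
#'
#' @param dir Model directory.
#' @return The \code{lsi_model}.
#' @export
load_lsi_model <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  vocab <- readLines(file.path(dir, "vocabulary.txt"))
  entities <- readLines(file.path(dir, "entities.txt"))
  U <- as.matrix(utils::read.delim(file.path(dir, "U.tsv"), header = FALSE))
  V <- as.matrix(utils::read.delim(file.path(dir, "V.tsv"), header = FALSE))
  dimnames(U) <- list(vocab, NULL)
  dimnames(V) <- list(entities, NULL)
  d <- as.numeric(readLines(file.path(dir, "singular_values.txt")))
  stoplist <- readLines(file.path(dir, "stoplist.txt"))
  structure(list(U = U, d = d, V = V, r = meta$r, k = meta$k,
                 E = if (is.null(meta$E)) NA_real_ else meta$E,
                 C = meta$C, vocab = vocab, entities = entities,
                 weighting = meta$weighting, stoplist = stoplist),
            class = "lsi_model")
}
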