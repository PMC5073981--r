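## Tokenization and the raw term-by-entity frequency matrix.

#' Tokenize free text
#'
#' Lowercases, replaces every punctuation character except hyphen and
#' underscore with a space, splits on whitespace, and drops stop words and
#' tokens without any alphanumeric character. Order and multiplicity are
#' preserved.
#'
#' @param text Character scalar (or vector; results are concatenated in
#'   order).
#' @param stoplist Character vector of lowercase stop words.
#' @return Character vector of tokens.
#' @examples
#' tokenize("MicroRNA-21 regulates, apoptosis.")
#' @export
tokenize <- function(text, stoplist = character()) {
  if (length(text) == 0L) return(character())
  x <- tolower(paste(text, collapse = " "))
  x <- gsub("[^a-z0-9_[:space:]-]+", " ", x)
  toks <- strsplit(trimws(x), "[[:space:]]+")[[1L]]
  toks <- toks[nzchar(toks) & grepl("[a-z0-9]", toks)]
  if (length(stoplist) > 0L) toks <- toks[!(toks %in% stoplist)]
  toks
}

#' Build the raw term-by-entity frequency matrix
#'
#' Entry \eqn{f_{ij}} is the number of occurrences of term \eqn{i} in
#' entity document \eqn{j}. The vocabulary is the lexicographically sorted
#' union of all retained tokens, so rebuilding from the same documents is
#' deterministic. Documents that tokenize to nothing are dropped with a
#' warning (every retained column has at least one nonzero entry).
#'
#' @param documents Data frame with columns \code{entity_id} and
#'   \code{text} (as from \code{\link{build_entity_documents}}), or a
#'   named character vector of document texts.
#' @param stoplist Character vector of lowercase stop words.
#' @return Sparse integer matrix (\code{dgCMatrix}) with terms as rows and
#'   entity IDs as columns.
#' @export
build_term_document_matrix <- function(documents, stoplist = character()) {
  if (is.data.frame(documents)) {
    texts <- stats::setNames(documents$text, documents$entity_id)
  } else {
    texts <- documents
    if (is.null(names(texts))) {
      names(texts) <- sprintf("doc%03d", seq_along(texts))
    }
  }
  if (length(texts) == 0L) stop("need at least one document")
  if (anyDuplicated(names(texts))) stop("entity IDs must be unique")
  toks <- lapply(texts, tokenize, stoplist = stoplist)
  empty <- vapply(toks, length, 1L) == 0L
  if (all(empty)) stop("all documents tokenize to empty")
  if (any(empty)) {
    warning("dropping ", sum(empty), " document(s) with no retained tokens: ",
            paste(utils::head(names(texts)[empty], 5L), collapse = ", "))
    toks <- toks[!empty]
  }
  vocab <- sort(unique(unlist(toks, use.names = FALSE)))
  i <- unlist(lapply(toks, function(tk) match(tk, vocab)), use.names = FALSE)
  j <- rep(seq_along(toks), vapply(toks, length, 1L))
  m <- Matrix::sparseMatrix(i = i, j = j, x = 1,
                            dims = c(length(vocab), length(toks)),
                            dimnames = list(vocab, names(toks)))
  log_stage("vectorize", "%d terms x %d entity documents, %d tokens",
            nrow(m), ncol(m), sum(m))
  m
}

#' Write a sparse matrix with row/column labels
#'
#' MatrixMarket coordinate format plus sidecar \code{<prefix>.rows.txt} and
#' \code{<prefix>.cols.txt} label files.
#'
#' @param m Sparse matrix with dimnames.
#' @param prefix Path prefix; files \code{<prefix>.mtx},
#'   \code{<prefix>.rows.txt}, \code{<prefix>.cols.txt} are written.
#' @export
write_labeled_matrix <- function(m, prefix) {
  Matrix::writeMM(methods::as(methods::as(m, "generalMatrix"), "CsparseMatrix"),
                  paste0(prefix, ".mtx"))
  writeLines(rownames(m), paste0(prefix, ".rows.txt"))
  writeLines(colnames(m), paste0(prefix, ".cols.txt"))
  invisible(prefix)
}

#' Read a sparse matrix written by \code{write_labeled_matrix}
#'
#' @param prefix Path prefix used when writing.
#' @return Sparse matrix with dimnames restored.
#' @export
read_labeled_matrix <- function(prefix) {
  m <- methods::as(Matrix::readMM(paste0(prefix, ".mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(paste0(prefix, ".rows.txt")),
                      readLines(paste0(prefix, ".cols.txt")))
  m
}
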