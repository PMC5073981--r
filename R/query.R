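## Query projection and cosine ranking in the truncated concept space.
##
## Term queries follow the classical construction: a binary indicator q0
## over the vocabulary is projected as q0' U_k, i.e. the sum of the U_k
## rows of the matched terms; entities are ranked by the cosine of q with
## the rows of V_k S_k. Entity queries are defined by the symmetry of the
## factorization (A' = V S U'): the sum of the V_k rows of the queried
## entities, with terms ranked against the rows of U_k S_k.

#' Build a term query vector
#'
#' Query text is tokenized with the model's tokenizer and stop list, so
#' multiword queries lose their stop words before projection. Matching is
#' binary: a term contributes once however often it appears in the query.
#'
#' @param terms Character vector of query words or phrases.
#' @param model A truncated \code{lsi_model}.
#' @return An \code{lsi_query} with fields \code{q} (k-vector),
#'   \code{matched}, \code{missed}, \code{side = "term"}.
#' @export
make_term_query <- function(terms, model) {
  stopifnot(inherits(model, "lsi_model"), !is.null(model$k))
  toks <- unique(tokenize(paste(terms, collapse = " "), model$stoplist))
  if (length(toks) == 0L) stop("query contains no usable tokens")
  idx <- match(toks, model$vocab)
  missed <- toks[is.na(idx)]
  matched <- toks[!is.na(idx)]
  if (length(matched) == 0L) {
    stop("no query term found in the model vocabulary; missing: ",
         paste(missed, collapse = ", "))
  }
  if (length(missed) > 0L) {
    warning("query term(s) not in vocabulary: ",
            paste(missed, collapse = ", "))
  }
  q <- colSums(model$U[idx[!is.na(idx)], , drop = FALSE])
  structure(list(q = q, matched = matched, missed = missed, side = "term"),
            class = "lsi_query")
}

#' Build an entity query vector
#'
#' The sum of the \eqn{V_k} rows of the queried entities (duplicates
#' count once: the indicator is binary).
#'
#' @param entities Character vector of entity IDs; all must be in the
#'   model.
#' @param model A truncated \code{lsi_model}.
#' @return An \code{lsi_query} with \code{side = "entity"}.
#' @export
make_entity_query <- function(entities, model) {
  stopifnot(inherits(model, "lsi_model"), !is.null(model$k))
  entities <- unique(as.character(entities))
  idx <- match(entities, model$entities)
  if (anyNA(idx)) {
    stop("unknown entity ID(s): ",
         paste(entities[is.na(idx)], collapse = ", "))
  }
  q <- colSums(model$V[idx, , drop = FALSE])
  structure(list(q = q, matched = entities, missed = character(),
                 side = "entity"),
            class = "lsi_query")
}

## Cosine of a query against the rows of M; zero rows score 0.
cosine_against_rows <- function(q, M) {
  qn <- sqrt(sum(q^2))
  if (qn == 0) stop("query vector is zero")
  rn <- sqrt(rowSums(M^2))
  s <- as.numeric(M %*% q) / (rn * qn)
  s[rn == 0] <- 0
  pmin(pmax(s, -1), 1)
}

ranked_list <- function(ids, scores, query, top_n = NULL) {
  ord <- order(-scores, ids)
  out <- data.frame(rank = seq_along(ord), id = ids[ord],
                    cosine = scores[ord], stringsAsFactors = FALSE)
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  attr(out, "query") <- query
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' Rank all entities against a query
#'
#' Cosine of the query vector with each entity's scaled vector (row of
#' \eqn{V_k S_k}), sorted descending; ties are broken lexicographically by
#' entity ID. Scores lie in [-1, 1].
#'
#' @param q An \code{lsi_query} (term or entity side).
#' @param model A truncated \code{lsi_model}.
#' @param top_n Optional cap on the list length.
#' @return A \code{ranked_list} data frame (\code{rank}, \code{id},
#'   \code{cosine}).
#' @export
rank_entities <- function(q, model, top_n = NULL) {
  stopifnot(inherits(q, "lsi_query"), inherits(model, "lsi_model"),
            !is.null(model$k))
  M <- scaled_entity_vectors(model)
  ranked_list(model$entities, cosine_against_rows(q$q, M), q, top_n)
}

#' Rank terms against a query
#'
#' Cosine of the query vector with each term's scaled vector (row of
#' \eqn{U_k S_k}), sorted descending and truncated to the top
#' \code{top_n} (default 300 — long term lists are impractical to
#' inspect).
#'
#' @param q An \code{lsi_query}.
#' @param model A truncated \code{lsi_model}.
#' @param top_n Maximum list length.
#' @return A \code{ranked_list} data frame.
#' @export
rank_terms <- function(q, model, top_n = 300L) {
  stopifnot(inherits(q, "lsi_query"), inherits(model, "lsi_model"),
            !is.null(model$k), top_n >= 1L)
  M <- scaled_term_vectors(model)
  ranked_list(model$vocab, cosine_against_rows(q$q, M), q, top_n)
}

#' @export
print.ranked_list <- function(x, n = 10L, ...) {
  cat(sprintf("ranked list: %d items\n", nrow(x)))
  print.data.frame(utils::head(x, n), row.names = FALSE, ...)
  if (nrow(x) > n) cat("...\n")
  invisible(x)
}

#' Pairwise entity-entity cosine matrix
#'
#' Cosines between all pairs of scaled entity vectors: symmetric, unit
#' diagonal, entries in [-1, 1]. Entities whose vector is zero in the
#' truncated space get cosine 0 with everything (diagonal still 1).
#'
#' @param model A truncated \code{lsi_model}.
#' @return Dense numeric matrix, entities x entities.
#' @export
pairwise_cosines <- function(model) {
  stopifnot(inherits(model, "lsi_model"), !is.null(model$k))
  X <- scaled_entity_vectors(model, normalize = TRUE)
  M <- tcrossprod(X)
  M <- pmin(pmax(M, -1), 1)
  diag(M) <- 1
  dimnames(M) <- list(model$entities, model$entities)
  M
}
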