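## Evaluation statistics: ROC/AUC for ranked retrieval, cohesion of entity
## sets, the shared-citation co-occurrence baseline, rank-sum comparison,
## information gain and recall of corpus construction.

#' Area under the ROC curve of a ranking
#'
#' The probability that a randomly chosen positive is ranked above a
#' randomly chosen negative: 1 for a perfect ranking (all positives
#' first), 0.5 in expectation for a random ranking, 0 for the worst
#' ranking. Tied scores contribute 1/2 per pair (Mann-Whitney
#' convention).
#'
#' @param ranking One of: a \code{ranked_list}; a named numeric vector of
#'   scores (higher = better); or a character vector of IDs ordered best
#'   first.
#' @param positives Character vector of positive IDs.
#' @param universe Optional character vector restricting evaluation to a
#'   subset of ranked IDs; defaults to everything in \code{ranking}. Must
#'   contain at least one positive and one negative.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(ranking, positives, universe = NULL) {
  if (inherits(ranking, "ranked_list")) {
    scores <- stats::setNames(ranking$cosine, ranking$id)
  } else if (is.numeric(ranking)) {
    if (is.null(names(ranking))) stop("score vector must be named")
    scores <- ranking
  } else if (is.character(ranking)) {
    scores <- stats::setNames(rev(seq_along(ranking)), ranking)
  } else {
    stop("unsupported ranking type")
  }
  if (is.null(universe)) universe <- names(scores)
  missing_ids <- setdiff(universe, names(scores))
  if (length(missing_ids) > 0L) {
    stop("universe member(s) absent from the ranking: ",
         paste(utils::head(missing_ids, 5L), collapse = ", "))
  }
  scores <- scores[universe]
  is_pos <- universe %in% positives
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L) stop("no positives in the universe")
  if (n_neg == 0L) stop("no negatives in the universe")
  r <- rank(scores)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Cohesion of an entity set
#'
#' For a set of \eqn{n} entities, each member in turn is used as a query:
#' the universe (minus the query member, which is neither positive nor
#' negative) is ranked by similarity to it, and the AUC of retrieving the
#' remaining \eqn{n - 1} members is computed. The cohesion is the median
#' of these \eqn{n} AUCs; sets of entities with closely related literature
#' score near 1.
#'
#' @param entities Character vector, at least 2 member IDs.
#' @param similarity A truncated \code{lsi_model} (cosine similarity) or a
#'   symmetric similarity matrix with entity IDs as dimnames (e.g. from
#'   \code{\link{cooccurrence_similarity}}).
#' @param universe Entity IDs over which rankings are evaluated; must
#'   contain all of \code{entities}. Defaults to every entity known to
#'   \code{similarity}.
#' @return A \code{cohesion_result}: list with \code{aucs} (named,
#'   per-member), \code{cohesion} (their median), \code{n}.
#' @export
cohesion <- function(entities, similarity, universe = NULL) {
  entities <- unique(as.character(entities))
  if (length(entities) < 2L) stop("cohesion needs at least 2 entities")
  sim <- if (inherits(similarity, "lsi_model")) {
    pairwise_cosines(similarity)
  } else {
    as.matrix(similarity)
  }
  if (is.null(universe)) universe <- rownames(sim)
  if (!all(entities %in% universe)) {
    stop("entity set must be contained in the universe")
  }
  if (!all(universe %in% rownames(sim))) {
    stop("universe member(s) missing from the similarity matrix")
  }
  aucs <- vapply(entities, function(e) {
    uni <- setdiff(universe, e)
    scores <- stats::setNames(sim[uni, e], uni)
    roc_auc(scores, positives = setdiff(entities, e))
  }, numeric(1))
  structure(list(aucs = aucs, cohesion = stats::median(aucs),
                 n = length(entities)),
            class = "cohesion_result")
}

#' @export
print.cohesion_result <- function(x, ...) {
  cat(sprintf("cohesion = %.4f (median of %d leave-one-out AUCs)\n",
              x$cohesion, x$n))
  invisible(x)
}

#' Shared-citation co-occurrence similarity
#'
#' The baseline similarity between two entities is the number of citations
#' their literature sets share; the diagonal holds each entity's citation
#' count.
#'
#' @param map Entity-citation map (long-format data frame).
#' @return Symmetric integer matrix, entities x entities.
#' @export
cooccurrence_similarity <- function(map) {
  map <- validate_entity_map(map)
  ents <- sort(unique(map$entity_id))
  cits <- sort(unique(map$citation_id))
  B <- Matrix::sparseMatrix(i = match(map$citation_id, cits),
                            j = match(map$entity_id, ents),
                            x = 1, dims = c(length(cits), length(ents)),
                            dimnames = list(cits, ents))
  M <- as.matrix(Matrix::crossprod(B))
  storage.mode(M) <- "integer"
  M
}

#' Rank-sum comparison of two per-member AUC lists
#'
#' Two-sample Wilcoxon rank-sum test between the per-member AUCs of a
#' category under two similarity models (e.g. LSI versus the
#' co-occurrence baseline), two-sided, with the direction of the median
#' difference reported.
#'
#' @param x,y \code{cohesion_result}s or numeric AUC vectors.
#' @return List with \code{p_value}, \code{direction} (\code{"x>y"},
#'   \code{"y>x"} or \code{"none"}) and \code{n_x}, \code{n_y}; when
#'   either side has fewer than 2 observations, \code{p_value} is
#'   \code{NA} and \code{flag = "insufficient observations"}.
#' @export
compare_cohesions <- function(x, y) {
  ax <- if (inherits(x, "cohesion_result")) x$aucs else as.numeric(x)
  ay <- if (inherits(y, "cohesion_result")) y$aucs else as.numeric(y)
  if (length(ax) < 2L || length(ay) < 2L) {
    return(list(p_value = NA_real_, direction = "none",
                n_x = length(ax), n_y = length(ay),
                flag = "insufficient observations"))
  }
  diff <- stats::median(ax) - stats::median(ay)
  if (all(sort(ax) == sort(ay))) {
    return(list(p_value = 1, direction = "none",
                n_x = length(ax), n_y = length(ay)))
  }
  p <- suppressWarnings(stats::wilcox.test(ax, ay, exact = NULL,
                                           correct = TRUE)$p.value)
  list(p_value = p,
       direction = if (diff > 0) "x>y" else if (diff < 0) "y>x" else "none",
       n_x = length(ax), n_y = length(ay))
}

#' Information gain of automated citation retrieval
#'
#' Relative increase in citation count over the curated set:
#' \eqn{(n_{retrieved} - n_{curated}) / n_{curated}}. Negative when
#' retrieval finds fewer citations than curation.
#'
#' @param n_retrieved Number of citations retrieved (vectorized).
#' @param n_curated Number of curated citations; must be >= 1.
#' @return Numeric information gain.
#' @export
information_gain <- function(n_retrieved, n_curated) {
  if (any(n_curated < 1)) {
    stop("information gain is undefined without curated citations")
  }
  (n_retrieved - n_curated) / n_curated
}

#' Recall of retrieved citations against a curated set
#'
#' Fraction of curated citations present among the retrieved ones.
#'
#' @param retrieved Character vector of retrieved citation IDs.
#' @param curated Non-empty character vector of curated citation IDs.
#' @return Recall in [0, 1].
#' @export
recall_against_curated <- function(retrieved, curated) {
  curated <- unique(curated)
  if (length(curated) == 0L) stop("curated set must be non-empty")
  length(intersect(unique(retrieved), curated)) / length(curated)
}
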