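## Corpus assembly: synonym expansion, citation specificity filtering and
## entity-document construction.

#' Expand an entity symbol into its spelling variants
#'
#' MicroRNA symbols appear in the literature under several spellings
#' (\code{mir19a}, \code{mir-19a}, \code{microRNA19a}, \code{microRNA-19a},
#' ...). This crosses a configurable set of base tokens with hyphenated and
#' unhyphenated joins to the symbol's suffix, so that a retrieval query can
#' cover all variants.
#'
#' The returned set always contains the input symbol itself and is closed
#' under hyphen removal: for every variant containing a hyphen, its
#' hyphen-free form is also present.
#'
#' @param symbol Entity symbol, e.g. \code{"mir-19a"} or
#'   \code{"hsa-miR-21"}. Must contain a recognizable base token
#'   (\code{mir}, \code{mirna} or \code{microrna}, case-insensitive,
#'   optionally preceded by a species prefix such as \code{hsa-}) followed
#'   by a non-empty suffix.
#' @param bases Character vector of base-token spellings to cross with the
#'   suffix. The default covers the common literature spellings.
#' @return Character vector (sorted, unique) of synonym strings.
#' @examples
#' expand_synonyms("mir-19a")
#' @export
expand_synonyms <- function(symbol, bases = c("mir", "miR", "microRNA")) {
  stopifnot(is.character(symbol), length(symbol) == 1L, !is.na(symbol))
  m <- regmatches(
    tolower(symbol),
    regexec("^(?:[a-z]{3}-)?(?:microrna|mirna|mir)[-_ ]?(.+)$", tolower(symbol))
  )[[1L]]
  if (length(m) < 2L || !nzchar(m[2L])) {
    stop("cannot parse entity symbol '", symbol,
         "': no base token ('mir'/'microRNA') with a suffix found")
  }
  suffix <- m[2L]
  variants <- c(symbol,
                paste0(rep(bases, each = 2L), c("", "-"), suffix))
  variants <- unique(c(variants, gsub("-", "", variants, fixed = TRUE)))
  sort(variants)
}

#' Build a retrieval query string from a synonym set
#'
#' Joins the sorted synonyms with \code{" OR "}, the form accepted by
#' PubMed-style boolean search interfaces.
#'
#' @param synonyms Non-empty character vector of synonyms.
#' @return A single query string.
#' @examples
#' build_query_string(expand_synonyms("mir-19a"))
#' @export
build_query_string <- function(synonyms) {
  synonyms <- unique(as.character(synonyms))
  if (length(synonyms) == 0L || any(!nzchar(synonyms))) {
    stop("synonym set must be non-empty")
  }
  paste(sort(synonyms), collapse = " OR ")
}

#' Citation specificity threshold by the IQR right-outlier rule
#'
#' Citations that reference implausibly many entities (e.g. abstracts of
#' large sequencing screens) carry little entity-specific information. The
#' threshold for flagging them is the smallest observed entity count that is
#' a right outlier: strictly greater than \eqn{Q3 + 1.5 \cdot IQR}, where
#' \eqn{IQR = Q3 - Q1}.
#'
#' @param counts Positive integer vector: for each citation, the number of
#'   distinct entities it references.
#' @param quantile_type Quantile convention passed to
#'   \code{\link[stats]{quantile}}; the default (type 7, linear
#'   interpolation between order statistics) is R's standard.
#' @return Integer threshold (a member of \code{counts}), with attributes
#'   \code{q1}, \code{q3} and \code{fence}; \code{NA} if no count exceeds
#'   the fence (meaning: no filtering).
#' @examples
#' compute_citation_specificity_threshold(c(1, 1, 1, 2, 2, 3, 100))
#' @export
compute_citation_specificity_threshold <- function(counts, quantile_type = 7) {
  if (length(counts) == 0L) stop("count list must be non-empty")
  counts <- as.numeric(counts)
  if (any(is.na(counts)) || any(counts < 1)) {
    stop("counts must be positive integers")
  }
  q <- stats::quantile(counts, c(0.25, 0.75), type = quantile_type,
                       names = FALSE)
  fence <- q[2L] + 1.5 * (q[2L] - q[1L])
  above <- counts[counts > fence]
  thr <- if (length(above) == 0L) NA_integer_ else as.integer(min(above))
  structure(thr, q1 = q[1L], q3 = q[2L], fence = fence)
}

## Validate the long-format entity-citation map (entity_id, citation_id,
## optional provenance); returns it deduplicated.
validate_entity_map <- function(map) {
  stopifnot(is.data.frame(map),
            all(c("entity_id", "citation_id") %in% names(map)))
  if (!"provenance" %in% names(map)) map$provenance <- "curated"
  map$entity_id <- as.character(map$entity_id)
  map$citation_id <- as.character(map$citation_id)
  map[!duplicated(map[c("entity_id", "citation_id")]), , drop = FALSE]
}

#' Number of distinct entities referenced by each citation
#'
#' @param map Entity-citation map: data frame with columns
#'   \code{entity_id}, \code{citation_id} and optionally
#'   \code{provenance}.
#' @return Named integer vector, one entry per citation.
#' @export
citation_entity_counts <- function(map) {
  map <- validate_entity_map(map)
  counts <- table(map$citation_id)
  stats::setNames(as.integer(counts), names(counts))
}

#' Remove nonspecific citations from an entity-citation map
#'
#' Drops every citation referencing \code{threshold} or more distinct
#' entities from all entities' link sets. Entities left with no citations
#' disappear from the map (only "active" entities — those with at least one
#' citation — remain).
#'
#' @param map Entity-citation map (long-format data frame).
#' @param threshold Integer threshold, typically from
#'   \code{\link{compute_citation_specificity_threshold}}; a citation is
#'   removed when its entity count is \code{>= threshold}. \code{NA} means
#'   no filtering (the map is returned unchanged, deduplicated).
#' @return Filtered map, same columns as the input.
#' @export
filter_nonspecific_citations <- function(map, threshold) {
  map <- validate_entity_map(map)
  if (length(threshold) != 1L) stop("threshold must be a single value")
  if (is.na(threshold)) {
    log_stage("filter", "sentinel threshold: no citations removed")
    return(map)
  }
  threshold <- as.integer(threshold)
  if (threshold < 1L) stop("threshold must be >= 1 (or NA for no filtering)")
  counts <- citation_entity_counts(map)
  bad <- names(counts)[counts >= threshold]
  out <- map[!(map$citation_id %in% bad), , drop = FALSE]
  rownames(out) <- NULL
  log_stage("filter",
            "removed %d nonspecific citations (threshold %d); %d of %d entities retained",
            length(bad), threshold,
            length(unique(out$entity_id)), length(unique(map$entity_id)))
  out
}

#' Assemble one document per entity from its citations
#'
#' Each active entity's document is the concatenation of the title and then
#' the abstract of every citation it references, in ascending
#' \code{citation_id} order, joined by single spaces (empty abstracts
#' contribute nothing).
#'
#' @param citations Data frame with columns \code{citation_id},
#'   \code{title}, \code{abstract} (and optionally \code{year}).
#' @param map Entity-citation map (long-format data frame); every
#'   \code{citation_id} in the map must exist in \code{citations}.
#' @return Data frame with columns \code{entity_id}, \code{text},
#'   \code{n_citations}, one row per active entity, sorted by entity ID.
#' @export
build_entity_documents <- function(citations, map) {
  stopifnot(is.data.frame(citations),
            all(c("citation_id", "title", "abstract") %in% names(citations)))
  map <- validate_entity_map(map)
  citations$citation_id <- as.character(citations$citation_id)
  if (anyDuplicated(citations$citation_id)) {
    stop("citation IDs must be unique")
  }
  unknown <- setdiff(map$citation_id, citations$citation_id)
  if (length(unknown) > 0L) {
    stop("entity map references unknown citation ID(s): ",
         paste(utils::head(unknown, 5L), collapse = ", "))
  }
  idx <- stats::setNames(seq_len(nrow(citations)), citations$citation_id)
  entities <- sort(unique(map$entity_id))
  docs <- lapply(entities, function(e) {
    cids <- sort(unique(map$citation_id[map$entity_id == e]))
    rows <- idx[cids]
    pieces <- as.character(rbind(citations$title[rows],
                                 citations$abstract[rows]))
    pieces[is.na(pieces)] <- ""
    data.frame(entity_id = e,
               text = paste(pieces[nzchar(pieces)], collapse = " "),
               n_citations = length(cids),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, docs)
  rownames(out) <- NULL
  log_stage("documents", "built %d entity documents from %d citation links",
            nrow(out), nrow(map))
  out
}
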