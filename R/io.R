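## Plain-text readers and writers for the corpus formats, and the
## file-backed retrieval client.

#' Read a citation table
#'
#' Tab-separated with columns \code{citation_id}, \code{year},
#' \code{title}, \code{abstract}. Tabs and newlines inside text fields are
#' not permitted (the writer replaces them with spaces).
#'
#' @param path File path.
#' @return Data frame of citations.
#' @export
read_citations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "",
                          na.strings = NULL)
  req <- c("citation_id", "year", "title", "abstract")
  if (!all(req %in% names(df))) {
    stop("citation file must have columns: ", paste(req, collapse = ", "))
  }
  df$year <- as.integer(df$year)
  if (anyDuplicated(df$citation_id)) stop("duplicate citation IDs in ", path)
  df
}

#' Write a citation table
#'
#' @param citations Data frame of citations.
#' @param path Output path.
#' @export
write_citations <- function(citations, path) {
  out <- citations
  for (col in c("title", "abstract")) {
    out[[col]] <- gsub("[\t\r\n]+", " ", out[[col]])
  }
  utils::write.table(out[c("citation_id", "year", "title", "abstract")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read citations from JSON lines
#'
#' One JSON object per line with keys \code{citation_id}, \code{year},
#' \code{title}, \code{abstract}.
#'
#' @param path File path.
#' @return Data frame of citations.
#' @export
read_citations_jsonl <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    data.frame(citation_id = as.character(rec$citation_id),
               year = as.integer(rec$year),
               title = as.character(rec$title),
               abstract = as.character(if (is.null(rec$abstract)) "" else rec$abstract),
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (anyDuplicated(df$citation_id)) stop("duplicate citation IDs in ", path)
  df
}

#' Read an entity-citation map
#'
#' Tab-separated with columns \code{entity_id}, \code{citation_id} and
#' optionally \code{provenance} (\code{curated} or \code{retrieved}).
#'
#' @param path File path.
#' @return Long-format map data frame.
#' @export
read_entity_map <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  validate_entity_map(df)
}

#' Write an entity-citation map
#'
#' @param map Long-format map data frame.
#' @param path Output path.
#' @export
write_entity_map <- function(map, path) {
  utils::write.table(validate_entity_map(map), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a stop-word list
#'
#' Plain text, one word per line; \code{#} starts a comment. Words are
#' lowercased.
#'
#' @param path File path; the default is the bundled generic English list.
#' @return Character vector of stop words.
#' @export
read_stoplist <- function(path = system.file("extdata",
                                             "stoplist_english.txt",
                                             package = "litlsi")) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  words <- tolower(trimws(lines))
  unique(words[nzchar(words)])
}

#' Read gold-standard categories
#'
#' Tab-separated with columns \code{category} and \code{entity_id} (or
#' \code{term}); one row per member.
#'
#' @param path File path.
#' @return Named list: category name -> character vector of members.
#' @export
read_gold_standard <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("gold standard needs two columns")
  lapply(split(df[[2L]], df[[1L]]), unique)
}

#' File-backed literature retrieval client
#'
#' A stand-in for a live literature-search service: it indexes a citation
#' table and answers OR-joined queries (as produced by
#' \code{\link{build_query_string}}) by case-insensitive whole-word match
#' of any synonym against title or abstract. A live E-utilities client
#' could implement the same \code{\link{fetch_citation_ids}} interface.
#'
#' @param citations Data frame of citations.
#' @return A \code{retrieval_client} object.
#' @export
mock_retrieval_client <- function(citations) {
  stopifnot(all(c("citation_id", "title", "abstract") %in% names(citations)))
  text <- tolower(paste(citations$title, citations$abstract))
  structure(list(citation_id = as.character(citations$citation_id),
                 text = text),
            class = "retrieval_client")
}

#' Fetch citation IDs matching a query
#'
#' @param client A retrieval client, e.g. from
#'   \code{\link{mock_retrieval_client}}.
#' @param query OR-joined query string.
#' @return Character vector of matching citation IDs.
#' @export
fetch_citation_ids <- function(client, query) {
  UseMethod("fetch_citation_ids")
}

#' @export
fetch_citation_ids.retrieval_client <- function(client, query) {
  synonyms <- trimws(strsplit(query, " OR ", fixed = TRUE)[[1L]])
  synonyms <- tolower(synonyms[nzchar(synonyms)])
  if (length(synonyms) == 0L) stop("empty query")
  hit <- rep(FALSE, length(client$text))
  for (s in synonyms) {
    pat <- paste0("(^|[^a-z0-9_-])", gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", s),
                  "($|[^a-z0-9_-])")
    hit <- hit | grepl(pat, client$text)
  }
  client$citation_id[hit]
}
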