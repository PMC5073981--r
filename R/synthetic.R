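## Synthetic corpora with planted topic structure, used for offline
## parameter-recovery testing of the whole pipeline.

#' Configuration for a synthetic abstract corpus
#'
#' Describes a corpus of short abstract-like documents with planted topic
#' structure: entities are assigned to topics, entities of the same topic
#' draw from a shared topic-specific vocabulary, and every document mixes
#' topic words with corpus-wide background words.
#'
#' The defaults emulate a small literature collection: 5 topics of 10
#' entities each, 5 citations per entity (literature collections of this
#' kind have a median of a few citations per entity), Poisson document
#' lengths with mean 60 tokens, 60 % topic-specific vocabulary per
#' document, 40 topic words per topic and 120 background words.
#'
#' @param n_entities Number of entities.
#' @param n_topics Number of planted topics; entities are assigned
#'   round-robin so group sizes differ by at most one.
#' @param docs_per_entity Citations generated per entity.
#' @param doc_length Mean document length in tokens (Poisson, floor 10).
#' @param topic_mixing Proportion of each document's tokens drawn from the
#'   entity's topic vocabulary (the rest are background words); in [0, 1].
#' @param topic_vocab_size Topic-specific words per topic (vocabularies of
#'   different topics are disjoint).
#' @param background_vocab_size Number of shared background words.
#' @param n_nonspecific Extra background-only citations, each linked to
#'   \code{nonspecific_breadth} random entities, for exercising the
#'   specificity filter.
#' @param nonspecific_breadth Entities linked per nonspecific citation.
#' @param seed Random seed; the same seed and configuration reproduce an
#'   identical corpus.
#' @return A \code{synthetic_corpus_config} list.
#' @export
synthetic_corpus_config <- function(n_entities = 50L, n_topics = 5L,
                                    docs_per_entity = 5L, doc_length = 60,
                                    topic_mixing = 0.6,
                                    topic_vocab_size = 40L,
                                    background_vocab_size = 120L,
                                    n_nonspecific = 0L,
                                    nonspecific_breadth = 10L,
                                    seed = 1L) {
  cfg <- list(n_entities = as.integer(n_entities),
              n_topics = as.integer(n_topics),
              docs_per_entity = as.integer(docs_per_entity),
              doc_length = as.numeric(doc_length),
              topic_mixing = as.numeric(topic_mixing),
              topic_vocab_size = as.integer(topic_vocab_size),
              background_vocab_size = as.integer(background_vocab_size),
              n_nonspecific = as.integer(n_nonspecific),
              nonspecific_breadth = as.integer(nonspecific_breadth),
              seed = as.integer(seed))
  with(cfg, {
    if (n_entities < 1L || n_topics < 1L || docs_per_entity < 1L ||
        topic_vocab_size < 1L || background_vocab_size < 1L ||
        doc_length <= 0) {
      stop("all counts and the document length must be positive")
    }
    if (n_topics > n_entities) stop("more topics than entities")
    if (topic_mixing < 0 || topic_mixing > 1) {
      stop("topic_mixing must lie in [0, 1]")
    }
    if (n_nonspecific > 0L && nonspecific_breadth > n_entities) {
      stop("nonspecific_breadth exceeds the number of entities")
    }
  })
  structure(cfg, class = "synthetic_corpus_config")
}

#' Generate a synthetic corpus with planted topics
#'
#' @param config A \code{\link{synthetic_corpus_config}}.
#' @return List with components \code{citations} (data frame:
#'   \code{citation_id}, \code{year}, \code{title}, \code{abstract}),
#'   \code{entity_map} (data frame: \code{entity_id}, \code{citation_id},
#'   \code{provenance}), \code{topics} (named character vector: planted
#'   topic label per entity — the ground truth for recovery tests) and
#'   \code{config}.
#' @examples
#' corpus <- generate_synthetic_corpus(synthetic_corpus_config(seed = 42))
#' head(corpus$citations$title, 2)
#' @export
generate_synthetic_corpus <- function(config) {
  if (!inherits(config, "synthetic_corpus_config")) {
    config <- do.call(synthetic_corpus_config, as.list(config))
  }
  with_seed(config$seed, {
    ents <- sprintf("ent%03d", seq_len(config$n_entities))
    topics <- sprintf("topic%02d",
                      rep_len(seq_len(config$n_topics), config$n_entities))
    names(topics) <- ents
    topic_vocab <- lapply(seq_len(config$n_topics), function(t) {
      sprintf("t%02dw%03d", t, seq_len(config$topic_vocab_size))
    })
    bg_vocab <- sprintf("bgw%03d", seq_len(config$background_vocab_size))

    draw_doc <- function(vocab, len) {
      n_topicw <- stats::rbinom(1L, len, config$topic_mixing)
      toks <- c(sample(vocab, n_topicw, replace = TRUE),
                sample(bg_vocab, len - n_topicw, replace = TRUE))
      sample(toks)
    }

    rows <- vector("list", config$n_entities * config$docs_per_entity +
                            config$n_nonspecific)
    links <- vector("list", length(rows))
    cid <- 0L
    for (i in seq_along(ents)) {
      vocab <- topic_vocab[[match(topics[i], sprintf("topic%02d",
                                                     seq_len(config$n_topics)))]]
      for (d in seq_len(config$docs_per_entity)) {
        cid <- cid + 1L
        len <- max(10L, stats::rpois(1L, config$doc_length))
        toks <- draw_doc(vocab, len)
        n_title <- min(8L, len)
        rows[[cid]] <- data.frame(
          citation_id = sprintf("CIT%06d", cid),
          year = sample(2000:2015, 1L),
          title = paste(toks[seq_len(n_title)], collapse = " "),
          abstract = paste(toks[-seq_len(n_title)], collapse = " "),
          stringsAsFactors = FALSE)
        links[[cid]] <- data.frame(entity_id = ents[i],
                                   citation_id = sprintf("CIT%06d", cid),
                                   provenance = "retrieved",
                                   stringsAsFactors = FALSE)
      }
    }
    for (j in seq_len(config$n_nonspecific)) {
      cid <- cid + 1L
      len <- max(10L, stats::rpois(1L, config$doc_length))
      toks <- sample(bg_vocab, len, replace = TRUE)
      rows[[cid]] <- data.frame(
        citation_id = sprintf("CIT%06d", cid),
        year = sample(2000:2015, 1L),
        title = paste(toks[seq_len(min(8L, len))], collapse = " "),
        abstract = paste(toks[-seq_len(min(8L, len))], collapse = " "),
        stringsAsFactors = FALSE)
      linked <- sample(ents, config$nonspecific_breadth)
      links[[cid]] <- data.frame(entity_id = linked,
                                 citation_id = sprintf("CIT%06d", cid),
                                 provenance = "retrieved",
                                 stringsAsFactors = FALSE)
    }
    citations <- do.call(rbind, rows)
    entity_map <- do.call(rbind, links)
    rownames(citations) <- rownames(entity_map) <- NULL
    list(citations = citations, entity_map = entity_map,
         topics = topics, config = config)
  })
}

#' Topic-specific vocabulary of a planted topic
#'
#' Convenience accessor for recovery tests: the words reserved for one
#' planted topic of a synthetic corpus.
#'
#' @param config A \code{\link{synthetic_corpus_config}}.
#' @param topic Topic index (1-based) or label like \code{"topic03"}.
#' @return Character vector of topic words.
#' @export
topic_vocabulary <- function(config, topic) {
  if (is.character(topic)) topic <- as.integer(sub("^topic", "", topic))
  stopifnot(topic >= 1L, topic <= config$n_topics)
  sprintf("t%02dw%03d", topic, seq_len(config$topic_vocab_size))
}
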