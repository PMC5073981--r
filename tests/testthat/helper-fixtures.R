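# Shared fixtures, built in code. The planted-topic corpus and its fitted
# model are expensive enough to cache across test files.

tiny_citations <- function() {
  data.frame(
    citation_id = c("P01", "P02", "P03", "P04"),
    year = c(2010L, 2011L, 2012L, 2013L),
    title = c("Alpha regulates beta", "Beta signaling overview",
              "Gamma pathway in cells", "Delta and alpha crosstalk"),
    abstract = c("A study of alpha in tumours.",
                 "",
                 "Gamma acts downstream of beta.",
                 "Joint analysis of delta with alpha."),
    stringsAsFactors = FALSE)
}

tiny_map <- function() {
  data.frame(
    entity_id = c("mirA", "mirA", "mirB", "mirB", "mirC"),
    citation_id = c("P01", "P04", "P02", "P03", "P03"),
    provenance = "curated",
    stringsAsFactors = FALSE)
}

.litlsi_cache <- new.env(parent = emptyenv())

# 5 planted topics x 10 entities, fixed seed; returns corpus plus fitted
# (entropy-truncated) model built with an empty stop list.
planted_fixture <- function() {
  if (!exists("planted", envir = .litlsi_cache)) {
    corpus <- generate_synthetic_corpus(synthetic_corpus_config(seed = 101L))
    cfg <- pipeline_config(citations = corpus$citations,
                           entity_map = corpus$entity_map,
                           stoplist = character())
    model <- run_build(cfg)
    assign("planted", list(corpus = corpus, config = cfg, model = model),
           envir = .litlsi_cache)
  }
  get("planted", envir = .litlsi_cache)
}

# Small deterministic random count matrix with labels.
random_count_matrix <- function(n_terms, n_docs, seed, lambda = 1.2) {
  set.seed(seed)
  F <- matrix(stats::rpois(n_terms * n_docs, lambda), n_terms, n_docs,
              dimnames = list(sprintf("t%03d", seq_len(n_terms)),
                              sprintf("d%03d", seq_len(n_docs))))
  # keep the term/document invariants: no empty rows or columns
  F[rowSums(F) == 0, 1L] <- 1L
  F[1L, colSums(F) == 0] <- 1L
  F
}
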