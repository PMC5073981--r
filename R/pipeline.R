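## Pipeline orchestration: configuration, end-to-end model building,
## querying, evaluation and network analysis with provenance logging.

#' Pipeline configuration
#'
#' Collects input paths and tunable settings with their standard defaults:
#' automatic IQR-based specificity threshold, entropy-based k, top 50
#' entities and top 300 terms per query, 99th-percentile cosine threshold
#' and 25 clusters for the network stage.
#'
#' @param citations Path to the citation TSV (or a citation data frame).
#' @param entity_map Path to the entity-citation TSV (or a data frame).
#' @param stoplist Path to a stop-word file; default: bundled English
#'   list.
#' @param gold_standard Optional path to a gold-standard TSV.
#' @param specificity_threshold \code{"auto"} (IQR right-outlier rule),
#'   an integer, or \code{NA} for no filtering.
#' @param k \code{"auto"} (entropy rule) or an integer override.
#' @param top_entities,top_terms Query output caps.
#' @param network_percentile,k_clusters Network stage settings.
#' @param seed Random seed for clustering restarts.
#' @return A \code{pipeline_config} list.
#' @export
pipeline_config <- function(citations = NULL, entity_map = NULL,
                            stoplist = NULL, gold_standard = NULL,
                            specificity_threshold = "auto", k = "auto",
                            top_entities = 50L, top_terms = 300L,
                            network_percentile = 99, k_clusters = 25L,
                            seed = 1L) {
  stopifnot(top_entities >= 1L, top_terms >= 1L,
            network_percentile > 0, network_percentile < 100,
            k_clusters >= 1L)
  structure(list(citations = citations, entity_map = entity_map,
                 stoplist = stoplist, gold_standard = gold_standard,
                 specificity_threshold = specificity_threshold, k = k,
                 top_entities = as.integer(top_entities),
                 top_terms = as.integer(top_terms),
                 network_percentile = as.numeric(network_percentile),
                 k_clusters = as.integer(k_clusters),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat keys matching the arguments of \code{\link{pipeline_config}};
#' relative paths are resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A \code{pipeline_config}.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  for (key in c("citations", "entity_map", "stoplist", "gold_standard")) {
    if (!is.null(raw[[key]]) && !file.exists(raw[[key]])) {
      cand <- file.path(dirname(path), raw[[key]])
      if (file.exists(cand)) raw[[key]] <- cand
    }
  }
  do.call(pipeline_config, raw)
}

resolve_input <- function(x, reader) {
  if (is.data.frame(x)) x else reader(x)
}

#' Build an LSI model end to end
#'
#' Runs corpus assembly, specificity filtering, tokenization, log-entropy
#' weighting, SVD and entropy-based truncation; optionally persists the
#' model with a provenance record (configuration echo, stage counts,
#' input checksums).
#'
#' @param config A \code{\link{pipeline_config}} with \code{citations}
#'   and \code{entity_map} set.
#' @param out_dir Optional directory to persist the model into.
#' @return The truncated \code{lsi_model}, with attribute
#'   \code{"provenance"}.
#' @export
run_build <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  citations <- resolve_input(config$citations, read_citations)
  map <- validate_entity_map(resolve_input(config$entity_map,
                                           read_entity_map))
  stoplist <- if (is.null(config$stoplist)) read_stoplist() else
    if (is.character(config$stoplist) && length(config$stoplist) == 1L &&
        file.exists(config$stoplist)) read_stoplist(config$stoplist) else
      as.character(config$stoplist)

  thr <- config$specificity_threshold
  if (identical(thr, "auto")) {
    thr <- compute_citation_specificity_threshold(citation_entity_counts(map))
  }
  n_citations_before <- length(unique(map$citation_id))
  map_f <- filter_nonspecific_citations(map, thr)
  docs <- build_entity_documents(citations, map_f)
  tdm <- build_term_document_matrix(docs, stoplist)
  W <- apply_log_entropy(tdm)
  model <- lsi_decompose(W)
  model <- lsi_truncate(model,
                        k = if (identical(config$k, "auto")) NULL else
                          as.integer(config$k))
  model$stoplist <- stoplist

  prov <- list(
    stages = list(
      citations_input = n_citations_before,
      citations_kept = length(unique(map_f$citation_id)),
      specificity_threshold = if (is.na(thr)) NULL else as.integer(thr),
      entities_active = nrow(docs),
      vocabulary_size = nrow(tdm),
      r = model$r, E = model$E, k = model$k),
    settings = list(k = config$k,
                    specificity_threshold = config$specificity_threshold,
                    seed = config$seed))
  if (is.character(config$citations)) {
    prov$input_md5 <- as.list(tools::md5sum(
      c(citations = config$citations, entity_map = config$entity_map)))
  }
  attr(model, "provenance") <- prov
  if (!is.null(out_dir)) {
    save_lsi_model(model, out_dir)
    jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  model
}

#' Run term and/or entity queries and write ranked TSVs
#'
#' @param config A \code{\link{pipeline_config}} (for the output caps).
#' @param model A truncated \code{lsi_model}.
#' @param terms Optional character vector of query words/phrases.
#' @param entities Optional character vector of entity IDs.
#' @param out_dir Directory for the TSV outputs; \code{NULL} to skip
#'   writing.
#' @return Named list of \code{ranked_list}s (\code{entities} for a term
#'   query; \code{entities} and \code{terms} for an entity query).
#' @export
run_query <- function(config, model, terms = NULL, entities = NULL,
                      out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(terms) && is.null(entities)) {
    stop("provide query terms and/or entities")
  }
  out <- list()
  if (!is.null(terms)) {
    q <- make_term_query(terms, model)
    out$entities <- rank_entities(q, model, top_n = config$top_entities)
  }
  if (!is.null(entities)) {
    q <- make_entity_query(entities, model)
    out$terms <- rank_terms(q, model, top_n = config$top_terms)
    if (is.null(out$entities)) {
      out$entities <- rank_entities(q, model, top_n = config$top_entities)
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      utils::write.table(out[[nm]],
                         file.path(out_dir, paste0("ranked_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' Evaluate a model against a gold standard
#'
#' Per category: the term-query AUC of retrieving the category's entities
#' (the category name is the query), and — for categories with at least 2
#' members in the model — the cohesion under the LSI model and under the
#' shared-citation co-occurrence baseline, with a rank-sum p-value.
#'
#' @param config A \code{\link{pipeline_config}}.
#' @param model A truncated \code{lsi_model}.
#' @param gold Named list (category -> member entity IDs) or a
#'   gold-standard TSV path; defaults to \code{config$gold_standard}.
#' @param map Entity-citation map for the co-occurrence baseline;
#'   defaults to \code{config$entity_map}.
#' @param universe Entity universe for AUC/cohesion; defaults to all
#'   model entities.
#' @param out_path Optional TSV report path.
#' @return Data frame: one row per category with \code{n_members},
#'   \code{n_in_model}, \code{auc_term_query}, \code{cohesion_lsi},
#'   \code{cohesion_cooccurrence}, \code{p_ranksum}, \code{flag}.
#' @export
run_evaluate <- function(config, model, gold = NULL, map = NULL,
                         universe = NULL, out_path = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.null(gold)) gold <- config$gold_standard
  if (is.character(gold)) gold <- read_gold_standard(gold)
  if (is.null(map)) map <- config$entity_map
  cooc <- if (!is.null(map)) {
    cooccurrence_similarity(validate_entity_map(resolve_input(map,
                                                              read_entity_map)))
  } else {
    NULL
  }
  if (is.null(universe)) universe <- model$entities
  rows <- lapply(names(gold), function(cat) {
    members <- intersect(gold[[cat]], model$entities)
    row <- data.frame(category = cat, n_members = length(gold[[cat]]),
                      n_in_model = length(members),
                      auc_term_query = NA_real_, cohesion_lsi = NA_real_,
                      cohesion_cooccurrence = NA_real_,
                      p_ranksum = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    if (length(members) == 0L) {
      row$flag <- "no members in model"
      warning("category '", cat, "' has no members in the model")
      return(row)
    }
    auc <- tryCatch({
      q <- make_term_query(cat, model)
      roc_auc(rank_entities(q, model), members, universe)
    }, error = function(e) NA_real_)
    row$auc_term_query <- auc
    if (length(members) < 2L) {
      row$flag <- "fewer than 2 members: cohesion skipped"
      warning("category '", cat, "': ", row$flag)
      return(row)
    }
    ch_lsi <- cohesion(members, model, universe)
    row$cohesion_lsi <- ch_lsi$cohesion
    if (!is.null(cooc) && all(members %in% rownames(cooc))) {
      uni_cooc <- intersect(universe, rownames(cooc))
      ch_base <- cohesion(members, cooc, uni_cooc)
      row$cohesion_cooccurrence <- ch_base$cohesion
      row$p_ranksum <- compare_cohesions(ch_lsi, ch_base)$p_value
    }
    row
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  if (!is.null(out_path)) {
    utils::write.table(report, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  report
}

#' Run the network stage: threshold, component, clusters, annotation
#'
#' @param config A \code{\link{pipeline_config}} (percentile and number
#'   of clusters).
#' @param model A truncated \code{lsi_model}.
#' @param out_dir Optional directory for edge-list, cluster and
#'   annotation TSVs.
#' @return List with \code{threshold}, \code{graph}, \code{component},
#'   \code{clusters}, \code{annotation}.
#' @export
run_network <- function(config, model, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  cos <- pairwise_cosines(model)
  thr <- percentile_threshold(cos, config$network_percentile)
  g <- build_graph(cos, thr)
  comp <- largest_connected_component(g)
  k <- min(config$k_clusters, length(comp))
  cl <- cluster_component(comp, model, k, seed = config$seed, graph = g)
  ann <- annotate_clusters(cl, model, top_n = config$top_terms)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_graph_edges(g, file.path(out_dir, "edges.tsv"))
    utils::write.table(
      data.frame(entity_id = names(cl$assignment),
                 cluster = unname(cl$assignment)),
      file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    ann_rows <- do.call(rbind, lapply(names(ann), function(cid) {
      data.frame(cluster = cid, ann[[cid]], stringsAsFactors = FALSE)
    }))
    utils::write.table(ann_rows, file.path(out_dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(threshold = thr, graph = g, component = comp, clusters = cl,
       annotation = ann)
}
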