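## Cosine similarity graph over entities: percentile thresholding, largest
## connected component, k-means clustering of the component's LSI vectors
## and top-term annotation of the clusters.

#' Percentile threshold over pairwise cosines
#'
#' The \code{pct}-th percentile (linear interpolation) of the
#' upper-triangle, off-diagonal cosine values — each unordered pair
#' counted once.
#'
#' @param cosines Symmetric cosine matrix (e.g. from
#'   \code{\link{pairwise_cosines}}).
#' @param pct Percentile in (0, 100); default 99.
#' @return Numeric threshold.
#' @export
percentile_threshold <- function(cosines, pct = 99) {
  cosines <- as.matrix(cosines)
  if (nrow(cosines) < 2L) stop("need at least 2 entities")
  if (pct <= 0 || pct >= 100) stop("pct must lie strictly between 0 and 100")
  vals <- cosines[upper.tri(cosines)]
  stats::quantile(vals, pct / 100, type = 7, names = FALSE)
}

#' Build the entity similarity graph
#'
#' Undirected graph with an edge between two entities iff their cosine is
#' strictly above the threshold; no self-loops; isolated nodes are kept.
#' Edge attribute \code{cosine} stores the similarity.
#'
#' @param cosines Symmetric cosine matrix with unit diagonal and entity
#'   dimnames.
#' @param threshold Cosine threshold (strict).
#' @return An \code{igraph} graph with graph attribute \code{threshold}.
#' @export
build_graph <- function(cosines, threshold) {
  cosines <- as.matrix(cosines)
  ids <- rownames(cosines)
  sel <- which(upper.tri(cosines) & cosines > threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[sel[, 1L]], to = ids[sel[, 2L]],
                      cosine = cosines[sel], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = ids))
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  log_stage("network", "%d nodes, %d edges above cosine %.5f",
            igraph::vcount(g), igraph::ecount(g), threshold)
  g
}

#' Largest connected component of the similarity graph
#'
#' Size ties are broken by the component containing the lexicographically
#' smallest entity ID.
#'
#' @param graph An \code{igraph} graph.
#' @return Sorted character vector of the component's node names.
#' @export
largest_connected_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("graph has no nodes")
  comp <- igraph::components(graph)
  sizes <- comp$csize
  cand <- which(sizes == max(sizes))
  members <- lapply(cand, function(cc) {
    sort(igraph::V(graph)$name[comp$membership == cc])
  })
  members[[order(vapply(members, `[`, "", 1L))[1L]]]
}

#' Cluster a connected component's entities by k-means
#'
#' Standard k-means (multiple restarts, fixed seed) on the unit-normalized
#' scaled LSI vectors of the component's entities. Every cluster is
#' non-empty. If a graph is supplied, each cluster is additionally tagged
#' with whether its induced subgraph is connected.
#'
#' @param nodes Character vector of entity IDs to cluster (typically from
#'   \code{\link{largest_connected_component}}).
#' @param model A truncated \code{lsi_model} containing all the nodes.
#' @param k_clusters Number of clusters; at most \code{length(nodes)}.
#' @param seed RNG seed for reproducible restarts.
#' @param nstart Number of random restarts.
#' @param graph Optional \code{igraph} graph for connectivity reporting.
#' @return A \code{cluster_set}: list with \code{assignment} (named
#'   integer vector), \code{clusters} (list of member vectors),
#'   \code{k}, and optionally \code{connected} (logical per cluster).
#' @export
cluster_component <- function(nodes, model, k_clusters, seed = 1L,
                              nstart = 10L, graph = NULL) {
  stopifnot(inherits(model, "lsi_model"), !is.null(model$k))
  nodes <- as.character(nodes)
  if (k_clusters > length(nodes)) {
    stop("k_clusters exceeds the number of entities to cluster")
  }
  missing_ids <- setdiff(nodes, model$entities)
  if (length(missing_ids) > 0L) {
    stop("node(s) not in model: ", paste(utils::head(missing_ids, 5L),
                                         collapse = ", "))
  }
  X <- scaled_entity_vectors(model, normalize = TRUE)[nodes, , drop = FALSE]
  cl <- if (k_clusters == 1L) {
    # degenerate partitions the iterative algorithm does not accept
    rep(1L, length(nodes))
  } else if (k_clusters == length(nodes)) {
    seq_along(nodes)
  } else {
    with_seed(seed, stats::kmeans(X, centers = k_clusters,
                                  nstart = nstart, iter.max = 100L))$cluster
  }
  assignment <- stats::setNames(cl, nodes)
  clusters <- split(nodes, assignment)
  out <- list(assignment = assignment, clusters = clusters,
              k = k_clusters)
  if (!is.null(graph)) {
    out$connected <- vapply(clusters, function(mem) {
      sub <- igraph::induced_subgraph(graph, mem)
      igraph::is_connected(sub)
    }, logical(1))
  }
  structure(out, class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster set: %d clusters over %d entities (sizes %s)\n",
              x$k, length(x$assignment),
              paste(vapply(x$clusters, length, 1L), collapse = ", ")))
  invisible(x)
}

#' Annotate clusters with their top-ranked terms
#'
#' For each cluster, the model is queried with all of the cluster's
#' entities and the top \code{top_n} terms are extracted.
#'
#' @param clusters A \code{cluster_set}.
#' @param model The \code{lsi_model} the clusters came from.
#' @param top_n Terms per cluster (default 300).
#' @return A \code{cluster_annotation}: named list of
#'   \code{ranked_list}s, one per cluster.
#' @export
annotate_clusters <- function(clusters, model, top_n = 300L) {
  stopifnot(inherits(clusters, "cluster_set"))
  ann <- lapply(clusters$clusters, function(mem) {
    rank_terms(make_entity_query(mem, model), model, top_n = top_n)
  })
  structure(ann, class = "cluster_annotation")
}

#' Export a similarity graph as an edge list
#'
#' @param graph An \code{igraph} graph with a \code{cosine} edge
#'   attribute.
#' @param path Output TSV path (\code{id1}, \code{id2}, \code{cosine}).
#' @export
write_graph_edges <- function(graph, path) {
  el <- igraph::as_data_frame(graph, what = "edges")
  names(el)[1:2] <- c("id1", "id2")
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
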