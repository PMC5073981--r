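test_that("percentile threshold interpolates over the upper triangle", {
  # degenerate: all pairwise cosines equal
  M <- matrix(0.3, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(M) <- 1
  expect_equal(percentile_threshold(M, 99), 0.3)
  # strict > makes the graph empty at that threshold
  g <- build_graph(M, percentile_threshold(M, 99))
  expect_equal(igraph::ecount(g), 0)

  # 100 evenly spaced pairwise values: independent hand interpolation
  n <- 15  # 105 pairs; use the first 100 and pad with repeats of max
  vals <- c(seq(0, 0.99, by = 0.01), rep(0.99, 5))
  M2 <- matrix(0, n, n)
  M2[upper.tri(M2)] <- vals
  M2 <- M2 + t(M2)
  diag(M2) <- 1
  dimnames(M2) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
  expected <- unname(sort(vals)[floor((length(vals) - 1) * 0.99) + 1] *
                       (1 - ((length(vals) - 1) * 0.99) %% 1) +
                     sort(vals)[floor((length(vals) - 1) * 0.99) + 2] *
                       (((length(vals) - 1) * 0.99) %% 1))
  got <- percentile_threshold(M2, 99)
  expect_equal(got, expected, tolerance = 1e-12)
  expect_gte(got, min(vals))
  expect_lte(got, max(vals))
  expect_error(percentile_threshold(M[1, 1, drop = FALSE], 99), "at least 2")
})

test_that("graph edges are strict-threshold upper-triangle pairs; isolates kept", {
  # orthogonal entities: identity cosine matrix, no edges
  I5 <- diag(5)
  dimnames(I5) <- list(letters[1:5], letters[1:5])
  g <- build_graph(I5, 0.5)
  expect_equal(igraph::ecount(g), 0)
  expect_equal(igraph::vcount(g), 5)

  # two identical entities at threshold below 1: exactly one edge
  M <- I5
  M["a", "b"] <- M["b", "a"] <- 1
  g1 <- build_graph(M, 0.9)
  expect_equal(igraph::ecount(g1), 1)

  # edge count equals brute-force count on random cosine matrices
  set.seed(71)
  for (rep in 1:5) {
    X <- matrix(rnorm(12 * 4), 12, 4,
                dimnames = list(sprintf("v%02d", 1:12), NULL))
    C <- brute_cosine_rows(X)
    diag(C) <- 1
    thr <- stats::quantile(C[upper.tri(C)], 0.8, names = FALSE)
    g <- build_graph(C, thr)
    expect_equal(igraph::ecount(g),
                     sum(C[upper.tri(C)] > thr))
    # raising the percentile never adds edges
    g_higher <- build_graph(C, stats::quantile(C[upper.tri(C)], 0.95,
                                               names = FALSE))
    expect_lte(igraph::ecount(g_higher), igraph::ecount(g))
  }
})

test_that("largest connected component matches a BFS oracle", {
  # path graph: the whole graph
  P <- diag(4)
  P[cbind(1:3, 2:4)] <- P[cbind(2:4, 1:3)] <- 0.9
  dimnames(P) <- list(letters[1:4], letters[1:4])
  expect_identical(largest_connected_component(build_graph(P, 0.5)),
                   letters[1:4])

  # components of sizes 5 and 3: the 5-set wins
  A <- diag(8)
  dimnames(A) <- list(letters[1:8], letters[1:8])
  for (pair in list(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(6, 7), c(7, 8))) {
    A[pair[1], pair[2]] <- A[pair[2], pair[1]] <- 0.9
  }
  expect_identical(largest_connected_component(build_graph(A, 0.5)),
                   letters[1:5])

  # random graphs against exhaustive BFS reachability
  set.seed(72)
  for (rep in 1:10) {
    n <- sample(5:20, 1)
    C <- matrix(0, n, n)
    edges <- which(upper.tri(C))
    on <- sample(edges, ceiling(length(edges) * 0.15))
    C[on] <- 0.9
    C <- C + t(C)
    diag(C) <- 1
    dimnames(C) <- list(sprintf("v%02d", 1:n), sprintf("v%02d", 1:n))
    got <- largest_connected_component(build_graph(C, 0.5))
    memb <- bfs_components(C > 0.5 & row(C) != col(C))
    sizes <- table(memb)
    best <- sort(names(memb)[memb %in%
      as.integer(names(sizes)[sizes == max(sizes)])])
    # igraph pick must be one of the maximal components; under ties our
    # rule takes the lexicographically smallest member
    expect_true(length(got) == max(sizes))
    expect_true(all(got %in% best))
  }
})

test_that("k-means clustering partitions the component deterministically", {
  fix <- planted_fixture()
  model <- fix$model
  ents <- model$entities
  cl <- cluster_component(ents, model, 5L, seed = 9L)
  expect_identical(sum(vapply(cl$clusters, length, 1L)), length(ents))
  expect_true(all(vapply(cl$clusters, length, 1L) > 0L))
  # determinism under the same seed
  cl2 <- cluster_component(ents, model, 5L, seed = 9L)
  expect_identical(cl$assignment, cl2$assignment)
  # singleton clusters when k equals the component size
  few <- ents[1:4]
  cl3 <- cluster_component(few, model, 4L)
  expect_true(all(vapply(cl3$clusters, length, 1L) == 1L))
  expect_error(cluster_component(few, model, 5L), "exceeds")
})

test_that("recovered clusters are tighter within than between", {
  fix <- planted_fixture()
  model <- fix$model
  cl <- cluster_component(model$entities, model, 5L, seed = 10L)
  M <- pairwise_cosines(model)
  same <- outer(cl$assignment, cl$assignment, "==")
  off <- row(M) != col(M)
  expect_gt(mean(M[same & off]), mean(M[!same]))
})

test_that("cluster annotation recovers planted vocabulary", {
  fix <- planted_fixture()
  topics <- fix$corpus$topics
  group <- names(topics)[topics == "topic03"]
  cl <- structure(list(assignment = stats::setNames(rep(1L, length(group)),
                                                    group),
                       clusters = list(`1` = group), k = 1L),
                  class = "cluster_set")
  ann <- annotate_clusters(cl, fix$model, top_n = 20L)
  top20 <- ann[["1"]]$id
  planted <- topic_vocabulary(fix$corpus$config, 3L)
  expect_gte(mean(top20 %in% planted), 0.8)
  expect_lte(nrow(ann[["1"]]), 20L)
  # singleton-cluster annotation is that entity's own term ranking
  solo <- structure(list(assignment = stats::setNames(1L, group[1]),
                         clusters = list(`1` = group[1]), k = 1L),
                    class = "cluster_set")
  ann1 <- annotate_clusters(solo, fix$model, top_n = 10L)
  direct <- rank_terms(make_entity_query(group[1], fix$model), fix$model,
                       top_n = 10L)
  expect_identical(ann1[["1"]]$id, direct$id)
})
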