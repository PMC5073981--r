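test_that("SVD factors reconstruct the matrix and match a Gram-matrix oracle", {
  d3 <- diag(c(3, 2, 1))
  dimnames(d3) <- list(paste0("t", 1:3), paste0("e", 1:3))
  m <- lsi_decompose(d3)
  expect_equal(m$d, c(3, 2, 1))

  set.seed(31)
  W <- matrix(rnorm(20 * 8), 20, 8)
  m <- lsi_decompose(W)
  # full-rank reconstruction
  R <- m$U %*% diag(m$d) %*% t(m$V)
  expect_lt(norm(W - R, "F"), 1e-8 * norm(W, "F"))
  # orthonormal columns
  expect_equal(crossprod(m$U), diag(m$r), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(crossprod(m$V), diag(m$r), tolerance = 1e-10,
               ignore_attr = TRUE)
  # singular values from an independent eigendecomposition of W'W
  expect_equal(m$d, sqrt(rev(sort(eigen(t(W) %*% W)$values))),
               tolerance = 1e-8)

  expect_error(lsi_decompose(W, rank = 9), "exceeds")
})

test_that("sign convention makes the decomposition reproducible", {
  set.seed(32)
  W <- matrix(rnorm(30 * 6), 30, 6)
  a <- lsi_decompose(W)
  b <- lsi_decompose(W)
  expect_identical(a$U, b$U)
  for (j in seq_len(a$r)) {
    expect_gt(a$U[which.max(abs(a$U[, j])), j], 0)
  }
})

test_that("contributions normalize squared singular values", {
  expect_equal(contributions(c(2, 1, 1)), c(4 / 6, 1 / 6, 1 / 6))
  expect_equal(contributions(5), 1)
  set.seed(33)
  for (rep in 1:5) {
    expect_equal(sum(contributions(runif(10))), 1)
  }
  expect_error(contributions(c(0, 0)), "positive")
})

test_that("spectrum entropy hits its analytic extremes and hand-derived value", {
  expect_equal(spectrum_entropy(c(1, 0, 0)), 0)
  expect_equal(spectrum_entropy(rep(1 / 7, 7)), 1)
  # sigma = [2,1,1]: E = -( (2/3)ln(2/3) + 2*(1/6)ln(1/6) ) / ln 3
  C <- contributions(c(2, 1, 1))
  expect_equal(spectrum_entropy(C),
               -(2 / 3 * log(2 / 3) + 2 * (1 / 6) * log(1 / 6)) / log(3),
               tolerance = 1e-12)
  expect_equal(spectrum_entropy(C), 0.78969, tolerance = 1e-5)
  # invariant to uniform scaling of the spectrum
  expect_equal(spectrum_entropy(contributions(c(20, 10, 10))),
               spectrum_entropy(C))
  expect_error(spectrum_entropy(1, r = 1), "r >= 2")
  expect_error(spectrum_entropy(c(0.2, 0.2)), "sum to 1")
})

test_that("k = round(E * r) clamped to [1, r]", {
  # near-rank-1 spectrum: E * r below 0.5 rounds to 0, clamped to 1
  near1 <- lsi_decompose(diag(c(10, 1e-4, 1e-4)))
  expect_identical(select_k(near1)$k, 1L)

  # perfectly uniform spectrum of rank 10
  uni <- lsi_decompose(diag(rep(2, 10)))
  expect_identical(select_k(uni)$k, 10L)

  # sigma = [2,1,1]: E * r ~ 2.369 -> k = 2
  m <- lsi_decompose(diag(c(2, 1, 1)))
  summ <- select_k(m)
  expect_equal(summ$E * summ$r, 2.369, tolerance = 1e-3)
  expect_identical(summ$k, 2L)
})

test_that("truncation respects k and reconstruction error decreases in k", {
  set.seed(34)
  W <- matrix(rnorm(15 * 6), 15, 6)
  full <- lsi_decompose(W)
  errs <- vapply(seq_len(full$r), function(k) {
    m <- lsi_truncate(full, k)
    norm(W - m$U %*% diag(m$d, k) %*% t(m$V), "F")
  }, numeric(1))
  expect_true(all(diff(errs) < 1e-10))
  expect_error(lsi_truncate(full, 0), "k must lie")
  expect_error(lsi_truncate(full, full$r + 1L), "k must lie")
})

test_that("scaled vectors reproduce column geometry at full rank", {
  set.seed(35)
  W <- matrix(rpois(12 * 5, 2) + 0.0, 12, 5,
              dimnames = list(sprintf("t%02d", 1:12), sprintf("e%d", 1:5)))
  model <- lsi_truncate(lsi_decompose(W), k = lsi_decompose(W)$r)
  EV <- scaled_entity_vectors(model)
  # entity vector norms equal the weighted-column norms
  expect_equal(unname(sqrt(rowSums(EV^2))), unname(sqrt(colSums(W^2))),
               tolerance = 1e-8)
  # normalized vectors have unit length
  EVn <- scaled_entity_vectors(model, normalize = TRUE)
  expect_equal(unname(sqrt(rowSums(EVn^2))), rep(1, 5), tolerance = 1e-12)
  # cosines in truncated space at k = r equal cosines of the original columns
  expect_equal(pairwise_cosines(model), brute_cosine_rows(t(W)),
               tolerance = 1e-8)
})

test_that("planted topic structure concentrates the spectrum relative to noise", {
  spectrum_of <- function(mixing) {
    corpus <- generate_synthetic_corpus(synthetic_corpus_config(
      n_entities = 30L, n_topics = 3L, topic_mixing = mixing, seed = 41L))
    docs <- build_entity_documents(corpus$citations, corpus$entity_map)
    W <- apply_log_entropy(build_term_document_matrix(docs))
    select_k(lsi_decompose(W))
  }
  for (mixing in c(0.95, 1)) {
    summ <- spectrum_of(mixing)
    # the top 3 axes dominate: they carry most of the variation
    expect_gt(sum(summ$C[1:3]), 0.5)
    # and the entropy-derived k stays well below the full rank
    expect_lt(summ$k, 0.75 * summ$r)
  }
})

test_that("models round-trip through the directory serialization", {
  fix <- planted_fixture()
  tmp <- withr::local_tempdir()
  save_lsi_model(fix$model, tmp)
  back <- load_lsi_model(tmp)
  expect_equal(back$U, fix$model$U, tolerance = 1e-12)
  expect_equal(back$V, fix$model$V, tolerance = 1e-12)
  expect_equal(back$d, fix$model$d, tolerance = 1e-12)
  expect_identical(back$k, fix$model$k)
  expect_identical(back$vocab, fix$model$vocab)
  expect_identical(back$entities, fix$model$entities)
  # a query against the reloaded model gives identical rankings
  q1 <- make_term_query("t01w001", fix$model)
  q2 <- make_term_query("t01w001", back)
  r1 <- rank_entities(q1, fix$model)
  r2 <- rank_entities(q2, back)
  expect_identical(r1$id, r2$id)
  expect_equal(r1$cosine, r2$cosine, tolerance = 1e-10)
})
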