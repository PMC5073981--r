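test_that("synonym expansion crosses bases with hyphen variants", {
  syn <- expand_synonyms("mir-19a")
  expect_true(all(c("mir19a", "mir-19a", "microRNA19a", "microRNA-19a") %in% syn))
  expect_true("mir-19a" %in% syn)

  syn1 <- expand_synonyms("mir-1")
  expect_true(all(c("mir1", "microRNA-1") %in% syn1))

  # identity membership and hyphen-stripping closure, across symbol shapes
  for (s in c("mir-19a", "miR21", "microRNA-155", "hsa-miR-200b", "mir_7")) {
    syn <- expand_synonyms(s)
    expect_true(s %in% syn)
    hyph <- syn[grepl("-", syn, fixed = TRUE)]
    expect_true(all(gsub("-", "", hyph, fixed = TRUE) %in% syn))
  }

  expect_error(expand_synonyms("mir"), "suffix")
  expect_error(expand_synonyms("tp53"), "cannot parse")
})

test_that("query strings are sorted OR-joins", {
  expect_identical(build_query_string(c("mir19a", "mir-19a")),
                   "mir-19a OR mir19a")
  expect_identical(build_query_string("x"), "x")
  q3 <- build_query_string(c("b", "a", "c"))
  expect_equal(lengths(regmatches(q3, gregexpr(" OR ", q3, fixed = TRUE))), 2L)
  expect_error(build_query_string(character()), "non-empty")
})

test_that("specificity threshold is the smallest right outlier under the IQR fence", {
  thr <- compute_citation_specificity_threshold(c(1, 1, 1, 2, 2, 3, 100))
  expect_identical(as.integer(thr), 100L)
  expect_equal(attr(thr, "q1"), 1)
  expect_equal(attr(thr, "q3"), 2.5)
  expect_equal(attr(thr, "fence"), 4.75)

  # constant data has zero IQR and no right outliers
  expect_true(is.na(compute_citation_specificity_threshold(c(2, 2, 2, 2))))

  # the threshold, when defined, is always a member of the input
  set.seed(11)
  for (rep in 1:20) {
    counts <- stats::rpois(40, 2) + 1L
    counts[sample.int(40, 2)] <- counts[sample.int(40, 2)] + sample(0:30, 2)
    thr <- compute_citation_specificity_threshold(counts)
    if (!is.na(thr)) {
      expect_true(as.integer(thr) %in% counts)
      expect_true(thr > attr(thr, "fence"))
      expect_true(all(counts[counts > attr(thr, "fence")] >= thr))
    }
  }
  expect_error(compute_citation_specificity_threshold(numeric()), "non-empty")
})

test_that("nonspecific-citation filtering removes at/above threshold and drops inactive entities", {
  # one citation referencing 7 entities, another referencing 6
  map <- data.frame(
    entity_id = c(sprintf("e%02d", 1:7), sprintf("e%02d", 1:6), "e08"),
    citation_id = c(rep("broad", 7), rep("mid", 6), "solo"),
    stringsAsFactors = FALSE)
  out <- filter_nonspecific_citations(map, 7L)
  expect_false("broad" %in% out$citation_id)   # 7 >= 7: removed
  expect_true("mid" %in% out$citation_id)      # 6 < 7: retained
  expect_true("solo" %in% out$citation_id)

  # entity whose every citation exceeds the threshold disappears
  expect_false("e07" %in% out$entity_id)

  # idempotence and monotone link count
  again <- filter_nonspecific_citations(out, 7L)
  expect_identical(out, again)
  expect_lte(nrow(out), nrow(map))

  # sentinel threshold is the identity transform
  ident <- filter_nonspecific_citations(map, NA)
  expect_setequal(ident$citation_id, map$citation_id)
})

test_that("entity documents concatenate title then abstract in citation order", {
  cites <- tiny_citations()
  docs <- build_entity_documents(cites, tiny_map())
  expect_identical(docs$entity_id, c("mirA", "mirB", "mirC"))
  expect_identical(docs$n_citations, c(2L, 2L, 1L))
  expect_identical(
    docs$text[docs$entity_id == "mirA"],
    paste("Alpha regulates beta", "A study of alpha in tumours.",
          "Delta and alpha crosstalk", "Joint analysis of delta with alpha."))
  # empty abstract contributes nothing but the title is present
  expect_identical(
    docs$text[docs$entity_id == "mirB"],
    paste("Beta signaling overview",
          "Gamma pathway in cells", "Gamma acts downstream of beta."))
  # one document per active entity
  expect_identical(nrow(docs), length(unique(tiny_map()$entity_id)))

  bad_map <- rbind(tiny_map(),
                   data.frame(entity_id = "mirA", citation_id = "NOPE",
                              provenance = "curated"))
  expect_error(build_entity_documents(cites, bad_map), "NOPE")
})

test_that("the file-backed retrieval client honors OR queries", {
  client <- mock_retrieval_client(tiny_citations())
  hits <- fetch_citation_ids(client, "alpha OR delta")
  expect_setequal(hits, c("P01", "P04"))
  expect_setequal(fetch_citation_ids(client, "gamma"), "P03")
  expect_length(fetch_citation_ids(client, "zeta"), 0L)
})

test_that("citation and map round-trips through TSV and JSONL preserve content", {
  tmp <- withr::local_tempdir()
  cites <- tiny_citations()
  write_citations(cites, file.path(tmp, "c.tsv"))
  back <- read_citations(file.path(tmp, "c.tsv"))
  expect_identical(back$citation_id, cites$citation_id)
  expect_identical(back$title, cites$title)
  expect_identical(back$abstract, cites$abstract)

  jl <- file.path(tmp, "c.jsonl")
  writeLines(vapply(seq_len(nrow(cites)), function(i) {
    jsonlite::toJSON(as.list(cites[i, ]), auto_unbox = TRUE)
  }, ""), jl)
  back2 <- read_citations_jsonl(jl)
  expect_identical(back2$abstract, cites$abstract)

  write_entity_map(tiny_map(), file.path(tmp, "m.tsv"))
  m <- read_entity_map(file.path(tmp, "m.tsv"))
  expect_setequal(paste(m$entity_id, m$citation_id),
                  paste(tiny_map()$entity_id, tiny_map()$citation_id))
})
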