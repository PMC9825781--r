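test_that("annotation records concept, axis, field and exact offsets", {
  lex <- demo_lexicon()
  doc <- tibble::tibble(doc_id = "d1", abstract = "Remdesivir blocks covid-19 replication.")
  ann <- annotate_document(doc, lex)
  expect_identical(nrow(ann), 2L)
  expect_identical(ann$concept_id, c("CHEBI:145994", "DEMO:0000001"))
  expect_identical(ann$matched_term, c("Remdesivir", "covid-19"))
  expect_identical(ann$axis, c("CHEM", "DIS"))
  expect_identical(ann$start, c(0L, 18L))
  expect_identical(ann$end, c(10L, 26L))

  expect_identical(nrow(annotate_document(doc, lex, axes = "CL")), 0L)
  expect_error(annotate_document(doc, lex, axes = "XYZ"), "unknown axis")
})

test_that("matching is spelling-robust in both directions via fused variants", {
  lex <- demo_lexicon()
  # document without the dash still matches the dashed lexicon form
  ann <- annotate_document(
    tibble::tibble(doc_id = "d2", abstract = "We studied COVID19 cases."), lex
  )
  expect_identical(ann$concept_id, "DEMO:0000001")
  expect_identical(ann$matched_term, "COVID19")
  # multi-token synonym matches as a consecutive phrase
  ann2 <- annotate_document(
    tibble::tibble(doc_id = "d3", title = "Coronavirus Disease 2019 update"), lex
  )
  expect_identical(ann2$concept_id, "DEMO:0000001")
  expect_identical(ann2$matched_term, "Coronavirus Disease 2019")
  expect_identical(ann2$field, "title")
})

test_that("within one concept the longest match at a start wins; overlaps across concepts are kept", {
  lex <- lexicon(tibble::tibble(
    id = c("A:1", "B:2"), axis = c("DIS", "DIS"),
    preferred_label = c("acute respiratory syndrome", "respiratory syndrome"),
    synonyms = list("acute", character()), xrefs = list(character(), character())
  ))
  ann <- annotate_document(
    tibble::tibble(doc_id = "d", abstract = "severe acute respiratory syndrome"), lex
  )
  a1 <- ann[ann$concept_id == "A:1", ]
  expect_identical(nrow(a1), 1L) # "acute" match absorbed by the longer phrase
  expect_identical(a1$matched_term, "acute respiratory syndrome")
  expect_identical(ann[ann$concept_id == "B:2", ]$matched_term, "respiratory syndrome")
})

test_that("corpus annotation equals independent per-document annotation and checks ids", {
  fix <- make_fixture(fixture_spec(n_docs = 10L, seed = 5))
  ann <- annotate_corpus(fix$documents, fix$lexicon)
  per_doc <- dplyr::bind_rows(lapply(seq_len(nrow(fix$documents)), function(i) {
    annotate_document(fix$documents[i, ], fix$lexicon)
  }))
  expect_identical(ann, per_doc)

  expect_identical(nrow(annotate_corpus(fix$documents[0, ], fix$lexicon)), 0L)
  expect_error(
    annotate_corpus(fix$documents[c(1, 1), ], fix$lexicon),
    "duplicate doc_id"
  )
  empty_doc <- tibble::tibble(doc_id = "e1", abstract = "")
  expect_identical(nrow(annotate_corpus(empty_doc, fix$lexicon)), 0L)
})

test_that("every emitted annotation re-normalizes to a phrase of its concept", {
  fix <- make_fixture(fixture_spec(n_docs = 25L, seed = 9))
  ann <- annotate_corpus(fix$documents, fix$lexicon)
  expect_gt(nrow(ann), 0)
  pt <- fix$lexicon$phrase_table
  texts <- fix$documents
  for (i in seq_len(nrow(ann))) {
    row <- ann[i, ]
    field_text <- texts[[row$field]][texts$doc_id == row$doc_id]
    slice <- substring(field_text, row$start + 1L, row$end)
    vsets <- normalize_tokens(slice)
    keys <- Reduce(
      function(acc, vs) as.vector(outer(acc, vs, paste)),
      vsets[-1], init = vsets[[1]]
    )
    hit <- any(vapply(keys, function(k) row$concept_id %in% pt[[k]], logical(1)))
    expect_true(hit, label = paste("slice", shQuote(slice), "for", row$concept_id))
  }
})

test_that("aggregate_stats reproduces published collection totals and floor averages", {
  counts <- collection_axis_counts()
  ndocs <- collection_doc_counts()
  stats <- dplyr::bind_rows(lapply(names(counts), function(coll) {
    aggregate_stats(counts[[coll]], ndocs[[coll]], collection = coll)
  }))
  expect_identical(stats$total, c(279535591, 724978858, 85400460))
  # 724978858 / 4722601 = 153.51...: truncation, not rounding
  expect_identical(stats$avg_per_doc, c(8, 153, 219))
  expect_identical(sum(stats$total), 1089914909)
  # conservation: total is always the sum of the nine per-axis counts
  expect_identical(stats$total, rowSums(as.matrix(stats[, AXES])))
})

test_that("aggregate_stats counts live annotations and validates inputs", {
  fix <- make_fixture(fixture_spec(n_docs = 15L, seed = 2))
  ann <- annotate_corpus(fix$documents, fix$lexicon)
  st <- aggregate_stats(ann, n_docs = 15L, collection = "syn")
  expect_identical(st$total, as.numeric(nrow(ann)))
  expect_identical(st$avg_per_doc, floor(nrow(ann) / 15))
  expect_identical(sum(unlist(st[AXES])), st$total)

  expect_error(aggregate_stats(ann, n_docs = 1L), "n_docs")
  expect_error(aggregate_stats(ann, n_docs = -1L), "n_docs")
  zero <- aggregate_stats(ann[0, ], n_docs = 5L)
  expect_identical(zero$total, 0)
  expect_identical(zero$avg_per_doc, 0)
  expect_identical(aggregate_stats(ann[0, ], n_docs = 0L)$avg_per_doc, 0)
})

test_that("annotation JSON export is valid JSONL with one record per document", {
  lex <- demo_lexicon()
  docs <- tibble::tibble(
    doc_id = c("d1", "d2"),
    abstract = c("remdesivir and covid-19", "nothing here")
  )
  ann <- annotate_corpus(docs, lex)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_annotations_json(ann, f, doc_ids = docs$doc_id)
  lines <- readLines(f)
  expect_length(lines, 2L)
  rec <- jsonlite::fromJSON(lines[[1]], simplifyDataFrame = FALSE)
  expect_identical(rec$doc_id, "d1")
  expect_length(rec$annotations, 2L)
  expect_setequal(
    names(rec$annotations[[1]]),
    c("exact", "concept_id", "preferred_label", "axis", "field", "start", "end")
  )
  expect_length(jsonlite::fromJSON(lines[[2]])$annotations, 0L)
})
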