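test_that("indexing emits every token variant once with matching doc lengths", {
  idx <- build_index(tibble::tibble(doc_id = "d1", abstract = "covid-19 covid-19"))
  expect_identical(idx$N, 1L)
  expect_identical(idx$doc_len[["d1"]], 4L)
  post <- dplyr::arrange(idx$postings, term)
  expect_identical(post$term, c("covid", "covid19"))
  expect_identical(post$tf, c(2L, 2L))

  two <- build_index(tibble::tibble(
    doc_id = c("a", "b"),
    abstract = c("remdesivir trial", "placebo trial")
  ))
  expect_identical(unname(two$df["remdesivir"]), 1L)
  expect_identical(unname(two$df["trial"]), 2L)

  empty <- build_index(tibble::tibble(doc_id = character(), abstract = character()))
  expect_identical(empty$N, 0L)
  expect_error(
    build_index(tibble::tibble(doc_id = c("a", "a"), abstract = c("x y z", "x y z"))),
    "duplicate doc_id"
  )
})

test_that("single-document BM25 score matches the closed form", {
  idx <- build_index(tibble::tibble(doc_id = "d1", abstract = "covid covid trial"))
  q <- weighted_query("covid")
  k1 <- 1.2
  b <- 0.75
  # N = 1, df = 1, tf = 2, len = avglen = 3
  expected <- log((1 - 1 + 0.5) / (1 + 0.5) + 1) * 2 * (k1 + 1) /
    (2 + k1 * (1 - b + b * 1))
  expect_equal(bm25_score(q, "d1", idx), expected, tolerance = 1e-12)
  # no shared terms -> 0
  expect_identical(bm25_score(weighted_query("absent"), "d1", idx), 0)
  expect_error(bm25_score(q, "nope", idx), "unknown doc_id")
})

test_that("ranking matches the brute-force scorer on random small corpora", {
  set.seed(101)
  for (rep in 1:50) {
    corpus <- random_oracle_corpus()
    idx <- build_index(corpus)
    terms <- sample(paste0("word", sprintf("%02d", 1:12)), 3)
    w <- stats::runif(3, 0.2, 3)
    got <- search_index(weighted_query(tibble::tibble(term = terms, weight = w)), idx)
    want <- oracle_bm25_rank(corpus, terms, w)
    expect_identical(got$doc_id, want$doc_id)
    expect_equal(got$score, want$score, tolerance = 1e-9)
  }
})

test_that("BM25 is monotone in tf and IDF monotone-decreasing in df", {
  base <- tibble::tibble(
    doc_id = c("d1", "d2", "pad1", "pad2"),
    abstract = c(
      "covid trial trial trial", "covid covid trial trial",
      "filler words only here", "filler words only here too"
    )
  )
  idx <- build_index(base)
  q <- weighted_query("covid")
  expect_gt(bm25_score(q, "d2", idx), bm25_score(q, "d1", idx))
  n <- 20
  dfs <- 1:n
  idfs <- log((n - dfs + 0.5) / (dfs + 0.5) + 1)
  expect_true(all(diff(idfs) < 0))
  expect_true(all(idfs > 0))
})

test_that("query weighting favors rare terms via reference DF", {
  q <- weight_query_terms("the spreaders", c(the = 999, spreaders = 2), 1000)
  w <- stats::setNames(q$terms$weight, q$terms$term)
  expect_equal(unname(w["spreaders"]), log(1000 / 3), tolerance = 1e-12)
  expect_equal(unname(w["the"]), 0, tolerance = 1e-12) # ln(1000/1000)
  expect_gt(w["spreaders"], w["the"])

  # unseen terms get the maximal weight ln(ref_N / 1)
  q2 <- weight_query_terms("novelterm", c(the = 999), 1000)
  expect_equal(q2$terms$weight, log(1000), tolerance = 1e-12)

  # duplicates merge by summing
  q3 <- weight_query_terms("covid covid", numeric(), 100)
  expect_identical(nrow(q3$terms), 1L)
  expect_equal(q3$terms$weight, 2 * log(100), tolerance = 1e-12)

  expect_error(weight_query_terms("x", numeric(), 0), "ref_N")
  expect_error(weight_query_terms("??", numeric(), 10), "no terms")
})

test_that("query expansion appends matched concept ids and is idempotent", {
  lex <- demo_lexicon()
  q <- weighted_query("remdesivir treatment", raw_text = "remdesivir treatment")
  q1 <- expand_query(q, lex)
  expect_identical(q1$concept_ids, "CHEBI:145994")
  expect_identical(q1$terms, q$terms)
  expect_identical(expand_query(q1, lex), q1)
  # nothing to match -> unchanged
  q2 <- weighted_query("unrelated words", raw_text = "unrelated words")
  expect_identical(expand_query(q2, lex)$concept_ids, character(0))
})

test_that("concept postings score expanded queries and never hurt annotated docs", {
  lex <- demo_lexicon()
  docs <- tibble::tibble(
    doc_id = c("d1", "d2", "d3"),
    abstract = c(
      "COVID19 pneumonia outcomes", "influenza pneumonia outcomes",
      "covid-19 vaccination drive"
    )
  )
  ann <- annotate_corpus(docs, lex)
  idx <- build_index(docs, annotations = ann)
  q <- weighted_query("pneumonia", raw_text = "covid-19 pneumonia")
  before <- search_index(q, idx)
  q_exp <- expand_query(q, lex)
  after <- search_index(q_exp, idx)
  expect_true("DEMO:0000001" %in% q_exp$concept_ids)
  # annotated doc d1 gains, unannotated d2 does not
  score <- function(res, d) c(res$score[res$doc_id == d], 0)[1]
  expect_gt(score(after, "d1"), score(before, "d1"))
  expect_equal(score(after, "d2"), score(before, "d2"), tolerance = 1e-12)
  # expansion retrieves the dashed-spelling doc the keyword query missed
  expect_false("d3" %in% before$doc_id)
  expect_true("d3" %in% after$doc_id)
})

test_that("search truncates at k, keeps positive scores, breaks ties by doc_id", {
  docs <- tibble::tibble(
    doc_id = c("b", "a", "c"),
    abstract = c("covid study", "covid study", "other topic")
  )
  idx <- build_index(docs)
  res <- search_index(weighted_query("covid"), idx, k = 1000)
  expect_identical(res$doc_id, c("a", "b")) # equal scores -> ascending doc_id
  expect_identical(res$rank, 1:2)
  expect_identical(nrow(search_index(weighted_query("covid"), idx, k = 1)), 1L)
  expect_identical(nrow(search_index(weighted_query("absent"), idx)), 0L)
})

test_that("weighted_query rejects invalid inputs", {
  expect_error(weighted_query(tibble::tibble(term = "x", weight = -1)), "non-negative")
  expect_error(weighted_query(tibble::tibble(term = "x", weight = Inf)), "finite")
  expect_error(weighted_query(character(), character()), "neither")
})

test_that("reference DF table round-trips through its TSV dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ref_df(c(alpha = 5L, beta = 2L), 100L, f)
  back <- read_ref_df(f)
  expect_identical(back$ref_N, 100L)
  expect_identical(back$ref_df, c(alpha = 5L, beta = 2L))
  writeLines("no header", f)
  expect_error(read_ref_df(f), "#N=")
})
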