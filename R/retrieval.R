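#' Inverted index with Okapi BM25 scoring
#'
#' A self-contained in-memory search engine over fielded documents. Document
#' fields are concatenated and tokenized with the same normalization used for
#' annotation; every variant of every token is emitted once into the index,
#' so `"covid-19"` contributes postings for both `covid` and `covid19` and
#' document length counts variant emissions. Concept identifiers attached by
#' the annotator are indexed alongside text tokens in a separate namespace
#' (terms prefixed `CID:`), so a query can carry both keywords and expanded
#' concept ids and both are scored with the same BM25 machinery.
#'
#' Scoring is Okapi BM25 with the non-negative IDF used by Lucene-family
#' engines: `idf(t) = ln((N - df + 0.5)/(df + 0.5) + 1)` and per-term
#' contribution `w_t * idf(t) * tf (k1+1) / (tf + k1 (1 - b + b len/avglen))`.
#' Defaults `k1 = 1.2`, `b = 0.75`.
#'
#' @name retrieval
NULL

CID_PREFIX <- "CID:"

.doc_variant_stream <- function(row) {
  texts <- unlist(row[intersect(.DOC_FIELDS, names(row))], use.names = FALSE)
  texts <- texts[!is.na(texts) & nzchar(texts)]
  if (!length(texts)) {
    return(character())
  }
  unlist(lapply(texts, function(t) unlist(tokenize(t)$variants)), use.names = FALSE)
}

#' Build an inverted index over a corpus
#'
#' @param corpus Document tibble (`doc_id` plus text fields).
#' @param annotations Optional annotation tibble (from [annotate_corpus()]);
#'   when supplied, each document's distinct concept occurrences are indexed
#'   under `CID:`-prefixed terms with tf = occurrence count.
#' @return A `triage_index` object: `postings` tibble (`term`, `doc_id`,
#'   `tf`), `df` named integer vector, `doc_len` and `N`, `avg_len`, plus a
#'   split postings list for fast per-term lookup.
#' @export
build_index <- function(corpus, annotations = NULL) {
  stopifnot(is.data.frame(corpus))
  dup <- corpus$doc_id[duplicated(corpus$doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  n <- nrow(corpus)
  cols <- as.list(corpus[intersect(.DOC_FIELDS, names(corpus))])
  streams <- purrr::map(seq_len(n), function(i) {
    .doc_variant_stream(lapply(cols, `[[`, i))
  })
  doc_len <- stats::setNames(lengths(streams), corpus$doc_id)
  postings <- purrr::map2(streams, corpus$doc_id, function(s, d) {
    if (!length(s)) {
      return(NULL)
    }
    tab <- table(s)
    tibble::tibble(term = names(tab), doc_id = d, tf = as.integer(tab))
  }) |> dplyr::bind_rows()
  if (!is.null(annotations) && nrow(annotations)) {
    unknown <- setdiff(annotations$doc_id, corpus$doc_id)
    if (length(unknown)) {
      stop("annotations reference unindexed doc_id(s): ",
        paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    cpost <- annotations |>
      dplyr::count(.data$concept_id, .data$doc_id, name = "tf") |>
      dplyr::transmute(
        term = paste0(CID_PREFIX, .data$concept_id),
        doc_id = .data$doc_id, tf = as.integer(.data$tf)
      )
    postings <- dplyr::bind_rows(postings, cpost)
  }
  if (!nrow(postings)) {
    postings <- tibble::tibble(term = character(), doc_id = character(), tf = integer())
  }
  df <- table(postings$term)
  structure(
    list(
      postings = postings,
      by_term = split(postings[c("doc_id", "tf")], postings$term),
      df = stats::setNames(as.integer(df), names(df)),
      doc_len = doc_len,
      N = n,
      avg_len = if (n > 0) mean(doc_len) else 0
    ),
    class = "triage_index"
  )
}

#' @export
print.triage_index <- function(x, ...) {
  n_cid <- sum(startsWith(names(x$df), CID_PREFIX))
  cat(
    "<triage_index> ", x$N, " docs, ", length(x$df) - n_cid, " terms, ",
    n_cid, " concept terms, avg doc length ", round(x$avg_len, 1), "\n",
    sep = ""
  )
  invisible(x)
}

.bm25_idf <- function(df, N) {
  log((N - df + 0.5) / (df + 0.5) + 1)
}

#' Construct a weighted query
#'
#' @param terms Tibble with columns `term`, `weight`, or a character vector
#'   (unit weights). Weights must be finite and non-negative.
#' @param concept_ids Character vector of concept CURIEs (scored against the
#'   concept namespace of the index).
#' @param focus Optional axis code the query is about.
#' @param raw_text The original query string.
#' @return A `weighted_query` object.
#' @export
weighted_query <- function(terms, concept_ids = character(), focus = NULL,
                           raw_text = "") {
  if (is.character(terms)) {
    terms <- tibble::tibble(term = terms, weight = rep(1, length(terms)))
  }
  terms <- tibble::as_tibble(terms)
  stopifnot(all(c("term", "weight") %in% names(terms)))
  if (any(!is.finite(terms$weight)) || any(terms$weight < 0)) {
    stop("query term weights must be finite and non-negative", call. = FALSE)
  }
  if (!nrow(terms) && !length(concept_ids)) {
    stop("query has neither terms nor concept ids", call. = FALSE)
  }
  if (!is.null(focus)) focus <- normalize_axis(focus)
  structure(
    list(
      terms = terms, concept_ids = unique(concept_ids),
      focus = focus, raw_text = raw_text
    ),
    class = "weighted_query"
  )
}

#' @export
print.weighted_query <- function(x, ...) {
  cat("<weighted_query> \"", x$raw_text, "\"\n", sep = "")
  cat(
    "  terms:", paste(sprintf("%s(%.3g)", x$terms$term, x$terms$weight), collapse = " "),
    "\n"
  )
  if (length(x$concept_ids)) cat("  concepts:", paste(x$concept_ids, collapse = " "), "\n")
  if (!is.null(x$focus)) cat("  focus:", x$focus, "\n")
  invisible(x)
}

#' Weight query terms by reference document frequencies
#'
#' Tokenizes and normalizes the raw query and weights each resulting term by
#' a smoothed inverse document frequency against a *reference* collection:
#' `w(t) = max(0, ln(ref_N / (ref_df[t] + 1)))`. Using DF from a large
#' general collection rather than the target corpus favors rare, informative
#' words. Terms absent from the table get df 0 (maximal weight); duplicate
#' terms are merged by summing weights.
#'
#' @param raw Query string.
#' @param ref_df Named numeric vector, term -> document frequency (may be
#'   empty).
#' @param ref_N Size of the reference collection (> 0, >= max(ref_df)).
#' @param focus Optional axis code carried on the query.
#' @return A [weighted_query()].
#' @export
weight_query_terms <- function(raw, ref_df = numeric(), ref_N, focus = NULL) {
  if (length(ref_N) != 1L || is.na(ref_N) || ref_N <= 0) {
    stop("ref_N must be a positive number", call. = FALSE)
  }
  if (length(ref_df) && max(ref_df) > ref_N) {
    stop("ref_df values exceed ref_N", call. = FALSE)
  }
  toks <- unlist(normalize_tokens(raw), use.names = FALSE)
  if (!length(toks)) {
    stop("query normalizes to no terms: ", deparse(raw), call. = FALSE)
  }
  df <- ifelse(toks %in% names(ref_df), ref_df[toks], 0)
  w <- pmax(0, log(ref_N / (df + 1)))
  terms <- tibble::tibble(term = toks, weight = as.numeric(w)) |>
    dplyr::summarise(weight = sum(.data$weight), .by = "term")
  weighted_query(terms, focus = focus, raw_text = raw)
}

#' Expand a query with concept ids found in its text
#'
#' Annotates the query's raw text with the lexicon and appends the distinct
#' matched concept ids to the query; keyword terms and weights are left
#' untouched. Idempotent.
#'
#' @param q A [weighted_query()].
#' @param lex A [lexicon()].
#' @return The expanded `weighted_query`.
#' @export
expand_query <- function(q, lex) {
  stopifnot(inherits(q, "weighted_query"), inherits(lex, "lexicon"))
  ann <- annotate_document(list(doc_id = "query", abstract = q$raw_text), lex)
  q$concept_ids <- union(q$concept_ids, unique(ann$concept_id))
  q
}

.query_all_terms <- function(q) {
  terms <- q$terms
  if (length(q$concept_ids)) {
    terms <- dplyr::bind_rows(
      terms,
      tibble::tibble(term = paste0(CID_PREFIX, q$concept_ids), weight = 1)
    )
  }
  terms
}

#' BM25 score of one document for a query
#'
#' Keyword terms are scored against token postings and concept ids against
#' concept postings, all summed; terms absent from the document contribute 0.
#'
#' @param q A [weighted_query()].
#' @param doc_id Document identifier (must be indexed).
#' @param index A [build_index()] result.
#' @param k1,b BM25 constants (`k1 > 0`, `0 <= b <= 1`).
#' @return Numeric score (>= 0 for non-negative weights).
#' @export
bm25_score <- function(q, doc_id, index, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(index, "triage_index"), k1 > 0, b >= 0, b <= 1)
  if (!doc_id %in% names(index$doc_len)) {
    stop("unknown doc_id: ", doc_id, call. = FALSE)
  }
  terms <- .query_all_terms(q)
  len <- index$doc_len[[doc_id]]
  norm <- k1 * (1 - b + b * len / index$avg_len)
  s <- 0
  for (i in seq_len(nrow(terms))) {
    t <- terms$term[[i]]
    p <- index$by_term[[t]]
    if (is.null(p)) next
    tf <- p$tf[match(doc_id, p$doc_id)]
    if (is.na(tf)) next
    idf <- .bm25_idf(index$df[[t]], index$N)
    s <- s + terms$weight[[i]] * idf * tf * (k1 + 1) / (tf + norm)
  }
  s
}

#' Retrieve the top-k documents for a query
#'
#' Scores every document holding at least one query term or concept and
#' returns those with positive score, sorted by score descending with ties
#' broken by ascending `doc_id`, truncated at `k`.
#'
#' @param q A [weighted_query()].
#' @param index A [build_index()] result.
#' @param k Maximum number of results (default 1000, the usual TREC run
#'   depth).
#' @param k1,b BM25 constants.
#' @return Tibble `doc_id`, `score`, `rank` (1-based), at most `k` rows.
#' @export
search_index <- function(q, index, k = 1000L, k1 = 1.2, b = 0.75) {
  stopifnot(inherits(q, "weighted_query"), inherits(index, "triage_index"), k >= 1)
  terms <- .query_all_terms(q)
  terms <- terms[terms$term %in% names(index$df), , drop = FALSE]
  empty <- tibble::tibble(doc_id = character(), score = numeric(), rank = integer())
  if (!nrow(terms) || index$N == 0L) {
    return(empty)
  }
  contrib <- purrr::map2(terms$term, terms$weight, function(t, w) {
    p <- index$by_term[[t]]
    idf <- .bm25_idf(index$df[[t]], index$N)
    len <- index$doc_len[p$doc_id]
    tibble::tibble(
      doc_id = p$doc_id,
      part = w * idf * p$tf * (k1 + 1) /
        (p$tf + k1 * (1 - b + b * len / index$avg_len))
    )
  }) |> dplyr::bind_rows()
  scores <- contrib |>
    dplyr::summarise(score = sum(.data$part), .by = "doc_id") |>
    dplyr::filter(.data$score > 0) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$doc_id) |>
    dplyr::slice_head(n = k)
  scores$rank <- seq_len(nrow(scores))
  scores
}
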