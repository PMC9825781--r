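#' Dictionary annotation of fielded documents
#'
#' Documents are tibbles with one row per document and columns `doc_id`,
#' `collection`, and any subset of the text fields `title`, `abstract`,
#' `body`, `keywords`. Annotation slides the compiled lexicon phrases over
#' the normalized token-variant stream of each field: at every token
#' position, every phrase key realizable from the consecutive per-token
#' variant sets is looked up, so a document spelling (`"COVID19"`) matches a
#' lexicon spelling (`"covid-19"`) and vice versa. Matches of different
#' concepts may overlap; for one concept, matches sharing a start are
#' resolved to the longest key, and repeated matches of the same concept at
#' the same span via different variants are deduplicated.
#'
#' @name annotate
NULL

.DOC_FIELDS <- c("title", "abstract", "body", "keywords")

.match_field <- function(text, field, lex) {
  toks <- tokenize(text, field)
  n <- nrow(toks)
  if (n == 0L || length(lex$phrase_table) == 0L) {
    return(NULL)
  }
  pt <- lex$phrase_table
  keyset <- names(pt)
  maxlen <- lex$max_phrase_len
  variants <- toks$variants
  h_cid <- character()
  h_start <- integer()
  h_end <- integer()
  for (i in seq_len(n)) {
    if (length(variants[[i]]) == 0L) next
    keys <- variants[[i]]
    for (l in seq_len(min(maxlen, n - i + 1L))) {
      if (l > 1L) {
        vs <- variants[[i + l - 1L]]
        if (length(vs) == 0L) break # a dead token cannot sit inside a phrase
        keys <- as.vector(outer(keys, vs, paste))
      }
      for (key in unique(keys[keys %in% keyset])) {
        cids <- pt[[key]]
        h_cid <- c(h_cid, cids)
        h_start <- c(h_start, rep.int(toks$start[[i]], length(cids)))
        h_end <- c(h_end, rep.int(toks$end[[i + l - 1L]], length(cids)))
      }
    }
  }
  if (!length(h_cid)) {
    return(NULL)
  }
  # greedy longest match per concept at a shared start, then dedup spans
  # (one annotation even when several variants of a token hit the concept)
  ord <- order(h_cid, h_start, -h_end)
  keep <- !duplicated(paste(h_cid, h_start)[ord])
  idx <- ord[keep]
  tibble::tibble(
    concept_id = h_cid[idx], field = field,
    start = h_start[idx], end = h_end[idx],
    matched_term = substring(text, h_start[idx] + 1L, h_end[idx])
  )
}

#' Annotate one document against a lexicon
#'
#' @param doc A one-row document tibble (or a named list) with `doc_id` and
#'   any of the fields `title`, `abstract`, `body`, `keywords`.
#' @param lex A [lexicon()].
#' @param axes Optional character vector restricting output to these axes
#'   (codes or full names).
#' @return Tibble of annotations sorted by (field, start, concept_id) with
#'   columns `doc_id`, `concept_id`, `matched_term`, `preferred_label`,
#'   `axis`, `field`, `start`, `end`. Offsets are 0-based half-open into the
#'   original field text.
#' @examples
#' lex <- lexicon(tibble::tibble(
#'   id = c("DEMO:0000001", "CHEBI:145994"),
#'   axis = c("DIS", "CHEM"),
#'   preferred_label = c("covid-19", "remdesivir"),
#'   synonyms = list("coronavirus disease 2019", character()),
#'   xrefs = list(character(), character())
#' ))
#' doc <- tibble::tibble(doc_id = "d1", abstract = "Remdesivir blocks covid-19.")
#' annotate_document(doc, lex)
#' @export
annotate_document <- function(doc, lex, axes = NULL) {
  stopifnot(inherits(lex, "lexicon"))
  if (is.data.frame(doc)) {
    stopifnot(nrow(doc) == 1L)
    doc <- as.list(doc)
    doc <- lapply(doc, function(x) if (is.list(x)) x[[1L]] else x)
  }
  if (!is.null(axes)) axes <- normalize_axis(axes)
  empty <- tibble::tibble(
    doc_id = character(), concept_id = character(), matched_term = character(),
    preferred_label = character(), axis = character(), field = character(),
    start = integer(), end = integer()
  )
  present <- intersect(.DOC_FIELDS, names(doc))
  hits <- purrr::map(present, function(f) {
    txt <- doc[[f]]
    if (is.null(txt) || is.na(txt) || !nzchar(txt)) {
      return(NULL)
    }
    .match_field(txt, f, lex)
  })
  hits <- dplyr::bind_rows(hits)
  if (!nrow(hits)) {
    return(empty)
  }
  info <- concept_info(lex, hits$concept_id)
  hits$preferred_label <- info$preferred_label
  hits$axis <- info$axis
  hits$doc_id <- doc$doc_id
  if (!is.null(axes)) hits <- hits[hits$axis %in% axes, , drop = FALSE]
  ord <- order(match(hits$field, .DOC_FIELDS), hits$start, hits$concept_id)
  hits[ord, c(
    "doc_id", "concept_id", "matched_term", "preferred_label",
    "axis", "field", "start", "end"
  )]
}

#' Annotate a whole corpus
#'
#' Applies [annotate_document()] independently to every document; annotation
#' is a once-only pass whose output feeds both indexing and triage.
#'
#' @param corpus Document tibble (one row per document).
#' @param lex A [lexicon()].
#' @param axes Optional axis restriction, as in [annotate_document()].
#' @return Tibble of annotations across all documents (possibly zero rows),
#'   same columns as [annotate_document()].
#' @export
annotate_corpus <- function(corpus, lex, axes = NULL) {
  stopifnot(is.data.frame(corpus))
  if (!nrow(corpus)) {
    return(annotate_document(list(doc_id = "x"), lex))
  }
  dup <- corpus$doc_id[duplicated(corpus$doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  cols <- as.list(corpus[intersect(c("doc_id", .DOC_FIELDS), names(corpus))])
  purrr::map(seq_len(nrow(corpus)), function(i) {
    annotate_document(lapply(cols, `[[`, i), lex, axes)
  }) |> dplyr::bind_rows()
}

#' Aggregate collection-level annotation statistics
#'
#' Counts annotations per axis, their total, and the truncated (floor)
#' average per document — documents with zero annotations still count in the
#' denominator. Accepts either an annotation tibble or pre-counted per-axis
#' totals (a named numeric vector), so published per-axis tallies can be
#' aggregated directly.
#'
#' @param annotations Annotation tibble from [annotate_corpus()], or a named
#'   numeric vector of per-axis counts (names are axis codes).
#' @param n_docs Number of documents in the collection (>= number annotated).
#' @param collection Collection tag.
#' @return One-row tibble: `collection`, one count column per axis (all nine,
#'   zero-filled), `total`, `n_docs`, `avg_per_doc` (= `floor(total/n_docs)`,
#'   0 when `n_docs` is 0).
#' @export
aggregate_stats <- function(annotations, n_docs, collection = "corpus") {
  if (length(n_docs) != 1L || is.na(n_docs) || n_docs < 0) {
    stop("n_docs must be a single non-negative number", call. = FALSE)
  }
  if (is.data.frame(annotations)) {
    n_annotated <- dplyr::n_distinct(annotations$doc_id)
    if (n_docs < n_annotated) {
      stop("n_docs (", n_docs, ") < number of annotated documents (",
        n_annotated, ")",
        call. = FALSE
      )
    }
    counts <- table(factor(normalize_axis(annotations$axis), levels = AXES))
    per_axis <- stats::setNames(as.numeric(counts), AXES)
  } else {
    stopifnot(is.numeric(annotations), !is.null(names(annotations)))
    per_axis <- stats::setNames(numeric(length(AXES)), AXES)
    per_axis[normalize_axis(names(annotations))] <- as.numeric(annotations)
  }
  total <- sum(per_axis)
  out <- tibble::as_tibble(as.list(per_axis))
  dplyr::bind_cols(
    tibble::tibble(collection = collection),
    out,
    tibble::tibble(
      total = total,
      n_docs = as.numeric(n_docs),
      avg_per_doc = if (n_docs > 0) floor(total / n_docs) else 0
    )
  )
}

#' Export annotations as per-document JSON
#'
#' Writes one JSON object per document in an exchange shape suited to
#' annotation-overlay viewers: `{doc_id, annotations: [{exact, concept_id,
#' preferred_label, axis, field, start, end}]}`, one line per document
#' (JSONL).
#'
#' @param annotations Annotation tibble.
#' @param path Output path.
#' @param doc_ids Optional document ids to include even when unannotated.
#' @return `path`, invisibly.
#' @export
write_annotations_json <- function(annotations, path, doc_ids = NULL) {
  ids <- unique(c(doc_ids, annotations$doc_id))
  lines <- purrr::map_chr(ids, function(d) {
    rows <- annotations[annotations$doc_id == d, ]
    anns <- purrr::pmap(rows, function(doc_id, concept_id, matched_term,
                                       preferred_label, axis, field, start, end) {
      list(
        exact = matched_term, concept_id = concept_id,
        preferred_label = preferred_label, axis = axis, field = field,
        start = start, end = end
      )
    })
    jsonlite::toJSON(list(doc_id = d, annotations = anns), auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
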