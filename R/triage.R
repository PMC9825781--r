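#' Focus-axis triage re-ranking
#'
#' Re-orders a retrieved list by a learning-free linear combination of three
#' per-document features: the base retrieval score, the *specificity* of the
#' document for the query's focus axis (number of distinct concepts of that
#' axis annotated in it), and the concept TF-IDF *density* (how saturated the
#' document is with ontology concepts relative to its length). Because raw
#' BM25 scores, concept counts and densities live on incommensurable scales,
#' each feature is min-max scaled to [0, 1] within the result list before
#' combination (a constant feature scales to 0 for all documents).
#'
#' @name triage
NULL

#' Triage re-ranking parameters
#'
#' @param w_base,w_spec,w_dens Non-negative feature weights (at least one
#'   positive). Defaults 1.0 / 0.5 / 0.5 keep the base ranking dominant while
#'   letting focus evidence reorder near-ties.
#' @param focus Axis code the triage is focused on.
#' @param normalize Min-max scale each feature within the result list
#'   (default `TRUE`).
#' @return A `triage_params` object.
#' @export
triage_params <- function(w_base = 1.0, w_spec = 0.5, w_dens = 0.5,
                          focus = "DIS", normalize = TRUE) {
  if (any(c(w_base, w_spec, w_dens) < 0) || !any(c(w_base, w_spec, w_dens) > 0)) {
    stop("weights must be non-negative with at least one positive", call. = FALSE)
  }
  structure(
    list(
      w_base = w_base, w_spec = w_spec, w_dens = w_dens,
      focus = normalize_axis(focus), normalize = isTRUE(normalize)
    ),
    class = "triage_params"
  )
}

#' Focus-axis specificity of a document
#'
#' Number of DISTINCT concept ids among a document's annotations whose axis
#' equals the focus; repeated mentions of one concept count once.
#'
#' @param annots Annotation tibble for one document (zero rows allowed).
#' @param focus Axis code or full name.
#' @return Integer count.
#' @export
specificity <- function(annots, focus) {
  focus <- normalize_axis(focus)
  if (is.null(annots) || !nrow(annots)) {
    return(0L)
  }
  dplyr::n_distinct(annots$concept_id[annots$axis == focus])
}

#' Concept TF-IDF density of a document
#'
#' Sum over the document's distinct annotated concepts of
#' `tf(c, doc) * max(0, ln(N / (df_c + 1)))` — tf being the concept's
#' occurrence count and df the number of indexed documents carrying it —
#' divided by the document's token length. Zero for unannotated documents;
#' the clipped IDF makes the single-document corpus degenerate to 0 rather
#' than negative.
#'
#' @param annots Annotation tibble for this document.
#' @param doc_id Document id (must be indexed with concept postings).
#' @param index A [build_index()] result built with annotations.
#' @return Numeric density >= 0.
#' @export
concept_density <- function(annots, doc_id, index) {
  stopifnot(inherits(index, "triage_index"))
  if (!doc_id %in% names(index$doc_len)) {
    stop("unknown doc_id: ", doc_id, call. = FALSE)
  }
  if (is.null(annots) || !nrow(annots)) {
    return(0)
  }
  len <- index$doc_len[[doc_id]]
  if (len == 0) {
    return(0)
  }
  cids <- unique(annots$concept_id)
  s <- 0
  for (cid in cids) {
    term <- paste0(CID_PREFIX, cid)
    p <- index$by_term[[term]]
    if (is.null(p)) next
    tf <- p$tf[match(doc_id, p$doc_id)]
    if (is.na(tf)) next
    s <- s + tf * max(0, log(index$N / (index$df[[term]] + 1)))
  }
  s / len
}

.minmax <- function(x) {
  r <- range(x)
  if (!is.finite(r[1]) || r[1] == r[2]) {
    return(rep(0, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Re-rank a retrieved list by the triage linear combination
#'
#' Computes the three features for every retrieved document and sorts by
#' `w_base * base + w_spec * specificity + w_dens * density` (features
#' min-max scaled when `params$normalize`). Ties keep the original order,
#' then ascending `doc_id`; the output is always a permutation of the input
#' documents. With `w_spec = w_dens = 0` and normalization off, the baseline
#' order is reproduced exactly.
#'
#' @param results Tibble `doc_id`, `score` (base ranking, best first), e.g.
#'   from [search_index()].
#' @param annotations Annotation tibble covering the corpus (only rows for
#'   retrieved documents are used).
#' @param index A [build_index()] result with concept postings.
#' @param params A [triage_params()].
#' @return A `triage_ranking` tibble: `doc_id`, `base_score`, `specificity`,
#'   `density`, `final_score`, `rank` (1..n, `final_score` non-increasing).
#' @export
rerank <- function(results, annotations, index, params) {
  stopifnot(inherits(params, "triage_params"), inherits(index, "triage_index"))
  if (!is.data.frame(results) || !nrow(results)) {
    stop("results must be a non-empty data frame", call. = FALSE)
  }
  stopifnot(all(c("doc_id", "score") %in% names(results)))
  by_doc <- if (!is.null(annotations) && nrow(annotations)) {
    split(annotations, annotations$doc_id)
  } else {
    list()
  }
  feats <- tibble::tibble(
    doc_id = results$doc_id,
    base_score = results$score,
    specificity = purrr::map_int(
      results$doc_id,
      function(d) specificity(by_doc[[d]], params$focus)
    ),
    density = purrr::map_dbl(
      results$doc_id,
      function(d) concept_density(by_doc[[d]], d, index)
    ),
    .orig = seq_len(nrow(results))
  )
  f1 <- feats$base_score
  f2 <- as.numeric(feats$specificity)
  f3 <- feats$density
  if (params$normalize) {
    f1 <- .minmax(f1)
    f2 <- .minmax(f2)
    f3 <- .minmax(f3)
  }
  feats$final_score <- params$w_base * f1 + params$w_spec * f2 + params$w_dens * f3
  out <- feats |>
    dplyr::arrange(dplyr::desc(.data$final_score), .data$.orig, .data$doc_id) |>
    dplyr::select(-".orig")
  out$rank <- seq_len(nrow(out))
  class(out) <- c("triage_ranking", class(out))
  out
}

#' One-call triage search
#'
#' The full pipeline for a single topic: DF-weighted query construction,
#' optional concept-id query expansion, BM25 retrieval, and optional triage
#' re-ranking.
#'
#' @param raw Query string.
#' @param index A [build_index()] result.
#' @param lex A [lexicon()] (needed when `expand = TRUE` or for re-ranking).
#' @param annotations Annotation tibble for the corpus (needed for
#'   re-ranking).
#' @param params A [triage_params()], or `NULL` for the plain baseline.
#' @param ref_df,ref_N Reference DF table and collection size for query
#'   weighting; when `ref_df` is `NULL`, all terms get unit weight.
#' @param expand Add concept-id query expansion.
#' @param k Retrieval depth.
#' @return A ranking tibble (`doc_id`, `score`/`final_score`, `rank`).
#' @export
triage_search <- function(raw, index, lex = NULL, annotations = NULL,
                          params = NULL, ref_df = NULL, ref_N = NULL,
                          expand = FALSE, k = 1000L) {
  q <- if (is.null(ref_df)) {
    toks <- unlist(normalize_tokens(raw), use.names = FALSE)
    if (!length(toks)) stop("query normalizes to no terms", call. = FALSE)
    weighted_query(unique(toks), raw_text = raw)
  } else {
    weight_query_terms(raw, ref_df, ref_N)
  }
  if (expand) {
    stopifnot(!is.null(lex))
    q <- expand_query(q, lex)
  }
  base <- search_index(q, index, k = k)
  if (is.null(params) || !nrow(base)) {
    return(base)
  }
  rerank(base, annotations, index, params)
}
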