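#' Broom-style tidiers
#'
#' `tidy()` returns the per-unit table of an object (per-topic metrics,
#' per-document ranking features, per-concept lexicon rows); `glance()`
#' returns a one-row summary.
#'
#' @param x An ontotriage object.
#' @param ... Unused.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy metrics_report
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @method glance metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(
    tag = attr(x, "tag"),
    n_topics = nrow(x),
    mean_p_at_k = mean(x$p_at_k),
    map = mean(x$ap),
    k = attr(x, "k"),
    cutoff = attr(x, "cutoff")
  )
}

#' @rdname tidiers
#' @method tidy triage_ranking
#' @export
tidy.triage_ranking <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname tidiers
#' @method glance triage_ranking
#' @export
glance.triage_ranking <- function(x, ...) {
  tibble::tibble(
    n_docs = nrow(x),
    mean_specificity = mean(x$specificity),
    mean_density = mean(x$density),
    top_doc = x$doc_id[[1L]]
  )
}

#' @rdname tidiers
#' @method tidy lexicon
#' @export
tidy.lexicon <- function(x, ...) {
  x$concepts
}

#' @rdname tidiers
#' @method glance lexicon
#' @export
glance.lexicon <- function(x, ...) {
  tibble::tibble(
    n_concepts = nrow(x$concepts),
    n_phrases = length(x$phrase_table),
    max_phrase_tokens = x$max_phrase_len,
    n_axes = dplyr::n_distinct(x$concepts$axis)
  )
}

#' @rdname tidiers
#' @method tidy triage_index
#' @export
tidy.triage_index <- function(x, ...) {
  x$postings
}

#' @rdname tidiers
#' @method glance triage_index
#' @export
glance.triage_index <- function(x, ...) {
  tibble::tibble(
    n_docs = x$N,
    n_terms = sum(!startsWith(names(x$df), CID_PREFIX)),
    n_concept_terms = sum(startsWith(names(x$df), CID_PREFIX)),
    avg_doc_len = x$avg_len
  )
}
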