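#' TREC-style retrieval evaluation
#'
#' Standard ad hoc evaluation over runs and relevance judgements, following
#' trec_eval conventions throughout: relevance is binary at grade > 0, the
#' average-precision denominator is the total number of relevant documents
#' judged for the topic, unjudged documents count as non-relevant, topics
#' with judgements but missing from the run contribute 0 and stay in the
#' means. File dialects: qrels `topic 0 doc_id grade`; runs
#' `topic Q0 doc_id rank score tag` with ranks 1..n per topic (gaps are a
#' validation error).
#'
#' @name evaluation
NULL

#' @rdname trec_io
#' @export
read_qrels <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (length(f) != 4L) {
      stop("qrels line ", i, ": expected 4 fields, got ", length(f), call. = FALSE)
    }
    grade <- suppressWarnings(as.integer(f[4L]))
    if (is.na(grade) || grade < 0) {
      stop("qrels line ", i, ": bad relevance grade: ", f[4L], call. = FALSE)
    }
    tibble::tibble(topic_id = f[1L], doc_id = f[3L], grade = grade)
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(topic_id = character(), doc_id = character(), grade = integer()))
  }
  dup <- duplicated(out[c("topic_id", "doc_id")])
  if (any(dup)) {
    stop("duplicate (topic, doc) pair(s) in qrels", call. = FALSE)
  }
  out
}

#' TREC run and qrels files
#'
#' @param path File path.
#' @param run Run tibble (`topic_id`, `doc_id`, `rank`, `score`, `tag`).
#' @return Tibbles mirroring the file contents; [write_run()] returns `path`
#'   invisibly. `read_run`/`write_run` round-trip is the identity.
#' @name trec_io
#' @export
read_run <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::imap(lines, function(line, i) {
    f <- strsplit(trimws(line), "[ \t]+")[[1L]]
    if (length(f) != 6L) {
      stop("run line ", i, ": expected 6 fields, got ", length(f), call. = FALSE)
    }
    rank <- suppressWarnings(as.integer(f[4L]))
    score <- suppressWarnings(as.numeric(f[5L]))
    if (is.na(rank) || is.na(score)) {
      stop("run line ", i, ": bad rank/score: ", line, call. = FALSE)
    }
    tibble::tibble(
      topic_id = f[1L], doc_id = f[3L], rank = rank, score = score, tag = f[6L]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    return(tibble::tibble(
      topic_id = character(), doc_id = character(), rank = integer(),
      score = numeric(), tag = character()
    ))
  }
  dup <- duplicated(out[c("topic_id", "doc_id")])
  if (any(dup)) {
    stop("duplicate (topic, doc) pair(s) in run", call. = FALSE)
  }
  out <- dplyr::arrange(out, .data$topic_id, .data$rank)
  bad <- out |>
    dplyr::summarise(
      ok = identical(.data$rank, seq_along(.data$rank)),
      .by = "topic_id"
    ) |>
    dplyr::filter(!.data$ok)
  if (nrow(bad)) {
    stop(
      "run ranks are not consecutive 1..n for topic(s): ",
      paste(bad$topic_id, collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' @rdname trec_io
#' @export
write_run <- function(run, path) {
  stopifnot(all(c("topic_id", "doc_id", "rank", "score", "tag") %in% names(run)))
  run <- dplyr::arrange(run, .data$topic_id, .data$rank)
  lines <- sprintf(
    "%s Q0 %s %d %.6g %s",
    run$topic_id, run$doc_id, run$rank, run$score, run$tag
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Convert a per-topic ranking to run rows
#'
#' @param ranking Tibble with `doc_id`, `rank` and a score column
#'   (`final_score` or `score`).
#' @param topic_id Topic identifier.
#' @param tag Run tag.
#' @return Run tibble rows for this topic.
#' @export
as_run <- function(ranking, topic_id, tag = "ontotriage") {
  score_col <- if ("final_score" %in% names(ranking)) "final_score" else "score"
  tibble::tibble(
    topic_id = topic_id, doc_id = ranking$doc_id, rank = ranking$rank,
    score = ranking[[score_col]], tag = tag
  )
}

.topic_ranked_docs <- function(run, topic) {
  rows <- run[run$topic_id == topic, , drop = FALSE]
  rows$doc_id[order(rows$rank)]
}

.relevant_set <- function(qrels, topic) {
  qrels$doc_id[qrels$topic_id == topic & qrels$grade > 0]
}

#' Precision at rank k for one topic
#'
#' Fraction of the first `k` retrieved documents that are relevant; when
#' fewer than `k` documents were retrieved the missing slots count as
#' non-relevant. A topic absent from the run scores 0 with a warning.
#'
#' @param run Run tibble.
#' @param qrels Qrels tibble.
#' @param topic Topic id.
#' @param k Rank cutoff (default 10).
#' @return Numeric in [0, 1].
#' @export
precision_at_k <- function(run, qrels, topic, k = 10L) {
  stopifnot(k >= 1)
  ranked <- .topic_ranked_docs(run, topic)
  if (!length(ranked)) {
    warning("topic ", topic, " absent from run; P@", k, " = 0", call. = FALSE)
    return(0)
  }
  rel <- .relevant_set(qrels, topic)
  sum(utils::head(ranked, k) %in% rel) / k
}

#' Average precision for one topic
#'
#' `AP = sum over relevant retrieved positions i <= cutoff of P@i, divided
#' by the total number of relevant documents in the qrels for the topic`
#' (trec_eval definition). Topics with no relevant documents score 0.
#'
#' @inheritParams precision_at_k
#' @param cutoff Rank cutoff (default 1000).
#' @return Numeric in [0, 1].
#' @export
average_precision <- function(run, qrels, topic, cutoff = 1000L) {
  stopifnot(cutoff >= 1)
  rel <- .relevant_set(qrels, topic)
  if (!length(rel)) {
    return(0)
  }
  ranked <- utils::head(.topic_ranked_docs(run, topic), cutoff)
  if (!length(ranked)) {
    return(0)
  }
  is_rel <- ranked %in% rel
  if (!any(is_rel)) {
    return(0)
  }
  prec_at_hits <- cumsum(is_rel)[is_rel] / which(is_rel)
  sum(prec_at_hits) / length(rel)
}

#' Evaluate a run against qrels
#'
#' Per-topic P@k and AP plus their means over all qrels topics (topics
#' missing from the run contribute 0).
#'
#' @param run Run tibble.
#' @param qrels Qrels tibble (non-empty).
#' @param k P@k cutoff (default 10).
#' @param cutoff AP rank cutoff (default 1000).
#' @param tag Run tag for the report.
#' @return A `metrics_report` tibble with one row per topic (`topic_id`,
#'   `p_at_k`, `ap`); means are available via [glance()].
#' @export
evaluate_run <- function(run, qrels, k = 10L, cutoff = 1000L, tag = "run") {
  if (!is.data.frame(qrels) || !nrow(qrels)) {
    stop("qrels is empty", call. = FALSE)
  }
  topics <- sort(unique(qrels$topic_id))
  in_run <- topics %in% run$topic_id
  out <- tibble::tibble(
    topic_id = topics,
    p_at_k = purrr::map2_dbl(topics, in_run, function(t, ok) {
      if (!ok) 0 else precision_at_k(run, qrels, t, k)
    }),
    ap = purrr::map_dbl(topics, function(t) average_precision(run, qrels, t, cutoff))
  )
  structure(out,
    class = c("metrics_report", class(out)),
    k = k, cutoff = cutoff, tag = tag
  )
}

#' Mean average precision of a run
#'
#' @inheritParams evaluate_run
#' @return MAP in [0, 1] — the mean AP over all qrels topics.
#' @export
mean_average_precision <- function(run, qrels, cutoff = 1000L) {
  mean(evaluate_run(run, qrels, cutoff = cutoff)$ap)
}

# round half away from zero, the convention used when typesetting signed
# percentage tables (base round() is round-half-even)
.round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evolutionary rate of a metric relative to a baseline
#'
#' Percentage change `100 * (run - baseline) / baseline`, rounded half away
#' from zero to two decimals, with an always-signed label (`"+19.17%"`,
#' `"-2.88%"`).
#'
#' @param baseline Baseline metric value (> 0).
#' @param run_value The comparison run's metric value.
#' @return One-row tibble: `baseline_value`, `run_value`, `rate_percent`,
#'   `label`.
#' @export
ev_rate <- function(baseline, run_value) {
  if (length(baseline) != 1L || is.na(baseline) || baseline <= 0) {
    stop("baseline must be a single positive value", call. = FALSE)
  }
  rate <- .round_half_up(100 * (run_value - baseline) / baseline, 2L)
  tibble::tibble(
    baseline_value = baseline,
    run_value = run_value,
    rate_percent = rate,
    label = sprintf("%+.2f%%", rate)
  )
}
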