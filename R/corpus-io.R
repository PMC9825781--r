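#' Corpus I/O (JSONL)
#'
#' Corpora are exchanged as JSON Lines: one document object per line with
#' keys `doc_id`, `collection`, and any of `title`, `abstract`, `body`,
#' `keywords` (strings). This emulates fielded bibliographic records
#' (MEDLINE/PMC-style title+abstract, preprint full text, author keywords)
#' without committing to any vendor XML.
#'
#' @param path File path.
#' @return [read_corpus()]: a document tibble with columns `doc_id`,
#'   `collection`, `title`, `abstract`, `body`, `keywords` (absent fields are
#'   `NA`).
#' @name corpus_io
NULL

#' @rdname corpus_io
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  rows <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(
      jsonlite::fromJSON(line, simplifyVector = TRUE),
      error = function(e) stop("line ", i, ": malformed JSON: ", conditionMessage(e), call. = FALSE)
    )
    if (is.null(rec$doc_id) || !nzchar(rec$doc_id)) {
      stop("line ", i, ": document lacks doc_id", call. = FALSE)
    }
    tibble::tibble(
      doc_id = rec$doc_id,
      collection = rec$collection %||% NA_character_,
      title = rec$title %||% NA_character_,
      abstract = rec$abstract %||% NA_character_,
      body = rec$body %||% NA_character_,
      keywords = rec$keywords %||% NA_character_
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!nrow(out)) {
    out <- tibble::tibble(
      doc_id = character(), collection = character(), title = character(),
      abstract = character(), body = character(), keywords = character()
    )
  }
  dup <- out$doc_id[duplicated(out$doc_id)]
  if (length(dup)) {
    stop("duplicate doc_id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out
}

#' @rdname corpus_io
#' @param corpus Document tibble.
#' @export
write_corpus <- function(corpus, path) {
  fields <- intersect(c("doc_id", "collection", .DOC_FIELDS), names(corpus))
  lines <- purrr::map_chr(seq_len(nrow(corpus)), function(i) {
    rec <- as.list(corpus[i, fields])
    rec <- rec[!vapply(rec, function(x) is.na(x) || !nzchar(x), logical(1))]
    jsonlite::toJSON(rec, auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
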