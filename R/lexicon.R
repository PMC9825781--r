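#' Axis-partitioned concept lexicons
#'
#' The controlled vocabulary is a flat table of concepts: a CURIE identifier,
#' a preferred label, optional synonyms, optional cross-references, and an
#' axis assigning the concept to one of nine thematic partitions:
#' BioMedical Vocabulary (BMV), Conceptual entities (CE), Cell lines (CL),
#' Clinical Trials (CT), Chemicals (CHEM), Diseases and Syndromes (DIS),
#' Geographic locations (GL), Organisms (ORG), Proteins and Genomes (PG).
#' Every surface form (the preferred label and each synonym) is matchable.
#'
#' A `lexicon` object holds the concept tibble plus a compiled phrase table:
#' a map from normalized token sequences (space-joined keys) to the concept
#' ids they evidence. The same normalization ([expand_token()]) is applied to
#' lexicon entries and to document text, so matching is robust to case,
#' typographic dashes and dash/slash spelling variation in either direction.
#'
#' @name lexicon
NULL

#' The nine axis codes
#' @export
AXES <- c("BMV", "CE", "CL", "CT", "CHEM", "DIS", "GL", "ORG", "PG")

.AXIS_FULL <- c(
  "biomedical vocabulary" = "BMV",
  "conceptual entities"   = "CE",
  "cell lines"            = "CL",
  "clinical trials"       = "CT",
  "chemicals"             = "CHEM",
  "diseases and syndromes" = "DIS",
  "geographic locations"  = "GL",
  "organisms"             = "ORG",
  "proteins and genomes"  = "PG"
)

#' Normalize an axis designation to its code
#'
#' Accepts the nine codes (any case) or the full axis names and returns the
#' canonical code; anything else is an error.
#'
#' @param axis Character vector of axis codes or full names.
#' @return Character vector of canonical codes.
#' @export
normalize_axis <- function(axis) {
  up <- toupper(trimws(axis))
  low <- tolower(trimws(axis))
  out <- ifelse(up %in% AXES, up, unname(.AXIS_FULL[low]))
  bad <- is.na(out) | !nzchar(axis)
  if (any(bad)) {
    stop("unknown axis code(s): ", paste(unique(axis[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

.validate_concepts <- function(concepts) {
  stopifnot(is.data.frame(concepts))
  req <- c("id", "axis", "preferred_label", "synonyms", "xrefs")
  missing_cols <- setdiff(req, names(concepts))
  if (length(missing_cols)) {
    stop("concept table lacks column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  dup <- concepts$id[duplicated(concepts$id)]
  if (length(dup)) {
    stop("duplicate concept id(s): ", paste(unique(dup), collapse = ", "),
      call. = FALSE
    )
  }
  if (any(!nzchar(concepts$id)) || any(is.na(concepts$id))) {
    stop("concept ids must be non-empty", call. = FALSE)
  }
  if (any(!nzchar(concepts$preferred_label)) || any(is.na(concepts$preferred_label))) {
    stop("preferred labels must be non-empty", call. = FALSE)
  }
  concepts$axis <- if (nrow(concepts)) normalize_axis(concepts$axis) else character()
  concepts
}

#' Build a lexicon from a concept table
#'
#' Validates the concepts (unique non-empty ids, known axes, non-empty
#' preferred labels) and compiles the phrase table. Concepts whose every
#' surface form normalizes away (e.g. a label of `"19"`) are kept in the
#' concept table but absent from the phrase table, with a warning.
#'
#' @param concepts Tibble/data frame with columns `id`, `axis`,
#'   `preferred_label`, `synonyms` (list of character vectors), `xrefs`
#'   (list of character vectors). `synonyms`/`xrefs` may also be plain
#'   character columns with `|`-separated values.
#' @return A `lexicon` object.
#' @export
lexicon <- function(concepts) {
  concepts <- tibble::as_tibble(concepts)
  if (!nrow(concepts)) {
    concepts <- tibble::tibble(
      id = character(), axis = character(), preferred_label = character(),
      synonyms = list(), xrefs = list()
    )
  }
  for (col in c("synonyms", "xrefs")) {
    if (!col %in% names(concepts)) {
      concepts[[col]] <- replicate(nrow(concepts), character(), simplify = FALSE)
    } else if (is.character(concepts[[col]])) {
      concepts[[col]] <- lapply(concepts[[col]], .split_multi)
    }
  }
  concepts <- .validate_concepts(concepts)
  pt <- compile_phrases(concepts)
  structure(
    list(concepts = concepts, phrase_table = pt$table, max_phrase_len = pt$max_len),
    class = "lexicon"
  )
}

#' @export
print.lexicon <- function(x, ...) {
  cat(
    "<lexicon> ", nrow(x$concepts), " concepts, ",
    length(x$phrase_table), " compiled phrases",
    " (max ", x$max_phrase_len, " tokens)\n",
    sep = ""
  )
  tab <- table(factor(x$concepts$axis, levels = AXES))
  cat("  per axis:", paste(names(tab), unname(tab), sep = ":", collapse = " "), "\n")
  invisible(x)
}

#' Compile surface forms into a normalized phrase table
#'
#' Every surface form of every concept is tokenized and normalized; an n-token
#' form yields one key per element of the cartesian product of its per-token
#' variant sets (so `"covid-19 vaccine"` yields both `"covid vaccine"` and
#' `"covid19 vaccine"`). Keys are space-joined variant sequences mapping to
#' the set of concept ids they evidence. Forms in which any token normalizes
#' to nothing are skipped. Deterministic and order-independent.
#'
#' @param concepts Validated concept tibble (see [lexicon()]).
#' @return List with `table` (named list: key -> character vector of concept
#'   ids, ids sorted) and `max_len` (max key length in tokens).
#' @export
compile_phrases <- function(concepts) {
  table <- new.env(parent = emptyenv())
  max_len <- 0L
  dropped <- character()
  for (i in seq_len(nrow(concepts))) {
    id <- concepts$id[[i]]
    forms <- unique(c(concepts$preferred_label[[i]], concepts$synonyms[[i]]))
    forms <- forms[!is.na(forms) & nzchar(forms)]
    any_key <- FALSE
    for (form in forms) {
      vsets <- normalize_tokens(form)
      if (length(vsets) == 0L || any(lengths(vsets) == 0L)) next
      keys <- Reduce(
        function(acc, vs) as.vector(outer(acc, vs, paste)),
        vsets[-1L],
        init = vsets[[1L]]
      )
      for (key in unique(keys)) {
        table[[key]] <- union(table[[key]], id)
        any_key <- TRUE
      }
      max_len <- max(max_len, length(vsets))
    }
    if (!any_key) dropped <- c(dropped, id)
  }
  if (length(dropped)) {
    warning(
      "concept(s) with no normalizable surface form (absent from phrase table): ",
      paste(dropped, collapse = ", "),
      call. = FALSE
    )
  }
  out <- as.list(table)
  if (length(out)) {
    out <- lapply(out, sort)[order(names(out))]
  }
  list(table = out, max_len = max_len)
}

.split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(character())
  }
  # split on unescaped "|", then unescape
  parts <- strsplit(x, "(?<!\\\\)\\|", perl = TRUE)[[1L]]
  gsub("\\|", "|", parts, fixed = TRUE)
}

.join_multi <- function(x) {
  if (length(x) == 0L) {
    return("")
  }
  paste(gsub("|", "\\|", x, fixed = TRUE), collapse = "|")
}

#' Read a lexicon from TSV or JSON
#'
#' The TSV dialect is UTF-8 with header
#' `id  axis  preferred_label  synonyms  xrefs` (tab-separated), `|` as the
#' multi-value separator inside `synonyms`/`xrefs` and `\|` escaping a
#' literal pipe. The JSON dialect is an array of objects with the same five
#' keys, `synonyms` and `xrefs` being string arrays.
#'
#' @param path Path to the lexicon file.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by extension).
#' @return A `lexicon` object.
#' @export
read_lexicon <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (format == "json") {
    recs <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    concepts <- purrr::map_dfr(recs, function(r) {
      for (k in c("id", "axis", "preferred_label")) {
        if (is.null(r[[k]])) stop("lexicon JSON record lacks key '", k, "'", call. = FALSE)
      }
      tibble::tibble(
        id = r$id, axis = r$axis, preferred_label = r$preferred_label,
        synonyms = list(as.character(unlist(r$synonyms))),
        xrefs = list(as.character(unlist(r$xrefs)))
      )
    })
    if (!length(recs)) concepts <- NULL
    return(lexicon(concepts %||% tibble::tibble()))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop("empty lexicon file (no header): ", path, call. = FALSE)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  expected <- c("id", "axis", "preferred_label", "synonyms", "xrefs")
  if (!identical(header, expected)) {
    stop("line 1: bad header, expected ", paste(expected, collapse = "\\t"),
      call. = FALSE
    )
  }
  body <- lines[-1L]
  body <- body[nzchar(body)]
  rows <- purrr::imap(body, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L || length(f) > 5L) {
      stop("line ", i + 1L, ": expected 5 tab-separated fields, got ", length(f),
        call. = FALSE
      )
    }
    f <- c(f, rep("", 5L - length(f)))
    tibble::tibble(
      id = f[1L], axis = f[2L], preferred_label = f[3L],
      synonyms = list(.split_multi(f[4L])), xrefs = list(.split_multi(f[5L]))
    )
  })
  lexicon(dplyr::bind_rows(rows))
}

#' Write a lexicon to TSV or JSON
#'
#' Inverse of [read_lexicon()]: round-trips the concept set exactly
#' (id, axis, label, synonyms, xrefs), independent of row order.
#'
#' @param lex A `lexicon` object.
#' @param path Output path.
#' @param format `"tsv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(lex, "lexicon"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  cc <- lex$concepts
  if (format == "json") {
    recs <- purrr::pmap(cc, function(id, axis, preferred_label, synonyms, xrefs) {
      list(
        id = id, axis = axis, preferred_label = preferred_label,
        synonyms = as.list(synonyms), xrefs = as.list(xrefs)
      )
    })
    jsonlite::write_json(recs, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    lines <- c(
      "id\taxis\tpreferred_label\tsynonyms\txrefs",
      purrr::pmap_chr(cc, function(id, axis, preferred_label, synonyms, xrefs) {
        paste(id, axis, preferred_label, .join_multi(synonyms), .join_multi(xrefs),
          sep = "\t"
        )
      })
    )
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}

#' Look up concept metadata by id
#' @param lex A `lexicon`.
#' @param ids Character vector of concept ids.
#' @return Tibble of matching concept rows (in `ids` order).
#' @keywords internal
concept_info <- function(lex, ids) {
  idx <- match(ids, lex$concepts$id)
  if (anyNA(idx)) {
    stop("unknown concept id(s): ", paste(ids[is.na(idx)], collapse = ", "),
      call. = FALSE
    )
  }
  lex$concepts[idx, ]
}
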