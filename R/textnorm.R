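#' Text normalization for dictionary matching
#'
#' Tokenization and token-variant expansion shared by the lexicon compiler,
#' the annotator and the retrieval index. A token is a maximal run of Unicode
#' letters/digits possibly containing *internal* dashes or slashes
#' (`"covid-19/flu"` is one token); any other character delimits tokens.
#' Each token then expands to a set of lowercase matchable variants: the token
#' is split on `-` and `/`, every fragment of length >= 3 is kept, and the
#' fusion of all fragments is added if it is itself of length >= 3. A
#' separator-free token yields itself (lowercased) when long enough. So
#' `"covid-19"` expands to `{"covid", "covid19"}` while `"19"` yields nothing:
#' short fragments carry too little signal to match on.
#'
#' Offsets always refer to the original, unmodified field text (0-based,
#' half-open), so annotations can be projected back onto the source document.
#'
#' @name textnorm
NULL

# typographic dash-like codepoints (hyphen, non-breaking hyphen, figure
# dash, en/em/horizontal-bar dashes, minus sign) folded to "-" before
# splitting; each replacement is one char for one char so offsets hold
.DASH_CLASS <- "[\u2010\u2011\u2012\u2013\u2014\u2015\u2212]"

.fold_dashes <- function(text) {
  gsub(.DASH_CLASS, "-", text, perl = TRUE)
}

.MIN_VARIANT_LEN <- 3L

#' Tokenize a text field with character offsets
#'
#' @param text A character scalar (may be empty or `NA`, both give zero rows).
#' @param field Field label attached to every token (one of `"title"`,
#'   `"abstract"`, `"body"`, `"keywords"`; any string is accepted because the
#'   tokenizer is also used on raw query strings).
#' @return A tibble with one row per token: `surface` (original spelling),
#'   `start`, `end` (0-based half-open character offsets into `text`),
#'   `field`, and `variants` (list column of character vectors of normalized
#'   variants, possibly empty).
#' @examples
#' tokenize("Remdesivir inhibits SARS-CoV-2.")
#' @export
tokenize <- function(text, field = "abstract") {
  stopifnot(length(text) == 1L)
  empty <- tibble::tibble(
    surface = character(), start = integer(), end = integer(),
    field = character(), variants = list()
  )
  if (is.na(text) || !nzchar(text)) {
    return(empty)
  }
  folded <- .fold_dashes(text)
  m <- gregexpr("[\\p{L}\\p{N}]+(?:[-/][\\p{L}\\p{N}]+)*", folded, perl = TRUE)[[1L]]
  if (m[1L] == -1L) {
    return(empty)
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  surface <- substring(text, start + 1L, start + len)
  tibble::tibble(
    surface = surface,
    start = start,
    end = start + len,
    field = field,
    variants = lapply(.fold_dashes(surface), expand_token)
  )
}

#' Expand one token into its normalized matchable variants
#'
#' Lowercases, splits on `-` and `/`, keeps each fragment of length >= 3, and
#' adds the fusion of all fragments when the token contained a separator.
#' Digits count toward length. The result never contains separators,
#' uppercase letters, or strings shorter than 3 characters.
#'
#' @param surface A single token (no whitespace).
#' @return Character vector of distinct variants (possibly empty).
#' @examples
#' expand_token("covid-19")   # "covid" "covid19"
#' expand_token("SARS-CoV-2") # "sars" "cov" "sarscov2"
#' expand_token("19")         # character(0)
#' @export
expand_token <- function(surface) {
  stopifnot(length(surface) == 1L, !is.na(surface))
  low <- tolower(.fold_dashes(surface))
  frags <- strsplit(low, "[-/]", perl = TRUE)[[1L]]
  frags <- frags[nzchar(frags)]
  if (length(frags) == 0L) {
    return(character())
  }
  out <- frags[nchar(frags) >= .MIN_VARIANT_LEN]
  if (length(frags) > 1L) {
    fused <- paste(frags, collapse = "")
    if (nchar(fused) >= .MIN_VARIANT_LEN) {
      out <- c(out, fused)
    }
  }
  unique(out)
}

#' Normalize a free-text string to its variant token sequences
#'
#' Convenience used by the phrase compiler and query parsing: tokenizes and
#' returns the per-token variant sets, dropping nothing.
#'
#' @param text Character scalar.
#' @return List of character vectors, one per token (empty vectors retained).
#' @keywords internal
normalize_tokens <- function(text) {
  tokenize(text)$variants
}
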