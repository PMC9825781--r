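#' Deterministic synthetic fixtures
#'
#' Generates everything the pipeline consumes — a mini-lexicon across all
#' nine axes, a corpus with concept surface forms planted at recorded
#' offsets, gold annotations, topics with a focus axis, relevance judgements
#' linked to planted focus-axis concept counts, and a reference
#' document-frequency table from a held-out filler corpus — so annotation,
#' retrieval, triage and evaluation are all testable offline with a known
#' ground truth. The same seed reproduces every artifact byte-identically.
#'
#' What the generator emulates: fielded bibliographic records whose concept
#' mentions are unambiguous planted dictionary forms, and topics whose
#' relevance is a monotone (logistic) function of how many distinct
#' focus-axis concepts a document mentions. What it does not emulate:
#' ambiguous or nested mentions, discontinuous spans, real term-frequency
#' distributions, or judging noise beyond the Bernoulli relevance draw.
#'
#' @name fixtures
NULL

# fixed filler vocabulary (shipped in-package for reproducibility); chosen
# to be >= 3 characters so every filler token survives normalization, and
# disjoint from the syllable-built concept pseudo-words
.FILLER_WORDS <- c(
  "the", "and", "with", "from", "were", "are", "this", "that", "study",
  "results", "patients", "analysis", "data", "using", "between", "among",
  "observed", "measured", "reported", "clinical", "significant", "increase",
  "decrease", "levels", "compared", "control", "group", "groups", "effect",
  "effects", "during", "after", "before", "within", "associated", "found",
  "showed", "suggest", "evidence", "however", "methods", "sample", "samples",
  "total", "mean", "median", "range", "values", "higher", "lower", "present",
  "absent", "cases", "cohort", "followup", "baseline", "outcome", "outcomes",
  "treatment", "therapy", "response", "authors", "review", "systematic",
  "random", "trial", "design", "model", "models", "estimated", "approach",
  "performed", "conducted", "included", "excluded", "criteria", "population"
)

.SYLLABLES <- c(
  "bar", "cor", "dil", "fus", "gal", "hex", "kir", "lom", "mur", "nep",
  "pol", "rin", "sul", "tav", "vex", "zor", "quel", "bran", "crom", "dast",
  "fent", "grin", "holm", "jarv", "kelt", "lorn", "mosk", "nilt", "pruv",
  "stel"
)

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

#' Fixture generation parameters
#'
#' @param n_concepts_per_axis Concepts generated for each of the nine axes.
#' @param n_docs Corpus size.
#' @param doc_length Two-element integer range of filler tokens per abstract.
#' @param plant_rate Expected planted concept mentions per document per axis
#'   (Poisson).
#' @param relevance_intercept,relevance_slope Logistic link from a
#'   document's distinct planted focus-axis concept count `c` to its
#'   relevance probability `plogis(intercept + slope * c)`.
#' @param n_topics Number of topics (each gets a focus axis and a query
#'   naming two focus-axis concepts plus common filler words).
#' @param seed Integer seed; same seed, same fixture.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_concepts_per_axis = 3L, n_docs = 120L,
                         doc_length = c(30L, 60L), plant_rate = 0.8,
                         relevance_intercept = -3, relevance_slope = 1.5,
                         n_topics = 3L, seed = 42L) {
  stopifnot(
    n_concepts_per_axis >= 1, n_docs >= 0, length(doc_length) == 2L,
    doc_length[1] >= 1, doc_length[2] >= doc_length[1], plant_rate >= 0,
    n_topics >= 1
  )
  structure(
    list(
      n_concepts_per_axis = as.integer(n_concepts_per_axis),
      n_docs = as.integer(n_docs),
      doc_length = as.integer(doc_length),
      plant_rate = plant_rate,
      relevance_intercept = relevance_intercept,
      relevance_slope = relevance_slope,
      n_topics = as.integer(n_topics),
      seed = as.integer(seed)
    ),
    class = "fixture_spec"
  )
}

.pseudo_words <- function(n) {
  # deterministic given the RNG state; guaranteed unique and filler-disjoint
  out <- character(0)
  while (length(out) < n) {
    w <- paste(sample(.SYLLABLES, sample(2:3, 1), replace = TRUE), collapse = "")
    if (!w %in% out && !w %in% .FILLER_WORDS) out <- c(out, w)
  }
  out
}

#' Generate a synthetic mini-lexicon
#'
#' Concepts across all nine axes with 1–3 synonyms each; some surface forms
#' carry internal dashes or slashes and some are two-token phrases, so the
#' normalization path is exercised. The DIS axis always contains the worked
#' dash-splitting example concept labeled `"covid-19"`.
#'
#' @param spec A [fixture_spec()].
#' @return A [lexicon()].
#' @export
make_lexicon <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed, {
    n_total <- 9L * spec$n_concepts_per_axis
    pool <- .pseudo_words(n_total * 5L)
    nxt <- 0L
    take <- function(k) {
      out <- pool[nxt + seq_len(k)]
      nxt <<- nxt + k
      out
    }
    rows <- purrr::map(AXES, function(ax) {
      purrr::map(seq_len(spec$n_concepts_per_axis), function(i) {
        base <- take(1L)
        style <- sample(c("plain", "dash", "slash", "phrase"), 1L,
          prob = c(0.4, 0.25, 0.15, 0.2)
        )
        label <- switch(style,
          plain = base,
          dash = paste(base, take(1L), sep = "-"),
          slash = paste(base, take(1L), sep = "/"),
          phrase = paste(base, take(1L))
        )
        n_syn <- sample(1:3, 1L)
        syns <- purrr::map_chr(seq_len(n_syn), function(j) {
          s <- take(1L)
          if (stats::runif(1) < 0.3) paste(s, take(1L), sep = "-") else s
        })
        tibble::tibble(
          id = sprintf("SYN:%s%04d", ax, i),
          axis = ax, preferred_label = label,
          synonyms = list(syns), xrefs = list(character())
        )
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    demo <- tibble::tibble(
      id = "DEMO:0000001", axis = "DIS", preferred_label = "covid-19",
      synonyms = list("coronavirus disease 2019"), xrefs = list(character())
    )
    lexicon(dplyr::bind_rows(rows, demo))
  })
}

.assemble_field <- function(items) {
  # items: tibble(text, is_plant, concept_id); returns field string + offsets
  if (!nrow(items)) {
    return(list(text = "", plants = NULL))
  }
  widths <- nchar(items$text)
  start <- cumsum(c(0L, widths[-length(widths)] + 1L)) # +1 for the joining space
  text <- paste(items$text, collapse = " ")
  plants <- items[items$is_plant, c("concept_id", "text")]
  if (nrow(plants)) {
    plants$start <- start[items$is_plant]
    plants$end <- plants$start + nchar(plants$text)
  }
  list(text = text, plants = plants)
}

#' Generate a synthetic corpus with planted concepts and evaluation files
#'
#' Documents are filler tokens with lexicon surface forms planted verbatim,
#' space-separated, at recorded character offsets; gold annotations list
#' every plant. Each topic focuses one axis; a document's relevance draw is
#' Bernoulli with probability `plogis(intercept + slope * c)` where `c` is
#' its number of distinct planted focus-axis concepts. The reference DF
#' table is computed from a held-out filler-only corpus, so common filler
#' words carry high df (low query weight) and concept words are unseen
#' (maximal weight).
#'
#' @param spec A [fixture_spec()].
#' @param lex A lexicon from [make_lexicon()] (same spec).
#' @return List: `documents` (tibble), `gold` (annotation tibble:
#'   `doc_id`, `concept_id`, `field`, `start`, `end`, `surface`), `topics`
#'   (`topic_id`, `query`, `focus`), `qrels`, `ref_df` (named vector),
#'   `ref_N`.
#' @export
make_corpus <- function(spec, lex) {
  stopifnot(inherits(spec, "fixture_spec"), inherits(lex, "lexicon"))
  cc <- lex$concepts
  .with_seed(spec$seed + 1L, {
    docs <- vector("list", spec$n_docs)
    gold <- vector("list", spec$n_docs)
    planted_ids <- vector("list", spec$n_docs)
    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("doc%04d", d)
      n_fill <- sample(spec$doc_length[1]:spec$doc_length[2], 1L)
      fill <- sample(.FILLER_WORDS, n_fill, replace = TRUE)
      # pick plants: per axis, Poisson(plant_rate) distinct concepts
      plant_rows <- purrr::map(AXES, function(ax) {
        k <- stats::rpois(1L, spec$plant_rate)
        if (k == 0L) {
          return(NULL)
        }
        cand <- which(cc$axis == ax)
        sel <- sample(cand, min(k, length(cand)))
        cc[sel, ]
      }) |> dplyr::bind_rows()
      plant_text <- if (nrow(plant_rows)) {
        purrr::pmap_chr(
          plant_rows[c("preferred_label", "synonyms")],
          function(preferred_label, synonyms) {
            forms <- c(preferred_label, synonyms)
            forms[[sample.int(length(forms), 1L)]]
          }
        )
      } else {
        character()
      }
      items <- tibble::tibble(
        text = fill, is_plant = FALSE, concept_id = NA_character_
      )
      if (nrow(plant_rows)) {
        items <- dplyr::bind_rows(
          items,
          tibble::tibble(
            text = plant_text, is_plant = TRUE, concept_id = plant_rows$id
          )
        )
        items <- items[sample.int(nrow(items)), ]
      }
      fld <- .assemble_field(items)
      docs[[d]] <- tibble::tibble(
        doc_id = doc_id, collection = "synthetic",
        title = paste(sample(.FILLER_WORDS, 4L), collapse = " "),
        abstract = fld$text, body = NA_character_, keywords = NA_character_
      )
      if (!is.null(fld$plants) && nrow(fld$plants)) {
        gold[[d]] <- tibble::tibble(
          doc_id = doc_id, concept_id = fld$plants$concept_id,
          field = "abstract", start = fld$plants$start, end = fld$plants$end,
          surface = fld$plants$text
        )
      }
      planted_ids[[d]] <- if (nrow(plant_rows)) unique(plant_rows$id) else character()
    }
    documents <- dplyr::bind_rows(docs)
    gold <- dplyr::bind_rows(gold)
    if (!nrow(gold)) {
      gold <- tibble::tibble(
        doc_id = character(), concept_id = character(), field = character(),
        start = integer(), end = integer(), surface = character()
      )
    }

    # topics: focus axes cycled over the axes, two focus concepts + filler
    focus_axes <- rep(c("DIS", "CHEM", "ORG", AXES), length.out = spec$n_topics)
    topics <- purrr::map(seq_len(spec$n_topics), function(i) {
      ax <- focus_axes[[i]]
      cand <- which(cc$axis == ax)
      sel <- sample(cand, min(2L, length(cand)))
      tibble::tibble(
        topic_id = sprintf("T%02d", i),
        query = paste(
          c(cc$preferred_label[sel], sample(.FILLER_WORDS, 2L)),
          collapse = " "
        ),
        focus = ax
      )
    }) |> dplyr::bind_rows()

    # qrels: relevance ~ Bernoulli(plogis(a + b * distinct focus concepts))
    qrels <- purrr::pmap(topics, function(topic_id, query, focus) {
      focus_ids <- cc$id[cc$axis == focus]
      counts <- vapply(
        planted_ids, function(ids) sum(ids %in% focus_ids), integer(1)
      )
      p <- stats::plogis(spec$relevance_intercept + spec$relevance_slope * counts)
      tibble::tibble(
        topic_id = topic_id, doc_id = documents$doc_id,
        grade = stats::rbinom(length(p), 1L, p)
      )
    }) |> dplyr::bind_rows()

    # reference DF from a held-out filler corpus
    ref_N <- 200L
    held <- purrr::map(seq_len(ref_N), function(i) {
      unique(sample(.FILLER_WORDS, 50L, replace = TRUE))
    })
    tab <- table(unlist(held))
    ref_df <- stats::setNames(as.integer(tab), names(tab))

    list(
      documents = documents, gold = gold, topics = topics, qrels = qrels,
      ref_df = ref_df, ref_N = ref_N
    )
  })
}

#' Generate a complete fixture in one call
#'
#' @param spec A [fixture_spec()].
#' @return List with `lexicon` plus all [make_corpus()] components.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  lex <- make_lexicon(spec)
  c(list(lexicon = lex), make_corpus(spec, lex))
}

#' Read/write a reference document-frequency table
#'
#' Two-column TSV `term df` preceded by a header line `#N=<ref_N>`.
#'
#' @param ref_df Named numeric vector of document frequencies.
#' @param ref_N Reference collection size.
#' @param path File path.
#' @return `read_ref_df()`: list with `ref_df` (named vector) and `ref_N`.
#' @name ref_df_io
#' @export
write_ref_df <- function(ref_df, ref_N, path) {
  lines <- c(
    sprintf("#N=%d", as.integer(ref_N)),
    sprintf("%s\t%d", names(ref_df), as.integer(ref_df))
  )
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname ref_df_io
#' @export
read_ref_df <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^#N=\\d+$", lines[[1L]])) {
    stop("reference DF table must start with a #N=<int> header line", call. = FALSE)
  }
  ref_N <- as.integer(sub("^#N=", "", lines[[1L]]))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop("reference DF line ", bad[[1L]] + 1L, ": expected 2 tab-separated fields",
      call. = FALSE
    )
  }
  df <- stats::setNames(
    as.integer(vapply(parts, `[[`, "", 2L)),
    vapply(parts, `[[`, "", 1L)
  )
  list(ref_df = df, ref_N = ref_N)
}

#' Write all fixture artifacts to a directory
#'
#' Emits `lexicon.tsv`, `corpus.jsonl`, `gold_annotations.jsonl`,
#' `topics.tsv`, `qrels.txt` and `ref_df.tsv`.
#'
#' @param fix A [make_fixture()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fix, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_lexicon(fix$lexicon, file.path(dir, "lexicon.tsv"))
  write_corpus(fix$documents, file.path(dir, "corpus.jsonl"))
  gold_ann <- dplyr::transmute(
    fix$gold,
    doc_id = .data$doc_id, concept_id = .data$concept_id,
    matched_term = .data$surface,
    preferred_label = NA_character_, axis = NA_character_,
    field = .data$field, start = .data$start, end = .data$end
  )
  write_annotations_json(
    gold_ann, file.path(dir, "gold_annotations.jsonl"),
    doc_ids = fix$documents$doc_id
  )
  writeLines(
    c(
      "topic_id\tquery\tfocus",
      sprintf("%s\t%s\t%s", fix$topics$topic_id, fix$topics$query, fix$topics$focus)
    ),
    file.path(dir, "topics.tsv"),
    useBytes = TRUE
  )
  writeLines(
    sprintf("%s 0 %s %d", fix$qrels$topic_id, fix$qrels$doc_id, fix$qrels$grade),
    file.path(dir, "qrels.txt"),
    useBytes = TRUE
  )
  write_ref_df(fix$ref_df, fix$ref_N, file.path(dir, "ref_df.tsv"))
  invisible(dir)
}

#' Run the four-condition retrieval experiment on one fixture
#'
#' Generates (or takes) a fixture, annotates and indexes it, then runs every
#' topic under four conditions — BM25 baseline, +QE (concept-id query
#' expansion), +RR (triage re-ranking), +QE+RR — and evaluates each against
#' the fixture qrels.
#'
#' @param spec A [fixture_spec()] (or a prebuilt [make_fixture()] list).
#' @param params A [triage_params()]; its `focus` is overridden per topic by
#'   the topic's focus axis.
#' @param k Retrieval depth.
#' @return Tibble: `condition`, `p_at_10`, `map` (means over topics).
#' @export
run_experiment <- function(spec = fixture_spec(), params = triage_params(),
                           k = 1000L) {
  fix <- if (inherits(spec, "fixture_spec")) make_fixture(spec) else spec
  ann <- annotate_corpus(fix$documents, fix$lexicon)
  idx <- build_index(fix$documents, annotations = ann)
  conditions <- c("baseline", "qe", "rr", "qe_rr")
  runs <- stats::setNames(vector("list", length(conditions)), conditions)
  for (i in seq_len(nrow(fix$topics))) {
    tp <- fix$topics[i, ]
    p <- triage_params(
      w_base = params$w_base, w_spec = params$w_spec, w_dens = params$w_dens,
      focus = tp$focus, normalize = params$normalize
    )
    base_q <- weight_query_terms(tp$query, fix$ref_df, fix$ref_N, focus = tp$focus)
    qe_q <- expand_query(base_q, fix$lexicon)
    base <- search_index(base_q, idx, k = k)
    qe <- search_index(qe_q, idx, k = k)
    add <- function(cond, ranking) {
      runs[[cond]] <<- dplyr::bind_rows(
        runs[[cond]], as_run(ranking, tp$topic_id, tag = cond)
      )
    }
    add("baseline", base)
    add("qe", qe)
    if (nrow(base)) add("rr", rerank(base, ann, idx, p))
    if (nrow(qe)) add("qe_rr", rerank(qe, ann, idx, p))
  }
  purrr::map(conditions, function(cond) {
    r <- runs[[cond]]
    if (is.null(r)) {
      return(tibble::tibble(condition = cond, p_at_10 = 0, map = 0))
    }
    rep <- evaluate_run(r, fix$qrels, k = 10L, cutoff = k, tag = cond)
    tibble::tibble(
      condition = cond, p_at_10 = mean(rep$p_at_k), map = mean(rep$ap)
    )
  }) |> dplyr::bind_rows()
}
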