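---
title: "Methods: ontology-aware annotation, retrieval and triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ontology-aware annotation, retrieval and triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontotriage)
```

## The problem

Literature triage for curation asks a different question than general
search: not "which documents mention these words" but "which documents are
*about* the thematic slice a curator is working on". `ontotriage` answers it
by coupling a keyword retrieval engine to a concept annotation layer over an
axis-partitioned controlled vocabulary, so that a query carries both words
and a *focus* — one of nine concept axes (diseases, chemicals, organisms,
cell lines, clinical trials, geography, proteins/genomes, conceptual
entities, general biomedical vocabulary) — and documents are prioritized by
how much focus-relevant conceptual content they carry.

## Normalization

All matching rides on one token normalization, applied identically to
documents, lexicon surface forms, and query strings:

* tokens are maximal runs of Unicode letters/digits, possibly containing
  internal `-` or `/`; typographic dashes (en/em dashes, minus sign) are
  folded to `-` first;
* each token is lowercased and split on `-` and `/`; every fragment of
  length ≥ 3 is a matchable variant, and the fusion of all fragments is
  added when it reaches length 3 (`covid-19` → `covid`, `covid19`; `19`
  is dropped);
* offsets always refer to the original text, so annotations can be
  projected back for highlighting.

Two generalization choices here were genuinely open. For tokens with more
than one separator we split on all separators and add a *single* fusion of
all fragments (`SARS-CoV-2` → `sars`, `cov`, `sarscov2`) rather than all
pairwise fusions — the simplest rule consistent with the single-dash
behaviour. And the ≥ 3-character filter applies to *every* variant,
including separator-free tokens, for uniformity: the filter is motivated by
fragment length, not fragment origin. Users indexing text where two-letter
symbols matter (gene names like `S1`) should be aware short tokens are
unmatchable by design.

## Annotation

The lexicon compiles every surface form (preferred label and synonyms) into
a phrase table keyed by normalized token sequences; an *n*-token form
contributes the cartesian product of its per-token variant sets. Matching
scans each document field's consecutive token variants against this table.
Concepts from different axes may overlap freely — high annotation densities
are expected and useful — while within one concept the longest match at a
shared start wins and identical spans reached through different variants are
deduplicated. Multi-token phrases must match consecutive tokens; no gaps are
allowed, the conservative default.

Collection statistics (`aggregate_stats()`) count annotations per axis, the
per-collection total, and the average per document using *truncated*
(floor) division — the convention that reproduces published
annotation-volume tables, where the average discriminates floor from
rounding.

## Retrieval

The index emits every variant of every token once, so document length is
counted in variant emissions and both spellings of a dashed term are
first-class index terms. Concept ids attached by the annotator are indexed
in the same structure under a `CID:` prefix, giving query expansion the same
scoring machinery as keywords.

Scoring is Okapi BM25 with the non-negative Lucene-style IDF,
`ln((N − df + 0.5)/(df + 0.5) + 1)`, with defaults `k1 = 1.2`, `b = 0.75` —
the defaults of the Lucene-family engines this component models. Query
terms carry weights from a reference document-frequency table:
`w(t) = max(0, ln(ref_N/(df_t + 1)))`, a smoothed inverse DF that favours
rare informative words and gives unseen terms maximal weight. The exact
weighting function, and the multiplicative way weights enter the BM25 sum,
are package design decisions (the approach is described in the field only
as DF-based weighting); both are small, documented, and isolated in
`weight_query_terms()` should users want a different scheme. Fields are
concatenated without per-field boosts.

## Triage re-ranking

Given a retrieved list and a focus axis, three features are computed per
document:

* `base_score` — the BM25 retrieval score;
* `specificity` — the number of *distinct* focus-axis concepts annotated in
  the document (repeated mentions count once);
* `density` — concept TF-IDF per token:
  `Σ_c tf(c)·max(0, ln(N/(df_c + 1))) / doc_len` over the document's
  distinct annotated concepts, clipped so the degenerate single-document
  corpus yields 0 rather than a negative value.

The final score is `w_base·f1 + w_spec·f2 + w_dens·f3`. Because raw BM25
scores, counts and densities are incommensurable, each feature is min-max
scaled to [0, 1] within the result list before combination (a constant
feature maps to 0). The defaults `w_base = 1.0, w_spec = 0.5,
w_dens = 0.5` keep the retrieval order dominant and let focus evidence
re-order near-ties; empirically tuned weights for a given collection are
not published anywhere we could adopt them from, so the defaults are chosen
for reproducibility and exposed in `triage_params()` and the CLI. Ties are
broken by the original rank, then document id, making re-ranking stable and
deterministic; with `w_spec = w_dens = 0` and normalization off it
reproduces the baseline exactly. All retrieved documents are re-ranked, not
a prefix.

## Evaluation

`evaluate_run()` follows trec_eval conventions: binary relevance at
grade > 0, AP's denominator is the total number of relevant documents
judged for the topic, unjudged documents are non-relevant, topics judged
but missing from a run score 0 and stay in the means. `ev_rate()` reports
`100·(run − baseline)/baseline` rounded half away from zero to two
decimals with an explicit sign, matching how retrieval tables typeset
percentage change. Statistical significance testing between runs is out of
scope.

## The synthetic fixture generator

`make_fixture()` is first-class, tested code, not a convenience: it is the
only way the pipeline can be exercised end-to-end offline with known ground
truth.

* **Lexicon**: `n_concepts_per_axis` (default 3) pseudo-word concepts per
  axis, 1–3 synonyms each, ~40% of forms carrying dashes/slashes or a
  second token, plus the worked dash-splitting concept `covid-19`.
  Pseudo-words are syllable-built and disjoint from the filler vocabulary,
  so no accidental matches occur.
* **Corpus**: default 120 documents of 30–60 filler tokens (a fixed
  in-package word list, for reproducibility), with per-axis plant counts
  drawn Poisson(`plant_rate` = 0.8) and surface forms inserted verbatim,
  space-separated, at recorded offsets. These defaults give each concept a
  presence in roughly a quarter of documents — dense enough that triage
  features carry signal at desk scale, sparse enough that ranking is
  non-trivial.
* **Relevance**: for each topic (default 3; a focus axis and a query naming
  two focus-axis concepts plus two common filler words), each document is
  relevant with probability `plogis(−3 + 1.5·c)` where `c` is its distinct
  planted focus-axis concept count — a logistic link making relevance
  monotone in focus content, which is precisely the structure the
  specificity/density features are designed to exploit. The filler words in
  the query make the baseline retrieve broadly, so re-ranking has room to
  act.
* **Reference DF**: computed from a held-out 200-document filler corpus, so
  filler words get high df (low weight) and planted concept words maximal
  weight.

Everything is generated under a caller-supplied seed with save/restore of
the RNG state; the same seed reproduces every artifact byte-identically.

What passing tests on these fixtures shows — and does not. Perfect planted
recall demonstrates the matcher misses nothing it was built to find;
it says nothing about recall on real text, where hedged spellings,
abbreviations and nested terms occur. The re-ranking lift on
focus-correlated fixtures shows the linear combination recovers a signal
that is *constructed* to be there; on real judgements the corresponding
effect direction must be re-established per collection.

## Problem sizes and runtime choices

The test suite and acceptance script run the multi-seed retrieval
experiment on 60-document, 2-topic fixtures over 20 (tests) or 10
(acceptance script) seeds, the oracle-equivalence checks on fifty 20-document
corpora and thirty random runs, and planted-recall on the default
120-document fixture — sizes chosen so the whole suite completes in a few
minutes on a single CPU while every property is averaged over enough
replicates to be stable.

## Known limitations

* No stemming, lemmatization or stop-word handling; matching is exact at
  the normalized-token level.
* Multi-token matching is gap-free; discontinuous mentions are missed.
* Concept-id postings count annotation occurrences, which conflates a
  concept mentioned via different synonyms with repeated mentions — the
  intended semantics for density, but not a mention-disambiguation model.
* The engine is in-memory and single-node by design; persistence,
  incremental ingestion and service layers are out of scope.
* Cross-references on concepts are metadata only and do not participate in
  matching.
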