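# Independent brute-force oracles used to cross-check the package's
# retrieval scoring and evaluation. Deliberately written as plain loops over
# raw counts, sharing no code with the package's index/search/evaluate paths.

# term statistics recomputed directly from the abstract text of each doc
oracle_corpus_stats <- function(corpus) {
  counts <- lapply(corpus$abstract, function(txt) {
    toks <- unlist(tokenize(txt)$variants, use.names = FALSE)
    if (!length(toks)) {
      return(integer(0))
    }
    tab <- table(toks)
    stats::setNames(as.integer(tab), names(tab))
  })
  names(counts) <- corpus$doc_id
  counts
}

# full BM25 ranking by double loop; same formula, independent code path
oracle_bm25_rank <- function(corpus, terms, weights = rep(1, length(terms)),
                             k1 = 1.2, b = 0.75) {
  counts <- oracle_corpus_stats(corpus)
  N <- length(counts)
  doclen <- vapply(counts, sum, numeric(1))
  avglen <- mean(doclen)
  scores <- numeric(N)
  for (d in seq_len(N)) {
    s <- 0
    for (j in seq_along(terms)) {
      t <- terms[[j]]
      tf <- counts[[d]][t]
      if (is.na(tf)) next
      df <- sum(vapply(counts, function(cnt) t %in% names(cnt), logical(1)))
      idf <- log((N - df + 0.5) / (df + 0.5) + 1)
      s <- s + weights[[j]] * idf * tf * (k1 + 1) /
        (tf + k1 * (1 - b + b * doclen[[d]] / avglen))
    }
    scores[[d]] <- s
  }
  keep <- scores > 0
  out <- data.frame(doc_id = corpus$doc_id[keep], score = scores[keep])
  out[order(-out$score, out$doc_id), ]
}

# straight-loop trec_eval-style evaluator
oracle_p_at_k <- function(ranked_docs, relevant, k = 10) {
  hits <- 0
  for (i in seq_len(min(k, length(ranked_docs)))) {
    if (ranked_docs[[i]] %in% relevant) hits <- hits + 1
  }
  hits / k
}

oracle_ap <- function(ranked_docs, relevant, cutoff = 1000) {
  if (!length(relevant)) {
    return(0)
  }
  found <- 0
  s <- 0
  for (i in seq_len(min(cutoff, length(ranked_docs)))) {
    if (ranked_docs[[i]] %in% relevant) {
      found <- found + 1
      s <- s + found / i
    }
  }
  s / length(relevant)
}

# random corpus of plain single-variant words for oracle comparisons
random_oracle_corpus <- function(n_docs = 20, vocab_size = 12, len = c(5, 15)) {
  vocab <- paste0("word", sprintf("%02d", seq_len(vocab_size)))
  tibble::tibble(
    doc_id = sprintf("d%03d", seq_len(n_docs)),
    abstract = vapply(seq_len(n_docs), function(i) {
      paste(sample(vocab, sample(len[1]:len[2], 1), replace = TRUE),
        collapse = " "
      )
    }, character(1))
  )
}

# random run + qrels for evaluator comparisons
random_run_and_qrels <- function(n_topics = 3, n_docs = 30) {
  docs <- sprintf("d%03d", seq_len(n_docs))
  run <- dplyr::bind_rows(lapply(seq_len(n_topics), function(t) {
    ranked <- sample(docs, sample(5:n_docs, 1))
    tibble::tibble(
      topic_id = sprintf("T%02d", t), doc_id = ranked,
      rank = seq_along(ranked), score = rev(seq_along(ranked)) + stats::runif(length(ranked)),
      tag = "rand"
    )
  }))
  qrels <- dplyr::bind_rows(lapply(seq_len(n_topics), function(t) {
    tibble::tibble(
      topic_id = sprintf("T%02d", t), doc_id = docs,
      grade = stats::rbinom(n_docs, 1, 0.3)
    )
  }))
  list(run = run, qrels = qrels)
}
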