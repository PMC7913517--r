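# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the package's own code paths.

# exact hypergeometric upper tail by direct enumeration of the pmf with
# integer binomial products (exact in doubles for N <= 25: the largest
# product of two binomials stays below 2^53)
hyper_tail_oracle <- function(k, K, n, N) {
  i <- k:min(K, n)
  i <- i[i >= max(0, n - (N - K))]
  if (length(i) == 0) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# naive per-document word counting, independent of word_atomize: its own
# tokenizer regex, stopword drop and synonym relabelling
naive_word_counts <- function(corpus, config) {
  lookup <- stats::setNames(
    rep(names(config$synonym_groups), lengths(config$synonym_groups)),
    unlist(config$synonym_groups, use.names = FALSE))
  totals <- list()
  docs <- list()
  for (i in seq_len(nrow(corpus))) {
    txt <- if (config$include_title && !is.na(corpus$abstract[i])) {
      paste(corpus$title[i], corpus$abstract[i])
    } else if (config$include_title) corpus$title[i] else corpus$abstract[i]
    toks <- regmatches(txt, gregexpr("[A-Za-z0-9]+(-[A-Za-z0-9]+)*", txt))[[1]]
    if (config$case_folding) toks <- tolower(toks)
    toks <- toks[nchar(toks) >= config$min_token_length]
    toks <- toks[!(toks %in% config$stopwords)]
    hit <- toks %in% names(lookup)
    toks[hit] <- lookup[toks[hit]]
    for (tk in toks) totals[[tk]] <- (totals[[tk]] %||% 0L) + 1L
    for (tk in unique(toks)) docs[[tk]] <- (docs[[tk]] %||% 0L) + 1L
  }
  list(totals = totals, docs = docs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# naive substring-scan omics classifier (regex boundary scan, no shared
# code with classify_article)
naive_classify <- function(title, abstract, map) {
  txt <- tolower(paste(title, if (!is.na(abstract)) abstract))
  hits <- character()
  for (cls in names(map)) {
    for (kw in map[[cls]]) {
      pat <- paste0("(?<![a-z0-9])",
                    gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1", tolower(kw)),
                    "(?![a-z0-9])")
      if (grepl(pat, txt, perl = TRUE)) { hits <- c(hits, cls); break }
    }
  }
  if (length(hits) == 0) "unclassified"
  else if (length(hits) == 1) hits
  else "multiomics"
}

# a tiny hand-built corpus used across modules
tiny_corpus <- function() {
  literature_corpus(
    record_id = c("A1", "A2", "A3", "A4"),
    title = c("Skin barrier study", "Gut microbiome survey",
              "Cytokine signalling review", "Title-only record"),
    abstract = c(
      "Skin barrier function is impaired. The skin microbiome shifts in disease.",
      "Gut dysbiosis precedes onset. Inflammation markers rise early.",
      "IL13 drives inflammatory signalling. Dupilumab blocks IL13 signalling.",
      NA),
    year = c(2018L, 2019L, 2020L, 2017L))
}
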