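#' Tokenisation and word-atomization configuration
#'
#' Controls how article text is decomposed into counted units: stopword
#' removal, synonym grouping (so e.g. "inflammatory" and "inflammation"
#' count as one entry under a shared display label), case folding, a
#' minimum token length, and whether titles are indexed alongside
#' abstracts.
#'
#' Synonym groups must be pairwise disjoint and disjoint from the stopword
#' list; both conditions are validated here.
#'
#' @param stopwords Character vector of tokens to drop. Defaults to the
#'   packaged English list ([default_stopwords()]).
#' @param synonym_groups Named list: display label -> character vector of
#'   surface tokens. Defaults to the packaged groups
#'   ([default_synonym_groups()]).
#' @param case_folding Lower-case text before matching? Default `TRUE`.
#' @param min_token_length Tokens shorter than this are dropped. Default 2.
#' @param include_title Index the title together with the abstract?
#'   Default `TRUE` (article metadata beyond the abstract is scanned).
#' @return An object of class `token_config`.
#' @export
token_config <- function(stopwords = default_stopwords(),
                         synonym_groups = default_synonym_groups(),
                         case_folding = TRUE,
                         min_token_length = 2L,
                         include_title = TRUE) {
  stopwords <- as.character(stopwords)
  if (case_folding) {
    stopwords <- tolower(stopwords)
    synonym_groups <- lapply(synonym_groups, tolower)
  }
  all_grouped <- unlist(synonym_groups, use.names = FALSE)
  if (anyDuplicated(all_grouped)) {
    dup <- all_grouped[duplicated(all_grouped)][1]
    oc_validation_error(
      sprintf("token '%s' appears in more than one synonym group", dup),
      field = "synonym_groups")
  }
  clash <- intersect(all_grouped, stopwords)
  if (length(clash) > 0L) {
    oc_validation_error(
      sprintf("token(s) both stopworded and synonym-grouped: %s",
              paste(clash, collapse = ", ")),
      field = "synonym_groups")
  }
  structure(
    list(stopwords = stopwords,
         synonym_groups = synonym_groups,
         case_folding = isTRUE(case_folding),
         min_token_length = as.integer(min_token_length),
         include_title = isTRUE(include_title)),
    class = "token_config")
}

#' Packaged English stopword list
#'
#' The standard snowball-style English function-word list shipped with the
#' package. Domain words are deliberately never stopworded: the corpus is
#' disease-scoped, so terms like "skin" or "patients" are informative
#' ranking results, not noise.
#'
#' @return Character vector of stopword tokens.
#' @export
default_stopwords <- function() {
  readLines(pkg_extdata("stopwords_en.txt"), encoding = "UTF-8")
}

#' Packaged synonym groups
#'
#' Seeded with the grouped display labels visible in published word
#' rankings ("cell/cells", "inflammatory/inflammation") plus a small set of
#' singular/plural folds. No stemmer is applied by default, so every
#' grouping decision is auditable in this file.
#'
#' @return Named list mapping display label to surface-token set.
#' @export
default_synonym_groups <- function() {
  read_synonym_file(pkg_extdata("synonyms_default.tsv"))
}

#' Read a synonym-group file
#'
#' Format: one group per line, `display_label<TAB>token1,token2,...`.
#'
#' @param path Path to the TSV file.
#' @return Named list mapping display label to token vector.
#' @export
read_synonym_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    oc_parse_error(sprintf("synonym file line %d has no token list", bad[1]))
  }
  groups <- lapply(parts, function(p) trimws(strsplit(p[2], ",")[[1]]))
  names(groups) <- vapply(parts, `[[`, character(1), 1L)
  groups
}

#' Read a stopword file (one token per line)
#'
#' @param path Path to the file.
#' @return Character vector of tokens.
#' @export
read_stopword_file <- function(path) {
  x <- readLines(path, encoding = "UTF-8")
  x[nzchar(trimws(x)) & !startsWith(x, "#")]
}

#' Tokenize free text
#'
#' Tokens are maximal runs of letters/digits/hyphens (so "IL-13" is a
#' single token), case-folded if configured; tokens shorter than the
#' configured minimum and stopwords are dropped. Order of occurrence is
#' preserved.
#'
#' @param text A character vector; elements are tokenized independently
#'   and concatenated.
#' @param config A [token_config()].
#' @return Character vector of tokens (empty for empty/NA input).
#' @export
tokenize <- function(text, config = token_config()) {
  stopifnot(inherits(config, "token_config"))
  text <- text[!is.na(text)]
  if (length(text) == 0L) return(character())
  toks <- unlist(stringr::str_extract_all(
    text, "[A-Za-z0-9]+(?:-[A-Za-z0-9]+)*"), use.names = FALSE)
  if (config$case_folding) toks <- tolower(toks)
  toks <- toks[nchar(toks) >= config$min_token_length]
  toks[!(toks %in% config$stopwords)]
}

record_text <- function(corpus, config) {
  if (config$include_title) {
    ifelse(is.na(corpus$abstract), corpus$title,
           paste(corpus$title, corpus$abstract))
  } else {
    corpus$abstract
  }
}

# token -> display label lookup built from the synonym groups
label_lookup <- function(config) {
  groups <- config$synonym_groups
  setNames(rep(names(groups), lengths(groups)),
           unlist(groups, use.names = FALSE))
}

#' Word atomization: ranked word counts over a corpus
#'
#' Decomposes every record's indexed text into tokens, folds synonym
#' groups into single entries under their display label, and returns the
#' `top_n` entries ranked by total mention count (ties broken
#' lexicographically on the display label). Both the total mention count
#' and the number of distinct documents containing the entry are reported.
#'
#' @param corpus A [literature_corpus()]; normally run after
#'   [filter_has_abstract()].
#' @param config A [token_config()].
#' @param top_n Number of entries to keep (>= 1); fewer are returned when
#'   the corpus has fewer distinct entries.
#' @return An object of class `word_ranking`: list with `entries` (tibble
#'   with columns `display_label`, `token_group` (list), `total_count`,
#'   `document_count`) and `corpus_size`.
#' @export
word_atomize <- function(corpus, config = token_config(), top_n = 30L) {
  if (!is.numeric(top_n) || length(top_n) != 1L || top_n < 1) {
    oc_validation_error("`top_n` must be >= 1", field = "top_n")
  }
  corpus <- validate_corpus(as_tibble(corpus))
  lookup <- label_lookup(config)
  per_doc <- lapply(record_text(corpus, config), tokenize, config = config)
  labelled <- lapply(per_doc, function(toks) {
    hit <- toks %in% names(lookup)
    toks[hit] <- lookup[toks[hit]]
    toks
  })
  all_toks <- unlist(labelled, use.names = FALSE)
  if (length(all_toks) == 0L) {
    return(new_word_ranking(
      tibble(display_label = character(), token_group = list(),
             total_count = integer(), document_count = integer()),
      corpus_size = nrow(corpus)))
  }
  totals <- table(all_toks)
  doc_counts <- table(unlist(lapply(labelled, unique), use.names = FALSE))
  labels <- names(totals)
  groups <- lapply(labels, function(l) {
    g <- config$synonym_groups[[l]]
    if (is.null(g)) l else g
  })
  entries <- tibble(
    display_label = labels,
    token_group = groups,
    total_count = as.integer(totals),
    document_count = as.integer(doc_counts[labels])
  )
  ord <- order(-entries$total_count, entries$display_label, method = "radix")
  entries <- entries[ord, , drop = FALSE]
  entries <- entries[seq_len(min(top_n, nrow(entries))), , drop = FALSE]
  new_word_ranking(entries, corpus_size = nrow(corpus))
}

new_word_ranking <- function(entries, corpus_size) {
  stopifnot(all(entries$document_count <= corpus_size),
            all(entries$total_count >= entries$document_count))
  structure(list(entries = entries, corpus_size = as.integer(corpus_size)),
            class = "word_ranking")
}

#' @export
print.word_ranking <- function(x, n = 10L, ...) {
  cat(sprintf("<word_ranking> %d entries over %d documents\n",
              nrow(x$entries), x$corpus_size))
  show <- utils::head(x$entries, n)
  for (i in seq_len(nrow(show))) {
    cat(sprintf("%3d %-30s total %5d  docs %5d\n", i, show$display_label[i],
                show$total_count[i], show$document_count[i]))
  }
  invisible(x)
}

#' Document frequency of a word group
#'
#' Counts the records in which at least one token of the group occurs at
#' least once, and the corresponding percentage of the corpus (rounded
#' half-up to one decimal). For an empty corpus the percentage is reported
#' as absent (`NA`), not as zero.
#'
#' @param corpus A [literature_corpus()].
#' @param word_group Character vector of surface tokens forming the group.
#' @param config A [token_config()]; tokens are normalised per its rules.
#' @return List with `count` (integer) and `percentage` (one-decimal
#'   percent, `NA` for an empty corpus).
#' @export
document_frequency <- function(corpus, word_group, config = token_config()) {
  corpus <- validate_corpus(as_tibble(corpus))
  if (config$case_folding) word_group <- tolower(word_group)
  hits <- vapply(record_text(corpus, config), function(txt) {
    any(tokenize(txt, config) %in% word_group)
  }, logical(1))
  count <- sum(hits)
  pct <- if (nrow(corpus) == 0L) NA_real_ else
    round_half_up1(100 * count / nrow(corpus))
  list(count = as.integer(count), percentage = pct)
}

#' Split text into sentences
#'
#' Sentences end at `.`, `!` or `?` followed by whitespace and a capital
#' letter. The terminal punctuation stays with its sentence.
#'
#' @param text A single string (`NA` gives an empty result).
#' @return Character vector of sentences.
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(text)) return(character())
  strsplit(text, "(?<=[.!?])\\s+(?=[A-Z])", perl = TRUE)[[1]]
}

#' Extract the sentences in which a term is cited
#'
#' The abstract is split into sentences and every sentence containing the
#' term (token-boundary match; case-insensitive unless requested
#' otherwise) is returned in order. Duplicate sentences are kept.
#'
#' @param record A single-row [literature_corpus()] slice, or a string
#'   treated as the abstract text.
#' @param term Non-empty surface string to locate.
#' @param case_sensitive Require an exact-case match? Default `FALSE`.
#' @return Character vector of matching sentences (possibly empty).
#' @export
extract_contexts <- function(record, term, case_sensitive = FALSE) {
  if (!is.character(term) || length(term) != 1L || !nzchar(term)) {
    oc_validation_error("`term` must be a non-empty string", field = "term")
  }
  text <- if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1L)
    record$abstract[[1]]
  } else {
    record
  }
  sentences <- split_sentences(text)
  sentences[vapply(sentences, has_term, logical(1), term = term,
                   ignore_case = !case_sensitive)]
}
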