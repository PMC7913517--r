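#' Construct a mention lexicon
#'
#' A lexicon maps canonical symbols to surface aliases and controls the
#' matching rules: symbols of four characters or fewer are matched
#' case-sensitively (short gene symbols such as C3 or SET are rife with
#' English homographs), longer ones case-insensitively; symbols on the
#' blocklist are never matched at all. Aliases duplicated across canonical
#' symbols are flagged ambiguous (warning) and attributed to the first
#' symbol that declares them.
#'
#' @param entries Named list: canonical symbol -> character vector of
#'   aliases (the canonical itself is always an implicit alias).
#' @param case_sensitive Aliases requiring exact-case match; `NULL`
#'   (default) selects every alias of `auto_case_threshold` characters or
#'   fewer plus any explicitly flagged ones.
#' @param blocklist Canonical symbols never matched.
#' @param auto_case_threshold Length at or below which aliases default to
#'   case-sensitive matching. Default 4.
#' @return An object of class `mention_lexicon`.
#' @export
lexicon <- function(entries, case_sensitive = NULL, blocklist = character(),
                    auto_case_threshold = 4L) {
  stopifnot(is.list(entries), !is.null(names(entries)))
  entries <- lapply(names(entries), function(sym) {
    unique(c(sym, as.character(entries[[sym]])))
  })
  names(entries) <- names(entries) <- vapply(entries, `[[`, character(1), 1L)
  matchable <- setdiff(names(entries), blocklist)
  entries <- entries[matchable]
  alias_tab <- tibble(
    canonical = rep(names(entries), lengths(entries)),
    alias = unlist(entries, use.names = FALSE)
  )
  if (anyDuplicated(alias_tab$alias)) {
    amb <- unique(alias_tab$alias[duplicated(alias_tab$alias)])
    warn(sprintf("ambiguous alias(es) across canonical symbols: %s",
                 paste(amb, collapse = ", ")))
    alias_tab <- alias_tab[!duplicated(alias_tab$alias), , drop = FALSE]
  }
  auto_cs <- alias_tab$alias[nchar(alias_tab$alias) <= auto_case_threshold]
  cs <- unique(c(auto_cs, case_sensitive))
  structure(
    list(entries = entries,
         alias_table = alias_tab,
         case_sensitive_symbols = cs,
         blocklist = as.character(blocklist)),
    class = "mention_lexicon")
}

#' @export
print.mention_lexicon <- function(x, ...) {
  cat(sprintf(
    "<mention_lexicon> %d symbols, %d aliases (%d case-sensitive), %d blocked\n",
    length(x$entries), nrow(x$alias_table),
    length(x$case_sensitive_symbols), length(x$blocklist)))
  invisible(x)
}

#' Read a lexicon from TSV
#'
#' Format: `canonical<TAB>alias1,alias2<TAB>flags`, where flags is a
#' comma-separated subset of `cs` (force case-sensitive matching) and
#' `block` (never match). The alias and flag fields may be empty.
#'
#' @param path Path to the TSV file.
#' @param auto_case_threshold Passed to [lexicon()].
#' @return A [lexicon()].
#' @export
read_lexicon <- function(path, auto_case_threshold = 4L) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  canonical <- vapply(parts, `[[`, character(1), 1L)
  aliases <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(p[2])) character() else
      trimws(strsplit(p[2], ",")[[1]])
  })
  flags <- lapply(parts, function(p) {
    if (length(p) < 3L || !nzchar(p[3])) character() else
      trimws(strsplit(p[3], ",")[[1]])
  })
  names(aliases) <- canonical
  blocked <- canonical[vapply(flags, function(f) "block" %in% f, logical(1))]
  forced_cs <- unlist(mapply(function(sym, al, fl) {
    if ("cs" %in% fl) c(sym, al) else character()
  }, canonical, aliases, flags, SIMPLIFY = FALSE), use.names = FALSE)
  lexicon(aliases, case_sensitive = forced_cs, blocklist = blocked,
          auto_case_threshold = auto_case_threshold)
}

#' Packaged gene lexicon
#'
#' An HGNC-style symbol/alias table of ~200 genes relevant to inflammatory
#' skin disease (interleukins, Notch pathway, barrier and keratin genes,
#' complement, JAK/STAT, ...), with a blocklist of English-word homograph
#' symbols. Users with broader needs can supply a full lexicon via
#' [read_lexicon()].
#'
#' @return A [lexicon()].
#' @export
default_gene_lexicon <- function() {
  read_lexicon(pkg_extdata("gene_lexicon.tsv"))
}

#' Packaged drug lexicon
#'
#' Biologics, small molecules and experimental agents commonly cited in
#' the dermatology omics literature (imiquimod, dupilumab, adalimumab,
#' ustekinumab, methotrexate, secukinumab, etanercept, infliximab,
#' cyclosporine, tofacitinib, ...).
#'
#' @return A [lexicon()].
#' @export
default_drug_lexicon <- function() {
  read_lexicon(pkg_extdata("drug_lexicon.tsv"))
}

# sentences scanned for mentions: title first (when indexed), then abstract
mention_sentences <- function(corpus, include_title = TRUE) {
  lapply(seq_len(nrow(corpus)), function(i) {
    s <- split_sentences(corpus$abstract[i])
    if (include_title && !is.na(corpus$title[i]) && nzchar(corpus$title[i])) {
      s <- c(corpus$title[i], s)
    }
    s
  })
}

alternation_pattern <- function(aliases) {
  ordered <- aliases[order(-nchar(aliases), aliases)]  # longest-first
  sprintf("(?<![A-Za-z0-9])(?:%s)(?![A-Za-z0-9])",
          paste(vapply(ordered, escape_regex, character(1)), collapse = "|"))
}

scan_sentence <- function(sentence, pattern, ignore_case) {
  m <- gregexpr(pattern, sentence, perl = TRUE, ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) character() else unlist(regmatches(sentence, list(m)))
}

#' Extract dictionary-based mentions from a corpus
#'
#' Emits one mention per (record, sentence, alias occurrence), matching on
#' token boundaries under the lexicon's case rules. Each mention carries
#' the sentence in which it occurs as its context, the matched surface
#' form, and an `unreviewed` curation status.
#'
#' @param corpus A [literature_corpus()].
#' @param lex A [lexicon()] (non-empty).
#' @param include_title Scan the title as an additional context sentence?
#'   Default `TRUE`.
#' @return A tibble of class `gene_mentions` with columns `record_id`,
#'   `canonical_symbol`, `matched_alias`, `context`, `status`.
#' @export
extract_gene_mentions <- function(corpus, lex = default_gene_lexicon(),
                                  include_title = TRUE) {
  stopifnot(inherits(lex, "mention_lexicon"))
  if (length(lex$entries) == 0L) {
    oc_validation_error("lexicon has no matchable symbols", field = "lexicon")
  }
  corpus <- validate_corpus(as_tibble(corpus))
  at <- lex$alias_table
  at$cs <- at$alias %in% lex$case_sensitive_symbols
  cs_aliases <- at$alias[at$cs]
  ci_aliases <- at$alias[!at$cs]
  cs_pat <- if (length(cs_aliases)) alternation_pattern(cs_aliases) else NULL
  ci_pat <- if (length(ci_aliases)) alternation_pattern(ci_aliases) else NULL
  cs_lookup <- setNames(at$canonical[at$cs], at$alias[at$cs])
  ci_lookup <- setNames(at$canonical[!at$cs], tolower(at$alias[!at$cs]))

  sent_sets <- mention_sentences(corpus, include_title)
  out <- vector("list", nrow(corpus))
  for (i in seq_len(nrow(corpus))) {
    rows <- list()
    for (s in sent_sets[[i]]) {
      hits_cs <- if (is.null(cs_pat)) character() else
        scan_sentence(s, cs_pat, ignore_case = FALSE)
      hits_ci <- if (is.null(ci_pat)) character() else
        scan_sentence(s, ci_pat, ignore_case = TRUE)
      if (length(hits_cs) + length(hits_ci) == 0L) next
      rows[[length(rows) + 1L]] <- tibble(
        record_id = corpus$record_id[i],
        canonical_symbol = c(unname(cs_lookup[hits_cs]),
                             unname(ci_lookup[tolower(hits_ci)])),
        matched_alias = c(hits_cs, hits_ci),
        context = s
      )
    }
    out[[i]] <- if (length(rows)) dplyr::bind_rows(rows) else NULL
  }
  mentions <- dplyr::bind_rows(out)
  if (nrow(mentions) == 0L) {
    mentions <- tibble(record_id = character(), canonical_symbol = character(),
                       matched_alias = character(), context = character())
  }
  mentions$status <- rep("unreviewed", nrow(mentions))
  class(mentions) <- unique(c("gene_mentions", class(mentions)))
  mentions
}

#' Summarise a mention table
#'
#' @param mentions Output of [extract_gene_mentions()].
#' @return List with `unique_genes` (distinct canonical symbols),
#'   `articles_with_genes` (distinct records) and `total_contexts`
#'   (number of mentions).
#' @export
summarize_gene_mentions <- function(mentions) {
  list(
    unique_genes = length(unique(mentions$canonical_symbol)),
    articles_with_genes = length(unique(mentions$record_id)),
    total_contexts = nrow(mentions)
  )
}

#' Read a curation decisions file
#'
#' Format: `symbol<TAB>status<TAB>reason`, status in
#' {associated, excluded}.
#'
#' @param path Path to the TSV file.
#' @return Tibble with columns `symbol`, `status`, `reason`.
#' @export
read_decisions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  tibble(
    symbol = vapply(parts, `[[`, character(1), 1L),
    status = vapply(parts, function(p) p[2] %||% "", character(1)),
    reason = vapply(parts, function(p) if (length(p) >= 3L) p[3] else "",
                    character(1))
  )
}

#' Apply curation decisions to a gene list
#'
#' Replaces the manual reader step with an explicit decisions table. Every
#' decided symbol must belong to the gene list. Undecided symbols remain
#' `unreviewed`: they are not associated, but they are accounted for
#' separately rather than silently merged into the exclusions (so
#' `|associated| + |excluded| + |unreviewed| = |genes|` always holds).
#'
#' @param genes Character vector (set) of candidate symbols.
#' @param decisions Tibble with columns `symbol`, `status`
#'   (associated/excluded) and `reason` (required for exclusions); see
#'   [read_decisions()].
#' @return List with `associated` (character set), `unreviewed`
#'   (character set) and `ledger` (a [curation_ledger()] over the decided
#'   exclusions).
#' @export
apply_gene_curation <- function(genes, decisions) {
  genes <- unique(as.character(genes))
  decisions <- as_tibble(decisions)
  stopifnot(all(c("symbol", "status") %in% names(decisions)))
  if (!"reason" %in% names(decisions)) decisions$reason <- ""
  unknown <- setdiff(decisions$symbol, genes)
  if (length(unknown) > 0L) {
    oc_validation_error(sprintf("decision for unknown symbol: %s",
                                paste(unknown, collapse = ", ")),
                        field = "symbol")
  }
  bad_status <- setdiff(unique(decisions$status), c("associated", "excluded"))
  if (length(bad_status) > 0L) {
    oc_validation_error(sprintf("unknown curation status: %s",
                                paste(bad_status, collapse = ", ")),
                        field = "status")
  }
  excl <- decisions[decisions$status == "excluded", , drop = FALSE]
  excl$reason[!nzchar(excl$reason)] <- "excluded_by_curation"
  associated <- decisions$symbol[decisions$status == "associated"]
  unreviewed <- setdiff(genes, decisions$symbol)
  ledger <- curation_ledger(
    retrieved = length(genes),
    excluded = tibble(item_id = excl$symbol, reason = excl$reason)
  )
  list(associated = sort(unique(associated)),
       unreviewed = sort(unreviewed),
       ledger = ledger)
}

#' Rank drug mentions in a corpus
#'
#' Dictionary matching as in [extract_gene_mentions()], summarised to a
#' [word_atomize()]-style ranking of drug labels by total mention count
#' (ties broken lexicographically), with document counts alongside.
#'
#' @param corpus A [literature_corpus()].
#' @param drug_lex A [lexicon()] of drug names; default the packaged one.
#' @param include_title Scan titles as well? Default `TRUE`.
#' @return A `word_ranking` over drug labels.
#' @export
extract_drug_mentions <- function(corpus, drug_lex = default_drug_lexicon(),
                                  include_title = TRUE) {
  mentions <- extract_gene_mentions(corpus, drug_lex,
                                    include_title = include_title)
  corpus <- as_tibble(corpus)
  if (nrow(mentions) == 0L) {
    return(new_word_ranking(
      tibble(display_label = character(), token_group = list(),
             total_count = integer(), document_count = integer()),
      corpus_size = nrow(corpus)))
  }
  agg <- mentions |>
    dplyr::group_by(.data$canonical_symbol) |>
    dplyr::summarise(total_count = dplyr::n(),
                     document_count = dplyr::n_distinct(.data$record_id),
                     .groups = "drop")
  entries <- tibble(
    display_label = agg$canonical_symbol,
    token_group = unname(drug_lex$entries[agg$canonical_symbol]),
    total_count = as.integer(agg$total_count),
    document_count = as.integer(agg$document_count)
  )
  ord <- order(-entries$total_count, entries$display_label, method = "radix")
  new_word_ranking(entries[ord, , drop = FALSE], corpus_size = nrow(corpus))
}
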