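PIPELINE_CONFIG_KEYS <- c(
  "corpus", "studies", "study_exclusions", "corpus_exclusions",
  "gene_lexicon", "drug_lexicon", "keywords", "study_keywords",
  "stopwords", "synonyms", "gmt", "gene_decisions",
  "top_words", "top_sets", "include_title")

#' Read and validate a pipeline configuration
#'
#' The configuration is a single YAML (or R list) with documented keys;
#' unknown keys are rejected by name, and every referenced file must
#' exist before any stage runs.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated configuration list with class `pipeline_config`.
#' @export
read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), PIPELINE_CONFIG_KEYS)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "omicscout_config_error")
  }
  if (is.null(config$corpus)) {
    abort("config must name a `corpus` JSONL file",
          class = "omicscout_config_error")
  }
  file_keys <- intersect(names(config), c(
    "corpus", "studies", "study_exclusions", "corpus_exclusions",
    "gene_lexicon", "drug_lexicon", "keywords", "study_keywords",
    "stopwords", "synonyms", "gmt", "gene_decisions"))
  for (key in file_keys) {
    if (!file.exists(config[[key]])) {
      abort(sprintf("config key `%s` points to a missing file: %s",
                    key, config[[key]]),
            class = "omicscout_config_error")
    }
  }
  config$top_words <- config$top_words %||% 30L
  config$top_sets <- config$top_sets %||% 10L
  config$include_title <- config$include_title %||% TRUE
  structure(config, class = c("pipeline_config", "list"))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage,
                  conditionMessage(e)),
          class = "omicscout_stage_error", stage = stage)
  })
}

ledger_summary <- function(ledger) {
  list(retrieved = ledger$retrieved,
       excluded = nrow(ledger$excluded),
       retained = ledger$retained,
       reasons = as.list(table(ledger$excluded$reason)))
}

read_exclusions_tsv <- function(path, id_col) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  out <- tibble(id = df[[1]], reason = if (ncol(df) >= 2L) df[[2]] else "")
  names(out)[1] <- id_col
  out
}

#' Run the full scanning pipeline on prepared inputs
#'
#' Executes filter, word atomization, gene and drug mention extraction,
#' omics categorisation, enrichment and (when a study table is supplied)
#' study curation/tabulation in order, writing one report file per stage
#' plus a run manifest. Stage outputs carry no timestamps, so reruns on
#' identical inputs are byte-identical; run provenance (config hash,
#' input digests, timestamp, ledgers) lives only in the manifest.
#'
#' @param config A configuration (see [read_pipeline_config()]).
#' @param out_dir Output directory for reports (created if needed).
#' @param seed Integer seed recorded in the manifest (the pipeline stages
#'   are deterministic; the seed matters when the config points at
#'   generated fixtures).
#' @return The run manifest (list), invisibly; report files are written
#'   under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, seed = 1L) {
  config <- read_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ledgers <- list()

  corpus <- run_stage("fetch", read_corpus(config$corpus))
  if (!is.null(config$corpus_exclusions)) {
    cur <- run_stage("curate-corpus", apply_corpus_curation(
      corpus, read_exclusions_tsv(config$corpus_exclusions, "record_id")))
    corpus <- cur$retained
    ledgers$corpus_curation <- ledger_summary(cur$ledger)
  }
  filt <- run_stage("filter", filter_has_abstract(corpus))
  ledgers$abstract_filter <- ledger_summary(filt$ledger)
  corpus <- filt$retained

  tok_cfg <- run_stage("configure", token_config(
    stopwords = if (is.null(config$stopwords)) default_stopwords() else
      read_stopword_file(config$stopwords),
    synonym_groups = if (is.null(config$synonyms)) default_synonym_groups()
    else read_synonym_file(config$synonyms),
    include_title = isTRUE(config$include_title)))

  ranking <- run_stage("atomize",
                       word_atomize(corpus, tok_cfg, top_n = config$top_words))
  write_report(ranking, file.path(out_dir, "word_ranking.tsv"))

  gene_lex <- if (is.null(config$gene_lexicon)) default_gene_lexicon() else
    read_lexicon(config$gene_lexicon)
  mentions <- run_stage("genes", extract_gene_mentions(
    corpus, gene_lex, include_title = isTRUE(config$include_title)))
  write_report(mentions, file.path(out_dir, "gene_mentions.jsonl"),
               format = "json")
  gene_summary <- summarize_gene_mentions(mentions)
  gene_symbols <- sort(unique(mentions$canonical_symbol))
  if (!is.null(config$gene_decisions)) {
    curation <- run_stage("curate-genes", apply_gene_curation(
      gene_symbols, read_decisions(config$gene_decisions)))
    ledgers$gene_curation <- ledger_summary(curation$ledger)
    query_genes <- curation$associated
  } else {
    query_genes <- gene_symbols
  }

  drug_lex <- if (is.null(config$drug_lexicon)) default_drug_lexicon() else
    read_lexicon(config$drug_lexicon)
  drugs <- run_stage("drugs", extract_drug_mentions(
    corpus, drug_lex, include_title = isTRUE(config$include_title)))
  write_report(drugs, file.path(out_dir, "drug_ranking.tsv"))

  kw_map <- if (is.null(config$keywords)) default_keyword_map() else
    read_keyword_map(config$keywords)
  categories <- run_stage("categorize", tabulate_categories(corpus, kw_map))
  write_report(tibble(category = names(categories),
                      count = unname(categories)),
               file.path(out_dir, "categories.tsv"))

  collection <- if (is.null(config$gmt)) default_gene_sets() else
    read_gmt(config$gmt)
  enr <- run_stage("enrich", suppressWarnings(
    enrich(query_genes, collection, top_n = config$top_sets)))
  write_report(enr, file.path(out_dir, "enrichment.tsv"))

  samples <- NULL
  if (!is.null(config$studies)) {
    studies <- run_stage("scan-omics", read_studies(config$studies))
    if (!is.null(config$study_exclusions)) {
      cur <- run_stage("scan-omics", apply_study_curation(
        studies, read_exclusions_tsv(config$study_exclusions, "accession")))
      ledgers$study_curation <- ledger_summary(cur$ledger)
      studies <- cur$retained
    }
    tab <- run_stage("scan-omics", tabulate_studies(studies))
    write_report(tab, file.path(out_dir, "study_table.tsv"))
    samples <- aggregate_sample_counts(studies)
  }

  input_files <- unlist(config[intersect(names(config), c(
    "corpus", "studies", "study_exclusions", "corpus_exclusions",
    "gene_lexicon", "drug_lexicon", "keywords", "stopwords", "synonyms",
    "gmt", "gene_decisions"))])
  manifest <- list(
    tool = "omicscout",
    version = as.character(utils::packageVersion("omicscout")),
    seed = as.integer(seed),
    config_hash = string_digest(jsonlite::toJSON(unclass(config),
                                                 auto_unbox = TRUE)),
    input_digests = as.list(vapply(input_files, file_digest, character(1))),
    timestamp = format(Sys.time(), tz = "UTC"),
    ledgers = ledgers,
    gene_summary = gene_summary,
    sample_totals = samples)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Write a report table to TSV or JSON
#'
#' TSV reports are tab-separated UTF-8 with a header row; JSON reports
#' are key-stable and round-trip through [jsonlite::fromJSON()].
#'
#' @param x A report object (`word_ranking`, `enrichment_result`,
#'   `study_tabulation`, `gene_mentions` or plain data frame).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @param ... Unused.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("tsv", "json"), ...) {
  format <- tryCatch(match.arg(format), error = function(e) {
    oc_validation_error(sprintf("unsupported report format: %s", format[1]),
                        field = "format")
  })
  UseMethod("write_report")
}

report_frame <- function(x) UseMethod("report_frame")

#' @export
report_frame.word_ranking <- function(x) {
  tibble(rank = seq_len(nrow(x$entries)),
         label = x$entries$display_label,
         total_count = x$entries$total_count,
         document_count = x$entries$document_count)
}

#' @export
report_frame.enrichment_result <- function(x) {
  as_tibble(x)[, c("set_id", "description", "k", "K", "n", "N",
                   "p_raw", "p_adj")]
}

#' @export
report_frame.study_tabulation <- function(x) as_tibble(x)

#' @export
report_frame.default <- function(x) as_tibble(x)

write_frame <- function(df, path, format) {
  if (format == "tsv") {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA,
                         dataframe = "rows", pretty = TRUE)
  }
  invisible(path)
}

#' @export
write_report.gene_mentions <- function(x, path, format = c("tsv", "json"),
                                       ...) {
  format <- match.arg(format)
  if (format == "json") {
    lines <- vapply(seq_len(nrow(x)), function(i) {
      jsonlite::toJSON(as.list(as_tibble(x)[i, ]), auto_unbox = TRUE)
    }, character(1))
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(path))
  }
  write_frame(as_tibble(x), path, format)
}

#' @export
write_report.default <- function(x, path, format = c("tsv", "json"), ...) {
  format <- match.arg(format)
  write_frame(report_frame(x), path, format)
}
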