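STUDY_REPOSITORIES <- c("geo", "bioproject", "biosample", "sra",
                        "gwas_catalog", "fixture")

# Table-style layout constants: declared row/column order for tabulations
DECLARED_TYPE_ROWS <- c(
  "transcriptome", "genome", "microbiome", "proteome", "metabolome",
  "genome and transcriptome", "transcriptome and proteome",
  "transcriptome and microbiome", "genome and microbiome",
  "proteome and microbiome")
DECLARED_PAIRS <- list(
  c("genome", "transcriptome"), c("transcriptome", "proteome"),
  c("transcriptome", "microbiome"), c("genome", "microbiome"),
  c("proteome", "microbiome"))
DECLARED_DISEASE_COLS <- c(
  "atopic dermatitis", "hidradenitis suppurativa", "psoriasis",
  "dowling degos disease", "adams oliver syndrome",
  "atopic dermatitis and psoriasis")

#' Build an omics-study table
#'
#' One row per deposited study. `diseases` and `omics_types` are list
#' columns holding label sets; `sample_count` must be non-negative.
#'
#' @param accession Character vector of unique accessions.
#' @param repository One of geo, bioproject, biosample, sra, gwas_catalog,
#'   fixture.
#' @param title,summary Free-text metadata.
#' @param diseases,omics_types Lists of character vectors (label sets).
#' @param sample_count Non-negative integers (`NA` allowed; treated as 0
#'   and reported by [aggregate_sample_counts()]).
#' @return A tibble of class `omics_studies`.
#' @export
omics_studies <- function(accession, repository = "fixture", title = "",
                          summary = "", diseases = NULL, omics_types = NULL,
                          sample_count = NA_integer_) {
  n <- length(accession)
  if (is.null(diseases)) diseases <- rep(list(character()), n)
  if (is.null(omics_types)) omics_types <- rep(list(character()), n)
  studies <- tibble(
    accession = as.character(accession),
    repository = rep_len(as.character(repository), n),
    title = rep_len(as.character(title), n),
    summary = rep_len(as.character(summary), n),
    diseases = diseases,
    omics_types = omics_types,
    sample_count = rep_len(as.integer(sample_count), n)
  )
  validate_studies(studies)
}

validate_studies <- function(studies) {
  if (anyDuplicated(studies$accession)) {
    dup <- studies$accession[duplicated(studies$accession)][1]
    oc_validation_error(sprintf("duplicate accession: %s", dup),
                        field = "accession")
  }
  bad_repo <- setdiff(unique(studies$repository), STUDY_REPOSITORIES)
  if (length(bad_repo) > 0L) {
    oc_validation_error(sprintf("unknown repository: %s",
                                paste(bad_repo, collapse = ", ")),
                        field = "repository")
  }
  if (any(!is.na(studies$sample_count) & studies$sample_count < 0L)) {
    oc_validation_error("sample_count must be non-negative",
                        field = "sample_count")
  }
  bad_type <- setdiff(unique(unlist(studies$omics_types)), OMICS_BASE_CLASSES)
  if (length(bad_type) > 0L) {
    oc_validation_error(sprintf("unknown omics type: %s",
                                paste(bad_type, collapse = ", ")),
                        field = "omics_types")
  }
  class(studies) <- unique(c("omics_studies", class(studies)))
  studies
}

#' Default disease vocabulary and aliases
#'
#' The five Notch-pathway skin disorders in scope, with common
#' abbreviations and spelling variants as matching aliases.
#'
#' @return Named list: canonical disease label -> alias vector.
#' @export
default_disease_map <- function() {
  list(
    "hidradenitis suppurativa" = c("hidradenitis suppurativa",
                                   "acne inversa", "HS"),
    "dowling degos disease" = c("dowling degos disease",
                                "dowling-degos disease", "DDD"),
    "adams oliver syndrome" = c("adams oliver syndrome",
                                "adams-oliver syndrome", "AOS"),
    "psoriasis" = c("psoriasis", "psoriatic", "PS"),
    "atopic dermatitis" = c("atopic dermatitis", "atopic eczema", "AD")
  )
}

#' Default keyword map for study-level omics typing
#'
#' The literature keyword map extended with assay names that appear in
#' repository summaries but rarely in abstracts (WGS, whole-genome /
#' whole-exome sequencing, scRNA-seq, 16S rRNA).
#'
#' @return A [keyword_map()].
#' @export
default_study_keywords <- function() {
  base <- unclass(default_keyword_map())
  base$genome <- c(base$genome, "WGS", "WES", "whole-genome sequencing",
                   "whole genome sequencing", "whole-exome sequencing",
                   "whole exome sequencing", "genotyping")
  base$transcriptome <- c(base$transcriptome, "scRNA-seq", "RNA sequencing",
                          "gene expression")
  base$microbiome <- c(base$microbiome, "16S rRNA", "shotgun metagenomics")
  keyword_map(base)
}

#' Label a study table with omics types and diseases
#'
#' Keyword triggers (case-insensitive, token-boundary) are scanned over
#' title+summary; disease aliases likewise. Studies from the GWAS Catalog
#' are typed `genome` by construction. Multi-type studies keep their full
#' type set (rendered as composite rows by [tabulate_studies()]). Studies
#' with no trigger at all keep empty label sets and are flagged in the
#' `needs_curation` column.
#'
#' @param studies An [omics_studies()] table.
#' @param map A [keyword_map()]; default [default_study_keywords()].
#' @param disease_map Named list of disease aliases; default
#'   [default_disease_map()]. Abbreviation aliases (all-caps, <= 4
#'   characters) match case-sensitively.
#' @return The study table with `diseases`, `omics_types` and
#'   `needs_curation` filled.
#' @export
classify_study <- function(studies, map = default_study_keywords(),
                           disease_map = default_disease_map()) {
  studies <- validate_studies(as_tibble(studies))
  stopifnot(inherits(map, "keyword_map"))
  txt <- paste(studies$title, studies$summary)
  studies$omics_types <- lapply(seq_len(nrow(studies)), function(i) {
    types <- trigger_hits(txt[i], map)
    if (studies$repository[i] == "gwas_catalog") {
      types <- union(types, "genome")
    }
    types
  })
  studies$diseases <- lapply(txt, function(text) {
    hit <- vapply(disease_map, function(aliases) {
      any(vapply(aliases, function(a) {
        cs <- nchar(a) <= 4L && a == toupper(a)
        has_term(text, a, ignore_case = !cs)
      }, logical(1)))
    }, logical(1))
    names(disease_map)[hit]
  })
  studies$needs_curation <- lengths(studies$omics_types) == 0L |
    lengths(studies$diseases) == 0L
  studies
}

#' Apply study-level curation exclusions
#'
#' @param studies An [omics_studies()] table.
#' @param exclusions Tibble with columns `accession` and `reason`; every
#'   accession must exist in `studies`.
#' @return List with `retained` (sorted by accession) and `ledger`.
#' @export
apply_study_curation <- function(studies, exclusions) {
  studies <- validate_studies(as_tibble(studies))
  exclusions <- as_tibble(exclusions)
  stopifnot(all(c("accession", "reason") %in% names(exclusions)))
  unknown <- setdiff(exclusions$accession, studies$accession)
  if (length(unknown) > 0L) {
    oc_validation_error(sprintf("exclusion for unknown accession: %s",
                                paste(unknown, collapse = ", ")),
                        field = "accession")
  }
  ledger <- curation_ledger(
    retrieved = nrow(studies),
    excluded = tibble(item_id = exclusions$accession,
                      reason = exclusions$reason))
  keep <- !(studies$accession %in% exclusions$accession)
  retained <- studies[keep, , drop = FALSE]
  retained <- retained[order(retained$accession, method = "radix"), ,
                       drop = FALSE]
  list(retained = retained, ledger = ledger)
}

# render a type set to its tabulation row label
type_row_label <- function(types) {
  types <- sort(unique(types))
  if (length(types) == 0L) return("untyped")
  if (length(types) == 1L) return(types)
  if (length(types) == 2L) {
    for (pair in DECLARED_PAIRS) {
      if (setequal(types, pair)) return(paste(pair, collapse = " and "))
    }
  }
  "multiomics (other)"
}

# render a disease set to its tabulation column label
disease_col_label <- function(diseases) {
  diseases <- sort(unique(diseases))
  if (length(diseases) == 0L) return("uncurated")
  if (length(diseases) == 1L) return(diseases)
  if (length(diseases) == 2L) return(paste(diseases, collapse = " and "))
  "multiple (other)"
}

order_labels <- function(observed, declared, tail_labels = character()) {
  main <- c(declared[declared %in% observed],
            sort(setdiff(observed, c(declared, tail_labels))))
  c(main, tail_labels[tail_labels %in% observed])
}

#' Cross-tabulate studies by omics type and disease
#'
#' Builds the survey table: one row per omics-type label (base classes
#' and the declared composite pairs; any other multi-type combination is
#' pooled as "multiomics (other)"), one column per disease group (single
#' diseases, two-disease combinations rendered "X and Y", three or more
#' pooled as "multiple (other)"). Studies with no disease label are
#' counted under an explicit `uncurated` column, never dropped. A
#' `global` column (row sums) and `total` row (column sums) are derived.
#'
#' @param studies A labeled [omics_studies()] table (see
#'   [classify_study()] or supply labels directly).
#' @return An object of class `study_tabulation`: list with `counts`
#'   (integer matrix, rows = type labels, cols = disease labels),
#'   `global` (row sums), `total` (column sums), `grand_total`.
#' @export
tabulate_studies <- function(studies) {
  studies <- validate_studies(as_tibble(studies))
  row_lab <- vapply(studies$omics_types, type_row_label, character(1))
  col_lab <- vapply(studies$diseases, disease_col_label, character(1))
  rows <- order_labels(unique(row_lab), DECLARED_TYPE_ROWS,
                       tail_labels = c("multiomics (other)", "untyped"))
  cols <- order_labels(unique(col_lab), DECLARED_DISEASE_COLS,
                       tail_labels = c("multiple (other)", "uncurated"))
  counts <- table(factor(row_lab, levels = rows),
                  factor(col_lab, levels = cols))
  counts <- matrix(as.integer(counts), nrow = length(rows),
                   dimnames = list(omics_type = rows, disease = cols))
  structure(
    list(counts = counts,
         global = rowSums(counts),
         total = colSums(counts),
         grand_total = sum(counts)),
    class = "study_tabulation")
}

#' @export
print.study_tabulation <- function(x, ...) {
  cat(sprintf("<study_tabulation> %d studies\n", x$grand_total))
  df <- cbind(global = x$global, as.data.frame.matrix(x$counts))
  df <- rbind(df, total = c(x$grand_total, x$total))
  print(df)
  invisible(x)
}

#' Convert a study tabulation to a tidy tibble
#'
#' @param x A `study_tabulation`.
#' @param ... Unused.
#' @return Tibble with `omics_type`, `global`, one column per disease
#'   group, plus a final `total` row.
#' @exportS3Method tibble::as_tibble
as_tibble.study_tabulation <- function(x, ...) {
  df <- tibble(omics_type = rownames(x$counts),
               global = unname(x$global))
  for (cl in colnames(x$counts)) df[[cl]] <- unname(x$counts[, cl])
  total <- tibble(omics_type = "total", global = x$grand_total)
  for (cl in colnames(x$counts)) total[[cl]] <- unname(x$total[[cl]])
  dplyr::bind_rows(df, total)
}

#' Aggregate sample counts over a study table
#'
#' @param studies An [omics_studies()] table. Missing sample counts are
#'   treated as 0 and reported via `n_missing`.
#' @return List with `per_repository` (named integer vector of
#'   subtotals), `grand_total` and `n_missing`.
#' @export
aggregate_sample_counts <- function(studies) {
  studies <- validate_studies(as_tibble(studies))
  n_missing <- sum(is.na(studies$sample_count))
  counts <- ifelse(is.na(studies$sample_count), 0L, studies$sample_count)
  per_repo <- tapply(counts, studies$repository, sum)
  per_repo <- setNames(as.integer(per_repo), names(per_repo))
  list(per_repository = per_repo,
       grand_total = as.integer(sum(counts)),
       n_missing = as.integer(n_missing))
}

# ---- study table I/O --------------------------------------------------------

#' Write a study table to TSV
#'
#' Label sets are serialised as `;`-joined fields; missing sample counts
#' as empty fields.
#'
#' @param studies An [omics_studies()] table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_studies <- function(studies, path) {
  studies <- validate_studies(as_tibble(studies))
  df <- data.frame(
    accession = studies$accession,
    repository = studies$repository,
    title = studies$title,
    summary = studies$summary,
    diseases = vapply(studies$diseases, paste, character(1), collapse = ";"),
    omics_types = vapply(studies$omics_types, paste, character(1),
                         collapse = ";"),
    sample_count = ifelse(is.na(studies$sample_count), "",
                          as.character(studies$sample_count)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a study table from TSV
#'
#' @param path Path to a file as written by [write_studies()].
#' @return An [omics_studies()] table.
#' @export
read_studies <- function(path) {
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          colClasses = "character", fileEncoding = "UTF-8")
  split_field <- function(x) {
    lapply(x, function(s) if (!nzchar(s)) character() else
      strsplit(s, ";", fixed = TRUE)[[1]])
  }
  omics_studies(
    accession = df$accession,
    repository = df$repository,
    title = df$title %||% "",
    summary = df$summary %||% "",
    diseases = split_field(df$diseases %||% character(nrow(df))),
    omics_types = split_field(df$omics_types %||% character(nrow(df))),
    sample_count = suppressWarnings(as.integer(df$sample_count))
  )
}
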