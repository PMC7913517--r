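OMICS_BASE_CLASSES <- c("genome", "transcriptome", "proteome",
                        "microbiome", "metabolome")

#' Construct a keyword map for omics categorisation
#'
#' Maps each of the five base omics classes to its trigger
#' keywords/phrases. Triggers match case-insensitively on token
#' boundaries. Overlapping triggers across classes are a validation error:
#' the rule set must partition unambiguously.
#'
#' @param map Named list with exactly the five base classes as names, each
#'   a non-empty character vector of triggers.
#' @return An object of class `keyword_map`.
#' @export
keyword_map <- function(map) {
  stopifnot(is.list(map))
  missing <- setdiff(OMICS_BASE_CLASSES, names(map))
  if (length(missing) > 0L) {
    oc_validation_error(sprintf("keyword map lacks base class(es): %s",
                                paste(missing, collapse = ", ")))
  }
  map <- map[OMICS_BASE_CLASSES]
  if (any(lengths(map) == 0L)) {
    oc_validation_error("every base class needs at least one trigger")
  }
  all_trig <- tolower(unlist(map, use.names = FALSE))
  if (anyDuplicated(all_trig)) {
    dup <- all_trig[duplicated(all_trig)][1]
    oc_validation_error(sprintf("trigger '%s' is mapped to more than one class",
                                dup))
  }
  structure(lapply(map, as.character), class = "keyword_map")
}

#' Default omics keyword map for literature categorisation
#'
#' The packaged, editable rule set. Epigenome/methylome triggers fold into
#' the genome class so that the category scheme stays at five base classes
#' plus multiomics.
#'
#' @return A [keyword_map()].
#' @export
default_keyword_map <- function() {
  read_keyword_map(pkg_extdata("keyword_map.tsv"))
}

#' Read a keyword map from TSV (`class<TAB>keyword`, one trigger per line)
#'
#' @param path Path to the TSV file.
#' @return A [keyword_map()].
#' @export
read_keyword_map <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad) > 0L) {
    oc_parse_error(sprintf("keyword map line %d lacks a keyword field", bad[1]))
  }
  cls <- vapply(parts, `[[`, character(1), 1L)
  kw <- vapply(parts, `[[`, character(1), 2L)
  keyword_map(split(kw, factor(cls, levels = unique(cls))))
}

trigger_hits <- function(text, map) {
  if (is.na(text) || !nzchar(text)) return(character())
  hit <- vapply(map, function(triggers) {
    any(vapply(triggers, has_term, logical(1), text = text,
               ignore_case = TRUE))
  }, logical(1))
  names(map)[hit]
}

#' Classify one article into an omics category
#'
#' Scans title+abstract for each class's triggers. An article hitting
#' exactly one base class gets that class; two or more, `multiomics`;
#' none, `unclassified`.
#'
#' @param record A single-row [literature_corpus()] slice.
#' @param map A [keyword_map()].
#' @return List with `base_classes` (character vector) and `category`
#'   (single string).
#' @export
classify_article <- function(record, map = default_keyword_map()) {
  stopifnot(inherits(map, "keyword_map"), nrow(record) == 1L)
  text <- paste(c(record$title[[1]],
                  if (!is.na(record$abstract[[1]])) record$abstract[[1]]),
                collapse = " ")
  base <- trigger_hits(text, map)
  category <- if (length(base) == 0L) "unclassified"
  else if (length(base) == 1L) base
  else "multiomics"
  list(base_classes = base, category = category)
}

#' Tabulate omics categories over a corpus
#'
#' Applies [classify_article()] to every record and counts categories.
#' Every record lands in exactly one category, so the counts always sum
#' to the corpus size.
#'
#' @param corpus A [literature_corpus()].
#' @param map A [keyword_map()].
#' @return Named integer vector over the seven category labels (five base
#'   classes, `multiomics`, `unclassified`), in that order.
#' @export
tabulate_categories <- function(corpus, map = default_keyword_map()) {
  corpus <- validate_corpus(as_tibble(corpus))
  labels <- c(OMICS_BASE_CLASSES, "multiomics", "unclassified")
  cats <- vapply(seq_len(nrow(corpus)), function(i) {
    classify_article(corpus[i, , drop = FALSE], map)$category
  }, character(1))
  counts <- table(factor(cats, levels = labels))
  setNames(as.integer(counts), labels)
}
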