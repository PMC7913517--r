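#' Construct a query specification
#'
#' A query spec holds the disease scope, optional topic terms and an
#' organism clause from which the boolean search strings for literature and
#' omics-repository scans are rendered. Rendering is deterministic: term
#' order is preserved exactly as given.
#'
#' @param diseases Character vector of disease names (non-empty).
#' @param topic_terms Character vector of topic terms; may be empty, in
#'   which case the topic clause is omitted from rendered queries.
#' @param organism_clause Single string appended verbatim as the final
#'   clause, e.g. `"'Homo sapiens' (orgn:__txid9606)"`.
#' @return An object of class `query_spec`.
#' @export
#' @examples
#' qs <- query_spec(c("Psoriasis", "Atopic Dermatitis"),
#'                  c("Genome", "transcriptome"),
#'                  "'Homo sapiens' (orgn:__txid9606)")
#' build_literature_query(qs)
query_spec <- function(diseases, topic_terms = character(),
                       organism_clause = "'Homo sapiens' (orgn:__txid9606)") {
  if (length(diseases) == 0L || any(!nzchar(diseases))) {
    oc_validation_error("`diseases` must be a non-empty character vector",
                        field = "diseases")
  }
  if (length(organism_clause) != 1L || !nzchar(organism_clause)) {
    oc_validation_error("`organism_clause` must be a single non-empty string",
                        field = "organism_clause")
  }
  structure(
    list(diseases = as.character(diseases),
         topic_terms = as.character(topic_terms),
         organism_clause = organism_clause),
    class = "query_spec"
  )
}

or_clause <- function(terms) paste0("(", paste(terms, collapse = " OR "), ")")

#' Render the literature-scan query string
#'
#' Produces `"(D1 OR D2 OR ...) AND (T1 OR T2 OR ...) AND <organism>"`.
#' The topic clause is omitted entirely when the spec has no topic terms.
#'
#' @param spec A [query_spec()].
#' @return A single query string.
#' @export
build_literature_query <- function(spec) {
  stopifnot(inherits(spec, "query_spec"))
  clauses <- or_clause(spec$diseases)
  if (length(spec$topic_terms) > 0L) {
    clauses <- c(clauses, or_clause(spec$topic_terms))
  }
  paste(c(clauses, spec$organism_clause), collapse = " AND ")
}

#' Render the omics-repository query string
#'
#' Same rendering as [build_literature_query()] but with no topic clause by
#' construction: repository scans are scoped by disease and organism only.
#'
#' @inheritParams build_literature_query
#' @return A single query string.
#' @export
build_omics_db_query <- function(spec) {
  stopifnot(inherits(spec, "query_spec"))
  paste(c(or_clause(spec$diseases), spec$organism_clause), collapse = " AND ")
}

#' Parse a rendered query string back into a query spec
#'
#' Inverse of the query renderers: recovers the disease list, topic terms
#' (if a second parenthesised clause is present) and organism clause.
#'
#' @param query A string produced by [build_literature_query()] or
#'   [build_omics_db_query()].
#' @return A [query_spec()].
#' @export
parse_query <- function(query) {
  stopifnot(is.character(query), length(query) == 1L)
  split_group <- function(x) strsplit(x, " OR ", fixed = TRUE)[[1]]
  m <- regmatches(query, regexec("^\\(([^()]*)\\) AND (.*)$", query))[[1]]
  if (length(m) == 0L) {
    oc_parse_error("query does not start with a parenthesised disease clause")
  }
  diseases <- split_group(m[2])
  rest <- m[3]
  m2 <- regmatches(rest, regexec("^\\(([^()]*)\\) AND (.*)$", rest))[[1]]
  if (length(m2) > 0L) {
    query_spec(diseases, split_group(m2[2]), m2[3])
  } else {
    query_spec(diseases, character(), rest)
  }
}

#' Build a literature corpus
#'
#' The corpus is a tibble with one row per article. Abstracts are
#' whitespace-normalised on construction; an abstract that is absent or
#' empty after normalisation is stored as `NA`.
#'
#' @param record_id Character vector of stable identifiers (e.g. PMIDs);
#'   must be non-empty and unique.
#' @param title Character vector of titles.
#' @param abstract Character vector of abstracts (`NA` allowed).
#' @param year Integer vector of publication years (`NA` allowed).
#' @param source Record provenance, one of `"pubmed"` or `"fixture"`.
#' @param mesh_terms List of character vectors of MeSH descriptors.
#' @return A tibble of class `literature_corpus`.
#' @export
literature_corpus <- function(record_id, title, abstract = NA_character_,
                              year = NA_integer_, source = "fixture",
                              mesh_terms = NULL) {
  n <- length(record_id)
  if (is.null(mesh_terms)) mesh_terms <- rep(list(character()), n)
  corpus <- tibble(
    record_id = as.character(record_id),
    title = rep_len(as.character(title), n),
    abstract = rep_len(as.character(abstract), n),
    year = rep_len(as.integer(year), n),
    source = rep_len(as.character(source), n),
    mesh_terms = mesh_terms
  )
  corpus$abstract <- vapply(corpus$abstract, squish, character(1),
                            USE.NAMES = FALSE)
  validate_corpus(corpus)
}

validate_corpus <- function(corpus) {
  if (any(!nzchar(corpus$record_id)) || anyNA(corpus$record_id)) {
    oc_validation_error("record_id must be non-empty", field = "record_id")
  }
  if (anyDuplicated(corpus$record_id)) {
    dup <- corpus$record_id[duplicated(corpus$record_id)][1]
    oc_validation_error(sprintf("duplicate record_id in corpus: %s", dup),
                        field = "record_id")
  }
  bad <- !is.na(corpus$abstract) & !nzchar(corpus$abstract)
  if (any(bad)) corpus$abstract[bad] <- NA_character_
  class(corpus) <- unique(c("literature_corpus", class(corpus)))
  corpus
}

empty_corpus <- function() {
  literature_corpus(character(), character())
}

#' Curation ledger
#'
#' Explicit retrieved/excluded/retained accounting attached to every
#' filtering step. The conservation identity
#' `retained = retrieved - nrow(excluded)` is enforced at construction.
#'
#' @param retrieved Number of items entering the step.
#' @param excluded Tibble with columns `item_id` and `reason` (non-empty
#'   reasons), one row per removed item.
#' @return An object of class `curation_ledger`.
#' @export
curation_ledger <- function(retrieved, excluded = tibble(item_id = character(),
                                                         reason = character())) {
  retrieved <- assert_scalar_count(retrieved, "retrieved")
  excluded <- as_tibble(excluded)
  stopifnot(all(c("item_id", "reason") %in% names(excluded)))
  if (nrow(excluded) > 0L && any(!nzchar(excluded$reason))) {
    oc_validation_error("every exclusion must carry a non-empty reason",
                        field = "reason")
  }
  if (nrow(excluded) > retrieved) {
    oc_validation_error("more exclusions than retrieved items")
  }
  structure(
    list(retrieved = retrieved,
         excluded = excluded,
         retained = retrieved - nrow(excluded)),
    class = "curation_ledger"
  )
}

#' @export
print.curation_ledger <- function(x, ...) {
  cat(sprintf("<curation_ledger> retrieved %d | excluded %d | retained %d\n",
              x$retrieved, nrow(x$excluded), x$retained))
  if (nrow(x$excluded) > 0L) {
    tab <- table(x$excluded$reason)
    for (r in names(tab)) cat(sprintf("  - %s: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Filter a corpus to records with abstracts
#'
#' Records whose abstract is absent (or empty after whitespace
#' normalisation) are excluded with reason `"no_abstract"`; title-only
#' records do not survive this filter.
#'
#' @param corpus A [literature_corpus()].
#' @return A list with elements `retained` (the filtered corpus) and
#'   `ledger` (a [curation_ledger()]).
#' @export
filter_has_abstract <- function(corpus) {
  corpus <- validate_corpus(as_tibble(corpus))
  missing <- is.na(corpus$abstract)
  ledger <- curation_ledger(
    retrieved = nrow(corpus),
    excluded = tibble(item_id = corpus$record_id[missing],
                      reason = rep("no_abstract", sum(missing)))
  )
  list(retained = corpus[!missing, , drop = FALSE], ledger = ledger)
}

#' Filter a corpus to a publication-year window
#'
#' Inclusive `[from_year, to_year]` filter on the `year` field, applied
#' post-fetch (source-side date syntax varies by database, so windowing is
#' done locally). Records with missing years are excluded with reason
#' `"no_year"`.
#'
#' @param corpus A [literature_corpus()].
#' @param from_year,to_year Inclusive bounds.
#' @return A list with `retained` and `ledger`, as [filter_has_abstract()].
#' @export
filter_year_window <- function(corpus, from_year, to_year) {
  stopifnot(from_year <= to_year)
  corpus <- validate_corpus(as_tibble(corpus))
  keep <- !is.na(corpus$year) & corpus$year >= from_year & corpus$year <= to_year
  reason <- ifelse(is.na(corpus$year), "no_year", "outside_year_window")
  ledger <- curation_ledger(
    retrieved = nrow(corpus),
    excluded = tibble(item_id = corpus$record_id[!keep],
                      reason = reason[!keep])
  )
  list(retained = corpus[keep, , drop = FALSE], ledger = ledger)
}

#' Apply a curation decision list to a corpus
#'
#' Removes explicitly excluded records (e.g. reviews, protocols or
#' off-topic articles identified by a human reader) and accounts for them
#' in a ledger with their per-item reasons.
#'
#' @param corpus A [literature_corpus()].
#' @param exclusions Tibble with columns `record_id` and `reason`.
#' @return A list with `retained` and `ledger`.
#' @export
apply_corpus_curation <- function(corpus, exclusions) {
  corpus <- validate_corpus(as_tibble(corpus))
  exclusions <- as_tibble(exclusions)
  stopifnot(all(c("record_id", "reason") %in% names(exclusions)))
  unknown <- setdiff(exclusions$record_id, corpus$record_id)
  if (length(unknown) > 0L) {
    oc_validation_error(sprintf("exclusion for unknown record_id: %s",
                                paste(unknown, collapse = ", ")),
                        field = "record_id")
  }
  ledger <- curation_ledger(
    retrieved = nrow(corpus),
    excluded = tibble(item_id = exclusions$record_id,
                      reason = exclusions$reason)
  )
  keep <- !(corpus$record_id %in% exclusions$record_id)
  list(retained = corpus[keep, , drop = FALSE], ledger = ledger)
}

# ---- PubMed XML and MEDLINE readers ----------------------------------------

#' Parse PubMed efetch XML into a literature corpus
#'
#' One record per `PubmedArticle`. Multi-paragraph abstracts (several
#' `AbstractText` elements) are concatenated with single spaces; articles
#' with no `AbstractText` carry an absent abstract. Articles lacking a PMID
#' are collected as record-level errors (attached as the `"errors"`
#' attribute) rather than aborting the parse.
#'
#' @param path Path to a PubmedArticleSet XML file, or a string of XML.
#' @return A [literature_corpus()]; the `"errors"` attribute lists any
#'   records skipped for a missing PMID.
#' @export
parse_pubmed_xml <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) {
      oc_parse_error(paste0("malformed PubMed XML: ", conditionMessage(e)))
    }
  )
  articles <- xml2::xml_find_all(doc, ".//PubmedArticle")
  errors <- character()
  rows <- lapply(seq_along(articles), function(i) {
    art <- articles[[i]]
    pmid <- xml2::xml_text(xml2::xml_find_first(art, ".//MedlineCitation/PMID"))
    if (is.na(pmid) || !nzchar(pmid)) {
      errors <<- c(errors, sprintf("article %d: missing PMID", i))
      return(NULL)
    }
    title <- squish(xml2::xml_text(xml2::xml_find_first(art, ".//ArticleTitle")))
    abst_nodes <- xml2::xml_find_all(art, ".//Abstract/AbstractText")
    abstract <- if (length(abst_nodes) == 0L) {
      NA_character_
    } else {
      squish(paste(xml2::xml_text(abst_nodes), collapse = " "))
    }
    year_txt <- xml2::xml_text(
      xml2::xml_find_first(art, ".//Article/Journal/JournalIssue/PubDate/Year"))
    if (is.na(year_txt)) {
      medline_date <- xml2::xml_text(
        xml2::xml_find_first(art, ".//PubDate/MedlineDate"))
      year_txt <- stringr::str_extract(medline_date, "\\d{4}")
    }
    mesh <- xml2::xml_text(
      xml2::xml_find_all(art, ".//MeshHeadingList/MeshHeading/DescriptorName"))
    list(record_id = pmid, title = title, abstract = abstract,
         year = suppressWarnings(as.integer(year_txt)), mesh = mesh)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  corpus <- if (length(rows) == 0L) {
    empty_corpus()
  } else {
    literature_corpus(
      record_id = vapply(rows, `[[`, character(1), "record_id"),
      title = vapply(rows, `[[`, character(1), "title"),
      abstract = vapply(rows, function(r) r$abstract, character(1)),
      year = vapply(rows, `[[`, integer(1), "year"),
      source = "pubmed",
      mesh_terms = lapply(rows, `[[`, "mesh")
    )
  }
  attr(corpus, "errors") <- errors
  corpus
}

#' Parse MEDLINE plain-text records
#'
#' Recognises the `PMID-`, `TI  -`, `AB  -`, `DP  -` and `MH  -` fields;
#' continuation lines (six-space indent) are joined with single spaces.
#' Records are separated by blank lines.
#'
#' @param path Path to a MEDLINE-format text file.
#' @return A [literature_corpus()].
#' @export
parse_medline <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  recs <- list()
  cur <- NULL
  cur_tag <- NULL
  flush_field <- function() cur
  push_record <- function(fields) {
    if (is.null(fields) || is.null(fields$PMID)) return()
    recs[[length(recs) + 1L]] <<- fields
  }
  fields <- NULL
  for (ln in c(lines, "")) {
    if (!nzchar(trimws(ln))) {
      push_record(fields)
      fields <- NULL
      cur_tag <- NULL
      next
    }
    if (grepl("^[A-Z]{2,4}\\s*- ", ln)) {
      tag <- trimws(sub("-.*$", "", ln))
      val <- sub("^[A-Z]{2,4}\\s*- ", "", ln)
      if (is.null(fields)) fields <- list()
      cur_tag <- tag
      if (tag == "MH") {
        fields$MH <- c(fields$MH, trimws(val))
      } else {
        fields[[tag]] <- if (is.null(fields[[tag]])) val else
          paste(fields[[tag]], val)
      }
    } else if (grepl("^\\s{6}", ln) && !is.null(cur_tag)) {
      cont <- trimws(ln)
      if (cur_tag == "MH") {
        fields$MH[length(fields$MH)] <-
          paste(fields$MH[length(fields$MH)], cont)
      } else {
        fields[[cur_tag]] <- paste(fields[[cur_tag]], cont)
      }
    }
  }
  if (length(recs) == 0L) return(empty_corpus())
  literature_corpus(
    record_id = vapply(recs, function(r) trimws(r$PMID), character(1)),
    title = vapply(recs, function(r) squish(r$TI %||% NA_character_),
                   character(1)),
    abstract = vapply(recs, function(r) squish(r$AB %||% NA_character_),
                      character(1)),
    year = vapply(recs, function(r) {
      y <- stringr::str_extract(r$DP %||% "", "\\d{4}")
      suppressWarnings(as.integer(y))
    }, integer(1)),
    source = "pubmed",
    mesh_terms = lapply(recs, function(r) r$MH %||% character())
  )
}

# ---- JSONL corpus store -----------------------------------------------------

#' Write a corpus to a JSONL store
#'
#' One UTF-8 JSON object per line with keys `record_id`, `title`,
#' `abstract`, `year`, `source`, `mesh_terms`. Absent abstracts/years are
#' written as JSON null. Write-then-read is the identity on records.
#'
#' @param corpus A [literature_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  corpus <- validate_corpus(as_tibble(corpus))
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      record_id = corpus$record_id[i],
      title = corpus$title[i],
      abstract = corpus$abstract[i],
      year = corpus$year[i],
      source = corpus$source[i],
      mesh_terms = corpus$mesh_terms[[i]]
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a corpus from a JSONL store
#'
#' @param path Path to a file written by [write_corpus()].
#' @return A [literature_corpus()].
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_corpus())
  recs <- lapply(seq_along(lines), function(i) {
    tryCatch(jsonlite::fromJSON(lines[i]), error = function(e) {
      oc_parse_error(sprintf("corpus store line %d is not valid JSON: %s",
                             i, conditionMessage(e)))
    })
  })
  literature_corpus(
    record_id = vapply(recs, function(r) as.character(r$record_id), character(1)),
    title = vapply(recs, function(r) as.character(r$title %||% NA_character_),
                   character(1)),
    abstract = vapply(recs, function(r)
      as.character(r$abstract %||% NA_character_), character(1)),
    year = vapply(recs, function(r) {
      y <- r$year
      if (is.null(y) || length(y) == 0L) NA_integer_ else as.integer(y)
    }, integer(1)),
    source = vapply(recs, function(r) as.character(r$source %||% "fixture"),
                    character(1)),
    mesh_terms = lapply(recs, function(r) as.character(r$mesh_terms %||%
                                                         character()))
  )
}

# ---- fetch with mandatory cache --------------------------------------------

#' Fixture fetch adapter
#'
#' Wraps a pre-built corpus as a fetch adapter, the default (and the only
#' one exercised in tests): fetching never touches the network.
#'
#' @param corpus A [literature_corpus()] to serve for any query.
#' @return A function `(query) -> corpus` with attribute `source = "fixture"`.
#' @export
fixture_fetcher <- function(corpus) {
  corpus <- validate_corpus(as_tibble(corpus))
  structure(function(query) corpus, source = "fixture")
}

#' Live PubMed E-utilities fetch adapter
#'
#' Constructs an adapter that queries NCBI esearch/efetch. Live fetching
#' must be requested explicitly (`allow_network = TRUE`) and is throttled
#' to at most 3 requests per second. Network failures raise a retriable
#' error; with a warm cache [fetch_records()] never calls the adapter.
#'
#' @param allow_network Must be set to `TRUE` to permit network access.
#' @param api_key Optional NCBI API key passed through to E-utilities.
#' @param retmax Maximum number of records to retrieve.
#' @return A fetch adapter function with attribute `source = "pubmed"`.
#' @export
pubmed_fetcher <- function(allow_network = FALSE, api_key = NULL,
                           retmax = 10000L) {
  if (!isTRUE(allow_network)) {
    oc_validation_error(paste(
      "live fetching requires allow_network = TRUE;",
      "use fixture_fetcher() for offline work"), field = "allow_network")
  }
  base <- "https://eutils.ncbi.nlm.nih.gov/entrez/eutils"
  last_request <- 0
  throttle <- function() {
    wait <- 1 / 3 - (as.numeric(Sys.time()) - last_request)
    if (wait > 0) Sys.sleep(wait)
    last_request <<- as.numeric(Sys.time())
  }
  key_arg <- if (!is.null(api_key)) paste0("&api_key=", api_key) else ""
  structure(function(query) {
    tryCatch({
      throttle()
      search_url <- paste0(base, "/esearch.fcgi?db=pubmed&retmax=", retmax,
                           "&term=", utils::URLencode(query, reserved = TRUE),
                           key_arg)
      ids <- xml2::xml_text(xml2::xml_find_all(
        xml2::read_xml(search_url), "//IdList/Id"))
      if (length(ids) == 0L) return(empty_corpus())
      throttle()
      fetch_url <- paste0(base, "/efetch.fcgi?db=pubmed&retmode=xml&id=",
                          paste(ids, collapse = ","), key_arg)
      parse_pubmed_xml(fetch_url)
    }, error = function(e) {
      abort(paste0("PubMed fetch failed (retriable): ", conditionMessage(e)),
            class = "omicscout_retriable_error")
    })
  }, source = "pubmed")
}

cache_key <- function(query, source) string_digest(paste(source, query, sep = "\n"))

#' Fetch literature records through a mandatory cache
#'
#' Results are cached in `cache_dir` keyed by (query, adapter source); a
#' repeated call with a warm cache performs no fetch at all. Records are
#' returned in deterministic order (ascending `record_id`).
#'
#' @param query Query string (see [build_literature_query()]).
#' @param fetcher A fetch adapter ([fixture_fetcher()] or [pubmed_fetcher()]).
#' @param cache_dir Directory for the cache (created if needed).
#' @param refresh If `TRUE`, ignore any cached result and fetch anew.
#' @return A [literature_corpus()], sorted by `record_id`.
#' @export
fetch_records <- function(query, fetcher, cache_dir, refresh = FALSE) {
  stopifnot(is.function(fetcher))
  source <- attr(fetcher, "source") %||% "unknown"
  dir.create(cache_dir, recursive = TRUE, showWarnings = FALSE)
  key <- cache_key(query, source)
  data_path <- file.path(cache_dir, paste0(key, ".jsonl"))
  meta_path <- file.path(cache_dir, paste0(key, ".meta.json"))
  if (!refresh && file.exists(data_path)) {
    if (!file.exists(meta_path)) {
      abort(sprintf("cache entry %s has no metadata sidecar", key),
            class = "omicscout_cache_error")
    }
    meta <- tryCatch(jsonlite::fromJSON(meta_path), error = function(e) NULL)
    corpus <- tryCatch(read_corpus(data_path), error = function(e) NULL)
    if (is.null(meta) || is.null(corpus) ||
        !identical(meta$query, query) ||
        !identical(as.integer(meta$n_records), nrow(corpus))) {
      abort(sprintf("cache entry %s is corrupt or inconsistent", key),
            class = "omicscout_cache_error")
    }
    return(corpus)
  }
  corpus <- validate_corpus(as_tibble(fetcher(query)))
  corpus <- corpus[order(corpus$record_id, method = "radix"), , drop = FALSE]
  write_corpus(corpus, data_path)
  jsonlite::write_json(
    list(query = query, source = source, n_records = nrow(corpus),
         retrieved_on = format(Sys.Date())),
    meta_path, auto_unbox = TRUE)
  corpus
}
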