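test_that("literature query renders the full disease/topic/organism form", {
  qs <- query_spec(
    diseases = c("Hidradenitis Suppurativa", "Dowling Degos Disease",
                 "Adams Oliver Syndrome", "Psoriasis", "Atopic Dermatitis"),
    topic_terms = c("Genome", "transcriptome", "proteome", "epigenome",
                    "microbiome", "metagenome", "metabolome", "omic",
                    "multi-omic"),
    organism_clause = "'Homo sapiens' (orgn:__txid9606)")
  expect_identical(
    build_literature_query(qs),
    paste0("(Hidradenitis Suppurativa OR Dowling Degos Disease OR ",
           "Adams Oliver Syndrome OR Psoriasis OR Atopic Dermatitis) AND ",
           "(Genome OR transcriptome OR proteome OR epigenome OR ",
           "microbiome OR metagenome OR metabolome OR omic OR multi-omic) ",
           "AND 'Homo sapiens' (orgn:__txid9606)"))
  expect_identical(
    build_omics_db_query(qs),
    paste0("(Hidradenitis Suppurativa OR Dowling Degos Disease OR ",
           "Adams Oliver Syndrome OR Psoriasis OR Atopic Dermatitis) AND ",
           "'Homo sapiens' (orgn:__txid9606)"))
})

test_that("query rendering handles edge cases and validates input", {
  expect_identical(
    build_literature_query(query_spec("X", character(), "'Homo sapiens'")),
    "(X) AND 'Homo sapiens'")
  expect_identical(
    build_literature_query(query_spec(c("A", "B"), "t", "<org>")),
    "(A OR B) AND (t) AND <org>")
  expect_identical(build_omics_db_query(query_spec("X", character(), "<org>")),
                   "(X) AND <org>")
  # derived by manual concatenation: order must be preserved
  expect_identical(
    build_omics_db_query(query_spec(c("c", "a", "b"), character(), "o")),
    "(c OR a OR b) AND o")
  expect_error(query_spec(character(), character(), "o"),
               class = "omicscout_validation_error")
  expect_error(query_spec(c("A", ""), character(), "o"),
               class = "omicscout_validation_error")
})

test_that("rendered queries round-trip through parse_query", {
  set.seed(11)
  for (i in 1:20) {
    diseases <- replicate(sample(1:5, 1),
                          paste(sample(letters, 6), collapse = ""))
    topics <- if (i %% 2 == 0) character() else
      replicate(sample(1:4, 1), paste(sample(letters, 5), collapse = ""))
    qs <- query_spec(diseases, topics, "'Homo sapiens' (orgn:__txid9606)")
    back <- parse_query(build_literature_query(qs))
    expect_identical(back$diseases, qs$diseases)
    expect_identical(back$topic_terms, qs$topic_terms)
    expect_identical(back$organism_clause, qs$organism_clause)
  }
})

test_that("PubMed XML parsing handles abstracts, joins and missing PMIDs", {
  path <- system.file("extdata", "pubmed_sample.xml", package = "omicscout")
  corpus <- parse_pubmed_xml(path)
  expect_equal(nrow(corpus), 3L)
  expect_identical(corpus$record_id, c("10000001", "10000002", "10000003"))
  # two AbstractText sections joined with a single space
  expect_identical(
    corpus$abstract[1],
    paste("Psoriasis is a chronic inflammatory skin disease.",
          "RNA-seq revealed IL17A driven expression programs."))
  expect_true(is.na(corpus$abstract[3]))
  expect_identical(corpus$year, c(2019L, 2018L, 2020L))
  expect_identical(corpus$mesh_terms[[1]], c("Psoriasis", "Transcriptome"))

  empty <- parse_pubmed_xml("<PubmedArticleSet></PubmedArticleSet>")
  expect_equal(nrow(empty), 0L)

  expect_error(parse_pubmed_xml("<PubmedArticleSet><oops"),
               class = "omicscout_parse_error")

  no_pmid <- parse_pubmed_xml(paste0(
    "<PubmedArticleSet><PubmedArticle><MedlineCitation>",
    "<Article><ArticleTitle>t</ArticleTitle></Article>",
    "</MedlineCitation></PubmedArticle></PubmedArticleSet>"))
  expect_equal(nrow(no_pmid), 0L)
  expect_match(attr(no_pmid, "errors"), "missing PMID")
})

test_that("MEDLINE text parsing joins continuation lines", {
  path <- system.file("extdata", "medline_sample.txt", package = "omicscout")
  corpus <- parse_medline(path)
  expect_equal(nrow(corpus), 2L)
  expect_identical(corpus$title[1],
                   "Proteome analysis of stratum corneum in atopic dermatitis patients.")
  expect_match(corpus$abstract[1], "altered filaggrin processing")
  expect_identical(corpus$year, c(2017L, 2016L))
  expect_identical(corpus$mesh_terms[[1]],
                   c("Dermatitis, Atopic", "Proteomics"))
})

test_that("abstract filter conserves counts and names every exclusion", {
  corpus <- literature_corpus(
    record_id = sprintf("R%02d", 1:10),
    title = "t",
    abstract = c(rep("An abstract here.", 7), NA, "   ", NA))
  out <- filter_has_abstract(corpus)
  expect_equal(out$ledger$retrieved, 10L)
  expect_equal(out$ledger$retained, 7L)
  expect_equal(nrow(out$retained), 7L)
  expect_setequal(out$ledger$excluded$item_id, c("R08", "R09", "R10"))
  expect_true(all(out$ledger$excluded$reason == "no_abstract"))
  # conservation identity
  expect_equal(out$ledger$retained + nrow(out$ledger$excluded),
               out$ledger$retrieved)

  all_present <- filter_has_abstract(tiny_corpus()[1:3, ])
  expect_equal(nrow(all_present$ledger$excluded), 0L)

  empty <- filter_has_abstract(literature_corpus(character(), character()))
  expect_equal(empty$ledger$retrieved, 0L)
  expect_equal(empty$ledger$retained, 0L)
  expect_equal(nrow(empty$retained), 0L)
})

test_that("corpus curation excludes listed records with reasons", {
  corpus <- literature_corpus(sprintf("P%02d", 1:11), "t", "Some abstract.")
  excl <- tibble::tibble(
    record_id = sprintf("P%02d", 1:6),
    reason = c(rep("review", 4), "protocol", "not_multiomics"))
  out <- apply_corpus_curation(corpus, excl)
  expect_equal(out$ledger$retained, 5L)
  expect_equal(nrow(out$retained), 5L)
  expect_error(
    apply_corpus_curation(corpus, tibble::tibble(record_id = "NOPE",
                                                 reason = "x")),
    class = "omicscout_validation_error")
})

test_that("year-window filter is inclusive and accounts for missing years", {
  corpus <- literature_corpus(sprintf("Y%d", 1:5), "t", "Abstract text.",
                              year = c(2015L, 2016L, 2020L, 2021L, NA))
  out <- filter_year_window(corpus, 2016, 2020)
  expect_identical(out$retained$record_id, c("Y2", "Y3"))
  expect_setequal(out$ledger$excluded$reason,
                  c("outside_year_window", "no_year"))
})

test_that("JSONL corpus store round-trips records exactly", {
  corpus <- tiny_corpus()
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(corpus, path)
  back <- read_corpus(path)
  expect_identical(as.data.frame(back), as.data.frame(corpus))
  # empty corpus round-trips too
  p2 <- withr::local_tempfile(fileext = ".jsonl")
  write_corpus(literature_corpus(character(), character()), p2)
  expect_equal(nrow(read_corpus(p2)), 0L)
})

test_that("fetch caches results and never refetches on a warm cache", {
  cache <- withr::local_tempdir()
  corpus <- tiny_corpus()[c(3, 1, 2), ]  # deliberately unsorted
  calls <- 0L
  counting_fetcher <- structure(function(query) { calls <<- calls + 1L; corpus },
                                source = "fixture")
  got <- fetch_records("(X) AND org", counting_fetcher, cache)
  expect_identical(got$record_id, c("A1", "A2", "A3"))  # ascending order
  expect_equal(calls, 1L)

  # warm cache: an adapter that would fail is never called
  poison <- structure(function(query) stop("network touched"),
                      source = "fixture")
  again <- fetch_records("(X) AND org", poison, cache)
  expect_identical(as.data.frame(again), as.data.frame(got))

  # empty result is cached as well
  none <- structure(function(query) literature_corpus(character(), character()),
                    source = "fixture")
  expect_equal(nrow(fetch_records("(Y) AND org", none, cache)), 0L)
  expect_equal(nrow(fetch_records("(Y) AND org", poison, cache)), 0L)
})

test_that("cache corruption raises an explicit integrity error", {
  cache <- withr::local_tempdir()
  fetch_records("(Z) AND org", fixture_fetcher(tiny_corpus()), cache)
  meta <- list.files(cache, pattern = "meta", full.names = TRUE)
  unlink(meta)
  expect_error(
    fetch_records("(Z) AND org", fixture_fetcher(tiny_corpus()), cache),
    class = "omicscout_cache_error")
})

test_that("live fetching must be requested explicitly", {
  expect_error(pubmed_fetcher(), class = "omicscout_validation_error")
})
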