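test_that("generation is byte-identical for identical spec and seed", {
  spec <- corpus_spec(
    10,
    word_plants = list(list(tokens = "skin", document_count = 4)),
    gene_plants = list(list(symbol = "IL13", n_mentions = 3,
                            distinct_articles = 2)),
    omics_plants = c(genome = 2, multiomics = 1),
    seed = 17)
  s1 <- generate_corpus(spec)
  s2 <- generate_corpus(spec)
  expect_identical(serialize(s1, NULL), serialize(s2, NULL))
  # a different seed changes the text
  s3 <- generate_corpus(corpus_spec(
    10, word_plants = list(list(tokens = "skin", document_count = 4)),
    gene_plants = list(list(symbol = "IL13", n_mentions = 3,
                            distinct_articles = 2)),
    omics_plants = c(genome = 2, multiomics = 1), seed = 18))
  expect_false(identical(s1$records$abstract, s3$records$abstract))
})

test_that("infeasible specs are rejected up front", {
  expect_error(corpus_spec(5, word_plants = list(
    list(tokens = "skin", document_count = 6))),
    class = "omicscout_validation_error")
  expect_error(corpus_spec(5, gene_plants = list(
    list(symbol = "IL13", n_mentions = 3, distinct_articles = 6))),
    class = "omicscout_validation_error")
  expect_error(corpus_spec(5, gene_plants = list(
    list(symbol = "IL13", n_mentions = 2, distinct_articles = 3))),
    class = "omicscout_validation_error")
  expect_error(corpus_spec(5, omics_plants = c(genome = 3, microbiome = 3)),
    class = "omicscout_validation_error")
  expect_error(corpus_spec(5, omics_plants = c(spectralome = 1)),
    class = "omicscout_validation_error")
  # planted word tokens must not collide with keyword triggers
  expect_error(generate_corpus(corpus_spec(5, word_plants = list(
    list(tokens = "genome", document_count = 2)))),
    class = "omicscout_validation_error")
})

test_that("an empty spec produces an empty corpus", {
  sim <- generate_corpus(corpus_spec(0))
  expect_equal(nrow(sim$records), 0L)
  expect_equal(sim$manifest$n_documents, 0L)
})

test_that("abstracts have 3 to 8 sentences of neutral filler", {
  sim <- generate_corpus(corpus_spec(25, seed = 3))
  n_sent <- vapply(sim$records$abstract,
                   function(a) length(split_sentences(a)), integer(1))
  expect_true(all(n_sent >= 3 & n_sent <= 8))
  toks <- unique(unlist(lapply(sim$records$abstract, tokenize,
                               config = token_config())))
  # filler never collides with lexicons or triggers
  expect_length(intersect(toks, unlist(unclass(default_keyword_map()))), 0L)
  expect_length(intersect(toupper(toks),
                          names(default_gene_lexicon()$entries)), 0L)
})

test_that("manifest expectations hold for every pipeline stage", {
  spec <- corpus_spec(
    15,
    word_plants = list(
      list(label = "skin", tokens = "skin", document_count = 9),
      list(label = "immune", tokens = "immune", document_count = 4,
           per_document_occurrences = 3)),
    gene_plants = list(list(symbol = "CD200", n_mentions = 6,
                            distinct_articles = 4)),
    drug_plants = list(list(symbol = "imiquimod", n_mentions = 2,
                            distinct_articles = 2)),
    omics_plants = c(transcriptome = 4, metabolome = 2, multiomics = 3),
    seed = 23)
  sim <- generate_corpus(spec)
  m <- sim$manifest

  # document_frequency: planted counts, exactly
  df <- document_frequency(sim$records, "skin")
  expect_equal(df$count, 9L)
  expect_equal(df$percentage, 60.0)

  # word_atomize: totals and document counts from the manifest
  ranking <- word_atomize(sim$records, token_config(), top_n = 1000)
  for (w in m$words) {
    row <- ranking$entries[ranking$entries$display_label == w$label, ]
    expect_equal(row$total_count, w$total_count)
    expect_equal(row$document_count, w$document_count)
  }

  # gene and drug mentions: manifest summary met exactly
  gm <- extract_gene_mentions(sim$records, default_gene_lexicon())
  expect_equal(summarize_gene_mentions(gm),
               list(unique_genes = m$gene_summary$unique,
                    articles_with_genes = m$gene_summary$articles,
                    total_contexts = m$gene_summary$contexts))
  dr <- extract_drug_mentions(sim$records)
  expect_equal(sum(dr$entries$total_count), m$drug_summary$contexts)

  # categories: planted counts met exactly
  expect_equal(unname(tabulate_categories(sim$records)[names(m$categories)]),
               unname(m$categories))
})

test_that("study-table generation round-trips through tabulation", {
  expect_equal(nrow(generate_study_table(tibble::tibble(
    omics_label = "genome", disease_label = "psoriasis", count = 0L))), 0L)

  set.seed(13)
  cells <- tibble::tibble(
    omics_label = sample(c("genome", "transcriptome",
                           "genome and transcriptome"), 6, replace = TRUE),
    disease_label = c("psoriasis", "atopic dermatitis", "psoriasis",
                      "uncurated", "atopic dermatitis and psoriasis",
                      "psoriasis"),
    count = sample(0:20, 6))
  cells <- dplyr::summarise(
    dplyr::group_by(cells, omics_label, disease_label),
    count = sum(count), .groups = "drop")
  tab <- tabulate_studies(generate_study_table(cells, seed = 4))
  for (i in seq_len(nrow(cells))) {
    if (cells$count[i] == 0) next
    expect_equal(unname(tab$counts[cells$omics_label[i],
                                   cells$disease_label[i]]),
                 cells$count[i])
  }
  expect_equal(tab$grand_total, sum(cells$count))
})

test_that("sample-count rules hit exact totals and ranges", {
  cells <- tibble::tibble(omics_label = "transcriptome",
                          disease_label = "psoriasis", count = 75L)
  st <- generate_study_table(cells, sample_count_rule = list(type = "total",
                                                             total = 2742L),
                             seed = 1, repository = "bioproject")
  expect_equal(sum(st$sample_count), 2742L)
  expect_equal(nrow(st), 75L)

  st2 <- generate_study_table(cells, sample_count_rule = list(type = "range",
                                                              min = 5,
                                                              max = 50),
                              seed = 1)
  expect_true(all(st2$sample_count >= 5 & st2$sample_count <= 50))

  expect_identical(distribute_total(10, 3), c(4L, 3L, 3L))
  expect_identical(sum(distribute_total(32003, 184)), 32003L)
  expect_error(generate_study_table(
    tibble::tibble(omics_label = "genome", disease_label = "psoriasis",
                   count = 1L),
    sample_count_rule = list(type = "bogus")),
    class = "omicscout_validation_error")
})
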