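test_that("planted gene mentions are recovered exactly from the manifest", {
  for (seed in c(3, 14, 15)) {
    spec <- corpus_spec(
      n_documents = 8,
      gene_plants = list(
        list(symbol = "IL13", n_mentions = 5, distinct_articles = 3),
        list(symbol = "CD200R1", n_mentions = 4, distinct_articles = 4),
        list(symbol = "NOTCH1", n_mentions = 3, distinct_articles = 2)),
      seed = seed)
    sim <- generate_corpus(spec)
    mentions <- extract_gene_mentions(sim$records, default_gene_lexicon())
    counts <- table(mentions$canonical_symbol)
    for (g in sim$manifest$genes) {
      expect_equal(unname(counts[[g$symbol]]), g$n_mentions)
      got_docs <- sort(unique(
        mentions$record_id[mentions$canonical_symbol == g$symbol]))
      expect_identical(got_docs, sim$records$record_id[g$doc_ids])
    }
    expect_equal(nrow(mentions), 12L)  # 5 + 4 + 3, precision 1 on fixtures
    s <- summarize_gene_mentions(mentions)
    expect_equal(s$unique_genes, sim$manifest$gene_summary$unique)
    expect_equal(s$articles_with_genes, sim$manifest$gene_summary$articles)
    expect_equal(s$total_contexts, sim$manifest$gene_summary$contexts)
  }
})

test_that("every mention's matched alias is findable verbatim in its context", {
  sim <- generate_corpus(corpus_spec(
    6, gene_plants = list(list(symbol = "IL13", n_mentions = 4,
                               distinct_articles = 3),
                          list(symbol = "FLG", n_mentions = 2,
                               distinct_articles = 2)),
    seed = 21))
  mentions <- extract_gene_mentions(sim$records, default_gene_lexicon())
  expect_gt(nrow(mentions), 0L)
  for (i in seq_len(nrow(mentions))) {
    expect_true(grepl(mentions$matched_alias[i], mentions$context[i],
                      fixed = TRUE))
  }
  expect_true(all(mentions$status == "unreviewed"))
})

test_that("short symbols match case-sensitively; blocklist never matches", {
  lex <- default_gene_lexicon()
  corpus <- literature_corpus(
    record_id = c("M1", "M2", "M3", "M4"),
    title = "plain title",
    abstract = c(
      "We studied the impact of treatment on skin.",   # homograph, lowercase
      "The IMPACT locus was genotyped in patients.",   # exact case: hit
      "A set of rest periods was recorded.",           # blocklisted words
      "Expression of C3 was elevated in lesions."))    # short symbol, exact
  mentions <- extract_gene_mentions(corpus, lex)
  expect_false("M1" %in% mentions$record_id)
  expect_true(any(mentions$record_id == "M2" &
                    mentions$canonical_symbol == "IMPACT"))
  expect_false("M3" %in% mentions$record_id)
  expect_true(any(mentions$record_id == "M4" &
                    mentions$canonical_symbol == "C3"))
  # lowercase "c3" does not match a short (case-sensitive) symbol
  lower <- literature_corpus("M5", "t", "the c3 fraction was measured.")
  expect_equal(nrow(extract_gene_mentions(lower, lex)), 0L)
})

test_that("long symbols match case-insensitively and aliases map to canonicals", {
  corpus <- literature_corpus(
    "A1", "t", "Filaggrin breakdown products fell. Dupilumab was effective.")
  gm <- extract_gene_mentions(corpus, default_gene_lexicon())
  expect_true(any(gm$canonical_symbol == "FLG" &
                    gm$matched_alias == "Filaggrin"))
  dm <- extract_gene_mentions(corpus, default_drug_lexicon())
  expect_true(any(dm$canonical_symbol == "dupilumab"))
})

test_that("corpus without lexicon tokens yields no mentions", {
  sim <- generate_corpus(corpus_spec(5, seed = 4))
  mentions <- extract_gene_mentions(sim$records, default_gene_lexicon())
  expect_equal(nrow(mentions), 0L)
  s <- summarize_gene_mentions(mentions)
  expect_equal(unlist(s), c(unique_genes = 0L, articles_with_genes = 0L,
                            total_contexts = 0L))
})

test_that("mention summaries count genes, articles and contexts", {
  mentions <- tibble::tibble(
    record_id = c("R1", "R1", "R2"),
    canonical_symbol = c("IL13", "FLG", "IL13"),
    matched_alias = c("IL13", "FLG", "IL13"),
    context = "ctx", status = "unreviewed")
  expect_equal(summarize_gene_mentions(mentions),
               list(unique_genes = 2L, articles_with_genes = 2L,
                    total_contexts = 3L))
})

test_that("gene curation conserves counts and tracks the unreviewed", {
  genes <- sprintf("G%03d", 1:546)
  decisions <- tibble::tibble(
    symbol = genes[1:506],
    status = c(rep("associated", 426), rep("excluded", 80)),
    reason = c(rep("", 426), rep("not_disease_related", 80)))
  out <- apply_gene_curation(genes, decisions)
  expect_equal(length(out$associated), 426L)
  expect_equal(nrow(out$ledger$excluded), 80L)
  expect_equal(length(out$unreviewed), 40L)
  # conservation: associated + excluded + unreviewed = all genes
  expect_equal(length(out$associated) + nrow(out$ledger$excluded) +
                 length(out$unreviewed), length(genes))
  expect_equal(out$ledger$retained, 546L - 80L)

  none <- apply_gene_curation(genes, decisions[0, ])
  expect_equal(length(none$associated), 0L)
  expect_equal(nrow(none$ledger$excluded), 0L)
  expect_equal(length(none$unreviewed), 546L)

  all_out <- apply_gene_curation(c("A", "B"), tibble::tibble(
    symbol = c("A", "B"), status = "excluded", reason = "r"))
  expect_equal(length(all_out$associated), 0L)
  expect_equal(all_out$ledger$retained, 0L)

  expect_error(
    apply_gene_curation("A", tibble::tibble(symbol = "Z",
                                            status = "excluded",
                                            reason = "r")),
    class = "omicscout_validation_error")
  expect_error(
    apply_gene_curation("A", tibble::tibble(symbol = "A",
                                            status = "maybe", reason = "")),
    class = "omicscout_validation_error")
})

test_that("drug ranking orders by mention count and ships the named drugs", {
  corpus <- literature_corpus(
    record_id = c("D1", "D2"),
    title = "t",
    abstract = c(
      "Dupilumab improved lesions. Dupilumab also reduced itch. Dupilumab won.",
      "Etanercept was compared with placebo."))
  ranking <- extract_drug_mentions(corpus)
  expect_identical(ranking$entries$display_label[1], "dupilumab")
  expect_equal(ranking$entries$total_count[1], 3L)
  expect_equal(ranking$entries$document_count[1], 1L)

  empty <- extract_drug_mentions(literature_corpus(character(), character()))
  expect_equal(nrow(empty$entries), 0L)

  named <- c("imiquimod", "dupilumab", "adalimumab", "ustekinumab",
             "methotrexate", "secukinumab", "etanercept", "infliximab",
             "cyclosporine", "tofacitinib")
  expect_true(all(named %in% names(default_drug_lexicon()$entries)))
})

test_that("planted drug mentions are recovered with precision one", {
  sim <- generate_corpus(corpus_spec(
    6, drug_plants = list(
      list(symbol = "dupilumab", n_mentions = 3, distinct_articles = 2),
      list(symbol = "etanercept", n_mentions = 1, distinct_articles = 1)),
    seed = 31))
  ranking <- extract_drug_mentions(sim$records)
  e <- ranking$entries
  expect_identical(e$display_label, c("dupilumab", "etanercept"))
  expect_identical(e$total_count, c(3L, 1L))
  expect_identical(e$document_count, c(2L, 1L))
})
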