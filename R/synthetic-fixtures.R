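# Neutral filler vocabulary: pronounceable nonwords, disjoint by
# construction from every packaged lexicon, trigger and stopword list
# (checked again at generation time), so planted counts are provably exact.
FILLER_VOCAB <- c(
  "abrelin", "ancrevo", "ardmel", "baltrev", "bentrilo", "berquil",
  "blenmar", "bortev", "brelcin", "brindova", "calmire", "cantrev",
  "cendrilo", "clamber", "cordvel", "crentil", "dalvore", "dempril",
  "dorvane", "drelmot", "elbrin", "entrevo", "ervandil", "faldrex",
  "fenquor", "fermilo", "flandrev", "fornelle", "galdrin", "gelmore",
  "glenvor", "gorbindal", "grelfin", "haldrevo", "helmquist", "hindrelo",
  "holvane", "imbrelo", "indrivex", "jalmore", "jendrik", "jorvale",
  "kelbrind", "kindrevo", "kolvane", "krentillo", "lambrev", "lendrio",
  "lorvette", "lumbrex", "maldrevo", "mendrilo", "morvane", "murbelt",
  "nalbrine", "nendrik", "norvelle", "nubrello", "olbrind", "ondrevale",
  "orvante", "palbrex", "pendrillo", "polvane", "prandevo", "quelbrin",
  "quindrel", "ralvone", "rembrilo", "rindovel", "rolvante", "rumbledor",
  "salbrine", "sendrovel", "sindrel", "solvante", "strelbin", "sulbrex",
  "talvorne", "tendrilo", "tindrevale", "tolbrine", "trandevo", "turbelline",
  "ulbrind", "undrevale", "urvante", "valbrex", "vendrillo", "vindrel",
  "volbane", "vrandel", "walbrine", "wendrovel", "windrel", "wolvante",
  "xalbrine", "xendril", "yalvorne", "yendrilo", "zalbrex", "zendrovel",
  "zindrel", "zolvante", "zumbrell", "quorvane", "plimdrex", "sorvelte",
  "kranmiel", "doltrevin", "fembrook", "garvelin", "hulprine", "jextrilo",
  "lompraven", "nister", "ostrevil", "pulgrane", "renvolt", "sablemir",
  "tregmund", "ulvreska", "vomtrel", "wexlind", "yubrant", "zifmore")

#' Specification of a synthetic literature corpus
#'
#' Declares the corpus size and the structure to plant: word groups with
#' exact document counts and per-document occurrence counts, gene and
#' drug mentions with exact mention/article counts, and omics-category
#' memberships. Generation is fully deterministic given the seed, and the
#' accompanying manifest states the exact expected output of every
#' downstream pipeline stage.
#'
#' @param n_documents Number of articles to generate.
#' @param word_plants List of plants, each
#'   `list(label=, tokens=, document_count=, per_document_occurrences=)`
#'   (label/occurrences optional; defaults: first token, 1).
#' @param gene_plants List of plants, each
#'   `list(symbol=, n_mentions=, distinct_articles=)`.
#' @param drug_plants As `gene_plants`.
#' @param omics_plants Named integer vector: category (base class or
#'   `"multiomics"`) -> number of documents; categories are planted in
#'   disjoint document sets, so the remaining documents are
#'   `unclassified`.
#' @param seed Integer RNG seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_documents, word_plants = list(),
                        gene_plants = list(), drug_plants = list(),
                        omics_plants = integer(), seed = 1L) {
  n_documents <- assert_scalar_count(n_documents, "n_documents")
  norm_word <- function(p) {
    stopifnot(!is.null(p$tokens), !is.null(p$document_count))
    list(label = p$label %||% p$tokens[[1]],
         tokens = as.character(p$tokens),
         document_count = assert_scalar_count(p$document_count,
                                              "document_count"),
         per_document_occurrences = assert_scalar_count(
           p$per_document_occurrences %||% 1L, "per_document_occurrences"))
  }
  norm_mention <- function(p) {
    stopifnot(!is.null(p$symbol), !is.null(p$n_mentions))
    out <- list(symbol = as.character(p$symbol),
                n_mentions = assert_scalar_count(p$n_mentions, "n_mentions"),
                distinct_articles = assert_scalar_count(
                  p$distinct_articles %||% min(p$n_mentions, n_documents),
                  "distinct_articles"))
    if (out$distinct_articles > out$n_mentions) {
      oc_validation_error(sprintf(
        "plant %s: distinct_articles exceeds n_mentions", out$symbol))
    }
    out
  }
  spec <- structure(
    list(n_documents = n_documents,
         word_plants = lapply(word_plants, norm_word),
         gene_plants = lapply(gene_plants, norm_mention),
         drug_plants = lapply(drug_plants, norm_mention),
         omics_plants = omics_plants,
         seed = as.integer(seed)),
    class = "corpus_spec")
  validate_corpus_spec(spec)
}

validate_corpus_spec <- function(spec) {
  n <- spec$n_documents
  for (p in spec$word_plants) {
    if (p$document_count > n) {
      oc_validation_error(sprintf(
        "word plant '%s': document_count %d exceeds corpus size %d",
        p$label, p$document_count, n))
    }
  }
  for (p in c(spec$gene_plants, spec$drug_plants)) {
    if (p$distinct_articles > n) {
      oc_validation_error(sprintf(
        "mention plant %s: distinct_articles %d exceeds corpus size %d",
        p$symbol, p$distinct_articles, n))
    }
  }
  if (length(spec$omics_plants) > 0L) {
    bad <- setdiff(names(spec$omics_plants),
                   c(OMICS_BASE_CLASSES, "multiomics"))
    if (length(bad) > 0L) {
      oc_validation_error(sprintf("unknown omics plant category: %s",
                                  paste(bad, collapse = ", ")))
    }
    if (sum(spec$omics_plants) > n) {
      oc_validation_error(sprintf(
        "omics plants (%d documents) exceed corpus size %d",
        sum(spec$omics_plants), n))
    }
  }
  spec
}

# every token the generator may emit on purpose
planted_tokens <- function(spec, map) {
  c(unlist(lapply(spec$word_plants, `[[`, "tokens"), use.names = FALSE),
    vapply(spec$gene_plants, `[[`, character(1), "symbol"),
    vapply(spec$drug_plants, `[[`, character(1), "symbol"),
    unlist(unclass(map), use.names = FALSE))
}

check_filler_disjoint <- function(spec, map) {
  reserved <- tolower(planted_tokens(spec, map))
  clash <- intersect(FILLER_VOCAB, reserved)
  if (length(clash) > 0L) {
    oc_validation_error(sprintf(
      "filler vocabulary collides with planted tokens: %s",
      paste(clash, collapse = ", ")))
  }
}

# planted structures must not interfere with one another: a word token
# that is also a keyword trigger (or a mention symbol) would corrupt the
# exactness guarantees of the manifest
check_plant_disjoint <- function(spec, map) {
  word_tokens <- tolower(unlist(lapply(spec$word_plants, `[[`, "tokens"),
                                use.names = FALSE))
  symbols <- tolower(c(vapply(spec$gene_plants, `[[`, character(1), "symbol"),
                       vapply(spec$drug_plants, `[[`, character(1), "symbol")))
  triggers <- tolower(unlist(unclass(map), use.names = FALSE))
  complain <- function(what, clash) {
    if (length(clash) > 0L) {
      oc_validation_error(sprintf("%s: %s", what,
                                  paste(unique(clash), collapse = ", ")))
    }
  }
  complain("word-plant token duplicated across plants",
           word_tokens[duplicated(word_tokens)])
  complain("mention symbol duplicated across plants",
           symbols[duplicated(symbols)])
  complain("word-plant token collides with a keyword trigger",
           intersect(word_tokens, triggers))
  complain("mention symbol collides with a keyword trigger",
           intersect(symbols, triggers))
  complain("word-plant token collides with a mention symbol",
           intersect(word_tokens, symbols))
}

cap_first <- function(x) sub("^(.)", "\\U\\1", x, perl = TRUE)

# insert a token at a random position >= 2 of a random sentence, so the
# sentence-initial capitalisation never touches a planted surface form
insert_token <- function(sentences, token) {
  si <- if (length(sentences) == 1L) 1L else sample.int(length(sentences), 1L)
  words <- sentences[[si]]
  pos <- if (length(words) < 2L) length(words) + 1L else
    sample(2:(length(words) + 1L), 1L)
  sentences[[si]] <- append(words, token, after = pos - 1L)
  sentences
}

#' Generate a synthetic literature corpus with planted structure
#'
#' Filler text is drawn from the packaged neutral vocabulary (disjoint
#' from all planted tokens, lexicon symbols and keyword triggers; checked
#' at generation time), so every planted count is exactly recoverable.
#' Abstracts are 3-8 sentences, exercising sentence-context extraction.
#'
#' @param spec A [corpus_spec()].
#' @param map The [keyword_map()] whose triggers realise the omics plants
#'   (default [default_keyword_map()]).
#' @return List with `records` (a [literature_corpus()]) and `manifest`,
#'   a planting record stating the exact expected outputs of
#'   [word_atomize()], [document_frequency()], [extract_gene_mentions()],
#'   [extract_drug_mentions()] and [tabulate_categories()].
#' @export
generate_corpus <- function(spec, map = default_keyword_map()) {
  stopifnot(inherits(spec, "corpus_spec"))
  check_filler_disjoint(spec, map)
  check_plant_disjoint(spec, map)
  n <- spec$n_documents
  if (n == 0L) {
    return(list(records = empty_corpus(),
                manifest = list(n_documents = 0L, seed = spec$seed)))
  }
  withr::with_seed(spec$seed, {
    titles <- replicate(n, sample(FILLER_VOCAB, 3L), simplify = FALSE)
    docs <- replicate(n, {
      n_sent <- sample(3:8, 1L)
      replicate(n_sent, sample(FILLER_VOCAB, sample(5:9, 1L), replace = TRUE),
                simplify = FALSE)
    }, simplify = FALSE)

    # omics plants: disjoint document sets per category
    cat_assign <- setNames(rep(NA_character_, n), NULL)
    if (length(spec$omics_plants) > 0L) {
      pool <- sample.int(n)
      offset <- 0L
      for (cat in names(spec$omics_plants)) {
        k <- spec$omics_plants[[cat]]
        ids <- pool[seq_len(k) + offset]
        offset <- offset + k
        cat_assign[ids] <- cat
        triggers <- if (cat == "multiomics") {
          c(map$genome[1], map$transcriptome[1])
        } else {
          map[[cat]][1]
        }
        for (id in ids) {
          for (tr in triggers) docs[[id]] <- insert_token(docs[[id]], tr)
        }
      }
    }

    # word plants: exact document counts and per-document occurrences
    word_manifest <- lapply(spec$word_plants, function(p) {
      ids <- sample.int(n, p$document_count)
      n_tok <- length(p$tokens)
      for (j in seq_along(ids)) {
        # rotate through the token group across documents and occurrences
        # so every surface form is exercised
        toks <- p$tokens[((j - 1L) * p$per_document_occurrences +
                            seq_len(p$per_document_occurrences) - 1L) %%
                           n_tok + 1L]
        for (tk in toks) docs[[ids[j]]] <<- insert_token(docs[[ids[j]]], tk)
      }
      list(label = p$label, tokens = p$tokens,
           total_count = p$document_count * p$per_document_occurrences,
           document_count = p$document_count, doc_ids = sort(ids))
    })

    plant_mentions <- function(plants) {
      lapply(plants, function(p) {
        ids <- sample.int(n, p$distinct_articles)
        alloc <- rep(1L, p$distinct_articles)
        extra <- p$n_mentions - p$distinct_articles
        if (extra > 0L) {
          idx <- rep_len(seq_len(p$distinct_articles), extra)
          alloc <- alloc + tabulate(idx, nbins = p$distinct_articles)
        }
        for (j in seq_along(ids)) {
          for (rep_i in seq_len(alloc[j])) {
            docs[[ids[j]]] <<- insert_token(docs[[ids[j]]], p$symbol)
          }
        }
        list(symbol = p$symbol, n_mentions = p$n_mentions,
             doc_ids = sort(ids))
      })
    }
    gene_manifest <- plant_mentions(spec$gene_plants)
    drug_manifest <- plant_mentions(spec$drug_plants)

    abstracts <- vapply(docs, function(sents) {
      paste(vapply(sents, function(w)
        paste0(cap_first(paste(w, collapse = " ")), "."), character(1)),
        collapse = " ")
    }, character(1))
    records <- literature_corpus(
      record_id = sprintf("SYN%05d", seq_len(n)),
      title = vapply(titles, function(w)
        cap_first(paste(w, collapse = " ")), character(1)),
      abstract = abstracts,
      year = 2016L + (seq_len(n) %% 5L),
      source = "fixture")
  })

  mention_summary <- function(manifest) {
    list(unique = length(manifest),
         articles = length(unique(unlist(lapply(manifest, `[[`, "doc_ids")))),
         contexts = sum(vapply(manifest, `[[`, integer(1), "n_mentions")))
  }
  planted_cats <- table(factor(cat_assign,
                               levels = c(OMICS_BASE_CLASSES, "multiomics")))
  categories <- c(setNames(as.integer(planted_cats), names(planted_cats)),
                  unclassified = n - as.integer(sum(planted_cats)))
  manifest <- list(
    n_documents = n,
    seed = spec$seed,
    words = word_manifest,
    genes = gene_manifest,
    gene_summary = mention_summary(gene_manifest),
    drugs = drug_manifest,
    drug_summary = mention_summary(drug_manifest),
    categories = categories)
  list(records = records, manifest = manifest)
}

#' Generate a study table realising exact tabulation targets
#'
#' Builds one study record per planted cell so that [tabulate_studies()]
#' on the output reproduces `target_cells` exactly. Sample counts follow
#' the given rule.
#'
#' @param target_cells Data frame with columns `omics_label` (a type row
#'   label, e.g. `"transcriptome"` or `"genome and transcriptome"`),
#'   `disease_label` (a disease column label, e.g. `"psoriasis"` or
#'   `"atopic dermatitis and psoriasis"`; `"uncurated"` for none) and
#'   `count`.
#' @param sample_count_rule One of `list(type = "constant", value = v)`,
#'   `list(type = "range", min =, max =)` (seeded uniform draw) or
#'   `list(type = "total", total = t)` (distributes `t` exactly over the
#'   generated records: floor share plus one for the first remainder
#'   records).
#' @param seed Integer RNG seed.
#' @param repository Repository tag for the generated records.
#' @return An [omics_studies()] table with planted labels filled in.
#' @export
generate_study_table <- function(target_cells,
                                 sample_count_rule = list(type = "constant",
                                                          value = 10L),
                                 seed = 1L, repository = "fixture") {
  target_cells <- as_tibble(target_cells)
  stopifnot(all(c("omics_label", "disease_label", "count") %in%
                  names(target_cells)))
  if (any(target_cells$count < 0)) {
    oc_validation_error("cell counts must be non-negative", field = "count")
  }
  parse_types <- function(lab) {
    if (lab == "untyped") return(character())
    types <- strsplit(lab, " and ", fixed = TRUE)[[1]]
    bad <- setdiff(types, OMICS_BASE_CLASSES)
    if (length(bad) > 0L) {
      oc_validation_error(sprintf("unparseable omics row label: %s", lab))
    }
    types
  }
  parse_diseases <- function(lab) {
    if (lab == "uncurated") return(character())
    strsplit(lab, " and ", fixed = TRUE)[[1]]
  }
  types <- list(); diseases <- list()
  for (i in seq_len(nrow(target_cells))) {
    cnt <- target_cells$count[i]
    if (cnt == 0L) next
    types <- c(types, rep(list(parse_types(target_cells$omics_label[i])), cnt))
    diseases <- c(diseases,
                  rep(list(parse_diseases(target_cells$disease_label[i])), cnt))
  }
  k <- length(types)
  if (k == 0L) {
    return(omics_studies(character()))
  }
  counts <- withr::with_seed(seed, switch(
    sample_count_rule$type,
    constant = rep(as.integer(sample_count_rule$value), k),
    range = sample(sample_count_rule$min:sample_count_rule$max, k,
                   replace = TRUE),
    total = distribute_total(sample_count_rule$total, k),
    oc_validation_error(sprintf("unknown sample_count_rule type: %s",
                                sample_count_rule$type))))
  omics_studies(
    accession = sprintf("SYNS%05d", seq_len(k)),
    repository = repository,
    title = sprintf("synthetic study %d", seq_len(k)),
    summary = "synthetic fixture record",
    diseases = diseases,
    omics_types = types,
    sample_count = counts)
}

#' Distribute an exact total over k records
#'
#' Floor share for everyone, plus one for the first `total %% k` records;
#' the parts always sum exactly to `total`.
#'
#' @param total Non-negative integer total.
#' @param k Number of parts (>= 1).
#' @return Integer vector of length `k` summing to `total`.
#' @export
distribute_total <- function(total, k) {
  total <- assert_scalar_count(total, "total")
  k <- assert_scalar_count(k, "k")
  if (k == 0L) oc_validation_error("k must be >= 1", field = "k")
  base <- total %/% k
  rem <- total %% k
  as.integer(base + (seq_len(k) <= rem))
}
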