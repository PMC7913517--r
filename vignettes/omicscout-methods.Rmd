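---
title: "Methods: scanning, atomization, categorisation and enrichment in omicscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scanning, atomization, categorisation and enrichment in omicscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicscout)
```

## Scope and model of the pipeline

`omicscout` implements the first, desk-scale phase of a disease-scoped
multiomics survey: interrogate the literature and the public omics
repositories for a fixed set of disorders, decompose what comes back into
counted units (words, gene and drug mentions, omics categories), and
tabulate the deposited studies by omics type and disorder. Everything
downstream of retrieval is deterministic, so the scientific contract of the
package is *accounting*: each filtering step returns a curation ledger in
which `retained = retrieved − |excluded|` holds exactly and every excluded
item carries a reason. Raw-data re-analysis and meta-analytic integration
of the retrieved studies are deliberately out of scope.

Two practical constraints shaped the design. First, live repository
queries drift: the same boolean term returns different counts a year
apart, and a survey's headline retrieval numbers are snapshots, not
reproducible quantities. The package therefore treats retrieval as an
exchangeable adapter (a rate-limited E-utilities client or a fixture) over
a mandatory cache, and all testing is done against synthetic corpora with
*planted* structure whose expected counts are known exactly. Second, the
association judgement — "is this gene actually related to the disease?" —
was a human step in the original workflow. It is not automated here;
it is replaced by a decisions file (symbol, status, reason) applied by
`apply_gene_curation()`, which additionally tracks an `unreviewed`
category so that decided and undecided symbols are never conflated.

## Query construction

`build_literature_query()` renders
`(D1 OR D2 OR …) AND (T1 OR T2 OR …) AND <organism clause>`, preserving
term order and omitting the topic clause entirely when no topic terms are
given; `build_omics_db_query()` is the same with no topic clause by
construction. Rendering is invertible (`parse_query()`), which the tests
use as a round-trip property. The organism clause is passed through
verbatim because its syntax is database-specific.

Date windowing ("the last five years") is applied post-fetch as an
inclusive `[from_year, to_year]` filter on the record's year
(`filter_year_window()`), since source-side date syntax varies across
databases.

## Word atomization

Tokens are maximal runs of letters, digits and hyphens — so `IL-13`
survives as one token — case-folded by default, with a minimum length of
2 and a packaged snowball-style English stopword list. Domain words are
deliberately *not* stopworded: in a disease-scoped corpus, "skin" and
"patients" ranking at the top is a finding, not noise.

Synonym handling is config-driven rather than stemmed: a synonym file maps
a display label (e.g. `inflammatory/inflammation`) to its surface tokens,
and the packaged defaults contain only the visibly grouped labels plus a
small set of singular/plural folds. A stemmer would fold more
aggressively but would make every count unauditable; with explicit
groups, each grouping decision is a reviewable line in a TSV.

The ranking key is the total mention count, with ties broken
lexicographically on the display label; the per-document count is reported
alongside. Whether a published "top cited" ranking used mentions or
documents is generally not stated, so both are computed and the rank is
defined on mentions. Percentages (document frequency) are rounded half-up
to one decimal, matching the convention of printed survey statistics such
as 63.4%; for an empty corpus the percentage is reported as absent rather
than zero. Titles are indexed together with abstracts by default
(`include_title` in `token_config()`), since scan metadata beyond the
abstract is part of what repositories expose; the switch exists because
the alternative convention (abstract-only) is also defensible.

## Gene and drug mention extraction

Matching is dictionary-based and token-boundary exact; hyphens count as
boundaries, so `IL13` is found inside `IL13-driven`. The case rule is the
package's main precision control, standing in for the manual curation a
human reader would apply: aliases of four characters or fewer match
case-sensitively (short symbols such as `C3`, `SET` or `REST` are dense in
English homographs), longer aliases case-insensitively, and a blocklist of
symbols is never matched at all. On synthetic corpora without adversarial
homographs the extractor is exact (recall and precision 1); with planted
homographs, precision is maintained by the case rule and blocklist — both
properties are asserted in the tests. Every emitted mention carries the
sentence in which it occurred (sentences split at `.`/`!`/`?` followed by
whitespace and a capital), the matched surface form verbatim, and an
`unreviewed` status.

The packaged gene lexicon is an HGNC-style table of roughly 215 symbols
relevant to inflammatory skin disease; it is a convenience default for
examples and tests, and any full lexicon in the same TSV dialect can be
substituted. The drug lexicon ships the biologics and small molecules
recurrent in this literature (imiquimod, dupilumab, adalimumab,
ustekinumab, methotrexate, secukinumab, etanercept, infliximab,
cyclosporine, tofacitinib, and others).

## Omics categorisation

Articles are assigned to base classes by keyword triggers matched
case-insensitively on token boundaries over title+abstract. The category
is the single triggered class, `multiomics` when two or more classes
trigger, `unclassified` when none does — so categories partition the
corpus and always sum to its size. The packaged trigger map folds
epigenome/methylome terms into the genome class, keeping the scheme at
five base classes plus `multiomics`. Trigger maps are validated for
cross-class overlaps (a trigger in two classes would silently inflate
`multiomics`). The published survey this design mirrors did not disclose
its trigger list, so categorical counts on real corpora depend on the map
supplied; the packaged map is an editable default, not a canonical one.

Study-level typing (`classify_study()`) uses the same engine with an
extended default map (`WGS`, `whole-genome sequencing`, `scRNA-seq`,
`16S rRNA`, …) because repository summaries name assays rather than omics
layers; GWAS Catalog records are typed `genome` by construction. Disease
labels come from an alias map of the five disorders in scope, with
all-caps abbreviations (`AD`, `PS`, `HS`, …) matched case-sensitively.

## Study tabulation

`tabulate_studies()` renders each study's type set as a row label — the
five base classes, the five composite pairs observed in this literature
(genome+transcriptome, transcriptome+proteome, transcriptome+microbiome,
genome+microbiome, proteome+microbiome), and a pooled
`multiomics (other)` row for anything else — and its disease set as a
column (single disorders; two-disorder combinations rendered
"X and Y"; three or more pooled as `multiple (other)`). Studies with no
disease label land in an explicit `uncurated` column rather than being
dropped. The `global` column and `total` row are derived sums, so the
marginal identities (row sums, column sums, grand total) hold exactly by
construction and are re-asserted over randomized fixtures in the tests.

## Over-representation analysis

The hypergeometric upper tail and the Benjamini–Hochberg adjustment are
implemented in the package itself (this machinery is the analytical core,
so it is authored rather than delegated); `stats::phyper` and
`stats::p.adjust` serve only as independent cross-checks in the test
suite, alongside an exact enumeration oracle. The tail is accumulated in
log space from `lchoose` terms with a log-sum-exp reduction, uses the
support's true lower bound, applies no continuity correction, and agrees
with exact rational enumeration to better than 12 significant digits over
every admissible configuration with `N ≤ 25` (where integer binomial
products are themselves exact in doubles).

Conventions, where the field is genuinely split:

- the default universe is the union of collection members, overridable by
  a supplied universe; query genes outside the universe are dropped with
  a warning after an explicit intersection (least-surprising ORA
  behaviour, and the dropped set is attached to the result);
- sets with zero overlap are excluded from the *report* but included in
  the BH family size `m` — the family is all tested sets;
- the report is ordered by raw p-value with ties broken on set id and
  truncated to `top_n` only after adjustment.

The packaged 40-set collection uses Reactome-style and GO-style
identifiers as label data over the packaged lexicon; it demonstrates
report shape and is not a pathway database. Published top-10 enrichment
tables typically omit p-values and universe definitions, so a ranking on
real data is not a comparable target — the report schema is.

## The synthetic-fixture generator

`generate_corpus()` is first-class, tested code, not a convenience: it is
how the pipeline's exactness claims are made checkable. A `corpus_spec`
plants (i) word groups with an exact document count and per-document
occurrence count, (ii) gene/drug mentions with exact mention and article
counts, and (iii) omics-category memberships over disjoint document sets.
All remaining text is drawn from a packaged vocabulary of pronounceable
nonwords, checked at generation time to be disjoint from every planted
token, lexicon alias, and keyword trigger; plants are also checked for
mutual interference (a planted word that is also a trigger would corrupt
the category counts). Planted tokens are inserted at sentence positions
other than the first word so sentence-initial capitalisation never touches
a planted surface form. Abstracts are 3–8 sentences of 5–9 words so that
sentence splitting and context extraction are genuinely exercised;
generation is byte-deterministic given the seed.

The generator's manifest states the exact expected output of every
downstream stage, and the test suite's backbone is the round-trip: over a
hundred seeded corpora, `word_atomize()`, `document_frequency()`,
`extract_gene_mentions()`, `extract_drug_mentions()` and
`tabulate_categories()` reproduce their manifests exactly.
`generate_study_table()` does the same for cross-tables, with sample-count
rules including an exact-total rule (floor share plus remainder) so that
printed repository subtotals can be planted as inputs and re-aggregated.

What the generator does *not* emulate is real language: no PubMed style,
no ambiguous phrasing, no distributional word frequencies. Passing tests
therefore demonstrate the pipeline's counting, matching and accounting are
exact under controlled conditions — they do not certify recall of a gene
dictionary against real abstracts, which depends on lexicon coverage.

## Problem sizes and numerical choices

The accounting fixtures are built at the survey's own scale (a
1252-record corpus for the abstract filter; 1170 documents for the
document-frequency statistic; 369 study records; 344 studies across the
cross-table; 75 + 184 repository records for sample aggregation), since
these sizes are trivial for the implementation. Property suites run on
many small corpora (6–50 documents) rather than few large ones, which
exercises edge cases (empty sets, single-document plants, zero-count
cells) far more densely per unit of compute. The exhaustive hypergeometric
verification stops at `N = 25`, the regime where the enumeration oracle is
itself exact in double precision; beyond that, correctness follows from
the log-space formulation and is spot-checked against `phyper`.

Degenerate inputs are defined, not accidental: an empty corpus atomizes to
an empty ranking with an absent (not zero) percentage; an empty study
table tabulates to an all-zero cross-table; `k = 0` tails are exactly 1;
a single p-value BH-adjusts to itself. Ties are always broken
lexicographically so identical inputs give byte-identical outputs, a
property the pipeline extends to its report files (no timestamps in data
files; provenance lives in the run manifest only).

## Known limitations

- Dictionary matching cannot find symbols absent from the lexicon, and
  resolves ambiguous aliases to their first declaring symbol (flagged
  with a warning at lexicon construction).
- Keyword categorisation is rule-based; articles describing an omics
  approach without naming it are `unclassified`, and the packaged trigger
  map is a default, not a standard.
- The enrichment module implements the plain hypergeometric ORA; it does
  not attempt GO-graph-aware elimination, ranked (GSEA-style) statistics,
  or ascertainment-bias corrections.
- Live retrieval is implemented but intentionally untested offline; cached
  fixtures are the supported path for reproducible work.
- Published survey counts that depend on a November-2020 database snapshot
  (total retrievals, gene totals from live abstracts) are treated as
  inputs to accounting identities, not as recomputable targets.
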