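#' Construct a gene-set collection
#'
#' @param sets Named list: set id -> list with `description` (string) and
#'   `members` (character vector).
#' @param universe Background gene universe; defaults to the union of all
#'   set members (the least surprising over-representation convention
#'   when no assay universe is supplied).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (anyDuplicated(names(sets))) {
    oc_validation_error("set ids must be unique", field = "sets")
  }
  sets <- lapply(sets, function(s) {
    list(description = as.character(s$description %||% ""),
         members = unique(as.character(s$members)))
  })
  all_members <- unique(unlist(lapply(sets, `[[`, "members"), use.names = FALSE))
  if (is.null(universe)) {
    universe <- all_members
  } else {
    universe <- unique(as.character(universe))
    outside <- setdiff(all_members, universe)
    if (length(outside) > 0L) {
      oc_validation_error(sprintf(
        "set member(s) outside the supplied universe: %s",
        paste(utils::head(outside, 5), collapse = ", ")), field = "universe")
    }
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets over a universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' One set per line: `name<TAB>description<TAB>member1<TAB>member2...`.
#' Duplicate members within a line are deduplicated. A line with fewer
#' than three fields is a parse error reported with its line number.
#'
#' @param path Path to the GMT file.
#' @param universe Optional explicit universe (default: union of members).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(gene_set_collection(structure(list(), names = character()),
                               universe = universe %||% character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad) > 0L) {
    oc_parse_error(sprintf("GMT line %d has fewer than 3 fields", bad[1]))
  }
  sets <- lapply(parts, function(p) {
    list(description = p[2], members = unique(p[-(1:2)]))
  })
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  gene_set_collection(sets, universe = universe)
}

#' Packaged demonstration gene-set collection
#'
#' A small collection of Reactome-style pathway and GO-style term
#' identifiers (immune signalling, cytokine response, defense response,
#' ...) whose members are drawn from the packaged gene lexicon. Intended
#' for examples and report-shape work, not as a substitute for a full
#' pathway database.
#'
#' @return A [gene_set_collection()].
#' @export
default_gene_sets <- function() {
  read_gmt(pkg_extdata("genesets.gmt"))
}

check_hyper_args <- function(k, K, n, N) {
  k <- assert_scalar_count(k, "k")
  K <- assert_scalar_count(K, "K")
  n <- assert_scalar_count(n, "n")
  N <- assert_scalar_count(N, "N")
  if (K > N) oc_validation_error("constraint violated: K <= N")
  if (n > N) oc_validation_error("constraint violated: n <= N")
  if (k > min(K, n)) oc_validation_error("constraint violated: k <= min(K, n)")
  list(k = k, K = K, n = n, N = N)
}

#' Hypergeometric upper-tail probability
#'
#' Exact `P(X >= k)` for `X ~ Hypergeometric(N, K, n)` (a universe of `N`
#' genes of which `K` are set members, with `n` genes drawn as the query),
#' the standard over-representation tail. Computed in log space via
#' `lchoose` with a log-sum-exp accumulation; no continuity correction.
#'
#' @param k Observed overlap (successes drawn).
#' @param K Gene-set size (successes in the universe).
#' @param n Query size (draws).
#' @param N Universe size.
#' @return The tail probability, in `(0, 1]`.
#' @export
hypergeometric_upper_tail <- function(k, K, n, N) {
  a <- check_hyper_args(k, K, n, N)
  kmin <- max(0L, a$n - (a$N - a$K))  # support lower bound
  kmax <- min(a$K, a$n)
  if (a$k <= kmin) return(1)
  i <- seq.int(a$k, kmax)
  log_terms <- lchoose(a$K, i) + lchoose(a$N - a$K, a$n - i) -
    lchoose(a$N, a$n)
  m <- max(log_terms)
  exp(m + log(sum(exp(log_terms - m))))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotone enforcement; the
#' output is aligned to the input order and capped at 1.
#'
#' @param p_values Numeric vector of raw p-values, each in `(0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) return(numeric())
  if (anyNA(p) || any(p <= 0) || any(p > 1)) {
    oc_validation_error("p-values must lie in (0, 1]", field = "p_values")
  }
  m <- length(p)
  ord <- order(p, decreasing = TRUE)          # largest first
  ranks <- m:1                                # rank of each ordered p
  adj_sorted <- pmin(1, cummin(p[ord] * m / ranks))
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

#' Over-representation analysis of a gene list
#'
#' Tests each gene set for enrichment of the query list by the
#' hypergeometric upper tail, adjusts over the whole family of tested
#' sets by Benjamini-Hochberg (sets with zero overlap count toward the
#' family size `m` even though they are omitted from the report), and
#' returns the `top_n` overlapping sets ordered by raw p-value (ties by
#' set id).
#'
#' Query genes outside the universe are dropped with a warning after an
#' explicit intersection step; the dropped symbols are recorded in the
#' result's `"dropped"` attribute.
#'
#' @param query_genes Character vector of query symbols.
#' @param collection A [gene_set_collection()].
#' @param top_n Number of rows to report (default 10).
#' @return A tibble of class `enrichment_result` with columns `set_id`,
#'   `description`, `k`, `K`, `n`, `N`, `p_raw`, `p_adj`; attributes
#'   `dropped` (symbols outside the universe) and `m` (family size).
#' @export
enrich <- function(query_genes, collection, top_n = 10L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (length(collection$universe) == 0L) {
    oc_validation_error("collection universe is empty", field = "universe")
  }
  query_genes <- unique(as.character(query_genes))
  dropped <- setdiff(query_genes, collection$universe)
  if (length(dropped) > 0L) {
    warn(sprintf("%d query gene(s) outside the universe were dropped",
                 length(dropped)))
  }
  query <- intersect(query_genes, collection$universe)
  N <- length(collection$universe)
  n <- length(query)
  ids <- names(collection$sets)
  res <- tibble(
    set_id = ids,
    description = vapply(collection$sets, `[[`, character(1), "description"),
    k = vapply(collection$sets, function(s)
      length(intersect(query, s$members)), integer(1)),
    K = vapply(collection$sets, function(s) length(s$members), integer(1)),
    n = n,
    N = N
  )
  res$p_raw <- vapply(seq_len(nrow(res)), function(i) {
    hypergeometric_upper_tail(res$k[i], res$K[i], res$n[i], res$N[i])
  }, numeric(1))
  res$p_adj <- bh_adjust(res$p_raw)
  m <- nrow(res)
  res <- res[res$k >= 1L, , drop = FALSE]
  ord <- order(res$p_raw, res$set_id, method = "radix")
  res <- res[ord, , drop = FALSE]
  res <- res[seq_len(min(top_n, nrow(res))), , drop = FALSE]
  attr(res, "dropped") <- dropped
  attr(res, "m") <- m
  class(res) <- unique(c("enrichment_result", class(res)))
  res
}
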