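#' @importFrom rlang abort warn %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom stats setNames
NULL

# validation error with a stable class so callers can catch it
oc_validation_error <- function(msg, field = NULL) {
  abort(msg, class = "omicscout_validation_error", field = field)
}

oc_parse_error <- function(msg, ...) {
  abort(msg, class = "omicscout_parse_error", ...)
}

assert_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != floor(x)) {
    oc_validation_error(sprintf("`%s` must be a single non-negative integer", name),
                        field = name)
  }
  as.integer(x)
}

# round half-up to one decimal, matching printed percentages like 63.4
round_half_up1 <- function(x) floor(x * 10 + 0.5) / 10

# collapse whitespace and trim; returns NA_character_ for NULL/NA
squish <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x)) return(NA_character_)
  stringr::str_squish(x)
}

# token-boundary regex for a literal term: letters/digits are boundary
# blockers, hyphens are treated as boundaries so "IL13" matches in
# "IL13-driven" and phrase triggers like "16S" match inside "16S rRNA"
boundary_pattern <- function(term) {
  sprintf("(?<![A-Za-z0-9])%s(?![A-Za-z0-9])", escape_regex(term))
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# number of token-boundary occurrences of `term` in `text`
count_term <- function(text, term, ignore_case = TRUE) {
  if (is.na(text) || !nzchar(text)) return(0L)
  m <- gregexpr(boundary_pattern(term), text, perl = TRUE,
                ignore.case = ignore_case)[[1]]
  if (m[1] == -1L) 0L else length(m)
}

has_term <- function(text, term, ignore_case = TRUE) {
  count_term(text, term, ignore_case) > 0L
}

# md5 of a string (used for cache keys and manifest digests)
string_digest <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf), add = TRUE)
  writeChar(x, tf, eos = NULL, useBytes = TRUE)
  unname(tools::md5sum(tf))
}

file_digest <- function(path) unname(tools::md5sum(path))

pkg_extdata <- function(...) {
  path <- system.file("extdata", ..., package = "omicscout", mustWork = FALSE)
  if (!nzchar(path)) {
    oc_validation_error(sprintf("packaged data file not found: %s",
                                file.path(...)))
  }
  path
}
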