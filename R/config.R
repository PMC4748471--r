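#' Configuration for parsing, normalization and mapping
#'
#' Bundles every tunable used by the shallow parser, the demodifier and the
#' mapping engine. All closed-class word lists are matched case-insensitively;
#' entries are stored lowercased.
#'
#' @param prepositions Closed-class preposition list. A preposition token
#'   opens a new (prepositional) phrase during parsing.
#' @param determiners Closed-class determiner list. A determiner is only
#'   recognized as such immediately after a preposition; elsewhere the word is
#'   treated as an ordinary content token.
#' @param atomic_terms Optional multiword phrases (e.g. "tetralogy of fallot")
#'   fused into a single HEAD token before role assignment. Works around
#'   multiword heads that the rule-based parser would otherwise split.
#' @param stopwords Tokens dropped during term normalization.
#' @param plural_exceptions Tokens never stripped of a trailing "s" during
#'   normalization (beyond the built-in guard for words ending in "ss").
#' @param bag_normalization If `TRUE` (default), normalized tokens are sorted
#'   so matching is word-order-insensitive, emulating UMLS-style
#'   normalization.
#' @param max_units Maximum number of modifier units per term before
#'   demodification is skipped (bounds the 2^k variant enumeration).
#' @param partials_for_all Diagnostic switch: compute partial mappings even
#'   for concepts that already hold a complete mapping.
#' @param flag_congenital If `TRUE`, partial-mapping tables gain a logical
#'   column marking targets whose term mentions "congenital" while the source
#'   term does not (a known conflation hazard; results are never altered).
#'
#' @return A list of class `phemap_config`.
#' @export
#' @examples
#' cfg <- mapping_config(bag_normalization = FALSE)
#' cfg$max_units
mapping_config <- function(prepositions = c("of", "in", "at", "on", "with",
                                            "to", "by", "from", "for",
                                            "during"),
                           determiners = c("the", "a", "an"),
                           atomic_terms = character(),
                           stopwords = c("the", "a", "an", "of"),
                           plural_exceptions = character(),
                           bag_normalization = TRUE,
                           max_units = 10L,
                           partials_for_all = FALSE,
                           flag_congenital = FALSE) {
  stopifnot(is.numeric(max_units), max_units >= 1)
  cfg <- list(
    prepositions = tolower(trimws(prepositions)),
    determiners = tolower(trimws(determiners)),
    atomic_terms = tolower(trimws(atomic_terms)),
    stopwords = tolower(trimws(stopwords)),
    plural_exceptions = tolower(trimws(plural_exceptions)),
    bag_normalization = isTRUE(bag_normalization),
    max_units = as.integer(max_units),
    partials_for_all = isTRUE(partials_for_all),
    flag_congenital = isTRUE(flag_congenital)
  )
  class(cfg) <- "phemap_config"
  cfg
}

#' Read a one-entry-per-line word list
#'
#' Helper for the `prepositions_file` / `determiners_file` /
#' `atomic_terms_file` configuration hooks: plain text, one entry per line,
#' case-insensitive, blank lines and lines starting with `#` ignored.
#'
#' @param path File path.
#' @return Character vector of lowercased entries.
#' @export
read_word_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  tolower(x)
}

# Run code with a private RNG stream, restoring the caller's state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Locale-stable sort used everywhere determinism matters.
sort_c <- function(x) sort(x, method = "radix")

`%||%` <- function(a, b) if (is.null(a)) b else a
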