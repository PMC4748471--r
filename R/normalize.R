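#' Normalize terms for matching
#'
#' Canonicalizes a term through a fixed pipeline: lowercase; punctuation to
#' spaces; whitespace collapse; stopword removal; naive plural stripping
#' (a trailing "s" on tokens longer than three characters, sparing tokens
#' ending in "ss" and listed exceptions); and, by default, token sorting so
#' matching is word-order-insensitive ("bag" mode). The pipeline is
#' idempotent, and case-insensitively equal inputs normalize identically.
#'
#' Normalization deliberately does not bridge true lexical variance —
#' "Atrophy of kidney" and "renal atrophy" stay distinct; such equivalences
#' must come from the synonymy lexicon.
#'
#' @param x Character vector of terms.
#' @param config A [mapping_config()].
#' @return Character vector of normalized forms (same length as `x`).
#' @export
#' @examples
#' normalize_term(c("Aplastic clavicles", "aplastic clavicle"))
normalize_term <- function(x, config = mapping_config()) {
  if (!length(x)) return(character())
  y <- tolower(x)
  y <- gsub("[^a-z0-9]+", " ", y)
  toks <- strsplit(trimws(y), " +")
  vapply(toks, function(tt) {
    tt <- tt[nzchar(tt)]
    tt <- tt[!tt %in% config$stopwords]
    strip <- nchar(tt) > 3L & grepl("s$", tt) & !grepl("ss$", tt) &
      !tt %in% config$plural_exceptions
    tt[strip] <- sub("s$", "", tt[strip])
    if (config$bag_normalization) tt <- sort(tt, method = "radix")
    paste(tt, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
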