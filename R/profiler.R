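#' Shallow-parse a phenotype term into roles and a lexico-syntactic profile
#'
#' Deterministic rule-based profiler. Tokenization splits on whitespace
#' (hyphens stay inside tokens, outer punctuation is stripped); prepositions
#' and determiners come from closed-class lists in the configuration; every
#' other token is a content token. Each preposition opens a new
#' (prepositional) phrase; a determiner is recognized only immediately after
#' a preposition. Within each phrase the final content token is the HEAD and
#' all earlier content tokens are MODs. The profile is the canonical role
#' string, e.g. `"[MOD-MOD-HEAD]"` or `"[HEAD][PREP-DET-HEAD]"`.
#'
#' Multiword heads (e.g. "tetralogy of fallot") can be protected via
#' `atomic_terms` in the configuration: a listed phrase is fused into a
#' single content token before role assignment.
#'
#' Unparseable inputs (empty after tokenization, a phrase with no content
#' token) never raise; they yield an object with `ok = FALSE` that
#' [classify_eligibility()] reports as `unparsed`.
#'
#' @param text A single term.
#' @param config A [mapping_config()].
#' @return Object of class `parsed_term`: list with `raw`, `tokens`
#'   (data.frame surface/role/phrase), `profile`, `ok`.
#' @export
#' @examples
#' parse_term("Bilateral renal atrophy")$profile    # "[MOD-MOD-HEAD]"
#' parse_term("Abnormality of the philtrum")$profile
parse_term <- function(text, config = mapping_config()) {
  stopifnot(length(text) == 1L)
  raw <- text
  out <- function(tokens, ok) {
    profile <- if (ok) profile_string(tokens) else ""
    structure(list(raw = raw, tokens = tokens, profile = profile, ok = ok),
              class = "parsed_term")
  }
  empty_tokens <- data.frame(surface = character(), role = character(),
                             phrase = integer(), stringsAsFactors = FALSE)
  if (is.na(text) || !nzchar(trimws(text))) return(out(empty_tokens, FALSE))

  surf <- strsplit(trimws(text), "\\s+")[[1]]
  surf <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", surf)
  surf <- surf[nzchar(surf)]
  if (!length(surf)) return(out(empty_tokens, FALSE))
  surf <- fuse_atomic(surf, config$atomic_terms)

  low <- tolower(surf)
  n <- length(surf)
  role <- rep("CONTENT", n)
  phrase <- integer(n)
  p <- 1L
  for (i in seq_len(n)) {
    if (low[i] %in% config$prepositions) {
      p <- p + 1L
      role[i] <- "PREP"
    } else if (i > 1L && role[i - 1L] == "PREP" &&
               low[i] %in% config$determiners) {
      role[i] <- "DET"
    }
    phrase[i] <- p
  }
  # main phrase must exist (term may not open with a preposition)
  if (!any(phrase == 1L)) {
    return(out(data.frame(surface = surf, role = role, phrase = phrase,
                          stringsAsFactors = FALSE), FALSE))
  }
  for (ph in unique(phrase)) {
    idx <- which(phrase == ph & role == "CONTENT")
    if (!length(idx)) {
      return(out(data.frame(surface = surf, role = role, phrase = phrase,
                            stringsAsFactors = FALSE), FALSE))
    }
    role[idx] <- c(rep("MOD", length(idx) - 1L), "HEAD")
  }
  out(data.frame(surface = surf, role = role, phrase = phrase,
                 stringsAsFactors = FALSE), TRUE)
}

# fuse occurrences of multiword atomic phrases into single tokens
fuse_atomic <- function(surf, atomic_terms) {
  atomic <- atomic_terms[grepl("\\s", atomic_terms)]
  if (!length(atomic)) return(surf)
  low <- tolower(surf)
  for (phrase in atomic) {
    words <- strsplit(phrase, "\\s+")[[1]]
    k <- length(words)
    i <- 1L
    while (i <= length(low) - k + 1L) {
      if (all(low[i:(i + k - 1L)] == words)) {
        surf <- c(surf[seq_len(i - 1L)],
                  paste(surf[i:(i + k - 1L)], collapse = " "),
                  surf[seq_len(length(surf))[-seq_len(i + k - 1L)]])
        low <- tolower(surf)
      }
      i <- i + 1L
    }
  }
  surf
}

profile_string <- function(tokens) {
  paste(vapply(split(tokens$role, tokens$phrase),
               function(r) paste0("[", paste(r, collapse = "-"), "]"),
               character(1)),
        collapse = "")
}

#' @export
print.parsed_term <- function(x, ...) {
  cat("<parsed_term> \"", x$raw, "\" -> ",
      if (x$ok) x$profile else "(unparsed)", "\n", sep = "")
  invisible(x)
}

#' Classify a parsed term's eligibility for demodification
#'
#' A term is `demodifiable` when its main phrase is a `[MOD]+[HEAD]` pattern
#' or it carries exactly one prepositional attachment (every content token of
#' the attachment counts as a removable modifier). Bare head nouns
#' (`"[HEAD]"`) are `head_only`; terms with more than one prepositional
#' attachment are `complex_multi_pp`; inputs the profiler could not segment
#' are `unparsed`.
#'
#' @param parsed A `parsed_term`.
#' @return List of class `profile_eligibility` with `status` (one of
#'   `demodifiable`, `head_only`, `complex_multi_pp`, `unparsed`) and
#'   `reason`.
#' @export
classify_eligibility <- function(parsed) {
  stopifnot(inherits(parsed, "parsed_term"))
  n_pp <- max(c(parsed$tokens$phrase, 1L)) - 1L
  res <- if (!parsed$ok) {
    list(status = "unparsed",
         reason = "term could not be segmented into role-bearing phrases")
  } else if (n_pp > 1L) {
    list(status = "complex_multi_pp",
         reason = sprintf("%d prepositional attachments (max 1 handled)",
                          n_pp))
  } else if (identical(parsed$profile, "[HEAD]")) {
    list(status = "head_only",
         reason = "single head noun; no modifier to remove")
  } else {
    list(status = "demodifiable",
         reason = sprintf("profile %s with %d modifier unit(s)",
                          parsed$profile,
                          length(modifier_unit_indices(parsed))))
  }
  class(res) <- "profile_eligibility"
  res
}

#' Tabulate lexico-syntactic profiles over a term collection
#'
#' @param terms Character vector of terms.
#' @param config A [mapping_config()].
#' @return data.frame with columns `profile`, `count`, `fraction`, sorted by
#'   descending count with lexicographic tie-break. Unparseable terms are
#'   pooled under `"<unparsed>"`.
#' @export
profile_census <- function(terms, config = mapping_config()) {
  if (!length(terms)) {
    return(data.frame(profile = character(), count = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  }
  profs <- vapply(terms, function(t) {
    p <- parse_term(t, config)
    if (p$ok) p$profile else "<unparsed>"
  }, character(1), USE.NAMES = FALSE)
  tab <- table(profs)
  out <- data.frame(profile = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$profile, method = "radix"), , drop = FALSE]
  out$fraction <- out$count / length(terms)
  rownames(out) <- NULL
  out
}
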