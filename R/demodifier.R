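# token indices of the removable modifier units, in original order:
# each MOD of the main phrase; each content token (MOD or HEAD) of the
# single prepositional attachment. PREP/DET never form units of their own.
modifier_unit_indices <- function(parsed) {
  tok <- parsed$tokens
  main_mod <- which(tok$phrase == 1L & tok$role == "MOD")
  pp_content <- which(tok$phrase == 2L & tok$role %in% c("MOD", "HEAD"))
  sort(c(main_mod, pp_content))
}

#' Enumerate the removable modifier units of a demodifiable term
#'
#' One unit per adjectival/noun modifier of the main phrase and one per
#' content token of the (single) prepositional attachment. The head noun of
#' the main phrase is never a unit, and prepositions/determiners are dragged
#' along with their phrase rather than counted.
#'
#' @param parsed A `parsed_term` with eligibility `demodifiable`.
#' @return data.frame with columns `index` (token position) and `surface`.
#' @export
#' @examples
#' enumerate_modifier_units(parse_term("Bilateral renal atrophy"))
enumerate_modifier_units <- function(parsed) {
  elig <- classify_eligibility(parsed)
  if (elig$status != "demodifiable") {
    stop("term is not demodifiable (eligibility: ", elig$status, ")")
  }
  idx <- modifier_unit_indices(parsed)
  data.frame(index = idx, surface = parsed$tokens$surface[idx],
             stringsAsFactors = FALSE)
}

#' Generate all demodified variants of a term
#'
#' Removes every non-empty combination of modifier units in increasing order
#' of aggressiveness: level 1 removes one unit, level 2 two, and so on until
#' only the head noun of the main phrase remains. When removing units empties
#' the prepositional attachment of content, its preposition (and determiner)
#' are dragged out as well without counting toward the level. Duplicate
#' surface texts keep the lowest level.
#'
#' @param parsed A `parsed_term` with eligibility `demodifiable`.
#' @param max_level Optional cap on the number of units removed; `NULL`
#'   (default) enumerates every level up to the unit count `k`.
#' @param config A [mapping_config()]; `config$max_units` bounds `k` — terms
#'   exceeding it are skipped with a warning (empty result), never a
#'   combinatorial blow-up.
#' @return data.frame with columns `variant`, `level`, `removed`
#'   (plus-joined removed unit surfaces), sorted by level then by original
#'   unit positions.
#' @export
#' @examples
#' demodify(parse_term("Bilateral renal atrophy"))
demodify <- function(parsed, max_level = NULL, config = mapping_config()) {
  units <- enumerate_modifier_units(parsed)
  k <- nrow(units)
  empty <- data.frame(variant = character(), level = integer(),
                      removed = character(), stringsAsFactors = FALSE)
  if (k > config$max_units) {
    warning("term '", parsed$raw, "' has ", k,
            " modifier units (cap ", config$max_units, "); skipped",
            call. = FALSE)
    return(empty)
  }
  lmax <- if (is.null(max_level)) k else min(as.integer(max_level), k)
  if (lmax < 1L) return(empty)

  tok <- parsed$tokens
  pp_content <- which(tok$phrase == 2L & tok$role %in% c("MOD", "HEAD"))
  pp_function <- which(tok$phrase == 2L & tok$role %in% c("PREP", "DET"))

  rows <- vector("list", 2^k)
  r <- 0L
  for (L in seq_len(lmax)) {
    combos <- utils::combn(k, L)
    for (j in seq_len(ncol(combos))) {
      sel <- combos[, j]
      drop_idx <- units$index[sel]
      if (length(pp_content) && all(pp_content %in% drop_idx)) {
        drop_idx <- c(drop_idx, pp_function)
      }
      r <- r + 1L
      rows[[r]] <- data.frame(
        variant = paste(tok$surface[-drop_idx], collapse = " "),
        level = L,
        removed = paste(units$surface[sel], collapse = "+"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[seq_len(r)])
  out <- out[!duplicated(out$variant), , drop = FALSE]  # lowest level wins
  rownames(out) <- NULL
  out
}
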