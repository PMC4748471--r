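#' Run the full mapping pipeline
#'
#' For every source concept: a complete lexical mapping when one exists;
#' otherwise both a partial lexical mapping (via demodification) and a
#' partial logical mapping (via closest-ancestor search) are attempted
#' independently. Per-concept failures are recorded, never fatal, and the
#' output ordering is deterministic (sorted by source id).
#'
#' @param source A `source_ontology`.
#' @param target A `target_terminology`.
#' @param lexicon A `synonymy_lexicon`.
#' @param config A [mapping_config()]. With `partials_for_all = TRUE`,
#'   partial mappings are also computed for completely mapped concepts
#'   (diagnostics); categories are unaffected.
#' @return Object of class `mapping_result`: list with data.frames
#'   `complete` (source_id, target_id, group_id), `partial_lexical`
#'   (source_id, level, target_id, term, variant), `partial_logical`
#'   (source_id, level, target_id, ancestor_id), `categories` (source_id,
#'   category, lexical_level, logical_level), `unmapped` (source_id,
#'   reason), plus the inputs' concept table and the config. When
#'   `config$flag_congenital` is set, both partial tables carry a
#'   `congenital_only` flag column.
#' @export
run_pipeline <- function(source, target, lexicon,
                         config = mapping_config()) {
  stopifnot(inherits(source, "source_ontology"),
            inherits(lexicon, "synonymy_lexicon"))
  index <- build_match_index(lexicon, target, config)
  em <- complete_lexical_map(source, lexicon, target, config, index = index)

  ids <- sort_c(source$concepts$id)
  complete_ids <- intersect(ids, names(em$targets))
  partial_ids <- if (config$partials_for_all) ids else
    setdiff(ids, complete_ids)

  lex_rows <- list()
  log_rows <- list()
  cat_rows <- list()
  unmapped <- list()
  cfg_part <- config
  cfg_part$partials_for_all <- TRUE  # the exclusivity gate lives here

  term_tab <- concept_terms(source)
  for (id in ids) {
    is_complete <- id %in% complete_ids
    lex <- NULL
    logm <- NULL
    if (id %in% partial_ids) {
      lex <- partial_lexical_map(source, id, em, lexicon, target,
                                 config = cfg_part, index = index)
      logm <- partial_logical_map(source, id, em, config = cfg_part)
    }
    if (!is.null(lex) && !is_complete) {
      lex_rows[[id]] <- data.frame(
        source_id = id, level = lex$level, target_id = lex$targets,
        term = lex$provenance$term[1], variant = lex$provenance$variant[1],
        stringsAsFactors = FALSE)
    }
    if (!is.null(logm) && !is_complete) {
      grid <- expand.grid(target_id = logm$targets,
                          ancestor_id = logm$provenance$ancestor_id,
                          stringsAsFactors = FALSE)
      # keep only (target, ancestor) pairs the ancestor actually supplies
      keep <- mapply(function(t, a) t %in% eq_targets(em, a),
                     grid$target_id, grid$ancestor_id)
      grid <- grid[keep, , drop = FALSE]
      log_rows[[id]] <- data.frame(
        source_id = id, level = logm$level, target_id = grid$target_id,
        ancestor_id = grid$ancestor_id, stringsAsFactors = FALSE)
    }
    category <- if (is_complete) "complete"
      else if (!is.null(lex) && !is.null(logm)) "both"
      else if (!is.null(lex)) "lexical_only"
      else if (!is.null(logm)) "logical_only"
      else "unmapped"
    cat_rows[[id]] <- data.frame(
      source_id = id, category = category,
      lexical_level = if (!is.null(lex) && !is_complete)
        lex$level else NA_integer_,
      logical_level = if (!is.null(logm) && !is_complete)
        logm$level else NA_integer_,
      stringsAsFactors = FALSE)
    if (category == "unmapped") {
      pref <- term_tab$term[term_tab$id == id & term_tab$is_preferred][1]
      elig <- classify_eligibility(parse_term(pref, config))
      lex_reason <- if (elig$status != "demodifiable") {
        paste0("lexical: ", elig$status)
      } else "lexical: no demodified variant matched"
      unmapped[[id]] <- data.frame(
        source_id = id,
        reason = paste(lex_reason, "logical: no equivalent ancestor",
                       sep = "; "),
        stringsAsFactors = FALSE)
    }
  }

  bind <- function(rows, proto) {
    if (length(rows)) {
      d <- do.call(rbind, rows)
      rownames(d) <- NULL
      d
    } else proto
  }
  res <- structure(list(
    concepts = source$concepts,
    complete = em$df,
    partial_lexical = bind(lex_rows, data.frame(
      source_id = character(), level = integer(), target_id = character(),
      term = character(), variant = character(), stringsAsFactors = FALSE)),
    partial_logical = bind(log_rows, data.frame(
      source_id = character(), level = integer(), target_id = character(),
      ancestor_id = character(), stringsAsFactors = FALSE)),
    categories = bind(cat_rows, data.frame(
      source_id = character(), category = character(),
      lexical_level = integer(), logical_level = integer(),
      stringsAsFactors = FALSE)),
    unmapped = bind(unmapped, data.frame(
      source_id = character(), reason = character(),
      stringsAsFactors = FALSE)),
    config = config
  ), class = "mapping_result")

  if (config$flag_congenital) {
    res$partial_lexical <- flag_congenital(res$partial_lexical, source,
                                           target)
    res$partial_logical <- flag_congenital(res$partial_logical, source,
                                           target)
  }
  res
}

# mark partial-mapping rows whose target term mentions "congenital" while
# the source preferred term does not (diagnostic only; results unchanged)
flag_congenital <- function(df, source, target) {
  if (!nrow(df)) {
    df$congenital_only <- logical()
    return(df)
  }
  src_term <- source$concepts$preferred_term[
    match(df$source_id, source$concepts$id)]
  tgt_term <- target$preferred_term[match(df$target_id, target$id)]
  df$congenital_only <- grepl("congenital", tolower(tgt_term %||% "")) &
    !grepl("congenital", tolower(src_term))
  df
}

#' @export
print.mapping_result <- function(x, ...) {
  tab <- table(factor(x$categories$category,
                      levels = c("complete", "both", "lexical_only",
                                 "logical_only", "unmapped")))
  cat("<mapping_result> ", nrow(x$categories), " source concepts\n",
      sep = "")
  for (nm in names(tab)) cat("  ", format(nm, width = 13), tab[[nm]], "\n")
  invisible(x)
}

#' Write pipeline outputs as TSV files
#'
#' Emits `complete.tsv`, `partial_lexical.tsv`, `partial_logical.tsv` and
#' `unmapped.tsv` under `dir`.
#'
#' @param result A `mapping_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mapping_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("complete", "partial_lexical", "partial_logical",
               "unmapped")) {
    utils::write.table(result[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
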