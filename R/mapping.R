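#' Build the normalized match index over lexicon and target terms
#'
#' Precomputes (a) normalized lexicon member term -> group ids and (b) group
#' id -> target ids, where a group's targets are its explicit links plus any
#' target concept one of whose terms matches a group member under
#' normalization.
#'
#' @param lexicon A `synonymy_lexicon`.
#' @param target A `target_terminology` (or `NULL` to use links only).
#' @param config A [mapping_config()].
#' @return List of class `match_index` with `term_groups` (named list:
#'   normalized form -> group ids) and `group_targets` (named list:
#'   group id -> target ids).
#' @export
build_match_index <- function(lexicon, target = NULL,
                              config = mapping_config()) {
  member_norm <- normalize_term(lexicon$terms$term, config)
  term_groups <- lapply(split(lexicon$terms$group_id, member_norm),
                        function(g) sort_c(unique(g)))

  group_targets <- lapply(split(lexicon$links$target_id,
                                lexicon$links$group_id),
                          function(t) sort_c(unique(t)))
  if (!is.null(target) && nrow(target) > 0) {
    tt <- concept_terms(as.data.frame(target))
    tnorm <- normalize_term(tt$term, config)
    targets_by_norm <- split(tt$id, tnorm)
    # every group whose member form coincides with a target term gains that id
    hit <- member_norm %in% names(targets_by_norm)
    if (any(hit)) {
      add <- data.frame(group_id = lexicon$terms$group_id[hit],
                        norm = member_norm[hit], stringsAsFactors = FALSE)
      for (i in seq_len(nrow(add))) {
        g <- add$group_id[i]
        group_targets[[g]] <- sort_c(unique(c(
          group_targets[[g]], targets_by_norm[[add$norm[i]]])))
      }
    }
  }
  structure(list(term_groups = term_groups, group_targets = group_targets),
            class = "match_index")
}

# groups and target ids reachable from one already-normalized form
index_lookup <- function(index, norm) {
  groups <- index$term_groups[[norm]]
  if (is.null(groups)) {
    return(list(groups = character(), targets = character()))
  }
  targets <- unlist(index$group_targets[groups], use.names = FALSE)
  targets <- if (is.null(targets)) character() else sort_c(unique(targets))
  list(groups = groups, targets = targets)
}

#' Complete lexical mappings through synonym-group equivalence
#'
#' A source concept maps to a target concept when any of its terms
#' (preferred term or synonym) and the target share a synonym group under
#' normalization — either through the group's explicit target links or
#' through a target term matching a group member. All qualifying targets are
#' collected; concepts with no matching term are absent from the map (an
#' empty set is never stored).
#'
#' @param source A `source_ontology` (or its concepts data.frame).
#' @param lexicon A `synonymy_lexicon`.
#' @param target A `target_terminology`.
#' @param config A [mapping_config()].
#' @param index Optional prebuilt [build_match_index()].
#' @return Object of class `equivalence_map`: list with `targets` (named
#'   list: source id -> target ids), `groups` (named list: source id ->
#'   justifying group ids), and `df` (long data.frame source_id, target_id,
#'   group_id).
#' @export
complete_lexical_map <- function(source, lexicon, target,
                                 config = mapping_config(), index = NULL) {
  if (is.null(index)) index <- build_match_index(lexicon, target, config)
  terms <- concept_terms(source)
  norms <- normalize_term(terms$term, config)

  tmap <- list()
  gmap <- list()
  rows <- list()
  for (id in unique(terms$id)) {
    sel <- which(terms$id == id)
    targets <- character()
    groups <- character()
    for (i in sel) {
      hit <- index_lookup(index, norms[i])
      if (length(hit$targets)) {
        targets <- c(targets, hit$targets)
        groups <- c(groups, hit$groups)
      }
    }
    targets <- sort_c(unique(targets))
    if (length(targets)) {
      groups <- sort_c(unique(groups))
      tmap[[id]] <- targets
      gmap[[id]] <- groups
      rows[[id]] <- expand.grid(source_id = id, target_id = targets,
                                stringsAsFactors = FALSE)
      rows[[id]]$group_id <- paste(groups, collapse = "+")
    }
  }
  df <- if (length(rows)) {
    d <- do.call(rbind, rows)
    rownames(d) <- NULL
    d
  } else {
    data.frame(source_id = character(), target_id = character(),
               group_id = character(), stringsAsFactors = FALSE)
  }
  structure(list(targets = tmap, groups = gmap, df = df),
            class = "equivalence_map")
}

#' @export
print.equivalence_map <- function(x, ...) {
  cat("<equivalence_map> ", length(x$targets),
      " source concepts with complete mappings\n", sep = "")
  invisible(x)
}

#' Target ids a source concept is equivalent to
#'
#' @param em An `equivalence_map`.
#' @param id Source concept id.
#' @return Character vector of target ids (empty if none).
#' @export
eq_targets <- function(em, id) em$targets[[id]] %||% character()

#' Partial lexical mapping of one concept via demodification
#'
#' Over all the concept's terms and all their demodified variants, finds the
#' minimum level (number of modifier units removed) at which at least one
#' variant achieves a complete-style match with target links; returns the
#' union of targets over all variants at that level across all terms
#' ("the less demodified term(s)"). Concepts already holding a complete
#' mapping are a contract violation unless `config$partials_for_all` is set.
#'
#' @param source A `source_ontology`.
#' @param concept_id Source concept id.
#' @param equivalences The `equivalence_map` from [complete_lexical_map()].
#' @param lexicon A `synonymy_lexicon`.
#' @param target A `target_terminology`.
#' @param config A [mapping_config()].
#' @param index Optional prebuilt [build_match_index()].
#' @return `NULL` when no variant at any level matches; otherwise a list of
#'   class `partial_mapping` with `source_id`, `method = "lexical"`,
#'   `level`, `targets`, and `provenance` (data.frame term, variant,
#'   removed).
#' @export
partial_lexical_map <- function(source, concept_id, equivalences, lexicon,
                                target, config = mapping_config(),
                                index = NULL) {
  if (length(eq_targets(equivalences, concept_id)) &&
      !config$partials_for_all) {
    stop("concept ", concept_id,
         " holds a complete mapping; partial lexical mapping not applicable")
  }
  if (is.null(index)) index <- build_match_index(lexicon, target, config)
  terms <- concept_terms(source)
  terms <- terms$term[terms$id == concept_id]
  if (!length(terms)) stop("unknown source concept: ", concept_id)

  cand <- list()
  for (tm in terms) {
    parsed <- parse_term(tm, config)
    if (classify_eligibility(parsed)$status != "demodifiable") next
    vars <- demodify(parsed, config = config)
    if (!nrow(vars)) next
    vars$term <- tm
    cand[[length(cand) + 1L]] <- vars
  }
  if (!length(cand)) return(NULL)
  cand <- do.call(rbind, cand)
  norms <- normalize_term(cand$variant, config)
  hits <- lapply(norms, function(nm) index_lookup(index, nm)$targets)
  has_hit <- lengths(hits) > 0
  if (!any(has_hit)) return(NULL)

  level <- min(cand$level[has_hit])
  at_min <- has_hit & cand$level == level
  structure(list(
    source_id = concept_id,
    method = "lexical",
    level = as.integer(level),
    targets = sort_c(unique(unlist(hits[at_min], use.names = FALSE))),
    provenance = {
      p <- cand[at_min, c("term", "variant", "removed"), drop = FALSE]
      rownames(p) <- NULL
      p
    }
  ), class = "partial_mapping")
}

#' Partial logical mapping of one concept via closest-ancestor search
#'
#' Breadth-first over the concept's ancestors by is-a edge distance d = 1,
#' 2, ...; at the first distance where at least one ancestor holds a
#' complete (equivalence) mapping, returns level = d and the union of those
#' ancestors' target sets. More distant ancestors are never explored. With
#' multiple parents, distance is the minimum over paths.
#'
#' @param source A `source_ontology`.
#' @param concept_id Source concept id (hard error when not in the graph).
#' @param equivalences The `equivalence_map` from [complete_lexical_map()].
#' @param config A [mapping_config()].
#' @return `NULL` when no ancestor up to the root holds an equivalence;
#'   otherwise a `partial_mapping` with `method = "logical"`, `level`,
#'   `targets`, and `provenance` (data.frame ancestor_id).
#' @export
partial_logical_map <- function(source, concept_id, equivalences,
                                config = mapping_config()) {
  if (!concept_id %in% source$concepts$id) {
    stop("concept ", concept_id, " is not in the subsumption graph")
  }
  if (length(eq_targets(equivalences, concept_id)) &&
      !config$partials_for_all) {
    stop("concept ", concept_id,
         " holds a complete mapping; partial logical mapping not applicable")
  }
  parents <- split(source$edges$parent, source$edges$child)
  visited <- concept_id
  frontier <- sort_c(unique(parents[[concept_id]] %||% character()))
  d <- 1L
  while (length(frontier)) {
    hits <- frontier[vapply(frontier, function(a) {
      length(eq_targets(equivalences, a)) > 0
    }, logical(1))]
    if (length(hits)) {
      targets <- sort_c(unique(unlist(
        lapply(hits, function(a) eq_targets(equivalences, a)),
        use.names = FALSE)))
      return(structure(list(
        source_id = concept_id,
        method = "logical",
        level = d,
        targets = targets,
        provenance = data.frame(ancestor_id = hits, stringsAsFactors = FALSE)
      ), class = "partial_mapping"))
    }
    visited <- c(visited, frontier)
    up <- unlist(parents[frontier], use.names = FALSE)
    frontier <- if (is.null(up)) character() else
      sort_c(setdiff(unique(up), visited))
    d <- d + 1L
  }
  NULL
}

#' @export
print.partial_mapping <- function(x, ...) {
  cat("<partial_mapping> ", x$source_id, " --", x$method, " level ",
      x$level, "--> {", paste(x$targets, collapse = ", "), "}\n", sep = "")
  invisible(x)
}
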