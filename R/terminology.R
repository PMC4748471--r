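#' Construct a source ontology (concepts + subsumption graph)
#'
#' The source side of a mapping problem: a set of concepts, each with one
#' preferred term and zero or more exact synonyms, arranged in a rooted is-a
#' DAG (multiple parents permitted).
#'
#' @param concepts data.frame with columns `id`, `preferred_term`,
#'   `synonyms` (pipe-joined string, possibly empty).
#' @param edges data.frame with columns `child`, `parent` (is-a edges).
#' @param root Identifier of the root concept.
#' @return An object of class `source_ontology`: a list with elements
#'   `concepts`, `edges`, `root`.
#' @export
source_ontology <- function(concepts, edges, root) {
  concepts <- as.data.frame(concepts, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "preferred_term") %in% names(concepts)))
  if (is.null(concepts$synonyms)) concepts$synonyms <- ""
  concepts$synonyms[is.na(concepts$synonyms)] <- ""
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(edges) == 0) {
    edges <- data.frame(child = character(), parent = character(),
                        stringsAsFactors = FALSE)
  }
  stopifnot(all(c("child", "parent") %in% names(edges)))

  if (anyDuplicated(concepts$id)) {
    stop("duplicate concept ids: ",
         paste(unique(concepts$id[duplicated(concepts$id)]), collapse = ", "))
  }
  concepts$preferred_term <- trimws(concepts$preferred_term)
  if (any(!nzchar(concepts$preferred_term))) {
    stop("empty preferred term for id(s): ",
         paste(concepts$id[!nzchar(concepts$preferred_term)], collapse = ", "))
  }
  # dedupe synonyms against the preferred term and drop empties
  concepts$synonyms <- vapply(seq_len(nrow(concepts)), function(i) {
    syn <- strsplit(concepts$synonyms[i], "|", fixed = TRUE)[[1]]
    syn <- trimws(syn)
    syn <- unique(syn[nzchar(syn)])
    syn <- setdiff(syn, concepts$preferred_term[i])
    paste(syn, collapse = "|")
  }, character(1))

  if (!root %in% concepts$id) {
    stop("root concept '", root, "' not among the loaded concepts")
  }
  bad <- setdiff(unique(c(edges$child, edges$parent)), concepts$id)
  if (length(bad)) {
    stop("edge endpoint(s) not among concepts: ", paste(bad, collapse = ", "))
  }
  check_acyclic(edges)

  ord <- order(concepts$id, method = "radix")
  concepts <- concepts[ord, , drop = FALSE]
  rownames(concepts) <- NULL
  edges <- edges[order(edges$child, edges$parent, method = "radix"), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(concepts = concepts, edges = edges, root = root),
            class = "source_ontology")
}

# Hard error listing one cycle if the child->parent edge set is cyclic.
# igraph decides acyclicity; the offending cycle is recovered by a small DFS.
check_acyclic <- function(edges) {
  if (nrow(edges) == 0) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE)
  if (igraph::is_dag(g)) return(invisible(TRUE))
  parents <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  cycle <- NULL
  visit <- function(v) {
    if (!is.null(cycle)) return()
    s <- get0(v, envir = state, ifnotfound = 0L)
    if (s == 1L) {
      cycle <<- c(path[which(path == v)[1]:length(path)], v)
      return()
    }
    if (s == 2L) return()
    assign(v, 1L, envir = state)
    path <<- c(path, v)
    for (p in parents[[v]] %||% character()) visit(p)
    path <<- path[-length(path)]
    assign(v, 2L, envir = state)
  }
  for (v in unique(edges$child)) {
    visit(v)
    if (!is.null(cycle)) break
  }
  stop("cycle detected in subsumption graph: ",
       paste(cycle, collapse = " -> "))
}

#' @export
print.source_ontology <- function(x, ...) {
  cat("<source_ontology> ", nrow(x$concepts), " concepts, ",
      nrow(x$edges), " is-a edges, root = ", x$root, "\n", sep = "")
  invisible(x)
}

#' All terms of every concept, one row per (id, term)
#'
#' @param x A `source_ontology` or a target terminology data.frame.
#' @return data.frame with columns `id`, `term`, `is_preferred`.
#' @export
concept_terms <- function(x) {
  concepts <- if (inherits(x, "source_ontology")) x$concepts else x
  syn <- strsplit(concepts$synonyms %||% rep("", nrow(concepts)),
                  "|", fixed = TRUE)
  n_syn <- lengths(syn)
  out <- data.frame(
    id = c(concepts$id, rep(concepts$id, n_syn)),
    term = c(concepts$preferred_term, unlist(syn, use.names = FALSE)),
    is_preferred = c(rep(TRUE, nrow(concepts)), rep(FALSE, sum(n_syn))),
    stringsAsFactors = FALSE
  )
  out <- out[nzchar(out$term), , drop = FALSE]
  out <- out[order(out$id, !out$is_preferred, out$term, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# children index; used for root-restricted selection
descendants_of <- function(edges, root) {
  children <- split(edges$child, edges$parent)
  seen <- root
  frontier <- root
  while (length(frontier)) {
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

#' Load a source ontology from OBO or the fixture TSV dialect
#'
#' Restricts the loaded ontology to `root_id` and its descendants, drops
#' obsolete concepts, and (for OBO) keeps only EXACT-scoped synonyms.
#'
#' @param path For `format = "obo"`, the OBO file. For `format = "tsv"`, the
#'   directory holding `concepts.tsv` (columns id, preferred_term,
#'   pipe-joined synonyms) and `edges.tsv` (columns child_id, parent_id).
#' @param format `"obo"` or `"tsv"`.
#' @param root_id Root concept id; a hard error names it when absent.
#' @return A `source_ontology`.
#' @export
load_source_ontology <- function(path, format = c("tsv", "obo"), root_id) {
  format <- match.arg(format)
  if (format == "obo") {
    parsed <- read_obo_terms(path)
    concepts <- parsed$concepts
    edges <- parsed$edges
  } else {
    concepts <- utils::read.delim(file.path(path, "concepts.tsv"),
                                  colClasses = "character")
    names(concepts) <- c("id", "preferred_term", "synonyms")[
      seq_len(ncol(concepts))]
    if (is.null(concepts$synonyms)) concepts$synonyms <- ""
    ef <- file.path(path, "edges.tsv")
    edges <- utils::read.delim(ef, colClasses = "character")
    names(edges) <- c("child", "parent")[seq_len(ncol(edges))]
  }
  if (!root_id %in% concepts$id) {
    stop("root concept '", root_id, "' not found in ", path)
  }
  check_acyclic(edges)
  keep <- descendants_of(edges, root_id)
  concepts <- concepts[concepts$id %in% keep, , drop = FALSE]
  edges <- edges[edges$child %in% keep & edges$parent %in% keep, ,
                 drop = FALSE]
  source_ontology(concepts, edges, root_id)
}

#' Write a source ontology in the fixture TSV dialect
#'
#' Emits `concepts.tsv` and `edges.tsv` under `dir`; reloading with
#' [load_source_ontology()] reproduces identical ids, terms and edges.
#'
#' @param onto A `source_ontology`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_source_ontology <- function(onto, dir) {
  stopifnot(inherits(onto, "source_ontology"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(
    onto$concepts[, c("id", "preferred_term", "synonyms")],
    file.path(dir, "concepts.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = c("id", "preferred_term", "synonyms"))
  edges <- onto$edges
  names(edges) <- c("child_id", "parent_id")
  utils::write.table(edges, file.path(dir, "edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Load a flat target terminology
#'
#' The target side is a flat concept/term set (its hierarchy is never
#' traversed): TSV with columns `id`, `term`, `term_type`
#' (preferred|synonym). Duplicate (id, term) rows collapse; every id must
#' carry exactly one preferred term.
#'
#' @param path Path to the TSV file.
#' @return data.frame of class `target_terminology` with columns `id`,
#'   `preferred_term`, `synonyms` (pipe-joined).
#' @export
load_target_terminology <- function(path) {
  raw <- utils::read.delim(path, colClasses = "character")
  names(raw) <- c("id", "term", "term_type")[seq_len(ncol(raw))]
  target_terminology(raw)
}

#' Construct a target terminology from long-format rows
#'
#' @param rows data.frame with columns `id`, `term`, `term_type`.
#' @return data.frame of class `target_terminology`.
#' @export
target_terminology <- function(rows) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) == 0) {
    out <- data.frame(id = character(), preferred_term = character(),
                      synonyms = character(), stringsAsFactors = FALSE)
    class(out) <- c("target_terminology", "data.frame")
    return(out)
  }
  rows$term <- trimws(rows$term)
  rows <- rows[nzchar(rows$term), , drop = FALSE]
  rows <- unique(rows[, c("id", "term", "term_type")])
  pref <- rows[rows$term_type == "preferred", , drop = FALSE]
  n_pref <- table(factor(pref$id, levels = unique(rows$id)))
  bad <- names(n_pref)[n_pref != 1L]
  if (length(bad)) {
    stop("target id(s) without exactly one preferred term: ",
         paste(bad, collapse = ", "))
  }
  syn <- rows[rows$term_type != "preferred", , drop = FALSE]
  syn_by_id <- split(syn$term, syn$id)
  ids <- sort_c(unique(rows$id))
  out <- data.frame(
    id = ids,
    preferred_term = pref$term[match(ids, pref$id)],
    synonyms = vapply(ids, function(i) {
      s <- setdiff(sort_c(unique(syn_by_id[[i]] %||% character())),
                   pref$term[match(i, pref$id)])
      paste(s, collapse = "|")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("target_terminology", "data.frame")
  out
}

#' Write a target terminology in the long TSV format
#'
#' @param target A `target_terminology`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_terminology <- function(target, path) {
  tt <- concept_terms(as.data.frame(target))
  out <- data.frame(id = tt$id, term = tt$term,
                    term_type = ifelse(tt$is_preferred, "preferred",
                                       "synonym"),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a synonymy lexicon
#'
#' Groups of terms considered synonymous, each group optionally linked to
#' target-terminology concept ids — the stand-in for UMLS concepts/CUIs.
#' A term may belong to several groups: ambiguity is preserved, never
#' collapsed.
#'
#' @param terms data.frame with columns `group_id`, `term`.
#' @param links data.frame with columns `group_id`, `target_id`.
#' @return An object of class `synonymy_lexicon`.
#' @export
synonymy_lexicon <- function(terms, links = NULL) {
  terms <- as.data.frame(terms, stringsAsFactors = FALSE)
  stopifnot(all(c("group_id", "term") %in% names(terms)))
  terms$term <- trimws(terms$term)
  terms <- unique(terms[nzchar(terms$term), c("group_id", "term")])
  if (is.null(links)) {
    links <- data.frame(group_id = character(), target_id = character(),
                        stringsAsFactors = FALSE)
  }
  links <- unique(as.data.frame(links, stringsAsFactors = FALSE))
  terms <- terms[order(terms$group_id, terms$term, method = "radix"), ,
                 drop = FALSE]
  links <- links[order(links$group_id, links$target_id, method = "radix"), ,
                 drop = FALSE]
  rownames(terms) <- rownames(links) <- NULL
  structure(list(terms = terms, links = links), class = "synonymy_lexicon")
}

#' @export
print.synonymy_lexicon <- function(x, ...) {
  cat("<synonymy_lexicon> ", length(unique(x$terms$group_id)), " groups, ",
      nrow(x$terms), " member terms, ", nrow(x$links),
      " target links\n", sep = "")
  invisible(x)
}

#' Load a synonymy lexicon
#'
#' Two dialects: `"tsv"` — columns group_id, term, linked_target_id (empty
#' allowed); `"rrf"` — pipe-delimited rows read by position as
#' CUI|SAB|CODE|STR, where rows whose SAB equals `target_sab` contribute
#' CODE as a linked target id. Malformed rows are skipped with a warning
#' naming the line number; zero loaded groups is a hard error.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"rrf"`.
#' @param target_sab Source-abbreviation tag marking target-terminology rows
#'   in the rrf dialect (default `"TARGET"`, matching e.g. "SNOMEDCT_US" in
#'   real RRF data).
#' @return A `synonymy_lexicon`.
#' @export
load_lexicon <- function(path, dialect = c("tsv", "rrf"),
                         target_sab = "TARGET") {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    lines <- readLines(path, warn = FALSE)
    if (length(lines) && grepl("^group_id\t", lines[1])) lines <- lines[-1]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    ok <- lengths(parts) >= 2
    if (any(!ok)) {
      for (i in which(!ok)) {
        warning("skipping malformed lexicon row at line ", i + 1L,
                call. = FALSE)
      }
    }
    parts <- parts[ok]
    gid <- vapply(parts, `[`, character(1), 1L)
    term <- vapply(parts, `[`, character(1), 2L)
    tid <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "",
                  character(1))
    terms <- data.frame(group_id = gid, term = term, stringsAsFactors = FALSE)
    links <- data.frame(group_id = gid[nzchar(tid)],
                        target_id = tid[nzchar(tid)],
                        stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path, warn = FALSE)
    parts <- strsplit(lines, "|", fixed = TRUE)
    ok <- lengths(parts) >= 4
    if (any(!ok)) {
      for (i in which(!ok)) {
        warning("skipping malformed RRF row at line ", i, call. = FALSE)
      }
    }
    parts <- parts[ok]
    cui <- vapply(parts, `[`, character(1), 1L)
    sab <- vapply(parts, `[`, character(1), 2L)
    code <- vapply(parts, `[`, character(1), 3L)
    str <- vapply(parts, `[`, character(1), 4L)
    terms <- data.frame(group_id = cui, term = str, stringsAsFactors = FALSE)
    is_tgt <- sab == target_sab & nzchar(code)
    links <- data.frame(group_id = cui[is_tgt], target_id = code[is_tgt],
                        stringsAsFactors = FALSE)
  }
  terms <- terms[nzchar(trimws(terms$term)), , drop = FALSE]
  if (nrow(terms) == 0) stop("no lexicon groups loaded from ", path)
  synonymy_lexicon(terms, links)
}

#' Write a synonymy lexicon in the fixture TSV dialect
#'
#' @param lexicon A `synonymy_lexicon`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lexicon, path) {
  terms <- lexicon$terms
  links_by_group <- split(lexicon$links$target_id, lexicon$links$group_id)
  rows <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    g <- terms$group_id[i]
    tids <- links_by_group[[g]] %||% character()
    # links are carried on the group's first member row; one row per link
    if (i == match(g, terms$group_id) && length(tids)) {
      data.frame(group_id = g, term = terms$term[i], linked_target_id = tids,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(group_id = g, term = terms$term[i], linked_target_id = "",
                 stringsAsFactors = FALSE)
    }
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Look up the synonym groups containing a term
#'
#' Total: any string returns a (possibly empty) character vector of group
#' ids, never an error. Matching uses [normalize_term()].
#'
#' @param lexicon A `synonymy_lexicon`.
#' @param term A single term string.
#' @param config A [mapping_config()].
#' @return Character vector of group ids.
#' @export
lexicon_lookup <- function(lexicon, term, config = mapping_config()) {
  if (!length(term) || is.na(term) || !nzchar(trimws(term))) {
    return(character())
  }
  key <- normalize_term(term, config)
  member_norm <- normalize_term(lexicon$terms$term, config)
  sort_c(unique(lexicon$terms$group_id[member_norm == key]))
}
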