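#' Specification for a synthetic mapping fixture
#'
#' Describes a randomized source ontology / target terminology / synonymy
#' lexicon triple with planted ground truth. Defaults emulate the study
#' conditions of the phenotype-mapping setting at desk scale: roughly 30%
#' of concepts with a complete mapping, a third of the remainder reachable
#' lexically, demodification mostly at level 1, and a small share of bare
#' head nouns and prepositional attachments.
#'
#' @param n_concepts Number of source concepts (including the root).
#' @param max_depth Maximum subsumption depth of any concept.
#' @param p_second_parent Probability a non-root concept gets a second
#'   parent (the graph is a DAG, not a tree).
#' @param complete_fraction Fraction of non-root concepts planted with a
#'   complete mapping.
#' @param lexical_fraction Among concepts without a complete mapping, the
#'   fraction planted with a lexically reachable head term.
#' @param level_probs Distribution of planted demodification levels
#'   (1, 2, ...).
#' @param pp_fraction Among lexically planted terms, the fraction built with
#'   one prepositional attachment.
#' @param head_only_fraction Among non-complete, non-lexical concepts, the
#'   fraction given a bare head-noun term.
#' @param seed Mandatory integer seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_concepts = 200L, max_depth = 6L,
                         p_second_parent = 0.2, complete_fraction = 0.30,
                         lexical_fraction = 0.33,
                         level_probs = c(0.75, 0.20, 0.05),
                         pp_fraction = 0.15, head_only_fraction = 0.05,
                         seed) {
  if (missing(seed)) stop("fixture_spec requires an explicit seed")
  fr <- c(p_second_parent, complete_fraction, lexical_fraction,
          pp_fraction, head_only_fraction)
  if (any(fr < 0 | fr > 1)) stop("all fractions must lie in [0, 1]")
  if (n_concepts < 1) stop("n_concepts must be positive")
  if (max_depth < 1 && n_concepts > 1) {
    stop("max_depth < 1 cannot host any concept besides the root")
  }
  if (abs(sum(level_probs) - 1) > 1e-8) {
    stop("level_probs must sum to 1")
  }
  structure(list(n_concepts = as.integer(n_concepts),
                 max_depth = as.integer(max_depth),
                 p_second_parent = p_second_parent,
                 complete_fraction = complete_fraction,
                 lexical_fraction = lexical_fraction,
                 level_probs = level_probs,
                 pp_fraction = pp_fraction,
                 head_only_fraction = head_only_fraction,
                 seed = as.integer(seed)),
            class = "fixture_spec")
}

#' Generate a synthetic fixture with planted ground truth
#'
#' Terms are built compositionally from disjoint vocabulary pools (one fresh
#' head word per concept, fresh modifier words per slot), so demodification
#' of a planted term provably reaches its lexicon-linked head at the planted
#' level and no cross-concept normalization collision can occur. Logical
#' ground truth is derived by an in-generator breadth-first ancestor search
#' over the generated graph, independent of the mapping engine's traversal.
#' The same seed yields byte-identical fixtures.
#'
#' @param spec A [fixture_spec()].
#' @return List with `source` (a `source_ontology`), `target`, `lexicon`,
#'   and `truth` — a data.frame with one row per concept: `id`, `category`,
#'   `lexical_level`, `lexical_targets`, `logical_level`, `logical_targets`
#'   (target sets semicolon-joined, sorted).
#' @export
generate_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, generate_fixture_impl(spec))
}

generate_fixture_impl <- function(spec) {
  n <- spec$n_concepts
  ids <- sprintf("S%04d", seq_len(n))
  depth <- integer(n)
  child <- character()
  parent <- character()

  # parents drawn from earlier concepts only: acyclic by construction
  for (i in seq_len(n)[-1]) {
    cand <- which(depth[seq_len(i - 1L)] < spec$max_depth)
    p1 <- cand[sample.int(length(cand), 1L)]
    ps <- p1
    if (length(cand) > 1L && stats::runif(1) < spec$p_second_parent) {
      cand2 <- setdiff(cand, p1)
      ps <- c(ps, cand2[sample.int(length(cand2), 1L)])
    }
    depth[i] <- min(depth[ps]) + 1L
    child <- c(child, rep(ids[i], length(ps)))
    parent <- c(parent, ids[ps])
  }

  kind <- character(n)
  kind[1] <- "root"
  for (i in seq_len(n)[-1]) {
    u <- stats::runif(1)
    kind[i] <- if (u < spec$complete_fraction) "complete" else {
      v <- stats::runif(1)
      if (v < spec$lexical_fraction) "lexical" else
        if (stats::runif(1) < spec$head_only_fraction) "head_only" else
          "plain"
    }
  }

  terms <- character(n)
  terms[1] <- "phenotypic abnormality"
  lex_terms <- list()
  lex_links <- list()
  tgt_rows <- list()
  lexical_level <- rep(NA_integer_, n)
  lexical_targets <- rep("", n)
  complete_target <- rep(NA_character_, n)
  mod_counter <- 0L
  new_mods <- function(k) {
    out <- sprintf("mod%04d", mod_counter + seq_len(k))
    mod_counter <<- mod_counter + k
    out
  }

  for (i in seq_len(n)[-1]) {
    if (kind[i] == "complete") {
      head_w <- sprintf("condition%04d", i)
      with_mod <- stats::runif(1) < 0.5
      term <- if (with_mod) paste(new_mods(1L), head_w) else head_w
      tid <- sprintf("T%04d", i)
      gid <- sprintf("G%04d", i)
      lex_terms[[gid]] <- data.frame(group_id = gid, term = term,
                                     stringsAsFactors = FALSE)
      lex_links[[gid]] <- data.frame(group_id = gid, target_id = tid,
                                     stringsAsFactors = FALSE)
      tgt_rows[[tid]] <- data.frame(id = tid, term = term,
                                    term_type = "preferred",
                                    stringsAsFactors = FALSE)
      terms[i] <- term
      complete_target[i] <- tid
    } else if (kind[i] == "lexical") {
      head_w <- sprintf("sign%04d", i)
      lev <- sample.int(length(spec$level_probs), 1L,
                        prob = spec$level_probs)
      use_pp <- stats::runif(1) < spec$pp_fraction
      term <- if (use_pp) {
        main_mods <- if (lev > 1L) new_mods(lev - 1L) else character()
        paste(c(main_mods, head_w, "of", new_mods(1L)), collapse = " ")
      } else {
        paste(c(new_mods(lev), head_w), collapse = " ")
      }
      tid <- sprintf("T%04d", i)
      gid <- sprintf("G%04d", i)
      lex_terms[[gid]] <- data.frame(group_id = gid, term = head_w,
                                     stringsAsFactors = FALSE)
      lex_links[[gid]] <- data.frame(group_id = gid, target_id = tid,
                                     stringsAsFactors = FALSE)
      tgt_rows[[tid]] <- data.frame(id = tid, term = head_w,
                                    term_type = "preferred",
                                    stringsAsFactors = FALSE)
      terms[i] <- term
      lexical_level[i] <- lev
      lexical_targets[i] <- tid
    } else if (kind[i] == "head_only") {
      terms[i] <- sprintf("trait%04d", i)
    } else {
      n_mod <- sample.int(2L, 1L)
      terms[i] <- paste(c(new_mods(n_mod), sprintf("trait%04d", i)),
                        collapse = " ")
    }
  }

  concepts <- data.frame(id = ids, preferred_term = terms, synonyms = "",
                         stringsAsFactors = FALSE)
  edges <- data.frame(child = child, parent = parent,
                      stringsAsFactors = FALSE)
  source <- source_ontology(concepts, edges, ids[1])
  lexicon <- synonymy_lexicon(do.call(rbind, lex_terms),
                             do.call(rbind, lex_links))
  target <- target_terminology(do.call(rbind, tgt_rows))

  # logical truth: generator-side BFS over parents to the nearest
  # complete-mapped ancestor(s); kept independent of the engine's traversal
  parents_by_child <- split(edges$parent, edges$child)
  has_complete <- !is.na(complete_target)
  names(has_complete) <- ids
  tgt_of <- stats::setNames(complete_target, ids)
  logical_level <- rep(NA_integer_, n)
  logical_targets <- rep("", n)
  for (i in seq_len(n)) {
    if (has_complete[i]) next
    seen <- ids[i]
    frontier <- parents_by_child[[ids[i]]] %||% character()
    d <- 1L
    while (length(frontier)) {
      hits <- frontier[has_complete[frontier]]
      if (length(hits)) {
        logical_level[i] <- d
        logical_targets[i] <- paste(sort_c(unique(tgt_of[hits])),
                                    collapse = ";")
        break
      }
      seen <- c(seen, frontier)
      frontier <- setdiff(
        unique(unlist(parents_by_child[frontier], use.names = FALSE)), seen)
      d <- d + 1L
    }
  }

  category <- ifelse(has_complete, "complete",
              ifelse(!is.na(lexical_level) & !is.na(logical_level), "both",
              ifelse(!is.na(lexical_level), "lexical_only",
              ifelse(!is.na(logical_level), "logical_only", "unmapped"))))
  truth <- data.frame(
    id = ids, category = category,
    lexical_level = ifelse(has_complete, NA_integer_, lexical_level),
    lexical_targets = ifelse(has_complete, "", lexical_targets),
    logical_level = logical_level,
    logical_targets = logical_targets,
    stringsAsFactors = FALSE)
  truth$lexical_level[truth$category == "complete"] <- NA_integer_
  truth <- truth[order(truth$id, method = "radix"), , drop = FALSE]
  rownames(truth) <- NULL

  list(source = source, target = target, lexicon = lexicon, truth = truth)
}

#' Write a generated fixture to disk
#'
#' Emits the standard formats (`concepts.tsv`, `edges.tsv`, `target.tsv`,
#' `lexicon.tsv`) plus `truth.tsv` under `dir`. Same fixture, same bytes.
#'
#' @param fixture Output of [generate_fixture()] or [worked_example()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_source_ontology(fixture$source, dir)
  write_target_terminology(fixture$target, file.path(dir, "target.tsv"))
  write_lexicon(fixture$lexicon, file.path(dir, "lexicon.tsv"))
  if (!is.null(fixture$truth)) {
    utils::write.table(fixture$truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
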