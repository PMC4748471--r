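# shared builders for in-code fixtures; everything is generated at test time

# a tiny source ontology from a compact edge list
tiny_ontology <- function(terms, edges, root) {
  source_ontology(
    data.frame(id = names(terms), preferred_term = unname(terms),
               synonyms = "", stringsAsFactors = FALSE),
    data.frame(child = edges$child, parent = edges$parent,
               stringsAsFactors = FALSE),
    root = root)
}

# lexicon from group -> (members, targets) lists
tiny_lexicon <- function(groups) {
  terms <- do.call(rbind, lapply(names(groups), function(g) {
    data.frame(group_id = g, term = groups[[g]]$members,
               stringsAsFactors = FALSE)
  }))
  links <- do.call(rbind, lapply(names(groups), function(g) {
    tids <- groups[[g]]$targets
    if (!length(tids)) return(NULL)
    data.frame(group_id = g, target_id = tids, stringsAsFactors = FALSE)
  }))
  synonymy_lexicon(terms, links)
}

tiny_target <- function(named_terms) {
  target_terminology(data.frame(
    id = names(named_terms), term = unname(named_terms),
    term_type = "preferred", stringsAsFactors = FALSE))
}

# random child->parent DAG on n nodes; parents only among earlier nodes
random_dag <- function(n, seed, p_second = 0.3) {
  set.seed(seed)
  ids <- sprintf("N%03d", seq_len(n))
  child <- character(); parent <- character()
  for (i in 2:n) {
    p1 <- sample.int(i - 1L, 1L)
    ps <- p1
    if (i > 2 && runif(1) < p_second) {
      p2 <- sample(setdiff(seq_len(i - 1L), p1), 1L)
      ps <- c(ps, p2)
    }
    child <- c(child, rep(ids[i], length(ps)))
    parent <- c(parent, ids[ps])
  }
  list(ids = ids, edges = data.frame(child = child, parent = parent,
                                     stringsAsFactors = FALSE))
}

# independent subset-enumeration oracle over modifier token indices:
# all variants of removing non-empty index subsets, with PP dragging
oracle_variants <- function(surfaces, unit_idx, pp_content = integer(),
                            pp_function = integer()) {
  k <- length(unit_idx)
  out <- list()
  for (mask in seq_len(2^k - 1L)) {
    sel <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    drop <- unit_idx[sel]
    if (length(pp_content) && all(pp_content %in% drop)) {
      drop <- c(drop, pp_function)
    }
    out[[length(out) + 1L]] <- list(
      text = paste(surfaces[-drop], collapse = " "),
      level = length(sel))
  }
  out
}

# targets reachable for a term through a prebuilt match index
index_targets_for <- function(idx, lex, term, config = mapping_config()) {
  groups <- lexicon_lookup(lex, term, config)
  targets <- unlist(idx$group_targets[groups], use.names = FALSE)
  if (is.null(targets)) character() else sort(unique(targets))
}

# build an ontology/target/lexicon triple for engine tests around one focus
# concept "X" whose ancestors' equivalences are freely configurable
chain_fixture <- function() {
  terms <- c(X = "Deep focus sign", A = "Mid sign", B = "High sign",
             R = "Root sign")
  edges <- list(child = c("X", "A", "B"), parent = c("A", "B", "R"))
  tiny_ontology(terms, edges, "R")
}
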