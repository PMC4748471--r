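# Minimal OBO 1.2/1.4 [Term]-stanza reader: id, name, EXACT synonyms, is_a,
# is_obsolete. Only what the source-ontology loader needs; no R OBO parser
# is part of the package's dependency set.

read_obo_terms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\\s*!.*$", "", lines)   # trailing comments
  lines <- trimws(lines)

  stanza_starts <- which(lines == "[Term]")
  other_starts <- which(grepl("^\\[", lines) & lines != "[Term]")
  ends <- c(sort(c(stanza_starts, other_starts))[-1] - 1L, length(lines))

  ids <- character()
  names_ <- character()
  syns <- character()
  children <- character()
  parents <- character()

  for (s in stanza_starts) {
    e <- ends[match(s, sort(c(stanza_starts, other_starts)))]
    block <- lines[(s + 1L):e]
    block <- block[nzchar(block)]
    get1 <- function(key) {
      hit <- block[startsWith(block, paste0(key, ":"))]
      if (!length(hit)) return(NA_character_)
      trimws(sub(paste0("^", key, ":"), "", hit[1]))
    }
    if (identical(get1("is_obsolete"), "true")) next
    id <- get1("id")
    nm <- get1("name")
    if (is.na(id) || is.na(nm)) next

    syn_lines <- block[startsWith(block, "synonym:")]
    exact <- syn_lines[grepl("\"\\s+EXACT\\b", syn_lines)]
    syn_txt <- regmatches(exact, regexpr("\"[^\"]*\"", exact))
    syn_txt <- gsub("^\"|\"$", "", syn_txt)

    isa <- block[startsWith(block, "is_a:")]
    pa <- trimws(sub("^is_a:", "", isa))
    pa <- vapply(strsplit(pa, "\\s+"), `[`, character(1), 1L)

    ids <- c(ids, id)
    names_ <- c(names_, nm)
    syns <- c(syns, paste(unique(syn_txt), collapse = "|"))
    if (length(pa)) {
      children <- c(children, rep(id, length(pa)))
      parents <- c(parents, pa)
    }
  }

  concepts <- data.frame(id = ids, preferred_term = names_, synonyms = syns,
                         stringsAsFactors = FALSE)
  # drop edges pointing at concepts outside the file (or obsolete)
  keep <- parents %in% ids
  edges <- data.frame(child = children[keep], parent = parents[keep],
                      stringsAsFactors = FALSE)
  list(concepts = concepts, edges = edges)
}
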