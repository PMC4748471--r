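test_that("OBO loading restricts to root descendants, drops obsolete terms and non-exact synonyms", {
  obo <- c(
    "format-version: 1.2",
    "",
    "[Term]",
    "id: HP:0000001",
    "name: All",
    "",
    "[Term]",
    "id: HP:0000118",
    "name: Phenotypic abnormality",
    "is_a: HP:0000001 ! All",
    "",
    "[Term]",
    "id: HP:0000202",
    "name: Oral cleft",
    "synonym: \"Cleft of the mouth\" EXACT []",
    "synonym: \"Mouth thing\" RELATED []",
    "is_a: HP:0000118 ! Phenotypic abnormality",
    "",
    "[Term]",
    "id: HP:0009999",
    "name: Gone concept",
    "is_obsolete: true",
    "is_a: HP:0000118",
    "",
    "[Typedef]",
    "id: part_of",
    "name: part of")
  f <- withr::local_tempfile(fileext = ".obo")
  writeLines(obo, f)
  onto <- load_source_ontology(f, format = "obo", root_id = "HP:0000118")
  expect_setequal(onto$concepts$id, c("HP:0000118", "HP:0000202"))
  expect_equal(onto$edges,
               data.frame(child = "HP:0000202", parent = "HP:0000118"))
  tt <- concept_terms(onto)
  expect_true("Cleft of the mouth" %in% tt$term)
  expect_false("Mouth thing" %in% tt$term)
  expect_error(load_source_ontology(f, format = "obo", root_id = "HP:9"),
               "HP:9")
})

test_that("degenerate root yields one concept and zero edges", {
  onto <- tiny_ontology(c(R = "Root only"),
                        list(child = character(), parent = character()), "R")
  expect_equal(nrow(onto$concepts), 1L)
  expect_equal(nrow(onto$edges), 0L)
})

test_that("cycles are a hard error naming a cycle", {
  expect_error(
    tiny_ontology(c(A = "a", B = "b", R = "r"),
                  list(child = c("A", "B", "R"), parent = c("B", "A", "A")),
                  "R"),
    "cycle")
})

test_that("source ontology round-trips through the fixture TSV dialect", {
  fx <- generate_fixture(fixture_spec(n_concepts = 40, seed = 11))
  d <- withr::local_tempdir()
  write_source_ontology(fx$source, d)
  back <- load_source_ontology(d, format = "tsv", root_id = fx$source$root)
  expect_identical(back$concepts, fx$source$concepts)
  expect_identical(back$edges, fx$source$edges)
})

test_that("every loaded concept reaches the root (BFS oracle)", {
  fx <- generate_fixture(fixture_spec(n_concepts = 60, seed = 3))
  onto <- fx$source
  g <- igraph::graph_from_data_frame(
    onto$edges, directed = TRUE,
    vertices = data.frame(name = onto$concepts$id))
  d <- igraph::distances(g, v = onto$concepts$id, to = onto$root,
                         mode = "out")
  expect_true(all(is.finite(d)))
})

test_that("target terminology loading collapses duplicates and enforces one preferred term", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tterm\tterm_type",
               "32398004\tBronchitis\tpreferred",
               "32398004\tBronchitis NOS\tsynonym",
               "32398004\tBronchitis NOS\tsynonym",
               "10509002\tAcute bronchitis\tpreferred",
               "35301006\tAcute tracheobronchitis\tpreferred"), f)
  tgt <- load_target_terminology(f)
  expect_equal(nrow(tgt), 3L)
  expect_equal(tgt$synonyms[tgt$id == "32398004"], "Bronchitis NOS")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tterm\tterm_type", "X1\tA name\tsynonym"), f2)
  expect_error(load_target_terminology(f2), "X1")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("id\tterm\tterm_type", f3)
  expect_equal(nrow(load_target_terminology(f3)), 0L)
})

test_that("target loader count equals distinct ids on a randomized fixture", {
  set.seed(42)
  n <- 100
  ids <- sprintf("T%03d", sample.int(60, n, replace = TRUE))
  rows <- data.frame(id = ids, term = paste("name", ids),
                     term_type = "preferred", stringsAsFactors = FALSE)
  syn <- data.frame(id = ids, term = paste("syn", seq_len(n)),
                    term_type = "synonym", stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(rbind(rows, syn), f, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tgt <- load_target_terminology(f)
  expect_equal(nrow(tgt), length(unique(ids)))
})

test_that("lexicon dialects load groups and target links; ambiguity preserved", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("group_id\tterm\tlinked_target_id",
               "G1\tbronchitis\t32398004",
               "G1\tbronchitis\t10509002",
               "G1\tbronchitis\t35301006",
               "G2\tlone term\t",
               "G3\tbronchitis\t",
               "badrow"), f)
  expect_warning(lex <- load_lexicon(f, dialect = "tsv"), "line")
  expect_setequal(lexicon_lookup(lex, "bronchitis"), c("G1", "G3"))
  idx <- build_match_index(lex, NULL)
  expect_setequal(index_targets_for(idx, lex, "bronchitis"),
                  c("32398004", "10509002", "35301006"))
  expect_equal(lexicon_lookup(lex, "lone term"), "G2")
  expect_equal(index_targets_for(idx, lex, "lone term"), character())
  # lookup is total
  expect_equal(lexicon_lookup(lex, "no such term"), character())
  expect_equal(lexicon_lookup(lex, ""), character())

  frrf <- withr::local_tempfile(fileext = ".rrf")
  writeLines(c("C0006277|TARGET|32398004|Bronchitis",
               "C0006277|MSH|D001991|Bronchitis",
               "C0006277|TARGET|10509002|Acute bronchitis"), frrf)
  rlex <- load_lexicon(frrf, dialect = "rrf")
  expect_equal(lexicon_lookup(rlex, "Bronchitis"), "C0006277")
  ridx <- build_match_index(rlex, NULL)
  expect_setequal(ridx$group_targets[["C0006277"]],
                  c("32398004", "10509002"))

  fempty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("group_id\tterm\tlinked_target_id", fempty)
  expect_error(load_lexicon(fempty), "no lexicon groups")
})

test_that("same term planted in two groups returns both (linear-scan oracle)", {
  set.seed(5)
  gids <- sprintf("G%02d", 1:20)
  terms <- sprintf("word%02d", sample.int(12, 20, replace = TRUE))
  lex <- synonymy_lexicon(data.frame(group_id = gids, term = terms))
  for (tm in unique(terms)) {
    oracle <- sort(unique(gids[terms == tm]))
    expect_identical(lexicon_lookup(lex, tm), oracle)
  }
})
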