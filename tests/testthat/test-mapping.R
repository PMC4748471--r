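test_that("normalization folds case, plurals and stopwords but not true lexical variance", {
  expect_equal(normalize_term("Bronchitis"), normalize_term("bronchitis"))
  expect_equal(normalize_term("Aplastic clavicles"),
               normalize_term("aplastic clavicle"))
  # synonymy beyond the pipeline must come from the lexicon, not normalization
  expect_false(normalize_term("Atrophy of kidney") ==
                 normalize_term("renal atrophy"))
  # idempotence
  x <- c("Abnormality of the mouth", "Recurrent bronchitis", "IgA, (x)")
  n1 <- normalize_term(x)
  expect_identical(normalize_term(n1), n1)
  # bag mode is order-insensitive; off restores order sensitivity
  expect_equal(normalize_term("renal atrophy"), normalize_term("atrophy renal"))
  cfg <- mapping_config(bag_normalization = FALSE)
  expect_false(normalize_term("renal atrophy", cfg) ==
                 normalize_term("atrophy renal", cfg))
})

test_that("complete lexical mapping collects all group-linked targets", {
  fx <- worked_example("extended_example")
  em <- complete_lexical_map(fx$source, fx$lexicon, fx$target)
  expect_setequal(eq_targets(em, "HP:0012387"),
                  c("32398004", "10509002", "35301006"))
  expect_setequal(eq_targets(em, "HP:0002788"),
                  c("54150009", "195708003"))
  # no term in any group -> absent, not empty
  expect_equal(eq_targets(em, "HP:0002109"), character())
  expect_false("HP:0002109" %in% names(em$targets))
  expect_false("HP:0002837" %in% names(em$targets))
})

test_that("a group matched through a target term (no explicit link) still maps", {
  onto <- tiny_ontology(c(X = "Mouth anomaly thing", R = "Root"),
                        list(child = "X", parent = "R"), "R")
  lex <- tiny_lexicon(list(G1 = list(members = c("mouth anomaly thing",
                                                 "anomaly of the mouth"),
                                     targets = character())))
  tgt <- tiny_target(c("128334002" = "Anomaly of the mouth"))
  em <- complete_lexical_map(onto, lex, tgt)
  expect_equal(eq_targets(em, "X"), "128334002")
})

test_that("partial lexical mapping finds the minimal level and unions targets", {
  fx <- worked_example("extended_example")
  em <- complete_lexical_map(fx$source, fx$lexicon, fx$target)
  pm <- partial_lexical_map(fx$source, "HP:0002837", em, fx$lexicon,
                            fx$target)
  expect_equal(pm$level, 1L)
  expect_setequal(pm$targets, c("32398004", "10509002", "35301006"))
  expect_equal(pm$provenance$variant, "bronchitis")

  fx2 <- worked_example("bilateral_renal_atrophy")
  em2 <- complete_lexical_map(fx2$source, fx2$lexicon, fx2$target)
  pm2 <- partial_lexical_map(fx2$source, "HP:0012586", em2, fx2$lexicon,
                             fx2$target)
  expect_equal(pm2$level, 1L)
  expect_equal(pm2$targets, "197659005")
  expect_equal(pm2$provenance$variant, "renal atrophy")

  # head-only terms have no variants
  onto <- tiny_ontology(c(X = "Gastroschisis", R = "Root"),
                        list(child = "X", parent = "R"), "R")
  em3 <- complete_lexical_map(onto, fx2$lexicon, fx2$target)
  expect_null(partial_lexical_map(onto, "X", em3, fx2$lexicon, fx2$target))

  # calling on a completely mapped concept violates the contract
  expect_error(partial_lexical_map(fx$source, "HP:0012387", em, fx$lexicon,
                                   fx$target), "complete")
})

test_that("reported lexical level is minimal (exhaustive re-enumeration oracle)", {
  # only the bare head is in the lexicon, so the minimal level is k = 2
  onto <- tiny_ontology(c(X = "crusty nodular keratoma", R = "Root"),
                        list(child = "X", parent = "R"), "R")
  lex <- tiny_lexicon(list(G1 = list(members = "keratoma", targets = "T1")))
  tgt <- tiny_target(c(T1 = "Keratoma"))
  em <- complete_lexical_map(onto, lex, tgt)
  idx <- build_match_index(lex, tgt)
  pm <- partial_lexical_map(onto, "X", em, lex, tgt)
  expect_equal(pm$level, 2L)
  expect_equal(pm$targets, "T1")
  v <- demodify(parse_term("crusty nodular keratoma"))
  below <- v$variant[v$level < pm$level]
  expect_length(below, 2L)
  for (b in below) {
    expect_equal(index_targets_for(idx, lex, b), character())
  }
})

test_that("partial logical mapping stops at the first distance with a hit", {
  fx <- worked_example("extended_example")
  em <- complete_lexical_map(fx$source, fx$lexicon, fx$target)
  pm <- partial_logical_map(fx$source, "HP:0002837", em)
  expect_equal(pm$level, 1L)
  expect_setequal(pm$targets, c("32398004", "10509002", "35301006",
                                "54150009", "195708003"))
  expect_setequal(pm$provenance$ancestor_id, c("HP:0012387", "HP:0002788"))

  fx3 <- worked_example("short_upper_lip")
  em3 <- complete_lexical_map(fx3$source, fx3$lexicon, fx3$target)
  pm3 <- partial_logical_map(fx3$source, "HP:0000188", em3)
  expect_equal(pm3$level, 3L)
  expect_equal(pm3$targets, "128334002")

  fx4 <- worked_example("oral_cleft")
  em4 <- complete_lexical_map(fx4$source, fx4$lexicon, fx4$target)
  pm4 <- partial_logical_map(fx4$source, "HP:0000202", em4)
  expect_equal(pm4$level, 1L)
  expect_equal(pm4$targets, "128334002")

  # every ancestor lacking an equivalence -> none
  expect_null(partial_logical_map(fx$source, "HP:0002109", em))
  expect_error(partial_logical_map(fx$source, "HP:9999999", em), "graph")
})

test_that("logical level equals BFS shortest distance (igraph oracle, random DAGs)", {
  for (seed in 1:6) {
    dag <- random_dag(30, seed = seed)
    terms <- stats::setNames(paste("term", dag$ids), dag$ids)
    onto <- tiny_ontology(terms, as.list(dag$edges), dag$ids[1])
    set.seed(seed + 100)
    eq_ids <- sample(dag$ids[-1], 8)
    em <- structure(list(
      targets = stats::setNames(lapply(eq_ids, function(i) paste0("T-", i)),
                                eq_ids),
      groups = list(), df = NULL), class = "equivalence_map")
    g <- igraph::graph_from_data_frame(onto$edges, directed = TRUE,
                                       vertices = dag$ids)
    dmat <- igraph::distances(g, mode = "out")
    for (id in setdiff(dag$ids, eq_ids)) {
      pm <- partial_logical_map(onto, id, em)
      dists <- dmat[id, eq_ids]
      if (all(is.infinite(dists))) {
        expect_null(pm)
      } else {
        dmin <- min(dists)
        expect_equal(pm$level, as.integer(dmin), info = paste(seed, id))
        # union completeness over ALL ancestors at the minimal distance
        expect_setequal(pm$targets,
                        paste0("T-", eq_ids[dists == dmin]))
      }
    }
  }
})

test_that("pipeline categories are exclusive and exhaustive", {
  fx <- worked_example("extended_example")
  res <- run_pipeline(fx$source, fx$target, fx$lexicon)
  cats <- res$categories
  expect_setequal(cats$source_id, fx$source$concepts$id)
  expect_equal(nrow(cats), nrow(fx$source$concepts))
  complete_ids <- cats$source_id[cats$category == "complete"]
  expect_false(any(complete_ids %in% res$partial_lexical$source_id))
  expect_false(any(complete_ids %in% res$partial_logical$source_id))
  expect_equal(cats$category[cats$source_id == "HP:0002837"], "both")
  # lexical targets are a subset of logical targets on this fixture
  lt <- res$partial_lexical$target_id[
    res$partial_lexical$source_id == "HP:0002837"]
  gt <- res$partial_logical$target_id[
    res$partial_logical$source_id == "HP:0002837"]
  expect_true(all(lt %in% gt))
})

test_that("a fixture where every concept maps completely has zero partials", {
  onto <- tiny_ontology(c(X = "alpha sign", Y = "beta sign", R = "root sign"),
                        list(child = c("X", "Y"), parent = c("Y", "R")), "R")
  lex <- tiny_lexicon(list(
    G1 = list(members = "alpha sign", targets = "T1"),
    G2 = list(members = "beta sign", targets = "T2"),
    G3 = list(members = "root sign", targets = "T3")))
  tgt <- tiny_target(c(T1 = "alpha sign", T2 = "beta sign", T3 = "root sign"))
  res <- run_pipeline(onto, tgt, lex)
  expect_true(all(res$categories$category == "complete"))
  expect_equal(nrow(res$partial_lexical), 0L)
  expect_equal(nrow(res$partial_logical), 0L)
})

test_that("pipeline reruns are byte-identical", {
  fx <- generate_fixture(fixture_spec(n_concepts = 80, seed = 31))
  r1 <- run_pipeline(fx$source, fx$target, fx$lexicon)
  r2 <- run_pipeline(fx$source, fx$target, fx$lexicon)
  keep <- setdiff(names(r1), "config")
  s1 <- jsonlite::toJSON(unclass(r1)[keep], auto_unbox = TRUE, digits = NA)
  s2 <- jsonlite::toJSON(unclass(r2)[keep], auto_unbox = TRUE, digits = NA)
  expect_identical(as.character(s1), as.character(s2))
})

test_that("congenital flag marks conflated targets without altering results", {
  fx <- worked_example("oral_cleft")
  cfg <- mapping_config(flag_congenital = TRUE)
  res <- run_pipeline(fx$source, fx$target, fx$lexicon, cfg)
  row <- res$partial_logical[res$partial_logical$source_id == "HP:0000202", ]
  expect_true(row$congenital_only)     # "Congenital anomaly of mouth"
  res0 <- run_pipeline(fx$source, fx$target, fx$lexicon)
  expect_identical(res$partial_logical[names(res0$partial_logical)],
                   res0$partial_logical)
})
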