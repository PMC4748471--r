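#' Hand-built worked-example fixtures
#'
#' Small, fully specified source/target/lexicon triples encoding classic
#' phenotype-mapping situations, each built in code (no files to download):
#'
#' * `"extended_example"` — *Recurrent bronchitis* [HP:0002837] with three
#'   direct ancestors; the bare head `bronchitis` is synonymous with three
#'   target concepts, and *Recurrent upper respiratory tract infections*
#'   with two more, so the concept maps lexically (level 1, 3 targets) and
#'   logically (level 1, 5 targets).
#' * `"bilateral_renal_atrophy"` — *Bilateral renal atrophy* [HP:0012586];
#'   the level-1 variant `renal atrophy` reaches *Atrophy of kidney*
#'   [197659005] while no ancestor holds an equivalence.
#' * `"short_upper_lip"` — a four-deep chain in which only *Abnormality of
#'   the mouth* [HP:0000153] holds an equivalence, making *Short upper lip*
#'   [HP:0000188] a level-3 logical mapping.
#' * `"oral_cleft"` — *Oral cleft* [HP:0000202] under HP:0000153: a level-1
#'   logical mapping to [128334002].
#' * `"congenital_absence_uvula"` — *Congenital absence of uvula*
#'   [HP:0010292], profile `[MOD-HEAD][PREP-HEAD]`; exercises
#'   preposition-dragging during demodification. Its lexicon group and
#'   target id (prefix `SYN`) are synthetic stand-ins — no published mapping
#'   exists for this concept — so the level-1 path is testable end to end.
#'
#' @param name One of the five fixture names above; anything else is a hard
#'   error listing the valid names.
#' @return List with `source` (a `source_ontology`), `target`
#'   (a `target_terminology`) and `lexicon` (a `synonymy_lexicon`).
#' @export
#' @examples
#' fx <- worked_example("extended_example")
#' fx$source
worked_example <- function(name) {
  valid <- c("extended_example", "bilateral_renal_atrophy",
             "short_upper_lip", "oral_cleft", "congenital_absence_uvula")
  if (length(name) != 1L || !name %in% valid) {
    stop("unknown worked example '", name, "'; valid names: ",
         paste(valid, collapse = ", "))
  }
  build <- function(concepts, edges, targets, groups) {
    src <- source_ontology(
      data.frame(id = names(concepts), preferred_term = unname(concepts),
                 synonyms = "", stringsAsFactors = FALSE),
      data.frame(child = edges$child, parent = edges$parent,
                 stringsAsFactors = FALSE),
      root = names(concepts)[length(concepts)])
    tgt <- target_terminology(data.frame(
      id = names(targets), term = unname(targets), term_type = "preferred",
      stringsAsFactors = FALSE))
    lex <- synonymy_lexicon(groups$terms, groups$links)
    list(source = src, target = tgt, lexicon = lex)
  }
  switch(name,
    extended_example = build(
      concepts = c(
        "HP:0002837" = "Recurrent bronchitis",
        "HP:0002109" = "Abnormality of the bronchi",
        "HP:0012387" = "Bronchitis",
        "HP:0002788" = "Recurrent upper respiratory tract infections",
        "HP:0002086" = "Abnormality of the respiratory system",
        "HP:0002719" = "Recurrent infections",
        "HP:0000118" = "Phenotypic abnormality"),
      edges = list(
        child = c("HP:0002837", "HP:0002837", "HP:0002837", "HP:0002109",
                  "HP:0012387", "HP:0002788", "HP:0002086", "HP:0002719"),
        parent = c("HP:0002109", "HP:0012387", "HP:0002788", "HP:0002086",
                   "HP:0002086", "HP:0002719", "HP:0000118", "HP:0000118")),
      targets = c(
        "32398004" = "Bronchitis",
        "10509002" = "Acute bronchitis",
        "35301006" = "Acute tracheobronchitis",
        "54150009" = "Upper respiratory infection",
        "195708003" = "Recurrent upper respiratory tract infection"),
      groups = list(
        terms = data.frame(
          group_id = c("G1", "G2", "G2"),
          term = c("bronchitis",
                   "recurrent upper respiratory tract infections",
                   "recurrent upper respiratory tract infection"),
          stringsAsFactors = FALSE),
        links = data.frame(
          group_id = c("G1", "G1", "G1", "G2", "G2"),
          target_id = c("32398004", "10509002", "35301006",
                        "54150009", "195708003"),
          stringsAsFactors = FALSE))),
    bilateral_renal_atrophy = build(
      concepts = c(
        "HP:0012586" = "Bilateral renal atrophy",
        "HP:0000077" = "Abnormality of the kidney",
        "HP:0000118" = "Phenotypic abnormality"),
      edges = list(child = c("HP:0012586", "HP:0000077"),
                   parent = c("HP:0000077", "HP:0000118")),
      targets = c("197659005" = "Atrophy of kidney"),
      groups = list(
        terms = data.frame(
          group_id = c("G1", "G1"),
          term = c("renal atrophy", "atrophy of kidney"),
          stringsAsFactors = FALSE),
        links = data.frame(group_id = "G1", target_id = "197659005",
                           stringsAsFactors = FALSE))),
    short_upper_lip = build(
      concepts = c(
        "HP:0000188" = "Short upper lip",
        "HP:0000177" = "Abnormality of upper lip",
        "HP:0000159" = "Abnormality of the lip",
        "HP:0000153" = "Abnormality of the mouth",
        "HP:0000118" = "Phenotypic abnormality"),
      edges = list(
        child = c("HP:0000188", "HP:0000177", "HP:0000159", "HP:0000153"),
        parent = c("HP:0000177", "HP:0000159", "HP:0000153", "HP:0000118")),
      targets = c("128334002" = "Congenital anomaly of mouth"),
      groups = list(
        terms = data.frame(
          group_id = c("G1", "G1", "G1"),
          term = c("abnormality of the mouth", "congenital anomaly of mouth",
                   "mouth abnormalities"),
          stringsAsFactors = FALSE),
        links = data.frame(group_id = "G1", target_id = "128334002",
                           stringsAsFactors = FALSE))),
    oral_cleft = build(
      concepts = c(
        "HP:0000202" = "Oral cleft",
        "HP:0000153" = "Abnormality of the mouth",
        "HP:0000118" = "Phenotypic abnormality"),
      edges = list(child = c("HP:0000202", "HP:0000153"),
                   parent = c("HP:0000153", "HP:0000118")),
      targets = c("128334002" = "Congenital anomaly of mouth"),
      groups = list(
        terms = data.frame(
          group_id = c("G1", "G1"),
          term = c("abnormality of the mouth", "congenital anomaly of mouth"),
          stringsAsFactors = FALSE),
        links = data.frame(group_id = "G1", target_id = "128334002",
                           stringsAsFactors = FALSE))),
    congenital_absence_uvula = build(
      concepts = c(
        "HP:0010292" = "Congenital absence of uvula",
        "HP:0000118" = "Phenotypic abnormality"),
      edges = list(child = "HP:0010292", parent = "HP:0000118"),
      targets = c("SYN0000001" = "Absence of uvula (synthetic)"),
      groups = list(
        terms = data.frame(group_id = "G1", term = "absence of uvula",
                           stringsAsFactors = FALSE),
        links = data.frame(group_id = "G1", target_id = "SYN0000001",
                           stringsAsFactors = FALSE))))
}
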