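---
title: "Partial mapping between phenotype terminologies: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partial mapping between phenotype terminologies: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phemap)
```

## The problem

Research phenotype ontologies (HPO-like) are deliberately finer-grained than
clinical terminologies (SNOMED CT-like). Equivalence ("complete") mappings
therefore cover only a minority of source concepts; for the rest, the
next-best relation is a *partial* mapping — a subclass (subsumption) relation
from a specific source concept to a more general target concept. `phemap`
derives partial mappings by two independent routes and contrasts them:

* **Partial lexical mapping.** Compositional terms such as *Bilateral renal
  atrophy* encode their specificity in modifiers. Deleting modifiers
  ("demodification") yields more general terms — *renal atrophy* — that may
  map completely. The *level* of the mapping counts the modifier units
  removed.
* **Partial logical mapping.** If an ancestor of the source concept in the
  is-a hierarchy is equivalent to some target concept, the source concept is
  a subclass of that target. The *level* counts is-a edges to the closest
  such ancestor.

Both routes rest on a synonymy lexicon (UMLS-like): groups of terms treated
as synonymous, each group optionally linked to target concept identifiers.
A source concept maps *completely* to every target sharing one of its
synonym groups.

## The shallow parser

The published approach used a full NLP minimal-commitment parser to assign
token roles. `phemap` replaces it with a deterministic rule-based profiler:

* tokens split on whitespace; hyphens stay inside tokens
  (*Pre-eclampsia* is one token);
* prepositions (`of in at on with to by from for during`) and determiners
  (`the a an`) are closed-class lists, overridable via plain-text word
  lists (`read_word_list()`); a determiner only counts as DET immediately
  after a preposition;
* each preposition opens a new phrase; within each phrase the final content
  token is HEAD and earlier content tokens are MOD;
* numbers and ordinals ("5th") are ordinary content tokens.

This reproduces the conventional profiles — `[MOD-MOD-HEAD]` for *Bilateral
renal atrophy*, `[MOD-HEAD][PREP-HEAD]` for *Congenital absence of uvula*,
`[HEAD][PREP-DET-HEAD]` for *Abnormality of the philtrum* — without an NLP
dependency, at the cost of two known failure modes, both deliberate:

* **Multiword heads.** *Pyruvate dehydrogenase complex deficiency* parses as
  three modifiers plus *deficiency*; *Tetralogy of Fallot* splits at "of".
  No multiword-head lexicon is shipped; the `atomic_terms` hook in
  `mapping_config()` lets users fuse known phrases into single HEAD tokens.
* **Coordination.** Terms with "and"/"or" and terms with more than one
  prepositional attachment are not analysed; they land in the
  `complex_multi_pp` or `unparsed` buckets and are reported as such.

Eligibility follows the profile: `[HEAD]` terms are `head_only` (nothing to
remove); more than one prepositional attachment is `complex_multi_pp`;
everything else parsed is `demodifiable`.

## Demodification and level accounting

`demodify()` enumerates every non-empty subset of *modifier units* in
increasing order of aggressiveness (level = units removed), until only the
main head noun remains. A unit is either one MOD of the main phrase or one
content token of the single prepositional attachment. Two accounting rules
are design choices worth stating:

* **Function words are never counted.** Removing the last content token of a
  prepositional attachment drags its preposition and determiner out
  automatically, at no extra level. The alternative — counting "of" as its
  own modifier — would inflate levels: *Bilateral renal atrophy* must map at
  level 1 through *renal atrophy*, and analogous single-deletion examples
  behave the same way only under this rule.
* **Duplicates keep the lowest level.** After deletion, distinct subsets can
  collide on one surface string; the least-aggressive derivation wins.

The enumeration is $2^k - 1$ variants for $k$ units; `max_units` (default
10, above the largest modifier count seen in practice, 8) bounds the
blow-up — longer terms are skipped with a warning. No inflection repair is
attempted on variants; robustness is delegated to normalization.

## Normalization

`normalize_term()` applies, in order: lowercasing; punctuation to spaces;
whitespace collapse; stopword removal (`the a an of`); naive plural
stripping (trailing "s" on tokens longer than three characters, sparing
"ss" endings and a user exceptions list); and token sorting ("bag" mode,
default on), which emulates UMLS-style order-insensitive normalization.
The pipeline is idempotent and deliberately shallow: *Atrophy of kidney*
and *renal atrophy* do **not** normalize together — bridging true lexical
variance is the lexicon's job, not the normalizer's. Naive stemming
artefacts ("abnormalities" → "abnormalitie") are harmless because both
sides of any comparison pass through the same pipeline, and a side benefit
is that near-misses do not silently merge.

## Mapping rules and tie-breaks

* **Complete first.** Partial mappings are computed only for concepts
  without a complete mapping (`partials_for_all` flips this for
  diagnostics). A completely mapped concept never carries a partial
  mapping, so every concept falls in exactly one coverage category:
  complete / lexical-only / logical-only / both / unmapped.
* **Lexical minimality, per concept.** Across *all* terms of a concept
  (preferred + synonyms) and all their variants, the minimum matching level
  L is found; targets are the union over all matching variants at L. When
  preferred term and synonym map at different levels, the per-concept
  minimum wins — the least-demodified term(s) define the mapping.
* **Ambiguity is preserved.** A variant matching several synonym groups
  unions all their targets (e.g. a bare *bronchitis* can legitimately reach
  three target concepts spanning related meanings).
* **Logical closest-ancestor.** Breadth-first over asserted is-a edges by
  distance d = 1, 2, …; at the first d with any equivalence-holding
  ancestor, level = d and targets = union over *all* ancestors at that
  distance; traversal stops there. With multiple parents, distance is the
  minimum over paths.
* **Congenitality conflation** (*anomaly* grouped with *congenital
  malformation* in real lexicons) is flagged, not fixed: with
  `flag_congenital = TRUE` partial-mapping rows gain a `congenital_only`
  column marking targets that mention "congenital" when the source term
  does not. Results are never altered.

## Reporting

`summarize_mappings()` gives exact integer counts per category with
percentages (round-half-even), level histograms at full resolution plus the
conventional bins (lexical 1/2/3+, logical 1–4/5+), and
`level_crosstab()` the lexical-by-logical level matrix with "none" margins;
the grand total equals the concepts lacking complete mappings.
`draw_review_sample()` reproduces the two manual-review designs — a 10%
fraction of the partial lexical mappings, or 25 per logical level — with a
mandatory explicit seed and no disturbance of the caller's RNG state.

## The synthetic generator

`generate_fixture()` builds a source ontology, target terminology and
lexicon with *planted* ground truth. Design:

* the is-a DAG draws parents only among earlier-generated concepts, so it is
  acyclic by construction; a second parent is added with probability 0.2;
* vocabulary pools are disjoint by construction (one fresh head word per
  concept, fresh modifier words per slot), so no cross-concept
  normalization collision can perturb the planted outcome;
* a planted lexical concept at level ℓ gets ℓ modifier units around a head
  word whose bare form is lexicon-linked — every shallower variant retains
  a unique modifier and provably cannot match;
* logical truth is *derived*, not planted: an in-generator breadth-first
  search (independent of the engine's traversal) finds each concept's
  nearest completely mapped ancestors.

Defaults mirror the study conditions at desk scale: ~30% of concepts with
complete mappings, a third of the remainder lexically reachable, planted
demodification levels distributed 0.75/0.20/0.05 (the observed dominance of
level 1–2), 15% of planted terms with one prepositional attachment, and a
small share of bare head nouns. What the generator does **not** emulate:
realistic term-length and profile distributions, synonym multiplicity,
lexicon noise (wrong groupings), or the congenitality conflation. Passing
the recovery tests therefore demonstrates the *machinery* is exact under
clean compositional conditions, not that real-corpus coverage rates would
be reproduced.

## Problem sizes and numerical choices

The test suite and the acceptance script use 200-concept fixtures across 10
to 20 seeds, 50-node random DAGs for the traversal oracle, and k ≤ 8 for
the demodification cardinality checks — sizes at which every check is
exhaustive rather than sampled. All orderings use radix (byte) sorting so
reruns are byte-identical regardless of locale; sampling always takes an
explicit seed and restores the caller's RNG state. Degenerate inputs are
defined, not errors: a root with no descendants loads as one concept;
punctuation-only terms classify as `unparsed`; lexicon lookup is total and
returns an empty set for unknown strings.

## Known limitations

* The rule-based profiler under-segments multiword heads and ignores
  coordination; both are surfaced as eligibility statuses rather than
  silently mis-parsed.
* Only asserted is-a edges are traversed — no OWL reasoning or
  classification, and the target terminology's own hierarchy is never used.
* Mappings are directional (source → target); no reverse mapping, no
  concept-pair confidence scoring, and no post-coordinated expression
  construction.
* Whether per-term or per-concept level minimality is the better selection
  rule is genuinely open; the per-concept minimum is implemented and
  documented above.
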