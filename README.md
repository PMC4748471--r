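# phemap

Partial lexical and logical mapping between phenotype terminologies.

Research phenotype ontologies (HPO-like) are finer-grained than the clinical
terminologies (SNOMED CT-like) used in electronic health records, so exact
(equivalence) mappings cover only a minority of concepts. For the rest, the
next-best relation is a **partial mapping** — a subclass relation from a
specific source concept to a more general target concept. `phemap` is for
terminology and ontology-alignment work: it derives partial mappings by two
complementary routes, reports which concepts each route reaches and how far
from the source the mapped target sits, and ships a synthetic fixture
generator with planted ground truth so the whole pipeline is testable with
no licensed downloads.

## Method

Let a source concept *c* carry terms *T(c)* (preferred + exact synonyms),
let *G* be a synonymy lexicon (UMLS-like groups of synonymous terms, each
group optionally linked to target concept ids), and let ≤ be the source
ontology's is-a order.

* **Complete lexical mapping** — *c* ≡ *t* when some term of *c* and the
  target *t* share a synonym group under normalization.
* **Partial lexical mapping** — each term is shallow-parsed into modifier
  (MOD), head (HEAD), preposition (PREP) and determiner (DET) roles, e.g.
  *Bilateral renal atrophy* → `[MOD-MOD-HEAD]`. Demodification deletes
  every non-empty combination of modifier units in increasing order of
  aggressiveness; the first (lowest) level at which a variant maps
  completely gives *c* ⊑ *t* at that level. Level = modifiers removed.
* **Partial logical mapping** — breadth-first up the is-a hierarchy; the
  closest ancestors holding a complete mapping give *c* ⊑ *t* at level =
  edge distance. Equal-distance ancestors contribute the union of their
  targets; more distant ancestors are never explored.

Complete-mapped concepts never carry partials, so every concept falls in
exactly one coverage category: complete / lexical-only / logical-only /
both / unmapped.

## Worked example

The classic demonstration concept is *Recurrent bronchitis* [HP:0002837],
which has no complete mapping. Lexically, removing the single modifier
leaves *bronchitis*, synonymous with three target concepts; logically, two
of its three parents hold equivalences contributing five targets:

```r
library(phemap)
fx  <- worked_example("extended_example")
res <- run_pipeline(fx$source, fx$target, fx$lexicon)
res
#> <mapping_result> 7 source concepts
#>    complete      2
#>    both          1
#>    lexical_only  0
#>    logical_only  0
#>    unmapped      4
res$partial_lexical
#>    source_id level target_id                 term    variant
#> 1 HP:0002837     1  10509002 Recurrent bronchitis bronchitis
#> 2 HP:0002837     1  32398004 Recurrent bronchitis bronchitis
#> 3 HP:0002837     1  35301006 Recurrent bronchitis bronchitis
res$partial_logical
#>    source_id level target_id ancestor_id
#> 1 HP:0002837     1 195708003  HP:0002788
#> 2 HP:0002837     1  54150009  HP:0002788
#> 3 HP:0002837     1  10509002  HP:0012387
#> 4 HP:0002837     1  32398004  HP:0012387
#> 5 HP:0002837     1  35301006  HP:0012387
```

Both routes fire at level 1; the three lexical targets are a subset of the
five logical ones — the two extra come through the second equivalent parent
(*Recurrent upper respiratory tract infections*). Demodification itself:

```r
demodify(parse_term("Bilateral renal atrophy"))
#>             variant level         removed
#> 1     renal atrophy     1       Bilateral
#> 2 Bilateral atrophy     1           renal
#> 3           atrophy     2 Bilateral+renal
```

`summary(res)` adds percentages and level histograms, `level_crosstab(res)`
the lexical-by-logical level matrix, and `draw_review_sample(res, mode,
seed)` reproducible review subsets. `generate_fixture(fixture_spec(seed = 1))`
builds a 200-concept synthetic triple whose planted categories, levels and
target sets the pipeline recovers exactly.

A command-line interface mirroring the R functions lives in `exec/phemap`
(subcommands `profile`, `demodify`, `map`, `report`, `fixture`).

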