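---
title: "Coding, comparing and analysing cranial suture contacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coding, comparing and analysing cranial suture contacts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sutura)
```

## The data model

CT reconstructions of skulls make it possible to describe not just *which*
bones touch, but *how*. `sutura` codes a contact between two bones with two
categorical axes:

* a **spatial relation** — `p` parallel, `o` overlapping / `u` underlying,
  `c` clasping / `cb` clasped-by, `t` vertically transverse. `o`/`u` and
  `c`/`cb` are the same geometry seen from either bone, so every record is
  stored on the alphabetically ordered bone pair with directional codes
  flipped as needed (`canonicalize_contact()`); canonicalization is
  idempotent and round-trips.
* an **ordinal suture depth** — `s` smooth < `if` faintly < `im` moderately
  < `is` strongly interfingering. A depth of `?` means the spatial relation
  could be determined but the suture type could not (typical of crushed
  fossil material); `?` takes part in no numeric comparison.

A contact that changes along its course is stored as an ordered list of
segments, **anterior to posterior**. Contacts can also be explicitly
`absent` (the bones demonstrably do not meet) or `unknown` (the region is
not interpretable); these are different statements and are kept distinct.
Two situations the schema cannot express are handled by convention and
flagged here: midline contacts of a paired bone with its antimere
(frontal–frontal and the like) are outside the model, because a record
requires two distinct bone names; and a contact known to exist whose
spatial relation is undeterminable is coded `unknown`, since there is no
"present, relation unknown" state.

## The similarity statistic

For two taxa, every bone pair scored in both enters the comparison. Two
present contacts are similar when their segments match: any difference in
spatial relation is dissimilarity, while suture depth only counts as
dissimilarity when the two depths are **at least two ordinal categories
apart** (the default `depth_threshold = 2`): a faintly interfingering
clasping suture is similar to a moderately interfingering one, but not to a
strongly interfingering one. Present versus absent is dissimilar. The
statistic is the percentage of comparable pairs that are similar, rounded
half-up to integers.

Several choices are not fixed by the rule above; `similarity_policy()`
exposes each:

* `both_absent` (default `exclude`): a pair absent in both taxa says the
  two skulls agree, but about a non-contact; by default it leaves the
  denominator. `count_similar` includes it.
* `unknown_depth` (default `treat_as_similar`): with matching spatial
  relations and a `?` depth, the pair is scored on the spatial relation
  alone. The alternative `exclude_pair` drops it from the denominator;
  since the fossil's similarities were evidently computed despite its
  undeterminable depths, wholesale exclusion cannot have been the original
  rule, which motivates the default.
* `multi_segment` (default `sequence_exact`): multi-segment contacts are
  compared position by position in anterior-to-posterior order (the order
  is part of the coding); `multiset` ignores order and asks for a perfect
  matching. Under both, differing segment counts are dissimilar.
* `excluded_bones` (default `nasal`): the nasal occurs in only one study
  taxon, so its contacts carry no comparative signal there.

Properties that hold by construction and are enforced by tests: symmetry in
the two taxa, percentages in [0, 100], self-similarity 100% when statuses
are known, `n_similar <= n_compared`, excluding a bone never increases the
denominator, and raising `depth_threshold` never lowers a similarity.

## The worked four-taxon example and its limits

`study_contacts()` ships a four-taxon table (one Cretaceous protostegid
known from a crushed holotype skull, two extant marine turtles, one extant
snapping turtle) transcribed from published per-bone anatomical
descriptions. Transcription conventions: "slightly interfingering" was read
as `if`; bare "interfingering" as `im`; "blunt", "loose" and "butting" as
`s`; segments were created only where the text describes
anterior-to-posterior variation, with variation along other axes
(medial/lateral, dorsal/ventral) collapsed to the first-mentioned coding;
depth `?` appears only in the fossil. The file lives under `inst/extdata/`
so it can be corrected against better sources without touching code.

```{r}
tab <- study_contacts()
sm <- similarity_matrix(tab, similarity_policy())
sm
rank_report(sm, "Desmatochelys_lowii")
```

The published study, working from its own tabulated contact data, reports
higher off-diagonal similarities (44/34/33/51/45/38) and finds the fossil
least similar to all three extant taxa. The matrix computed from this
prose-derived transcription does not reproduce those six values under any
setting of the policy flags, and the ordinal claim does not hold under all
of them either. The dominant cause is segment granularity: the running text
describes the same suture in different taxa at different levels of detail,
and both comparison modes treat differing segment counts as dissimilarity,
which depresses exactly the extant–extant comparisons the original found
most similar. The acceptance suite states the published values as the
expected result and is allowed to fail there, rather than papering over the
difference; reconciling it requires the study's own contact tables.

## Simulating contact evolution

`simulate_tables()` provides data with known structure for testing: an
ancestral table (each pair present with probability 1/2; a present contact
has one segment, or two with probability `p_multi_segment = 0.2`; spatial
relation uniform over the six codes, depth uniform over the four levels)
evolves along a tree by per-branch Poisson event counts — presence toggles
(`rate_gain_loss`), uniform spatial switches (`rate_spatial_switch`) and
±1 depth steps clipped to the scale (`rate_depth_step`), so a
two-category depth difference arises only through repeated events, matching
the granularity of the similarity rule. Default rates (0.3, 0.3, 0.1) per
unit branch length and 50 pairs give mid-range similarities on trees whose
branch lengths are uniform on [0.1, 1.9] (`random_tree()`). Everything is
seeded and byte-reproducible. The generator emulates categorical structure
and rate heterogeneity in time, not correlated evolution among neighbouring
sutures, ontogenetic fusion, or preservation artifacts — so passing
distance-decay and zero-rate tests validates the statistic's behaviour, not
any claim about real skulls.

Two calibration checks run in the acceptance suite: with all rates zero
every tip equals the ancestor and all similarities are 100%; with the
default rates, similarity correlates negatively with patristic distance
(Spearman) in at least 95% of 200 four-taxon replicates.

## Character matrices and their bookkeeping

`character_matrix` stores taxa × characters with `?` (missing), `-`
(gap/inapplicable, treated as missing when counting), polymorphic sets
(`{01}`), a per-character ordered flag and a per-taxon active flag; NEXUS
(DATA block, TYPESET `ord:` list) and TNT (`xread`, `ccode +`) dialects
round-trip. The study-specific bookkeeping is reproduced as data plus
guarded operations:

* `new_characters_table3()` — the seven added cranial characters with their
  published codings for the four study taxa (all other taxa become `?`),
  at positions 32, 33, 62, 64, 87, 88 and 92 of the final numbering.
  `insert_characters()` shifts the pre-existing columns accordingly and
  returns the old→new index map (old 74 → 78). The published dual
  numbering is internally inconsistent for two rows (its "(86)" and
  "(90)" cannot coexist with inserts at 87 and 88); the final-position
  reading is used, and the patch guard below surfaces any mismatch rather
  than miscoding silently.
* `dlowii_recoding_patch()` / `apply_recoding_patch()` — the ten
  reinterpretation-driven cell updates for the fossil, each guarded by its
  expected old state: the patch applies exactly once, and applying it to an
  already-patched or differently numbered matrix refuses with a report.
* `set_ordered()` — the 37 morphocline characters run ordered;
  `deactivate_taxa()` — deactivated taxa (81 in the study, leaving 73
  active of 154) stay in the file but leave the analysis.

The study's own 154 × 263 matrix is supplementary material that cannot be
redistributed here; tests and the acceptance script exercise the assembly
on a synthetic base matrix with the documented dimensions, which checks the
bookkeeping, not the published codings.

## Parsimony

Tree length honours the per-character flags: unordered characters cost 1
per change (Fitch state-sets on bitmasks), ordered characters cost
`|i − j|` (a Sankoff pass with linear costs). Missing leaves never force
changes; a polymorphic cell may resolve to any listed state free of charge
(the common TNT-style reading); length is invariant to rooting and leaf
order. `tree_length()` also reports, per character, the minimum conceivable
steps `m` and the star-tree length `g`, and the indices CI = Σm/L and
RI = (Σg − L)/(Σg − Σm). Two numerical conventions matter: `m` and the
informative-character flag are computed from determinate cells only, so
polymorphic cells can never push CI above 1; and with L = 0 or Σg = Σm the
indices are undefined and reported as `NA`, not forced to a number.
Excluding parsimony-uninformative characters from the index sums is
available as a flag and off by default.

`exhaustive_search()` (up to 9 taxa) enumerates topologies by stepwise
addition with branch-and-bound pruning — safe because adding a leaf never
shortens a tree, and ties are kept by pruning only on strict excess.
`heuristic_search()` follows the classic recipe: random addition sequences
(seeded) build a starting tree greedily, then tree bisection and
reconnection accepts the first strictly improving rearrangement until none
exists; trees of equal length reachable from the optimum are pooled up to
`plateau_cap` per replicate, deduplicated by a canonical Newick form. A
backbone constraint (a possibly non-binary tree over a taxon subset;
unconstrained taxa float freely) is enforced by rejection at every stage —
starting-tree placements and rearrangements that would violate it are never
accepted — which for this use is equivalent to searching the constrained
space. Determinism: the same seed yields the same tree set; all tie-breaks
are by deterministic edge order.

`strict_consensus()` intersects the bipartition sets of the inputs and
rebuilds the (possibly non-binary) tree; `prune_taxa()` drops named
wildcard taxa after consensus. Both are cross-checked in the tests against
independent bipartition computations (and `ape::consensus`).

Scale: the published analysis ran 1,000 random-addition replicates on 73
active taxa and reports 10 most parsimonious trees of 932 steps with the
supplementary matrix. That matrix is not available here, so the pipeline's
correctness is certified at oracle scale instead: per-character lengths
against exhaustive internal-assignment enumeration (100 random instances),
heuristic-vs-exhaustive best lengths on simulated 8-taxon matrices (≥95%
agreement required), and an end-to-end run at the documented 154 × 263
dimensions with a backbone constraint on a synthetic base matrix. These
sizes keep the whole suite within minutes while the engine itself has no
small-size assumptions.

## Pipelines

`run_phenetic_pipeline()` and `run_phylo_pipeline()` wire the stages
together file-to-file (contacts → similarity matrix, counts audit, rank
reports; base matrix → patched matrix → constrained search → strict
consensus → pruned consensus → length/CI/RI report) and write a manifest of
every policy flag and seed, so outputs are reproducible from inputs plus
manifest alone. Stage errors are reported with the stage name; a seed is
mandatory for any stochastic stage.
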