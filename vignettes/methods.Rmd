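---
title: "Compiling culture media and predicting organism–media pairings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compiling culture media and predicting organism–media pairings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mediarec)
```

`mediarec` addresses two connected problems.  First, published culture-media
recipes are bookkeeping puzzles — mixed units, strain-specific edit
instructions, declared volumes that may or may not mean anything, and
cross-references to stock solutions that are themselves recipes — and must
be compiled into standardized molar compositions before any quantitative
analysis is possible.  Second, a catalogue of *positive-only*
organism–media pairings carries predictive structure: related organisms
grow on related media.  This vignette documents the models, conventions
and numerical choices behind both halves, and what the accompanying tests
do and do not establish.

## The recipe compiler

### Units and the per-litre convention

Raw ingredient lines carry one of ~30 raw units mapped onto five standard
ones: g/l, l/l, mol/l, `trace` and `gas_substrate`.  Mass and molar
amounts are interpreted per litre of final medium, following the
microbiological rule of thumb that listed quantities produce one litre.
Percentages are mass/volume (1% = 10 g/l).  The unit map
(`default_unit_map()`) is a plain tibble and can be extended by
row-binding, keeping every conversion auditable.  `trace` and
`gas_substrate` entries deliberately carry no numeric concentration: a
trace supplement's dose is not meaningfully comparable across recipes, and
a gas substrate is not dissolved at a recipe-controlled molarity.

### Volume resolution: fill and scale

A declared volume may mean nothing (the recipe is "filled" to 1 l) or may
mean everything (a 100 ml stock is a 10x concentrate).  `resolve_volume()`
uses a deterministic general rule — fill when no volume is declared or the
declared volume is within 1% of 1 l, scale otherwise — with a per-medium
override table that always wins.  The rule is a reconstruction: practice
in this area resolves ambiguous recipes by curation, and the override
table is exactly that curation hook.  The 1% tolerance absorbs recipes
declaring 1,000 ml plus a few drops of titrant.

### Unpacking cross-references

Submedia are treated as nested parentheses: the per-litre composition of a
referenced medium is computed recursively — including that medium's *own*
fill/scale multiplier — then multiplied by the referenced volume fraction
and merged into the parent.  Two conventions matter:

* volumes of *individual compounds* convert to grams at 1 g/ml (a liquid
  reagent's volume is a mass proxy); volumes of *submedia* never do — they
  remain dilution fractions;
* the same constituent arriving from several nesting levels is summed
  after conversion to standard units, so a salt listed both in a stock and
  in the main recipe accumulates correctly.

Cycles in the reference graph are an error that names the cycle.
Gram-to-mole conversion divides by the molecular weight *including hydrate
waters* (the mass on the balance is the hydrate's), then multiplies by the
integer molar ratio of each constituent ion; full dissociation in solution
is assumed throughout, which is the convention for composition matrices of
this kind.  Mass conservation of this conversion is enforced by a property
test at relative tolerance 1e-9.

## Similarity and the sharing association

Phylogenetic distance between organisms is purely topological: the leaf
count beneath the lowest common ancestor divided by total leaves, in
(0, 1].  It needs only a taxonomy, not branch lengths, and similarity is
its complement.  Ecological similarity is the Jaccard index of co-growth
across environments; two organisms with no recorded environments raise an
error rather than silently scoring zero.  Media similarity operates on
compiled constituent IDs — so spelling variants of a salt can never
mismatch — with complex components matched by category tag.

`binned_association()` bins organism pairs by distance (equal-width by
default; count-balanced optional — the appropriate binning is not a
settled convention, so both are exposed) and reports the fraction of pairs
per bin sharing at least one medium, with a Spearman correlation over
occupied bins.  Pairs where either organism has no media are excluded and
counted: such pairs cannot share a medium by construction, and leaving
them in would deflate every bin.  With all fractions equal the summary is
flagged degenerate and the correlation is `NA`, not a number.

## Transitivity

If A and B share m1, B and C share m2, and C grows on m3, transitivity
predicts A grows on m3.  Media with fewer than 3 or more than 100
organisms are excluded before mining: the former cannot witness sharing,
the latter connect everything to everything.

Sampling patterns "uniformly at random" is stated easily and implemented
less easily: plain rejection sampling (draw six IDs, accept if the witness
relations hold) has acceptance probabilities around 1e-10 at realistic
sparsity.  `mine_patterns()` instead counts valid tuples per ordered media
triple in closed form over the sparse co-growth structure, allocates the
requested sample across triples by sequential hypergeometric draws, and
materialises only the sampled triples — exactly uniform, without
replacement (so duplicate tuples are impossible), and reproducible
bit-for-bit under a seed.  A brute-force enumeration oracle checks the
tuple universe on small databases in the test suite.

The evaluation compares test positives (A, m3) against a control where A
is replaced by a random organism distinct from A, B, C.  The binomial
upper tail P(X ≥ k | n, p) is computed by log-sum-exp over log densities,
so its logarithm stays finite far below the smallest positive double; the
null rate defaults to `max(control positives, 1)/n` — conservative, never
zero, and equal to 1/n when the control shows a single positive.  The
prediction operation deduplicates implied pairs and reports witness
counts computed in closed form, never materialising the full universe.

## Collaborative filtering

The score of (organism, medium) sums `cutoff / max(d, floor)` over
within-cutoff neighbours documented on the medium.  Defaults: cutoff 0.04
on subtree distance with distance weighting; Jaccard distance 0.15
unweighted in ecological mode.  The floor (default 1/total_leaves, the
smallest possible subtree distance) exists because the raw weight
`cutoff/d` is unbounded as d shrinks; flooring caps any single
near-identical strain's vote at `cutoff/floor`.  Every weight then lies in
[1, cutoff/floor], which is asserted as an invariant.

Scores never consult the test organism's own pairings, so `is_known`
predictions are leave-one-out true positives, not circularity.  The
reference predictor (`null_predict()`) pairs organisms with media sampled
independently proportional to popularity; enrichment over it is scored by
an empirical permutation test, p = (1 + #{null TP ≥ observed}) / (K + 1),
with K null sets of matched size.  Score-bin evaluation uses logarithmic
bins (scores are heavy-tailed) and complements the Spearman correlation
with a partial Spearman controlling mean media popularity per bin —
computed as the Pearson correlation of rank-regression residuals with a
t-test on n − 3 degrees of freedom — because popularity alone already
predicts true positives.

Salt and oxygen filters remove aerobic×anaerobic mismatches in both
directions and high-salt×fresh / low-salt×salty pairs; facultative and
unknown classes pass.  Since an organism's classes are derived from its
own documented media, a documented pairing can never contradict the
profile it induced: the filters are provably unable to remove true
positives and only discard incompatible novel predictions.  A medium's
oxygen status is an annotation column, not an inference — a component
list does not say whether the bottle was prepared anaerobically.  The
NaCl-equivalent of a compiled medium is `min(mol Na+, mol Cl−) × 58.44`
plus complex sea-salts entries, a documented approximation that ignores
counter-ion pairing across salts.

## Richness

Richness is a weighted g/l sum over complex components plus a configurable
list of rich defined components, with classes split at 5 and 15 g/l.
Three choices were genuinely open and are fixed as follows: category
weights default to 1.0 per g/l (the appropriate relative weighting of
digests is empirical; the config file is the contract, and the defaults
are explicitly non-canonical); boundary scores go to the lower class; and
preference ties break toward the lower class — when designing a starting
medium, the conservative error is offering too little nutrition, not too
much.  Organism preference is the argmax of score sums over
salt/oxygen-filtered predictions, and the gold standard maps only
organisms whose documented media are unanimous in class.  Category
enrichment uses the exact rank-sum null for small untied samples and the
tie-corrected normal approximation otherwise.

## The synthetic generator

`synth_generate()` plants exactly the structure the predictors assume:
clades of 8 on a balanced binary taxonomy of 256 organisms (so a whole
clade sits within the 0.04 cutoff: 8/256 ≈ 0.031), 3 preferred media per
clade consistent with the clade's planted salt/oxygen/richness classes,
and 3 documented pairings per organism — sparse, as in real strain
catalogues, where organisms rarely list more than a handful of media.
Each pairing comes from the clade preference set with probability `s` and
uniformly otherwise; the default s = 0.8 represents strong but imperfect
clade structure.  30% of clades are anaerobic and 20% high-salt (coarse
nods to the anaerobe and halophile shares of culture collections), with a
40/35/25 richness mix.  The ground-truth ledger carries every planted
assignment, so recovery tests compare against exact expectations rather
than re-derived ones.

`plant_transitivity()` mixes "clique" groups (nine organisms on all three
group media — every mined tuple is positive) with "chain" groups (A on m1,
B on m1+m2, C on m2+m3 — provably never positive, across all role
assignments) and solves for group counts whose tuple-weighted mixture hits
the requested positive fraction f; because per-archetype tuple counts are
measured by enumeration rather than algebra, the realized f recorded in
the ledger is exact.

What the generator does *not* emulate: realistic chemical compositions
(media have four components, not forty), popularity heavy tails,
taxonomies with uneven clade sizes, correlated ecological/phylogenetic
structure beyond the shared clade labels, and curation noise.  Passing
recovery tests therefore demonstrates that the machinery extracts planted
signal correctly — not that real catalogues carry signal of that strength.

## Problem sizes and determinism

The test suite runs the signal-recovery comparison over 20 seeds per
condition at 256 organisms with 40 held-out organisms per seed, mines
1,000 patterns per planted fraction, and sizes the enumeration oracles at
≤ 16 leaves, n ≤ 12 binomial trials and combined rank-sum n ≤ 10 — sizes
at which exhaustive enumeration is exact and fast.  Every stochastic
operation takes an explicit seed and restores the caller's RNG state, and
end-to-end determinism under a fixed seed is asserted for the generator,
the miner and the command-line front end.

## Limitations

The compiler trusts its compound table; a wrong molecular weight
propagates silently.  Subtree distance saturates at the root and carries
no branch-length information.  The positive-only database means all
"true positive" rates are lower bounds — an unlisted pairing is not a
negative — and popularity weighting in the null predictor inherits
whatever investigator bias produced the catalogue.  The richness weight
table and rich-component list shipped as defaults are starting points to
be replaced by curation.
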