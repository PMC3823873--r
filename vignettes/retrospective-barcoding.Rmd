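---
title: "Methods: retrospective evaluation of DNA barcoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retrospective evaluation of DNA barcoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retrobarcode)
```

This vignette documents the models, conventions and numerical choices
behind `retrobarcode`: what each stage of the pipeline computes, what
the synthetic-data generator does and does not emulate, and where the
design was genuinely open and a choice had to be frozen.

## The evaluation problem

A barcode reference library is only as good as the taxonomy used to
label it. The package's core idea is *retrospective* evaluation: run
every identification method under one labelling of the specimens (for
instance a coarse, morphology-era taxonomy) and score the outcomes
against a second labelling treated as truth (a revised taxonomy, or the
generator's truth for simulated data). Because the same sequences are
scored twice, failures can be attributed to the method rather than to
data quality.

## Distances

Pairwise distances use the Kimura 2-parameter model. For a pair of
aligned sequences, only sites where both carry an unambiguous A/C/G/T
are compared (*pairwise deletion*; gaps and IUPAC ambiguity codes are
non-comparable). With transition proportion $P$ (A–G, C–T) and
transversion proportion $Q$ over the $n$ comparable sites,

$$d = -\tfrac12 \ln(1 - 2P - Q) - \tfrac14 \ln(1 - 2Q).$$

Distances are held in substitutions/site internally and multiplied by
100 only in reports. Two error conditions abort a matrix build rather
than degrade it silently: a pair with no comparable sites, and a
*saturated* pair ($1-2P-Q \le 0$ or $1-2Q \le 0$) whose distance is
undefined. Capping such pairs at an arbitrary large value would distort
every overlap statistic downstream, so they are treated as data errors.
The implementation computes the whole matrix from one-hot site
indicator products; tests pin it against a per-site loop oracle at
1e-12 and against an established K2P implementation.

## Barcoding-gap analytics

`pool_distances()` classifies each unordered pair as intra- or
inter-specific under one taxonomy. Singleton species contribute no
intraspecific distances but keep a nearest-neighbour distance, so they
appear in local-gap plots with `max_intra = 0`.

**Global overlap.** The overlap interval runs from the minimum
interspecific to the maximum intraspecific distance. The "90% overlap"
variant discards the largest `ceiling(0.05 * n)` intraspecific and
smallest `ceiling(0.05 * n)` interspecific values *by count* — not by
interpolated percentile — because the count convention is the only one
that reproduces near-total overlap percentages on heavily lumped data.
`pct_observations` uses the combined intra+inter pool as its
denominator, and interval membership is closed (boundary ties count as
inside). A degenerate interval (upper ≤ lower) reports zero width and
zero percent.

**Local gaps.** A species has a local gap when its nearest-neighbour
distance strictly exceeds its maximum intraspecific distance; equality
is reported separately (`absent_on_line`) since points on the 1:1 line
are conventionally counted as gap-absent.

**ABGD-style scan.** `abgd_partition()` is a deliberate re-derivation
of automatic barcode-gap discovery, not a port: for each prior $p$ on a
log-spaced grid, it scans the sorted pairwise distances for the first
spacing between two consecutive distances *both above* $p$ that is
wider than $X \cdot p$, splits the specimens by single linkage at the
spacing's midpoint, and recurses within groups until no spacing
qualifies. Defaults: $p \in [0.001, 0.1]$, 20 steps, $X = 1.5$. Two
conventions matter and were fixed after deliberate consideration:

* Both endpoints of a candidate spacing must exceed the prior.
  Otherwise a pair of identical haplotypes (distance 0) manufactures a
  "gap" between 0 and the smallest positive distance at every small
  prior, yielding a stable, absurd everyone-is-a-species mode.
* The modal group count — and the consensus threshold range — are taken
  over the priors that found a gap. Priors whose scan fails carry no
  threshold; they only feed the `no_gap` flag (raised when every prior
  fails). Counting them as competing "1 group" partitions would let the
  tail of over-large priors outvote the informative middle of the grid.

Exact numeric parity with the original ABGD server is not claimed (its
gap detector is slope-based); what is claimed, and tested, is parameter
recovery: on simulated radiations with a true gap the modal partition
equals the generator's species map and the consensus threshold falls
inside the realized gap.

**Thresholds and ANOVA.** `threshold_10x()` is ten times the mean
pooled intraspecific distance — included because it is a standard rule
and because showing how absurd its output becomes under lumping (often
>30%) is part of the analysis. `anova_intraspecific()` is a fixed-effects
one-way ANOVA on per-species summary values (mean or maximum
intraspecific distance) between two taxonomies; species with a single
specimen are excluded since they have no intraspecific distances.

## Trees

`neighbor_joining()` implements Saitou–Nei agglomeration with the Q
criterion. Two determinism conventions: ties in Q (within a 1e-12
relative band) are broken by the lexicographically smallest pair of
cluster names, a cluster being named by its smallest leaf id; negative
branch-length estimates are clamped to zero with the deficit moved to
the sister branch of the join, which preserves path lengths through the
joined node. Downstream identification uses clades, not signed lengths,
so clamping is harmless there. On additive matrices the output
reproduces the generating tree exactly (tested to 1e-10).

`bootstrap_support()` resamples alignment columns with replacement,
rebuilds matrix and tree per replicate, and reports for each internal
bipartition of the original (unrooted) tree the percentage of usable
replicates containing it. A replicate that produces a saturated pair is
skipped and counted, not imputed.

## Identification methods

All matching methods evaluate a query against the reference set with
the query's own record removed (leave-one-out), otherwise every query
would self-match at distance zero. Distance ties at the decision
boundary ($d = t$) count as within the threshold; ties for the nearest
reference are recognised at 1e-12 relative tolerance and make the
outcome ambiguous when they span species.

* **Best Match** — species of the nearest reference(s); ambiguous on a
  cross-species tie.
* **Best Close Match** — as Best Match but `no_match` when the nearest
  reference lies beyond the threshold.
* **All Species Barcodes** — all references within the threshold must
  be conspecific for success; several species is ambiguous; a single
  wrong species is a misidentification; an empty neighbourhood is
  `no_match`.
* **Distance to exemplar** — references are one designated exemplar per
  species. By default exemplar specimens are themselves scored (against
  the other exemplars); summary sweeps exclude them, matching the
  usual convention in which the exemplar rows of a results table cover
  the non-exemplar specimens. Both conventions sit behind a flag.
* **NJ tree placement** — for each query, the smallest bipartition side
  of the tree containing the query and at least one exemplar is
  examined. One exemplar species matching the query's label: success.
  Two or more species entering together: ambiguous. One non-matching
  species $X$: the query's maximal exemplar-free side decides — if the
  query sits alone, or among specimens labelled $X$, it is embedded in
  $X$'s material and misidentified; if it sits in an exemplar-free
  clade of other specimens none of which carry $X$'s label, it is
  flagged as an ambiguous *new-species candidate*. The same candidate
  flag is attached to multi-species ambiguity when the clade carries
  none of the entering labels. These clade rules are a reconstruction
  of tree-based identification criteria whose original tabular wording
  is not available in full; they are frozen here and exercised against
  simulated truth (clean radiations identify perfectly; an unsampled
  species' clade is flagged; an introgressed specimen inside the donor
  clade is misidentified).

## Retrospective scoring and discovery

`score_against_truth()` passes success, misidentification and plain
ambiguity through, and classifies flagged queries (no match, or NJ
new-candidates) against the truth taxonomy: *correctly flagged, part of
a known complex* when the evaluation label lumps two or more truth
species (the complex membership test runs first, because the "new
species" category is defined to exclude complex members); *correctly
flagged new* when the truth species has no remaining reference;
*incorrectly flagged* otherwise. Reference availability is judged
against the reference set the method actually used — all specimens for
the matching methods, the exemplars for the exemplar and tree methods.
Percentages are always recomputed from counts, and counts partition the
scored queries exactly.

`discovery_assessment()` restricts references to specimens with
`known_historic` status and queries the rest. Each query lands in
exactly one category, by the cross of flagged/grouped with its truth
status: a flagged new taxon is correct (or, when its truth label sits
inside a recorded complex, "correctly flagged, part of a known
complex"); a flagged new *form* of an existing species is an incorrect
flag; a grouped new form is correct; a grouped new taxon is an
incorrect lumping. For the NJ method, ambiguity counts as flagging.

## The synthetic-data generator

`simulate_dataset()` draws a root sequence uniformly (length 650 by
default — a COI barcode), evolves it along a species tree under a
continuous-time K80-type process with transition/transversion rate
ratio `kappa` (default 4, a typical mitochondrial value), then evolves
each specimen independently for `intra_depth / 2` below its
population's ancestral sequence, so expected intraspecific pairwise
divergence equals `intra_depth`. The generator matches the estimator's
model family on purpose: K2P is unbiased on its own generating process,
which turns estimator/generator agreement into a test rather than a
confound. Genealogies are star-shaped — no coalescent structure —
because every downstream method consumes only the distance
distributions. The optional codon screen redraws any codon that mutates
into a vertebrate-mitochondrial stop (and builds a stop-free root), so
screened datasets pass translation QC the way real protein-coding
barcodes do; presets enable it, the raw generator defaults to off.

What the generator does *not* emulate: rate heterogeneity among sites,
indels, selection, within-species population structure, and
misassigned specimens (each truth species maps to exactly one historic
label). Passing tests therefore demonstrate the correctness of the
pipeline's logic under the stated structural regimes, not performance
on any particular empirical fauna.

**Presets.** The preset sizes are desk-scale study conditions chosen
once: large enough for stable category percentages, small enough that
the whole suite simulates hundreds of datasets in seconds.

* `gapped` — 20 species × 5 specimens, 2% intraspecific depth, 10%
  interspecific splits: a clean global gap for control runs and
  parameter-recovery tests.
* `skink1977` — 96 specimens. Five recently diverged species pairs
  (0.8% splits) sit at the tips of deep (~13%) lineages; the historic
  scheme lumps the five "a" populations under one name and the five
  "b" populations under another, emulating the classic failure where
  one old name spans several distant clusters, so each population's
  nearest neighbour carries a *different* historic label while its
  historic conspecifics sit a deep divergence away. Three further
  within-clade lumped complexes, one mtDNA-capturing hybrid pair
  (k = 2) and three small species (n = 1–3) complete the fauna. Under
  the historic labels there is no barcoding gap: ~99% of pooled
  distances fall inside the overlap interval.
* `skink_current` — 116 specimens, the revised-taxonomy analogue:
  complexes split, two recent pairs and the hybrid pair retained,
  every species keeps at least two specimens (so no query is stranded
  beyond a 10% threshold), leaving a partial gap and a moderate
  ambiguous fraction.
* `discovery` — eight known reference species plus three new taxa
  (one of them historically hidden inside a named complex) and two
  new forms attached 0.5% from their parent species.

`inject_hybrids()` models mitochondrial capture: k recipient specimens
get fresh draws from the donor's intraspecific process while keeping
their labels. The recipient's exemplar is never captured when enough
other specimens exist, since losing the exemplar would change the
method under test rather than the data.

## Numerical conventions and degenerate inputs

* Sequence comparison is case-insensitive; records are stored lower
  case. The IUPAC alphabet plus `-` is enforced at construction.
* Empty pools, all-singleton taxonomies, sub-codon sequences, unknown
  labels and over-large trims raise errors naming the offending object;
  no statistic is computed from an empty set.
* Reading-frame QC translates all three frames (vertebrate
  mitochondrial code by default) and picks the frame with the fewest
  internal stops, ties to the lowest frame; ambiguity codons translate
  to X and never count as stops.
* All randomness flows through explicit integer seeds; a simulation
  config reproduces its FASTA byte for byte.

## Known limitations

The ABGD re-derivation shares the original's instability at very small
priors (over-splitting), which the modal-consensus rule absorbs but
does not remove. The NJ identification criteria are a frozen
reconstruction, not a validated copy of any published rule table. The
evaluation assumes the truth taxonomy refines the evaluation taxonomy
(a lumping map); specimens misassigned *across* historic species are
outside the model. And the headline percentages of any real study
depend on its actual sequences — the bundled presets reproduce regimes
and contrasts, not empirical values.
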