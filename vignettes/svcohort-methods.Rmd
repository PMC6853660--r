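---
title: "Merging, classifying and QC-ing cohort SV callsets with svcohort"
author: "svcohort authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Merging, classifying and QC-ing cohort SV callsets with svcohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svcohort)
```

# The problem

Structural variants are discovered per sample from short-read alignment
signals, which localize a breakpoint only to within tens of base pairs.
A breakpoint is a *pair* of strand-oriented breakends, and the same
physical variant appears in different samples at slightly different
coordinates. Building a cohort callset therefore requires (i) merging
per-sample calls that describe the same event despite positional
disagreement, (ii) re-genotyping every sample at every merged site,
and (iii) deciding what each event actually *is* — a deletion,
duplication, inversion, mobile-element insertion (MEI) or a generic
break-end (BND) — which novel-adjacency evidence alone cannot settle.

`svcohort` implements this cohort stage. Its inputs are per-sample
discovery VCFs whose records carry, in addition to the usual
`SVTYPE`/`STRANDS`/`END`/`SU` annotations, a per-base probability
distribution over each breakend's confidence interval
(`CIPOS`+`PRPOS`, `CIEND`+`PREND`).

# Positional uncertainty and merging

## Representation

A breakend distribution is stored as a numeric vector with one entry
per base, anchored at a 0-based leftmost coordinate, and normalized to
sum to one on construction. We chose the discretized per-base encoding
(rather than, say, a parametric Gaussian) because it makes summation of
evidence across samples exact and matches the per-base annotation the
discovery VCFs already carry. The point estimate of a breakend is the
most probable base, with ties broken to the left so results are
deterministic and invariant under rescaling.

## Clustering

Calls are grouped by single linkage within strata of
`(chromA, chromB, strandA, strandB)`. Two calls are linked when the
supports of their distributions — the bases with positive probability,
each widened by a `slop` parameter — intersect at **both** breakends.
Requiring both ends prevents one-ended coincidences (e.g. two distinct
deletions sharing a start region) from merging. The default
`slop = 0` reflects that the distributions already encode the
positional uncertainty; the parameter exists as an escape hatch for
callers that truncate their reported intervals.

Note the strand pair, not the declared `SVTYPE`, defines the stratum:
deletions, MEIs and direct-orientation BNDs share the `(+,-)`
configuration and are deliberately merged together, since a breakpoint
caller cannot distinguish them; classification happens downstream.

The implementation sweeps each stratum in order of breakend-A support
start, testing each call only against calls whose A-support can still
reach it. This is algebraically identical to union-find over all
pairwise overlap tests (the test suite verifies this equivalence
against an independent brute-force implementation on a thousand random
inputs) while bounding the work per call.

## Combining evidence

A cluster's combined distribution at each breakend is the per-base sum
of member distributions, weighted by each member's supporting-read
count `SU` (`weighting = "evidence"`, the default, following the idea
that better-supported samples should pull the coordinate harder;
`"uniform"` weighting is available). The refined position is the mode
of the combined distribution. The reported interval is the smallest
contiguous interval that contains the mode and at least 95% of the
combined mass — a deterministic rule chosen because it is testable and
shrinks as evidence accumulates; the stored distribution is trimmed to
it and renormalized. `SU` is summed and the `SNAME` provenance list is
the union over members, so the number of input calls always equals the
sum of `|SNAME|` over outputs (a partition invariant the tests assert).

Merged ids inherit the lexicographically smallest member id; the
pipeline wrapper applies `make.unique` afterwards so that site lists
have unique keys in the rare case a physical variant splits into two
clusters.

## Tiered merging

For cohorts too large to merge in one pass, `tiered_merge()` merges
within batches of samples and then merges the batch-level variants.
Because combined distributions are (weighted) sums of member
distributions, batch-level merging sees essentially the same evidence
as bulk merging; on low-jitter cohorts the two produce identical
variant counts (asserted in the tests), and provenance accumulates
through both tiers. With heavy jitter the tiers can occasionally
differ on borderline clusters, which is why the equivalence test is run
at low jitter.

# Cohort assembly

`lsort()` concatenates per-sample VCFs, tags each record with
`SNAME=sample:original_id`, and sorts by (header contig order, POS,
END, ID); contig order comes from the first input's header so no
reference genome is needed, and all inputs must declare identical
contig dictionaries. `vcfpaste()` column-joins per-sample genotyped
VCFs onto the merged site list and refuses any id/order mismatch
outright — a silent misalignment would corrupt every downstream
statistic. Copy number arrives separately (`attach_copynumber()`), as
read-depth estimation is a different measurement than breakpoint
genotyping. `afreq()` computes the allele frequency from genotype
dosages over called diploid genotypes (allele balance is kept separate:
it is evidence for classification, not an allele count). Records are
biallelic by construction; multi-allelic sites are out of scope.

# Classification

## Regression (large cohorts)

For each variant with a copy-number-compatible orientation, copy number
is regressed on allele balance by ordinary least squares (`stats::lm`).
At diploid baseline, allele-balance dosage 0 → ½ → 1 maps to copy
number 2 → 1 → 0 for a deletion (slope −2) and 2 → 3 → 4 for a
duplication (slope +2), while balanced variants are flat. The decision
thresholds default to `slope_min = 1.0` — the midpoint between the null
slope 0 and the expected magnitude 2 — and `r2_min = 0.2` to demand
that the trend actually explains the data. Both are exposed as
configuration. A fit is attempted only with at least
`min_informative = 8` samples observed for both AB and CN and at least
one carrier; an undefined fit leaves the original type unchanged.
Strand compatibility is enforced: a `(-,+)` call can never become DEL,
nor a `(+,-)` call DUP.

## Naive Bayes (small cohorts)

With few samples, per-variant regression rests on a handful of carrier
points and is fragile. The small-cohort classifier is a naive Bayes
model over carrier copy number: for each class (DEL, DUP, balanced
BND) and genotype stratum (`0/1`, `1/1`), a Gaussian is fitted to the
training carriers' CN (variances floored at 1e-3), with empirical class
priors. A variant's log-posterior sums the log-likelihood over its
carriers; the argmax wins, ties falling to BND. CN-only features,
stratified by genotype, are the smallest model consistent with
combining breakpoint-genotype and read-depth information. In the
simulation study the model is trained on the generator's labels (with
MEI pooled into the balanced class, since an insertion leaves the
reference interval's copy number unchanged); in real use one trains on
a previously classified callset.

## MEI and inversions

An MEI's breakpoints mimic a deletion of the reference mobile element,
so a `(+,-)` variant is relabeled MEI when (a) either breakend's
confidence interval, widened by `mei_slop = 100` bp, touches an
annotated mobile element and (b) the regression shows no copy-number
effect (undefined fit or `|slope| < slope_min`). Copy-number evidence
deliberately takes precedence: a genuine deletion inside a repeat stays
DEL.

An inversion is called when a `(+,+)` and a `(-,-)` breakpoint are
co-detected with mutually overlapping intervals at both ends (within
`inv_slop = 100` bp). Candidates are matched greedily by the distance
between point estimates with a deterministic leftmost tie-break — on
well-separated inversions this equals the optimal matching (tested
against exhaustive matching) — and the fused INV spans the outer
coordinates, pooling provenance and evidence. Unpaired inverted calls
remain BND.

# Refinement and QC

*Pruning* removes redundant same-type records whose breakend point
estimates are both within `eval_dist = 100` bp: while any conflict
remains, the record with the lowest `SU` (ties: rightmost, then
lexicographically larger id) is removed, so the best-supported leftmost
record survives. The operation is a subset of its input and idempotent.

*Confidence scoring* defines `MSQ` as the mean sample quality over
carrier samples; the high-confidence subset keeps variants with MSQ at
or above a per-type threshold (defaults: 100 for DEL/DUP/INV/MEI, 250
for BND, reflecting that a generic break-end needs stronger evidence).
These thresholds are this package's own operational definition of
"high confidence" and are plain configuration.

*Mendelian errors*: an autosomal variant is informative for a trio when
all three members are called and at least one is non-reference — the
strictest deterministic reading of "informative" — and an error is a
child genotype impossible under transmission of one allele from each
parent. The classifier is validated against exhaustive enumeration of
all 27 trio genotype combinations. Sex chromosomes are excluded
(ploidy is fixed at 2).

*Sensitivity* against a truth set counts a truth variant as detected
for a sample when a callset variant of the same strand-pair type class
has both breakends within `match_slop = 100` bp and a non-reference
genotype in that sample — the same both-breakend semantics the merge
engine uses, as is `lookup`'s matching rule.

# The synthetic cohort generator

The generator emulates the statistical structure of the pipeline's
inputs so every stage is testable offline. Its defaults describe the
desk-scale study cohort used throughout the tests: 30 samples including
3 parent-offspring trios, and 500 variants (150 DEL, 100 DUP, 75 INV,
100 MEI, 75 BND) on two 12-Mb contigs.

* **Population model.** Allele frequencies are Beta(0.2, 2) (clipped to
  [0.01, 0.95]), giving the rare-variant-heavy site-frequency spectrum
  under which joint analysis matters; unrelated genotypes follow
  Hardy–Weinberg equilibrium and trio children receive one allele from
  each parent.
* **Positional noise.** Per-sample breakpoints are perturbed by rounded
  Gaussian jitter (sd 10 bp, the low end of typical per-sample
  breakpoint resolution); the reported distribution is a discretized
  Gaussian (sd 20 bp) over a ±50 bp confidence interval centered on the
  perturbed position. Carried variants are missed at discovery with
  probability 0.03.
* **Genotyping noise.** Allele balance is drawn around 0/0.5/1 per
  emitted genotype (sd 0.05, clipped to [0, 1]); copy number is
  2 + dosage·Δ (Δ = −1 DEL, +1 DUP, 0 otherwise) from the *true*
  dosage plus Gaussian noise (sd 0.25), since read depth reflects the
  physical state rather than the genotype call. Genotype errors are
  modeled the way they occur in real callsets: concentrated at
  systematically difficult sites (5% of variants flip genotypes at rate
  0.25 and draw all carrier qualities from the low-SQ range 5–40)
  plus a small residual per-sample error rate (0.005); confident calls
  draw SQ from 150–300. This site-level error structure is what makes
  MSQ-based confidence filtering meaningful — wholesale unreliable
  sites get low MSQ and are removed, reproducing the characteristic
  all → high-confidence drop in trio Mendelian-error rates.
* **Presentation.** MEIs are emitted as `DEL`-typed direct-orientation
  breakpoints and inversions as two separate `(+,+)`/`(-,-)` records,
  as a breakpoint caller would report them, so reclassification is
  exercised honestly. Mobile elements are annotated under every true
  MEI plus decoy elements placed away from all breakends.

Fixed seeds give byte-identical output files. What the generator does
*not* model: sequence content and alignment artifacts, batch effects,
multi-allelic and complex multi-breakpoint events, relatedness beyond
trios, and sex chromosomes. Passing tests therefore demonstrate the
correctness of the merging/classification/QC machinery under the stated
statistical assumptions, not performance on real WGS data.

# Numerical and design notes

* Probability vectors are serialized with 6 significant digits; parsing
  renormalizes, so round-trips are stable and file sizes bounded.
* VCF is 1-based inclusive; BEDPE 0-based half-open; the interval
  conversion subtracts 1 from starts only. BEDPE carries both mates'
  INFO strings (`INFO_A`/`INFO_B`), which makes VCF → BEDPE → VCF exact.
* Intervals that would start before a chromosome are clamped to 0 with
  the leading probability entries dropped, with a warning.
* Records missing `PRPOS`/`PREND` get a synthesized distribution over
  the confidence interval — uniform by default, point-mass optionally —
  with a warning, so legacy inputs degrade gracefully.
* In merged output the modal member `SVTYPE` is kept (priority order
  DEL, DUP, INV, MEI, BND on ties); this matters only for mixed
  clusters, which the downstream classifier re-labels anyway.
* The end-to-end simulation study uses the naive-Bayes classifier:
  30 samples is squarely the small-cohort regime, where per-variant
  regression would rest on one or two carrier observations for the many
  rare variants drawn from the Beta(0.2, 2) frequency spectrum.
* Problem sizes in the test suite (cohorts of 5–40 samples, up to 2 000
  samples for Hardy–Weinberg checks, 500-variant acceptance cohort,
  1 000 randomized clustering trials) were chosen so the whole suite
  exercises every stage in a couple of minutes on a laptop.

# Known limitations

Only biallelic records are supported. Complex rearrangements are
resolved no further than inversion pairing; translocation-like BNDs are
reported but never reclassified. The Mendelian-error logic assumes
autosomal diploidy. The merge is streamed per stratum but the callset
is held in memory, which is fine for desk-scale cohorts and batches;
very large studies should use the tiered path per batch.
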