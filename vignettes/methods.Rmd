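---
title: "Methods: classifying, harmonizing and clustering age-related diseases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying, harmonizing and clustering age-related diseases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ageTraits)
```

# The problem

Genetic studies of aging need a defensible list of age-related diseases
(ARDs) and traits (ARTs): phenotypes whose population prevalence is not
merely high in the elderly but *characteristically* late-rising. Curated
lists exist but are small, inconsistent across catalogs (GWAS vs PheWAS
terminologies), and rarely connected to the vocabularies other resources
speak (MeSH, ICD, UK Biobank phenotype codes). `ageTraits` turns the
construction of such a compendium into a reproducible pipeline with five
stages: profile classification, vocabulary harmonization, symptom-network
decomposition, genetic-correlation clustering, and mortality overlap.

This vignette explains each stage's model, its tunable parameters, the
numerical choices made where the design was genuinely open, what the
synthetic-data generator does and does not emulate, and the known
limitations.

# Stage 1: prevalence-profile classification

A trait's profile is its prevalence (proportion, rate, or raw patient
count) over age bins. The classifier calls a trait age-related iff, after
smoothing:

1. the profile is **unimodal**;
2. prevalence **rises after mid-life** (> 40 years);
3. the **global peak is at 60 years or later**.

Every internal comparison is a ratio or an order comparison, so the verdict
is invariant to uniform rescaling — proportions and counts classify
identically, which matters because real catalogs report either.

## Parameters

| parameter | default | unit | role |
|---|---|---|---|
| `midlifeAge` | 40 | years | rise must occur after this age |
| `minPeakAge` | 60 | years | minimum age of the global maximum |
| `peakTolerance` | 0 | years | slack on `minPeakAge` ("around 60") |
| `smoothWindow` | 3 | bins | centred moving-average window |
| `modeTolerance` | 0.02 | fraction of max | minimum mode prominence |
| `minRiseFraction` | 0.8 | fraction | non-decreasing step share, first post-40 bin to peak |

The 40- and 60-year anchors are the substantive definition; the remaining
knobs operationalize the qualitative words "unimodal", "around" and
"increasing" for noisy registry data. "Around 60" defaults to exactly 60
(`peakTolerance = 0`) because any other choice is arbitrary; the tolerance
is exposed rather than hidden. "Increasing after mid-life" uses a step
fraction rather than strict monotonicity because empirical prevalence
curves wiggle; 0.8 allows one contrary step in a typical five-step climb.

## Numerical choices

* **Plateaus count once.** Runs of exactly equal values are merged before
  local-maximum detection, so a flat-topped peak is one mode. Boundary
  bins may be maxima — the last bin is an open-ended "85+" style bin in
  real tables.
* **Mode prominence.** A secondary maximum counts as a mode only if it is
  separated from the global maximum by a valley at least
  `modeTolerance × max(values)` below it. With tolerance 0 this reduces to
  the strict plateau-merged local-maximum count, which is what the
  exhaustive-scan oracle in the test suite checks (all profiles of length
  ≤ 8 with values in {0, 1, 2}, plus random integer profiles).
* **Ties.** The peak age is the earliest bin attaining the maximum.
* **Degenerate inputs.** All-zero profiles and profiles with fewer than
  three bins are classification errors, not silent non-ARTs. A peak at or
  before the first post-mid-life bin means nothing rose after mid-life and
  yields `FALSE`, not an error.
* **Smoothing edges.** The moving average truncates its window at the
  profile edges, preserving length and bins; window 1 is the identity.

## Noise sensitivity — a real limitation

The prominence tolerance (2% of max) defines the classifier's noise
envelope. Additive noise with standard deviation *s* × peak produces,
after window-3 smoothing, valley-to-peak fluctuations of roughly
2*s*/√3; whenever those exceed the 2% tolerance, spurious modes appear and
genuinely unimodal traits are rejected as multimodal. In practice the
classifier is reliable for *s* up to about `modeTolerance`/3 (≈ 0.7% of
peak) and degrades — *conservatively*: only toward false negatives, never
false positives — beyond that. The test suite pins both facts: at noise
0.005 of peak, planted-label agreement is ≥ 95%; at noise 0.05,
specificity remains exactly 1 while sensitivity collapses. Users with
noisy registry data should widen `smoothWindow` or raise `modeTolerance`
deliberately rather than trust the defaults blindly.

# Stage 2: vocabulary harmonization

The trait → MeSH mapping is **data, not code**: a curated table (trait
name, catalog, phecode, MeSH disease id, MeSH anatomy id, mapping rule)
that the package consumes and never second-guesses. Five rules are
recorded: *exact* 1-to-1 matches; *parental* (a specific trait mapped to
its parent term, e.g. a hand/wrist fracture to "fracture"); *alternate
category* (non-disease traits mapped into anatomy/chemical/diagnosis
branches); *causal* (co-morbidity traits mapped to the shared causal
disease, e.g. hypertensive heart/renal disease to "hypertension"); and
*pick-one* (ambiguous co-morbidities resolved to the single curated
target). Name lookup is case-, whitespace- and punctuation-insensitive,
with a trailing-"s" retry so singular/plural catalog variants land on the
same node. Unmapped traits are never dropped: every input appears exactly
once in the mapped records or the rejects report, and the mapping is
idempotent.

Top-level MeSH categories derive deterministically from the first tree
number (lexically smallest when a node has several, so a node filed under
both C10 and F03 counts once, under C10). ICD-9/-10/-10-CM codes attach by
phecode join; one phecode may map to many codes, and records without a
phecode pass through unchanged.

# Stage 3: symptom-shared subnetworks

The similarity input is an edge list over MeSH diseases with scores in
[0, 1]. Reading canonicalizes it: self-loops are dropped, duplicate
unordered pairs collapse keeping the **maximum** score (conservative
toward connectivity), and out-of-range scores are errors. The graph is
induced on the ARD term set and thresholded **strictly** at
`minSimilarity` (default 0.55, an empirically optimized threshold for this
kind of network; an edge at exactly 0.55 is excluded). Connected
components are computed with igraph and cross-checked against a
depth-first-search oracle in the tests; components are numbered by
decreasing size with lexical tie-breaks, and a component is "primary" when
it has ≥ `minPrimarySize` members (default 5 — the notion of a "primary"
subnetwork is not defined anywhere authoritative, so the package
operationalizes it as a configurable size floor). Labels are the plurality
disease category among members, suffixed with the plurality tissue, ties
lexical. Exports carry node attributes (category, tissue, subnetwork id)
and the similarity edge attribute in GraphML, or topology plus a sidecar
attribute TSV in SIF.

# Stage 4: genetic-correlation clustering

Raw p-values of pairwise genetic correlations are adjusted with the
Benjamini–Hochberg step-up (delegated to `p.adjust(method = "BH")` after
validation; the test suite and acceptance script verify it against a
brute-force implementation of the step-up definition to 1e-12).
Significance is strict FDR < `alpha` (default 0.05).

Clustering operates on the distance **d = 1 − r_g** (range [0, 2]); r_g
estimates slightly outside ±1 — which LD-score regression can produce —
are clamped with a warning. Missing pairs are imputed at the maximal
distance 2.0 so that *absent evidence never binds phenotypes together*.
The linkage default is **complete**; the clustering idiom this mirrors
does not state its linkage, and complete linkage is that idiom's default,
so it is the default here too, exposed as a parameter. Both choices
(distance and linkage) are design decisions, not published constants, and
are therefore configurable in `cutParams()`.

## The dynamic tree cut

The dendrogram is decomposed with a from-scratch top-down "tree" variant:

1. sever the tree at `cutHeight` (default 0.99, interpreted on **raw**
   merge heights; `normalizeHeights = TRUE` rescales the tallest merge to
   1 for users matching the fraction-of-height convention);
2. each severed branch with ≥ `minClusterSize` leaves (default 3) seeds a
   cluster;
3. each smaller branch walks up the tree and merges into the **nearest
   qualifying branch** — the first ancestor on whose other side a
   qualifying branch exists; if several qualify there, the largest wins,
   ties broken by the lexically smallest member label;
4. branches that reach the root without finding a qualifying neighbour
   stay unassigned (cluster id 0);
5. cluster ids are renumbered by decreasing final size.

Degenerate cases are defined, not accidental: a tree entirely below the
cut is one cluster; a cut below the lowest merge leaves every leaf
unassigned with a warning. `minClusterSize = 3` is a floor chosen so that
a "cluster" is at least a triangle of mutually correlated phenotypes;
real analyses of this kind produce clusters an order of magnitude larger,
so the default is not binding in practice.

One ambiguity deserves note: when a correlation table covers more
phenotypes than the age-related subset, the FDR adjustment universe (all
pairs vs subset pairs) changes the significant set. The package computes
FDR over whatever table it is given, so both conventions are available by
subsetting before or after `bhAdjust()`; the pipeline driver adjusts over
the full input table before selection.

# Stage 5: mortality overlap

A cause of death overlaps the compendium when its MeSH translation is in
the ARD set. Causes with no MeSH mapping are excluded from the overlap but
**kept in the denominator**, because the quantity of interest is the share
of *all* deaths in the table attributable to ARDs:
coverage = 100 × Σ deaths(overlap) / Σ deaths(all). Coverage is monotone
in the overlap set and order-invariant; a zero-death table is an error.

# The synthetic-data generator

`synthSpec()` fixes every input from one master seed (per-stage streams
are derived arithmetically, so generators are independently
bit-reproducible). What it emulates, and what it does not:

* **Profiles.** Age-related: smooth Gaussian-shaped bumps with peak age
  uniform in [62, 82] and width 10–15 years over 5-year bins 0–85, plus a
  2% baseline — satisfying all three criteria by construction at zero
  noise. Non-age-related: early-peak bumps (15–35 years), bimodal
  early+late mixtures, and flat profiles, in rotation. Noise is truncated
  Gaussian with s.d. `noiseSd` × peak. Real registry curves have
  count-dependent (not constant-relative) noise, missing bins and coding
  artifacts; passing tests on these shapes shows the classifier logic is
  right, not that real EMR data are this clean.
* **Network.** Planted modules (defaults sized 41, 24, 10, 8, 7, 32,
  mirroring the six-subnetwork structure of the real symptom network) made
  complete within-module with scores in (0.6, 1.0], plus a sparse 5% of
  cross-module pairs in [0, 0.5]. Both ranges clear the 0.55 threshold by
  construction, so recovery is exact; a warning fires if a user's ranges
  straddle the threshold. Real similarity networks are not
  block-complete.
* **Correlations.** Two planted blocks of 29 and 25 phenotypes (54 total,
  matching the scale of the real two-cluster analysis), within-block
  r_g ≈ 0.7, between-block ≈ −0.3, s.e. 0.1, with p = 2Φ(−|r_g/se|) — the
  conventional normal approximation for LD-score r_g significance. Real
  r_g matrices have heterogeneous noise and missing entries.
* **Mortality.** 100 causes, a planted 54% overlapping the ARD set,
  log-uniform death counts in [100, 100 000]. The resulting death
  *coverage* is whatever the draws imply (the generator records it), so
  coverage comparisons in tests are generator-vs-pipeline bookkeeping
  checks, not assertions about real vital-statistics data.

# Verification strategy and problem sizes

The package separates implementation from verification: every
algorithmically interesting operation is checked against an independent
brute-force oracle written directly from the definition — BH step-up on
1,000 random p-vectors (agreement to 1e-12), connected components vs
depth-first search on 500 random graphs (n ≤ 30), mode counting vs an
exhaustive plateau scan on all ~9,800 small profiles, linkage merge
heights vs a naive O(n³) agglomeration on matrices with n ≤ 7, plus
planted-structure recovery (adjusted Rand index 1.0 on two- and
three-block correlation designs and on the six-module network), FDR
control under a 200-replicate simulated global null, and byte-level
determinism of repeated pipeline runs. These sizes keep the whole suite
under a minute while exercising every code path; they are the package's
chosen verification scale, and all are re-run from scratch by
`scripts/acceptance.R`.

# Known limitations

* The classifier's defaults assume profile noise well below 2% of peak
  (see the noise-envelope discussion above); noisy data need wider
  smoothing or a larger `modeTolerance`, traded explicitly against
  sensitivity to true bimodality.
* The vocabulary stage is only as good as its curated mapping table; the
  package deliberately refuses to guess matches (no fuzzy/NLP matching),
  so coverage gaps surface as rejects rather than silent errors.
* "Primary" subnetwork, the clustering linkage, the 1 − r_g distance and
  the FDR universe are operationalized design choices, exposed as
  parameters, not published constants.
* The dynamic tree cut implements the top-down tree variant only; the
  hybrid variant (which re-assigns leaves by dissimilarity to cluster
  cores) is out of scope.
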