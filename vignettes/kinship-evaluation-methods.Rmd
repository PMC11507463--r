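---
title: "Evaluating SNP-based kinship inference: simulation design, estimators and fusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating SNP-based kinship inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinfuse)
```

## The problem

Forensic investigative genetic genealogy identifies unknown individuals by
matching dense SNP genotypes against relatives as distant as the seventh
degree. Practitioners choose between two families of kinship estimators:
method-of-moments (MoM) estimators that summarise genome-wide
identity-by-state (IBS) counts, and identity-by-descent (IBD) segment
detectors that locate chromosomal stretches shared from a common ancestor.
Casework samples are often degraded or low-input, so two questions dominate
tool choice: how many SNPs does each approach need, and how much genotyping
error can it absorb? `kinfuse` provides a controlled test bench for these
questions — a pedigree simulator with exact IBD ground truth, a
genotyping-error model, reference implementations of four estimator
archetypes, degree classification and metrics, and a linear fusion of the
four estimators that stays usable when error rates are extreme.

## Simulation model

**Genetic map.** `generate_map()` builds 22 autosomes whose genetic lengths
follow a fixed human-like shape vector rescaled to a total of 3346.30 cM,
with a constant recombination rate (default 1 cM/Mb). The constant rate
makes physical thresholds (Mb) and genetic thresholds (cM) mutually
consistent, which matters because the probability-thresholded detector
states its length floors in Mb while kinship conversions work in cM.

**Founders.** `generate_founders()` draws marker positions uniformly over
the map and phased founder haplotypes with *independent sites*: allele
frequencies come from a `uniform(0.05, 0.5)` law (the post-filter spectrum
of a MAF > 0.05 panel is not otherwise constrained) and every haplotype is
an independent Bernoulli draw. There is deliberately no linkage
disequilibrium: the no-LD null makes chance-match behaviour of the
detectors analytically checkable. The price is that effects driven by
redundant correlated SNPs on real arrays — notably kinship overestimation
when millions of non-independent markers are fed to a
probability-thresholded detector — are outside what these simulations can
show.

**Pedigree.** `template_pedigree()` is a fixed five-generation family with
11 founders and 12 descendants, containing lineal, full-collateral and
half-collateral branches (a half-sib line through one remarried founder).
Its 30 designated pairs realise the per-family degree histogram
3/5/6/4/4/3/2 for first through seventh degree plus 3 unrelated founder
pairs, so a full design of 18 families per replicate and 10 replicates
yields 540/900/1080/720/720/540/360 related pairs and 540 unrelated pairs.
The exact published family topology is not recoverable from text, so any
fixed template reproducing those counts is admissible; ours is verified in
the test suite by the recursive kinship algorithm
(`pedigree_kinship()` / `degree_from_kinship()`).

**Gamete dropping.** `simulate_family()` drops gametes down the pedigree
with a `Poisson(L/100)` crossover count per chromosome and uniform
breakpoint positions — no crossover interference and a sex-averaged map,
matching the default behaviour of standard pedigree simulators. Founder
origin is tracked exactly (`true_ibd_segments()`), so detector recall can
be scored against truth rather than against another detector.

**Genotyping errors.** `inject_errors()` perturbs each genotype
independently with the configured rate; the error type is drawn from a
composition over drop-in (homozygote to heterozygote), drop-out
(heterozygote to homozygote) and switch (opposite homozygotes), restricted
to the types applicable to the genotype class. The default composition is
uniform over applicable types because the reference simulator exposes only
a rate. Phased haplotypes are updated consistently so the phased detector
sees erroneous data under retained true phase — the substitute for
statistical re-phasing, whose errors can instead be emulated with
`inject_phase_errors()`.

## The four estimators

* **MoM from IBS counts** (`king_theta()`):
  `theta = (N_AaAa - 2 N_AA,aa) / (N_Aa^i + N_Aa^j)` — the
  homogeneous-population form; no allele frequencies needed, estimates may
  be negative.
* **IBS-run detector** (`ibis_segments()`): maximal runs free of
  opposite-homozygote sites, kept when at least 2 cM *and* 186 markers
  long; identical-genotype sub-runs meeting the same criteria are emitted
  as IBD2. Kinship adds a supplemental constant:
  `theta = kappa2/2 + kappa1/4 + 0.00138`.
* **Probability-thresholded detector** (`truffle_segments()`): candidate
  IBD1 runs (no opposite homozygotes) and IBD2 runs (identical genotypes)
  are kept when the Hardy–Weinberg chance-compatibility probability of the
  whole run is below 1e-8 and the physical span reaches 5 Mb (IBD1) / 2 Mb
  (IBD2). Per-site compatibility probabilities are `1 - 2 p^2 q^2` (IBD1)
  and `p^4 + (2pq)^2 + q^4` (IBD2). A built-in error model is emulated by a
  bridging rule: an incompatible site is tolerated inside a run when no
  other incompatible site lies within 100 markers — at most one isolated
  mismatch per 100 consecutive markers. This reproduces the qualitative
  robustness profile (unaffected below ~1% error, collapsing above) of the
  original tool, whose exact error-model parameters are unpublished.
* **Phased exact-match detector** (`germline_segments()`): maximal exactly
  matching stretches between the four cross-individual haplotype pairs,
  kept at 3 cM or longer; intervals where both haplotypes can be matched
  are IBD2. The scan is a vectorised run-length pass over the haplotype
  equality profile — an exact equivalent of seed-and-extend word hashing,
  which in R would only change speed, not output.

Segment lengths are summed in genetic units across autosomes and converted
through the Cotterman coefficients `kappa1 = L(IBD1)/L(genome)`,
`kappa2 = L(IBD2)/L(genome)`, `theta = kappa2/2 + kappa1/4`, with
`L(genome) = 3346.30` cM.

### Why the IBS-run detector emits IBD2 by default

With IBD2 emission disabled, a full-sib pair's IBD2 share is counted once
instead of twice and its kinship is systematically underestimated by
`kappa2/4` (about 0.06 — a full degree). Published estimates for sibs sit
at the theoretical 1/4, so the package enables IBD2 sub-run emission by
default (`ibis_ibd2 = TRUE`); disabling it restores the IBD1-only
behaviour.

## Classification and metrics

`classify_degree()` implements the empirical criteria: boundaries at the
geometric midpoints `1/2^((2k+3)/2)` between adjacent expected kinship
values, left-closed/right-open, with `theta >= 1/2^(3/2)` classed
twin/same individual and everything below `1/2^(17/2)` (including negative
MoM estimates) unrelated. `compute_metrics()` reports sensitivity, positive
predictive value, overall accuracy, and the overlapping rate — the
proportion of estimates inside per-class reference intervals
(`reference_ranges()`, observed min–max by default with a quantile option;
min–max reproduces the observed "lower bounds all zero" behaviour of
segment detectors for distant classes). Undefined estimates count as
misclassifications for sensitivity and accuracy but never enter a PPV
denominator; the twin bin exists only as an inferred class because no
simulated pair is labelled twin.

## Estimator fusion

`build_features()` constructs 13 variables from the four estimates: the
levels, six pairwise differences, and three ratios with the IBS-run
estimate as denominator (its supplemental constant keeps it strictly
positive). `fit_stepwise()` performs bidirectional stepwise selection by a
small-sample-corrected information criterion (AICc) from the intercept-only
model — the difference features are exact linear combinations of the
levels, so the full design is rank-deficient by construction and selection,
not inversion, resolves the aliasing — followed by seeded 10-fold
cross-validation and a refit on all data. `fit_combination_model()` stacks
one observation per pair per error level, with features from that level and
the response always the pair's error-free "expected kinship coefficient"
(the four-method mean, `expected_theta()`). Pooling the levels is what lets
one model serve every error rate; unrelated pairs are included so the model
sees the full support of the classification task. The bundled models
`combination_models()` (M1–M7, all tool subsets) are published constants
applied verbatim; refitting never overwrites them.

## Numerical and design choices

* Coordinates are 0-based half-open internally and 1-based in VCF output.
* Missing genotype calls never terminate a candidate run and are excluded
  from IBS counts and discordance denominators.
* Classification boundaries are compared left-closed; ties in stepwise
  selection resolve to the first candidate, making fits reproducible.
* Pedigree kinship values of outbred pedigrees are dyadic rationals and
  therefore exact in binary floating point.
* The Hardy–Weinberg filter for real data uses a hand-implemented exact
  test (standard recurrence over heterozygote counts), applied only at the
  VCF entry point — simulated genotypes are in HWE by construction.

## Problem sizes used in the checks

The panel-density regime determines which estimators can be calibrated at
all: the marker-count and probability thresholds translate into minimum
*genetic* lengths only at sufficient density (about 49 markers/cM — a
164,000-marker panel over the full map, the smallest panel at which all
four estimators remain calibrated).
Below it, the IBS-run detector's 186-marker floor and the
probability-thresholded detector's 1e-8 product criterion correspond to
tens of centimorgans and the detectors are expected to undershoot — that
degradation is itself one of the reproduced findings, not a defect. The
calibration checks therefore run on an 18-family cohort over a 164,000
marker panel (error-free), the trend checks reuse that cohort across the
error ladder 0/0.1/0.5/1/5/10% and a panel ladder down to 5,000 markers,
and the fusion robustness check trains on an independently seeded 6-family
cohort across all error levels (1,080 observations for a 13-feature linear
model). Smaller fixtures (two-family cohorts at 8,000 markers; a
two-chromosome, 300 cM genome at reference density) back the unit and
property tests. Detector implementations are verified against naive
quadratic reference scanners on hundreds of randomised instances of up to
1,000 markers.

## Known limitations

A single pooled-levels linear fusion cannot fit all error levels equally
well: under the no-LD synthetic conditions the per-level relationships
between features and the error-free target differ (segment estimators
collapse entirely at 5–10%), so the pooled model's training R² sits well
below the near-unity value achievable by a fit on error-free data alone.
The pooled model is nevertheless the right deployment object — it is the
one whose accuracy stays ahead of the segment detectors at high error
rates, which is its purpose. Other limitations: no crossover interference,
no sex-specific maps, no inbred pedigrees, no twin pairs in the simulated
cohorts (the twin bin exists only as an inferred class), and no
missing-data simulation (missingness is handled at the VCF entry point
only).

## What passing tests do and do not show

The simulations emulate panel size, marker density, genotyping-error rate
and pedigree structure. They do not emulate linkage disequilibrium,
population structure or array-chemistry error profiles, so quantitative
accuracy values obtained here need not match analyses of real array data —
only the qualitative orderings (density thresholds for segment methods, MoM
error robustness, fusion stability) are expected to transfer. The phased
detector is evaluated under true phase; with statistical phasing of
high-missingness data its real-world performance degrades further.

## A worked run

```{r example, eval = FALSE}
map <- generate_map()
founders <- generate_founders(208, 20000, map, seed = 1)
cohort <- run_cohort(founders, founders$panel, map, seed = 2)

est <- estimate_cohort(cohort)
aggregate(cbind(theta_KING, theta_GERMLINE) ~ degree, est, mean)

grid <- run_error_grid(cohort, seed = 3)
subset(grid$AC, error_rate == 0.05)
```
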