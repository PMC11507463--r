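# kinfuse

Evaluation toolkit for SNP-based kinship inference in forensic
investigative genetic genealogy (FIGG). Casework DNA is often low-input or
degraded; whether a relationship as distant as the seventh degree can still
be recovered depends on how many SNPs survive genotyping and how many of
them are wrong. `kinfuse` packages a controlled simulation bench for that
question: pedigree simulation with exact identity-by-descent (IBD) ground
truth, a genotyping-error model, reference implementations of four kinship
estimator archetypes, relationship-degree classification with evaluation
metrics, and a linear fusion of the four estimators that remains usable at
extreme error rates.

## What it computes

The kinship coefficient θ (expected `1/2^(d+1)` for degree-*d* outbred
relatives) is estimated four ways:

* **MoM (IBS counts)** — `θ = (N_Aa,Aa − 2·N_AA,aa) / (N_Aa^i + N_Aa^j)`,
  the homogeneous-population method-of-moments estimator; may be negative.
* **IBS-run segments** — maximal runs without opposite homozygotes, kept at
  ≥ 2 cM and ≥ 186 markers; `θ = κ2/2 + κ1/4 + 0.00138`.
* **Probability-thresholded segments** — runs kept when their
  Hardy–Weinberg chance-match probability is < 1e-8 and they span ≥ 5 Mb
  (IBD1) / ≥ 2 Mb (IBD2), with an error-bridging rule tolerating one
  isolated mismatch per 100 markers.
* **Phased exact-match segments** — haplotype matches ≥ 3 cM between all
  cross-individual haplotype pairs.

Segment lengths convert through Cotterman coefficients
`κ1 = L(IBD1)/L(genome)`, `κ2 = L(IBD2)/L(genome)` over a 3346.30 cM
autosomal map, and `θ = κ2/2 + κ1/4`. Degrees are classified by the
empirical interval criteria with boundaries `1/2^((2k+3)/2)`; performance
is reported as overlapping rate, sensitivity, PPV and overall accuracy.
A 13-variable stepwise linear fusion (levels, pairwise differences, ratios
against the IBS-run estimate) predicts the error-free "expected kinship
coefficient" from error-affected estimates; published fusion coefficients
for all tool subsets (M1–M7) ship as constants.

## Worked example

```r
library(kinfuse)

map      <- generate_map()                                 # 22 autosomes, 3346.30 cM
founders <- generate_founders(208, 20000, map, seed = 1)   # phased founder pool
cohort   <- run_cohort(founders, founders$panel, map, seed = 2)
cohort
#> Kinship cohort: 18 families, 540 labelled pairs, 20,000 markers

est <- estimate_cohort(cohort)
agg <- aggregate(cbind(theta_KING, theta_GERMLINE) ~ degree, est, mean)
agg[-1] <- round(agg[-1], 4)
agg
#>      degree theta_KING theta_GERMLINE
#> 1       1st     0.2485         0.2494
#> 2       2nd     0.1228         0.1260
#> 3       3rd     0.0587         0.0629
#> 4       4th     0.0282         0.0335
#> 5       5th     0.0118         0.0179
#> 6       6th     0.0049         0.0107
#> 7       7th     0.0017         0.0073
#> 8 unrelated     0.0013         0.0042
```

Close kin sit on the theoretical ladder (1/4, 1/8, 1/16, …); at this
20 K-marker density the phased detector drifts upward for distant degrees
(chance matches over few markers) — the kind of density effect the package
exists to expose. Error robustness of the fusion, fit on this cohort across
the error ladder and applied level by level:

```r
base   <- run_error_grid(cohort, model = NULL, seed = 3)    # four estimators
fusion <- fit_combination_model(base$estimates, seed = 4)   # stepwise + 10-fold CV
grid   <- run_error_grid(cohort, model = fusion, seed = 3)
reshape(grid$AC, idvar = "method", timevar = "error_rate", direction = "wide")
#>        method      AC.0  AC.0.001  AC.0.005   AC.0.01    AC.0.05     AC.0.1
#> 1        KING 0.6833333 0.6796296 0.6055556 0.4833333 0.10185185 0.10000000
#> 2        IBIS 0.5944444 0.5425926 0.3333333 0.1259259 0.10000000 0.10000000
#> 3     TRUFFLE 0.4351852 0.4166667 0.3462963 0.1851852 0.10000000 0.10000000
#> 4    GERMLINE 0.7129630 0.7166667 0.7296296 0.7222222 0.29259259 0.12222222
#> 5 COMBINATION 0.6962963 0.6925926 0.6703704 0.6685185 0.60740741 0.31111111
```

The single estimators collapse toward the unrelated floor (AC 0.10) as the
error rate grows — the IBS-run detector first, then the MoM estimator —
while the fused estimate still classifies 61% of pairs correctly at 5%
error and stays ahead of every component at 10%. `real_data_entry()` runs
the same machinery on VCF genotypes with a genetic-map file, including
MAF/HWE filtering and discordance profiling (drop-in / drop-out / switch
errors).

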