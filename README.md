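# hrnegsig

Prognostic gene-signature discovery and multigene-index evaluation for
node-negative, hormone receptor-negative (HRneg) and triple-negative (Tneg)
breast cancer.

Most early-stage HRneg/Tneg patients managed without adjuvant chemotherapy
never develop distant metastases, yet nearly all receive aggressive
treatment: the established multigene predictors are driven by proliferation
modules and carry almost no prognostic information in this subtype.
`hrnegsig` implements, as tested reusable R functions, a discovery pipeline
for distant metastasis-free survival (DMFS) predictors in pooled
multi-source expression cohorts, and the composite-index machinery to
evaluate what it finds.

## What it computes

**Candidate discovery** (`discover_signature()`), run on the full HRneg
cohort and again on its Tneg subset, then unioned:

1. per-source nearest-shrunken-centroid (PAM) screen against the
   metastasis outcome, intersected across sources with sign-consistency;
2. Monte-Carlo cross-validation Cox screen on variance-filtered,
   per-source Z-transformed, pooled data: 100 stratified learning/test
   splits, univariate Cox per gene per half; selection requires mean Wald
   P &lt; 0.01 *and* the same coefficient sign in &gt; 80% of split pairs;
3. univariate/multivariate Cox sign-consistency filtering (ridge-stabilized
   joint fit on degenerate designs);
4. hold-out confirmation by coefficient sign in reserved source(s).

**Composite index** (`compute_index()`): for a signature with
hazard-increasing members *P* and protective members *N*,

```
index_s = ( sum_{i in P} x_is  -  sum_{j in N} x_js ) / n
```

with *n* the number of signature genes mapped to the cohort (missing genes
shrink the denominator) and genes equally weighted. Higher index = worse
predicted prognosis. Evaluation: percentile dichotomization with
Kaplan-Meier / log-rank / Cox hazard ratios (`dichotomize_index()`),
log-rank-optimal cut-point search restricted to the 20th–80th percentiles
(`optimize_cutpoint()`), greedy stepwise gene prioritization
(`stepwise_addition()`, `stepwise_subtraction()`), multi-signature
comparison at a common median cut (`compare_prognosis()`), index-index
Pearson correlation matrices with cross-cohort consistency flags
(`correlate_indices()`), and T-/B-lymphocyte infiltration scores
(`lymphocyte_scores()`).

A synthetic multi-source cohort generator (`simulate_cohort()`) with known
ground truth — batch-shifted log2 expression, a shared latent risk factor
carried by mostly protective prognostic genes, exponential
proportional-hazards survival calibrated to ~33% metastasis with ~85% of
events inside 5 years, and a bimodal ERBB2-like gene for HER2
stratification — makes every stage testable without external data. The
published 14-gene HRneg/Tneg signature (and its 11-gene HRneg, 7-gene Tneg
and truncated 7-gene variants) ships as plain TSV files
(`hrnegsig_signatures()`).

## Worked example

Simulate a 199-sample, three-source cohort with ten planted prognostic
genes among 2,000, discover a signature using two sources for screening and
one for confirmation, and evaluate its index:

```r
library(hrnegsig)

sim    <- simulate_cohort(sim_params(n_genes = 2000, n_prognostic = 10,
                                     effect_sizes = 1.2,
                                     samples_per_source = c(69, 66, 64),
                                     seed = 42))
bundle <- assign_her2_status(sim$bundle)

# PAM budget scaled to the feature count (~1.35% per source)
fit <- discover_signature(bundle, discovery = c("S1", "S2"), holdout = "S3",
                          config = discovery_config(pam_top_k = 27,
                                                    mccv = mccv_config(seed = 42)))
fit
#> Prognostic signature fit
#>   cohort: 199 samples (147 triple-negative)
#>   HRneg candidates confirmed: 7
#>   Tneg  candidates confirmed: 3
#>   combined signature size:    7

zb  <- z_transform_within_source(bundle)
idx <- predict(fit, zb)
dichotomize_index(idx, zb, percentile = 75)
#> cut 0.3141 (75.4th pct): low n=150, high n=49
#>   HR high vs low = 12.30 (95% CI 7.92-19.08), Cox P = 4.54e-29
#>   log-rank P = 9.13e-42
```

All seven discovered genes are planted prognostic genes (7 of 10
recovered, no false positives at this scale). The upper-third-quartile cut
puts 75% of patients in the good-prognosis group while isolating a
high-risk quarter with a twelve-fold hazard of distant metastasis;
`optimize_cutpoint()` confirms the best cut in [20, 80] sits near that
quartile (79.4th percentile here).

`run_pipeline()` drives the same stages from a YAML/JSON configuration and
writes TSV/JSON artifacts plus a checksummed run manifest;
`inst/cli/hrnegsig.R` is a thin command-line front end over it.

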