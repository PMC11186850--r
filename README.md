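# pwmr — proteome-wide Mendelian randomization and colocalization

`pwmr` nominates causal plasma (or CSF) proteins for a complex disease
from summary statistics alone. Given cis-pQTL summary data for each
protein, a disease GWAS, and an LD reference, it runs the full
drug-target triage that proteome-wide MR studies use: instrument
selection, a family of two-sample MR estimators with diagnostics, GSMR
with outlier removal, the cis-region HEIDI test, Bayesian
colocalization, discovery/validation FDR gating, and a three-tier
evidence classification. A built-in simulator generates LD-structured
summary statistics with known causal architecture, so every stage is
testable without access to large cohort data.

It is written for statistical geneticists and target-discovery teams who
have per-variant association files (protein level and disease) and want
a reproducible, scriptable triage from thousands of proteins down to a
ranked table of candidate targets.

## The statistics in brief

For instruments with exposure effects `b_xj` (SE `s_xj`) and outcome
effects `b_yj` (SE `s_yj`) on a shared effect allele:

- **Wald ratio** (single instrument): `beta = b_y / b_x`, SE `s_y/|b_x|`.
- **Random-effects IVW**: `beta = Σ w_j b_xj b_yj / Σ w_j b_xj²` with
  `w_j = 1/s_yj²`; SE inflated by `max(1, sqrt(Q/(k−1)))` with Cochran's
  Q about the IVW slope.
- **LD-aware IVW**: generalized least squares with
  `Ω_ij = s_yi s_yj r_ij` from the LD reference.
- **MR-Egger**: weighted regression with intercept; the intercept tests
  directional pleiotropy.
- **Weighted median / weighted mode**: robust estimators tolerating up
  to 50% (respectively plurality) invalid weight.
- **GSMR**: GLS combination of per-SNP ratios with variance
  `(s_yj² + b_xyj² s_xj²)/b_xj²` and LD covariance, iteratively removing
  outlier SNPs whose deviation p-value falls below 0.01.
- **HEIDI**: tests whether ratios across a cis region (SNPs with
  exposure p ≤ 1.57e-3, 3–20 SNPs) are homogeneous with the top SNP's
  ratio; the statistic is a quadratic form in correlated normals,
  referred to an eigenvalue-weighted chi-square null.
- **Colocalization**: Wakefield log-ABFs
  `0.5·log(1−r) + 0.5·r·z²`, `r = W/(V+W)` per SNP and trait,
  accumulated into posteriors for H0–H4 under priors
  `p1 = p2 = 1e-4`, `p12 = 1e-6`; `PP.H4 ≥ 0.80` is strong support for a
  shared causal variant.
- **Steiger**: compares instrument-explained variance in exposure vs
  outcome via Fisher-transformed correlations.

Evidence tiers for associations significant in discovery
(BH-FDR < 0.05) and validation (p < 0.05, same direction): tier 3 if
PP.H4 < 0.5, or the confounder-exclusion sensitivity refit fails, or the
GSMR/LD-aware-IVW confirmation fails; tier 1 if PP.H4 ≥ 0.8, HEIDI
p ≥ 0.05, heterogeneity and pleiotropy diagnostics clean (or not
assessable), and the protein is associated with ≥ 2 outcomes; tier 2
otherwise.

## Worked example

Simulate a three-protein study (one protein with a shared causal
variant, one causal protein with some pleiotropic instruments, one null
protein), write the input files, and run the pipeline:

```r
library(pwmr)

sim <- simulate_proteome(c(protA = "H4", protB = "pleiotropy", protC = "H1"),
                         scale = "paper_like", seed = 2025)
cfg <- write_proteome_files(sim, "simdir", seed = 11)
cfg$outdir <- "simdir/run"
tab <- run_pipeline(cfg)
tab[, c("protein", "discovery_method", "discovery_pval", "discovery_q",
        "validation_pval", "pp_h4", "heidi_pval", "significant", "tier")]
```

```
  protein discovery_method discovery_pval  discovery_q validation_pval
1   protA       wald_ratio   1.322912e-12 3.968737e-12    1.322912e-12
2   protB       ivw_random   1.130546e-03 1.695820e-03    1.072645e-03
3   protC       wald_ratio   6.327491e-01 6.327491e-01    6.327491e-01
         pp_h4 heidi_pval significant tier
1 9.999926e-01 0.06702711        TRUE    2
2 4.835172e-07 0.19310214        TRUE    3
3 3.506707e-04 0.70352400        FALSE   NA
```

protA's single shared causal variant gives a Wald-ratio discovery hit,
near-certain colocalization (PP.H4 ≈ 1) and a passing HEIDI test; it
lands in tier 2 only because, with a single outcome in this toy study,
no protein can meet the ≥ 2-outcomes tier-1 rule. protB (ten causal
exposure variants, four with pleiotropic outcome effects) is estimated
by random-effects IVW and replicates, but its polygenic cis
architecture violates the single-causal-variant assumption of the
colocalization model, so PP.H4 collapses and the association is graded
tier 3 — exactly the triage such a signal should receive. The null
protein protC is never significant and receives no tier. The run also
writes `simdir/run/associations.tsv` (all per-stage metrics) and a JSON
manifest; re-running with the same config and seed reproduces the TSV
byte for byte.

The classifier can also be applied directly to a published association
table; the packaged 22-row table of plasma-protein/migraine
associations is the reference:

```r
fx <- load_tier_fixture()
fx$significant <- TRUE
table(classify_tier(fx))
#>  1  2  3
#>  6  9  7
```

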