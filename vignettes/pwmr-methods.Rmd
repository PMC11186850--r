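---
title: "Methods: proteome-wide MR, colocalization and evidence tiering in pwmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteome-wide MR, colocalization and evidence tiering in pwmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmr)
```

`pwmr` re-implements, as one reusable pipeline, the summary-statistics
workflow used to nominate causal plasma proteins for complex disease:
cis-pQTL instrument selection, two-sample MR with diagnostics, GSMR,
HEIDI, Bayesian colocalization, FDR-gated discovery/validation, and
tier classification. This vignette documents the models, the parameters
that matter, the numerical choices, and what the synthetic-data tests
do and do not establish.

## Instrument selection

Candidate instruments for a protein are variants inside the cis window
— the protein-coding gene's span plus a 500 kb flank on each side,
1-based and inclusive at both boundaries — with association
p < 5×10⁻⁸ and minor allele frequency ≥ 0.01 (`min(eaf, 1−eaf)`,
computed from the exposure study because instrument-side frequencies
are always available). Palindromic variants (A/T, G/C) with exposure
frequency in [0.4, 0.6] are removed: their strand cannot be resolved
from alleles alone exactly where the frequency carries no information.
The extended HLA region (default chr6:29–34 Mb, configurable because
coordinates are build-dependent) is excluded for its complex LD and
pleiotropy. Remaining candidates are greedily clumped: take the
smallest-p variant, drop everything within 10 Mb at r² ≥ 0.001, repeat;
ties break lexicographically on variant id so runs are deterministic.
Every exclusion is recorded with the rule that caused it, so a
selection can be audited after the fact.

Two selection tracks exist side by side: the strict track (r² < 0.001)
feeds the discovery/validation estimates, and a relaxed track
(r² < 0.1) feeds GSMR and the LD-aware IVW, which model the retained
correlation explicitly.

Instrument strength is summarised per variant as F = (β/se)², the
standard approximation when only marginal summary effects are
available; F ≥ 10 is the conventional weak-instrument gate. The cis
window is anchored to the gene body rather than the TSS — a superset of
TSS-anchored windows, so no TSS-proximal instrument is lost.

## Harmonization and proxies

Exposure and outcome records are joined on variant id and expressed on
the exposure's effect allele: a swapped orientation negates the outcome
beta and complements its frequency; strand complements are accepted for
non-palindromic variants; alleles matching neither orientation drop the
variant with an `allele_mismatch` flag. Harmonization is idempotent.

Instruments missing from the outcome file can be replaced by the
outcome-present variant with the highest r² ≥ 0.8. The proxy's effect
is re-oriented by allele matching against the LD reference when allele
annotations exist, otherwise by the sign of r; negative LD transfers
the effect with a sign flip. Raising the proxy threshold can only
reduce the number of resolved variants.

## The estimator family

With per-variant exposure effects $b_{xj}$ (SE $s_{xj}$) and outcome
effects $b_{yj}$ (SE $s_{yj}$):

* **Wald ratio** — $\hat\beta = b_y/b_x$ with first-order SE
  $s_y/|b_x|$, matching the IVW weighting convention below; a
  second-order option adds the exposure-variance term and agrees with
  Monte-Carlo ratio SEs within 2% for instruments with $|b_x|/s_x>10$.
* **IVW (random effects)** — the inverse-variance-weighted combination
  with weights $1/s_{yj}^2$ (equivalently zero-intercept weighted
  regression). The random-effects SE multiplies the fixed SE by
  $\max(1,\sqrt{Q/(k-1)})$: heterogeneity inflates uncertainty but
  never deflates it below the fixed-effect value. A single instrument
  falls through to the Wald ratio with an explicit note.
* **LD-aware IVW** — GLS with outcome covariance
  $\Omega_{ij}=s_{yi}s_{yj}r_{ij}$; reduces exactly to fixed-effect IVW
  at identity LD.
* **MR-Egger** — weighted regression with intercept after orienting all
  exposure effects non-negative; the intercept estimates directional
  pleiotropy. SEs use the same floor-1 inflation and t-tests on k−2 df.
* **Weighted median** — ratios ordered, weights $b_{xj}^2/s_{yj}^2$
  normalised, linear interpolation at cumulative weight 0.5; SE by a
  seeded parametric bootstrap (default 1,000 draws). Consistent while
  valid instruments carry > 50% of the weight.
* **Weighted mode** — argmax of a weighted normal-kernel density over
  the ratios; bandwidth is a weighted Silverman-type rule
  ($1.06\,s\,k^{-1/5}$, $s=\min(\mathrm{sd},\mathrm{IQR}/1.349)$) times
  a configurable factor (default 1).
* **Steiger directionality** — per-SNP $r^2 = z^2/(z^2+n-2)$, summed
  over independent instruments and capped at 1; direction from
  comparing $|r_x|$ and $|r_y|$, p-value from Fisher-transformed
  correlations. For binary outcomes the z-based $r^2$ on the effective
  sample size is an observed-scale approximation and is labelled as
  such; a liability-scale conversion is out of scope.

Binary-outcome effects are log-odds throughout; odds ratios are
`exp(beta)`.

One calibration subtlety is worth stating. The floor-1 random-effects
inflation truncates the SE distribution, which makes IVW and Egger
p-values slightly conservative for small instrument panels (the floor
binds on roughly half of null datasets). The effect vanishes as the
panel grows, so the package's null-uniformity and type-I calibration
studies use panels of 100 (IVW) and 50 (Egger) instruments, where the
estimators' nominal behaviour is the thing actually under test; at
k = 20 the Egger intercept test's true level is ≈ 0.04 rather than
0.05.

## GSMR and HEIDI

GSMR combines per-SNP ratios $\hat b_{xy,j}=b_{yj}/b_{xj}$ with
delta-method variances
$v_j = (s_{yj}^2 + \hat b_{xy,j}^2 s_{xj}^2)/b_{xj}^2$ — unlike plain
IVW, the exposure-side sampling variance enters — by GLS under the LD
covariance $V_{ij}=r_{ij}\sqrt{v_i v_j}$. Outlier removal exploits a
GLS identity: $\mathrm{cov}(\hat b_{xy,j},\hat\beta)$ equals
$\mathrm{var}(\hat\beta)$ for every SNP, so each deviation
$d_j=\hat b_{xy,j}-\hat\beta$ has variance $v_j-\mathrm{var}(\hat\beta)$
in closed form. The worst SNP is removed while its two-sided deviation
p-value is below 0.01, refitting each time; the loop terminates in at
most k iterations and errors only in the degenerate all-removed case.

HEIDI asks whether the cis region's association pattern is consistent
with a single shared causal variant. Anchoring on the top exposure SNP,
eligible SNPs (exposure p ≤ 1.57×10⁻³; r² with the top SNP between
0.05 and 0.9, the published defaults of the SMR tool — too-strong LD
duplicates the top SNP, too-weak LD makes the ratio uninformative; at
least 3 and at most 20 SNPs, capped by exposure |z|) contribute
deviations $d_j = \hat b_{xy}(j)-\hat b_{xy}(\mathrm{top})$ whose
delta-method covariance includes both traits' LD terms. The statistic
$T=\sum_j d_j^2/\mathrm{var}(d_j)$ is a quadratic form in correlated
normals; its p-value comes from the eigenvalue-weighted chi-square
distribution. Fewer than 3 eligible SNPs yields a "not assessable"
result with the reason recorded.

Interpretation convention: HEIDI p ≥ 0.05 *passes* (no evidence against
a single shared causal variant); p < 0.05 indicates distinct linked
variants. Published descriptions of the test occasionally state the
opposite reading in prose, but the evidence grading in the study this
package's tier rules reproduce treats large HEIDI p as favourable
(every top-tier association there has p_HEIDI ≥ 0.05), and that is the
only reading consistent with the test's construction.

The weighted-chi-square tail probability is computed by
characteristic-function inversion (an Imhof-type integral). The
integrand oscillates with asymptotic period $4\pi/T$ under a
polynomially decaying envelope, so the implementation integrates
period-aligned chunks and stops when contributions vanish —
asymptotically an alternating series, bounding the truncation error by
the last chunk — rather than handing an infinite oscillatory range to
adaptive quadrature (which fails silently there). A
Satterthwaite moment-matched scaled chi-square is the fallback if the
integration does not converge. The implementation is verified against
the exact chi-square special case and 2×10⁶-draw Monte Carlo.

## Colocalization

Per SNP and trait, the Wakefield log approximate Bayes factor is
$\mathrm{lABF} = \tfrac12\log(1-r) + \tfrac12 r z^2$ with
$r = W/(V+W)$, $V = se^2$. Prior effect SDs default to 0.15 for
quantitative traits and 0.2 (log-odds) for binary traits; only the
beta/se parameterisation is used. Hypothesis weights are accumulated on
the log scale with log-sum-exp; the H3 (distinct variants) sum over
ordered pairs is computed stably as
$\exp(L_1+L_2)-\exp(L_{12})$ via `log1p`. Posteriors are validated
against brute-force enumeration over all causal configurations to
1×10⁻¹⁰. Priors are `p1 = p2 = 1e-4`, `p12 = 1e-6`; support labels are
strong (PP.H4 ≥ 0.80) and moderate (≥ 0.50). The model assumes at most
one causal variant per trait per region — under a polygenic cis
architecture PP.H4 is legitimately small even for truly causal
proteins, which is why colocalization is a grading input rather than a
gate on discovery.

## Pipeline and tier classification

Per protein × outcome: discovery estimate (Wald ratio for one
instrument, random-effects IVW otherwise) in the discovery pQTL study;
BH-FDR jointly across *all* discovery tests (the grading family is the
whole proteome × outcome grid); validation estimate in the second pQTL
study with a same-direction requirement; confirmation by GSMR on the
relaxed track (LD-aware IVW when fewer than 5 SNPs survive;
`insufficient_snps` below 2); heterogeneity (Cochran Q) and pleiotropy
(Egger intercept) diagnostics on the relaxed set; HEIDI and
colocalization on the full cis region; a sensitivity refit excluding
instruments listed in a confounder-association table (the offline
stand-in for a phenome-database query), with optional pre-filters
dropping variants that are genome-wide significant for the outcome or
fail a cross-cohort heterogeneity screen; and reverse MR using the
outcome's genome-wide instruments (threshold relaxed from 5×10⁻⁸ to
1×10⁻⁵ only when the strict threshold yields none).

"Significant" means discovery FDR < 0.05 *and* validation p < 0.05 with
the same direction; "suggestive" means nominal p < 0.05 in both pQTL
studies with the same direction. A protein's associated-outcome count
includes both.

Tiers, applied to significant records only:

* **tier 3** — PP.H4 < 0.5, or sensitivity failure, or confirmation
  failure;
* **tier 1** — PP.H4 ≥ 0.8, HEIDI p ≥ 0.05, Q p ≥ 0.05 (or not
  assessable), intercept p ≥ 0.05 (or not assessable), and ≥ 2
  associated outcomes;
* **tier 2** — everything else.

Counting non-assessable heterogeneity/pleiotropy as passing reflects
how published tables grade sparse-instrument associations; a
conservative flag (`na_aux_passes = FALSE`) flips that. A HEIDI result
that is not assessable does not qualify for tier 1. The rule table
reproduces the published 22-row migraine association table exactly
(6 tier-1, 9 tier-2, 7 tier-3); that table ships in
`inst/extdata/migraine_associations.tsv` with printed "<0.01" values
stored as 0.009.

The whole run is configuration-driven (`run_pipeline()` on a YAML
file), seeds all randomness from the configuration, and emits a
tab-delimited association table plus a JSON manifest; identical
configurations give byte-identical outputs.

## The synthetic-data generator

The generator works on the standardized-genotype scale: joint effects
$b$ per variant, true marginal effects $Rb$ for LD matrix $R$ (AR1,
constant-correlation blocks, or identity — all PSD by construction),
observed z-scores drawn $\mathrm{MVN}(z_{\mathrm{true}}, R)$, and
per-allele betas reconstructed with $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})}$
so emitted files look like real GWAS output. Binary outcomes use the
effective sample size $n_\mathrm{eff} = 4/(1/n_\mathrm{case}+1/n_\mathrm{control})$
and standardized SE $2/\sqrt{n_\mathrm{eff}}$, consistent with the
logistic-regression SE at the study's case fraction. Scenario presets
cover H0–H4, directional pleiotropy, 40%-invalid instrument panels,
reverse causation and a confounder-acting variant, each in a 60-SNP
AR1(0.5) region with MAF uniform on [0.01, 0.5].

Study sizes follow the two-study design the pipeline targets: a
7,213-sample discovery and a 35,559-sample validation pQTL study, and a
migraine-scale outcome GWAS of 79,495 cases / 1,259,808 controls at
`scale = "paper_like"`. The default `scale = "small"` keeps the
exposure studies at full size (summary-level simulation cost does not
depend on n) and scales the outcome to 2,000 / 20,000 — a 40× reduction
in cases — while enlarging shared-variant outcome effects (0.16 vs
0.025 on the standardized log-odds scale) so the causal variant keeps
an outcome z-score near 6: the calibration questions the tests ask
(does colocalization recognise a shared variant; does HEIDI keep its
size) are about that signal regime, not about absolute sample size.
Per-SNP exposure effects are 0.12–0.15 SD (2% of exposure variance for
a single causal pQTL variant), and the standard causal effect in
recovery tests is 0.1 log-odds per SD of protein.

An individual-level generator (latent-Gaussian haplotypes thresholded
at the MAF quantile, linear exposure, logistic outcome) serves as an
independent oracle: marginal regression estimates agree with the
summary-level generator's expectations within Monte-Carlo error.
One caveat is deliberate: thresholding latent Gaussians attenuates
pairwise dosage correlation below the latent $\rho$ (the tetrachoric
effect), so the agreement is checked against the realized dosage LD —
the identity the summary generator encodes is marginal = LD × joint for
the LD of the genotypes actually analysed.

What passing these tests shows — and does not. The simulator emulates
LD-correlated effect estimates under known architectures; it does not
model recombination-map LD, population structure, allele-frequency–
dependent architectures, imputation error, or platform-specific protein
measurement effects. Calibration on these data therefore establishes
internal statistical correctness, not robustness to every property of
real cohort data.

## Numerical choices and degenerate inputs

* LD matrices are ridge-regularized before any inversion:
  $R' = (R+\lambda I)/(1+\lambda)$, $\lambda=10^{-3}$, keeping the unit
  diagonal; reference panels routinely give near-singular matrices.
* Underflowed p-values (printed as 0) are clamped to the smallest
  positive double at load rather than rejected.
* Zero exposure effects make the Wald ratio undefined and error
  explicitly; variants absent from the LD reference are treated as
  uncorrelated during clumping (with a warning) rather than dropped.
* Bootstrap and simulation RNG is always seeded; internal draws save
  and restore the global RNG state.
* Problem sizes in the packaged test-and-acceptance runs: 2,000
  replicates for IVW null uniformity, 1,000 for Egger type-I and HEIDI
  size, 200 each for colocalization scenario rates, GSMR recovery and
  outlier removal, 500 for Steiger direction — sizes chosen so
  Monte-Carlo error is small against each acceptance band.

## Known limitations

Single-causal-variant colocalization only (no multi-signal
decomposition); cis instruments only; no liability-scale Steiger for
binary traits; no trans-pQTL support, genome-build liftover, live
LD-server or phenome-database queries. The confounder-exclusion table
is a user-supplied input; curating it is the analyst's responsibility.
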