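Package: pwmr
Title: Proteome-Wide Two-Sample Mendelian Randomization and Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for nominating causal plasma proteins for complex disease
    from cis-pQTL and GWAS summary statistics. Implements instrument
    selection (cis windows, genome-wide significance, palindromic and HLA
    filters, LD clumping, F statistics), a family of summary-data Mendelian
    randomization estimators (Wald ratio, random-effects IVW, LD-aware IVW,
    MR-Egger, weighted median, weighted mode) with heterogeneity, pleiotropy
    and Steiger directionality diagnostics, GSMR with outlier removal,
    the cis-region HEIDI test of linkage versus a shared causal variant,
    single-causal-variant Bayesian colocalization via Wakefield approximate
    Bayes factors, and a discovery/validation pipeline with
    Benjamini-Hochberg FDR gating and a three-tier evidence classifier for
    drug-target nomination. A summary-statistic simulator with known causal
    architecture supports end-to-end testing without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
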