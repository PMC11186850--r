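# cis-instrument selection, clumping, instrument strength, cross-cohort
# heterogeneity.

test_that("cis window is inclusive at exactly flank distance", {
  region <- gene_region("G1", "1", 2e6, 2.1e6)
  pos <- c(2e6 - 5e5,       # exactly at the lower boundary: retained
           2e6 - 5e5 - 1,   # one bp outside: removed
           2.1e6 + 5e5)     # exactly at the upper boundary: retained
  pqtl <- summary_stats(toy_records(3, pos = pos, pval = 1e-12),
                        "p", "quantitative")
  ld <- toy_ld(diag(3))
  iv <- select_cis_instruments(pqtl, region, ld)
  expect_setequal(iv$variants$variant_id, c("rs1", "rs3"))
  audit <- iv$audit
  expect_equal(audit$rule[audit$variant_id == "rs2"], "outside_cis_window")
})

test_that("HLA-region variants are excluded regardless of strength", {
  region <- gene_region("G1", "6", 29.4e6, 29.6e6)
  pqtl <- summary_stats(toy_records(2, chrom = "6",
                                    pos = c(29.5e6, 28.95e6), pval = 1e-12),
                        "p", "quantitative")
  iv <- select_cis_instruments(pqtl, region, toy_ld(diag(2)))
  expect_false("rs1" %in% iv$variants$variant_id)
  expect_true("rs2" %in% iv$variants$variant_id)
  expect_equal(iv$audit$rule[iv$audit$variant_id == "rs1"], "hla_region")
})

test_that("six-variant toy table leaves exactly one instrument", {
  # 2 above the p threshold, 1 palindromic at intermediate frequency,
  # 3 mutually correlated at r2 = 0.5 -> 1 survivor
  region <- gene_region("G1", "1", 1e6, 1.2e6)
  rec <- toy_records(6, pos = 1e6 + (0:5) * 1e4)
  rec$pval <- c(1e-6, 1e-4, 1e-12, 1e-20, 1e-15, 1e-10)
  rec$ea[3] <- "A"; rec$oa[3] <- "T"; rec$eaf[3] <- 0.45
  r <- diag(6)
  for (i in 4:6) for (j in 4:6) if (i != j) r[i, j] <- sqrt(0.5)
  iv <- select_cis_instruments(rec_stats <- summary_stats(rec, "p", "quantitative"),
                               region, toy_ld(r))
  expect_equal(iv$variants$variant_id, "rs4")   # smallest p of the LD trio
  rules <- iv$audit
  expect_setequal(rules$rule[rules$variant_id %in% c("rs1", "rs2")],
                  "above_p_threshold")
  expect_equal(rules$rule[rules$variant_id == "rs3"],
               "palindromic_intermediate_af")
  expect_setequal(rules$rule[rules$variant_id %in% c("rs5", "rs6")], "clumped")
})

test_that("MAF filter uses the minor-allele side of eaf", {
  region <- gene_region("G1", "1", 1e6, 1.2e6)
  rec <- toy_records(2, pval = 1e-12)
  rec$eaf <- c(0.995, 0.5)   # maf 0.005 fails, 0.5 passes
  iv <- select_cis_instruments(summary_stats(rec, "p", "quantitative"),
                               region, toy_ld(diag(2)))
  expect_equal(iv$variants$variant_id, "rs2")
})

test_that("greedy clumping follows p-value order with deterministic ties", {
  ld3 <- toy_ld({r <- matrix(0.9, 3, 3); diag(r) <- 1; r})
  cand <- data.frame(variant_id = c("rs1", "rs2", "rs3"),
                     pos = c(1, 2, 3) * 1e6,
                     pval = c(1e-10, 1e-20, 1e-9))
  expect_equal(clump(cand, ld3, r2 = 0.1, window_bp = 1e7), "rs2")

  # below-threshold correlation keeps both
  ld2 <- toy_ld({r <- diag(2); r[1, 2] <- r[2, 1] <- sqrt(5e-4); r})
  cand2 <- data.frame(variant_id = c("rs1", "rs2"), pos = c(1e6, 2e6),
                      pval = c(1e-10, 1e-9))
  expect_setequal(clump(cand2, ld2, r2 = 0.001, window_bp = 1e7),
                  c("rs1", "rs2"))

  # identical p-values: lexicographically smaller id becomes the index
  cand3 <- data.frame(variant_id = c("rsB", "rsA"), pos = c(1e6, 1.1e6),
                      pval = c(1e-10, 1e-10))
  ldAB <- ld_matrix({r <- matrix(0.9, 2, 2); diag(r) <- 1; r},
                    c("rsB", "rsA"))
  expect_equal(clump(cand3, ldAB, r2 = 0.1, window_bp = 1e7), "rsA")

  # far outside the physical window: correlation ignored
  cand4 <- data.frame(variant_id = c("rs1", "rs2"), pos = c(1e6, 2e7 + 1e6),
                      pval = c(1e-10, 1e-9))
  ld4 <- toy_ld({r <- matrix(0.9, 2, 2); diag(r) <- 1; r})
  expect_setequal(clump(cand4, ld4, r2 = 0.1, window_bp = 1e7),
                  c("rs1", "rs2"))

  # missing from the LD reference: retained with a warning
  cand5 <- data.frame(variant_id = c("rs1", "zz9"), pos = c(1e6, 1.1e6),
                      pval = c(1e-10, 1e-9))
  expect_warning(kept <- clump(cand5, ld2, r2 = 0.001, window_bp = 1e7),
                 "absent from LD reference")
  expect_setequal(kept, c("rs1", "zz9"))
})

test_that("palindromic and HLA filters commute", {
  # all four variants inside the cis window; one plain HLA variant, one
  # intermediate-frequency palindrome inside the HLA region, one outside,
  # and one clean survivor
  region <- gene_region("G1", "6", 29.4e6, 29.6e6)
  rec <- toy_records(4, chrom = "6",
                     pos = c(29.5e6, 29.45e6, 28.96e6, 28.95e6), pval = 1e-12)
  rec$ea[2] <- "C"; rec$oa[2] <- "G"; rec$eaf[2] <- 0.55
  rec$ea[3] <- "C"; rec$oa[3] <- "G"; rec$eaf[3] <- 0.55
  ss <- summary_stats(rec, "p", "quantitative")
  ld <- toy_ld(diag(4))
  # packaged order: palindromic filter then HLA filter
  iv1 <- select_cis_instruments(ss, region, ld)
  # reverse order: pre-remove HLA variants, then run with a vacuous HLA
  # region so only the palindromic filter acts
  params_noop_hla <- selection_params(hla_region = list(chrom = "0", start = 0,
                                                        end = 0))
  pre <- ss$records[!(ss$records$chrom == "6" & ss$records$pos >= 29e6 &
                        ss$records$pos <= 34e6), ]
  iv2 <- select_cis_instruments(summary_stats(pre, "p", "quantitative"),
                                region, ld, params_noop_hla)
  expect_setequal(iv1$variants$variant_id, iv2$variants$variant_id)
  expect_setequal(iv1$variants$variant_id, "rs4")
})

test_that("tightening thresholds never enlarges the instrument set", {
  set.seed(21)
  region <- gene_region("G1", "1", 1e6, 1.05e6)
  m <- 30
  rec <- toy_records(m, pos = 1e6 + (0:(m - 1)) * 3000,
                     beta = rnorm(m, 0.12, 0.05), se = 0.01,
                     eaf = runif(m, 0.02, 0.5))
  ss <- summary_stats(rec, "p", "quantitative")
  ld <- toy_ld(0.6^abs(outer(1:m, 1:m, "-")))
  base <- select_cis_instruments(ss, region, ld)
  base_cand <- setdiff(ss$records$variant_id,
                       base$audit$variant_id[base$audit$rule != "clumped"])
  for (p2 in list(selection_params(p_threshold = 1e-12),
                  selection_params(maf_min = 0.1),
                  selection_params(clump_r2 = 1e-4),
                  selection_params(cis_flank_bp = 1e4))) {
    tight <- select_cis_instruments(ss, region, ld, p2)
    # the pre-clump candidate pool shrinks monotonically...
    tight_cand <- setdiff(ss$records$variant_id,
                          tight$audit$variant_id[tight$audit$rule != "clumped"])
    expect_true(all(tight_cand %in% base_cand))
    # ...and the retained instrument count does not grow
    expect_lte(nrow(tight$variants), nrow(base$variants))
  }
})

test_that("clumped instrument sets are pairwise independent", {
  set.seed(22)
  m <- 40
  region <- gene_region("G1", "1", 1e6, 1.1e6)
  rec <- toy_records(m, pos = 1e6 + (0:(m - 1)) * 2500,
                     beta = rnorm(m, 0.1, 0.04), se = 0.01)
  ld <- toy_ld(0.8^abs(outer(1:m, 1:m, "-")))
  iv <- select_cis_instruments(summary_stats(rec, "p", "quantitative"),
                               region, ld, selection_params(clump_r2 = 0.01))
  ids <- iv$variants$variant_id
  if (length(ids) > 1) {
    sub <- ld$r[ids, ids]
    expect_lt(max(sub[upper.tri(sub)]^2), 0.01)
  }
})

test_that("per-SNP F statistic is the squared z-score", {
  expect_equal(per_snp_f(0.10, 0.02), 25)
  expect_equal(per_snp_f(c(0.1, -0.1), c(0.02, 0.02)), c(25, 25))
  expect_error(per_snp_f(0.1, 0))
})

test_that("F approximates the classical first-stage F in simulation", {
  # instrument explaining R2 of a quantitative trait, large n
  set.seed(23)
  n <- 50000
  r2_true <- 0.02
  f_ref <- (n - 2) * r2_true / (1 - r2_true)
  f_sim <- replicate(200, {
    g <- rbinom(n, 2, 0.3)
    y <- sqrt(r2_true) * scale(g) + rnorm(n, 0, sqrt(1 - r2_true))
    fit <- summary(lm(y ~ g))$coefficients
    per_snp_f(fit["g", 1], fit["g", 2])
  })
  expect_lt(abs(mean(f_sim) - f_ref) / f_ref, 0.10)
})

test_that("cross-cohort heterogeneity matches hand calculation", {
  h <- cross_cohort_het(c(0.1, 0.3), c(0.1, 0.1))
  expect_equal(h$Q, 2.0)
  expect_equal(h$i2, 0.5)
  expect_equal(h$p, pchisq(2, 1, lower.tail = FALSE), tolerance = 1e-12)

  bad <- cross_cohort_het(c(0.1, 0.5), c(0.1, 0.1))   # Q = 8: clear failure
  expect_false(bad$pass)

  hom <- cross_cohort_het(c(0.2, 0.2, 0.2), c(0.1, 0.1, 0.1))
  expect_equal(hom$Q, 0)
  expect_equal(hom$i2, 0)
  expect_equal(hom$p, 1)
  expect_true(hom$pass)

  single <- cross_cohort_het(0.2, 0.1)
  expect_false(single$assessable)
})
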