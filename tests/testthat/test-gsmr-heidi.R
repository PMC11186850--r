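# GSMR with outlier removal; cis-region HEIDI test; weighted chi-square
# tail probabilities.

test_that("weighted chi-square tail matches closed forms", {
  # equal weights collapse to an ordinary chi-square
  expect_equal(quadform_pval(3.5, c(1, 1)),
               pchisq(3.5, 2, lower.tail = FALSE), tolerance = 1e-6)
  expect_equal(quadform_pval(2.1, 1),
               pchisq(2.1, 1, lower.tail = FALSE), tolerance = 1e-10)
  # Monte-Carlo check with unequal weights
  set.seed(41)
  lam <- c(2, 1, 0.5, 0.25)
  draws <- colSums(lam * matrix(rchisq(4 * 2e5, 1), 4))
  q <- 6
  expect_lt(abs(quadform_pval(q, lam) - mean(draws > q)), 0.005)
})

test_that("GSMR with identity LD and negligible exposure noise matches IVW", {
  set.seed(42)
  k <- 8
  df <- data.frame(variant_id = paste0("v", 1:k),
                   beta_x = rnorm(k, 0.3, 0.05), se_x = 1e-8,
                   beta_y = rnorm(k, 0.03, 0.01), se_y = 0.05)
  p <- harmonized_pair(df)
  ld <- toy_ld(diag(k), ids = df$variant_id)
  g <- gsmr_fit(p, ld, outlier_alpha = 1e-12, ridge = 0)
  f <- mr_ivw(p, method = "fixed")
  expect_equal(g$beta, f$beta, tolerance = 1e-6)
  expect_equal(g$se, f$se, tolerance = 1e-6)
  expect_equal(nrow(g$removed_outliers), 0)
})

test_that("GSMR removes a planted outlier and only it", {
  hits <- sapply(1:200, function(i) {
    cfg <- sim_config(n_snps = 10, ld_model = list(model = "identity"),
                      n_x = 35559, n_case = 20000, n_control = 20000,
                      causal_x = data.frame(index = 1:10, beta = 0.12),
                      causal_beta = 0.1,
                      causal_y = data.frame(index = 10, beta = 0.1),
                      seed = 4000 + i)
    s <- simulate_summary_stats(cfg)
    g <- gsmr_fit(harmonize_pair(s$exposure, s$outcome), s$ld,
                  outlier_alpha = 0.01)
    identical(g$removed_outliers$variant_id, "rs10")
  })
  expect_gte(mean(hits), 0.90)
})

test_that("GSMR recovers the causal effect under AR(1) LD", {
  est <- sapply(1:200, function(i) {
    cfg <- sim_config(n_snps = 10, ld_model = list(model = "ar1", rho = 0.3),
                      n_x = 35559, n_case = 20000, n_control = 20000,
                      causal_x = data.frame(index = 1:10, beta = 0.12),
                      causal_beta = 0.1, seed = 11000 + i)
    s <- simulate_summary_stats(cfg)
    gsmr_fit(harmonize_pair(s$exposure, s$outcome), s$ld)$beta
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.1), 3 * mc_se)
})

test_that("the outlier loop terminates and never empties the set", {
  set.seed(43)
  k <- 6
  df <- data.frame(variant_id = paste0("v", 1:k),
                   beta_x = rep(0.3, k), se_x = 0.01,
                   beta_y = seq(-0.5, 0.5, length.out = k), se_y = 0.001)
  ld <- toy_ld(diag(k), ids = df$variant_id)
  g <- gsmr_fit(harmonized_pair(df), ld, outlier_alpha = 0.5)
  expect_gte(g$n_snps_used, 1)
  expect_lte(nrow(g$removed_outliers), k - 1)
  expect_length(intersect(g$used_ids, g$removed_outliers$variant_id), 0)
})

test_that("HEIDI is not assessable below the minimum SNP count", {
  set.seed(44)
  m <- 2
  df <- data.frame(variant_id = c("a", "b"), ea = "A", oa = "G",
                   beta_x = c(0.5, 0.4), se_x = 0.01,
                   beta_y = c(0.05, 0.04), se_y = 0.02,
                   pval_x = c(1e-20, 1e-15))
  ld <- ld_matrix({r <- diag(2); r[1, 2] <- r[2, 1] <- 0.5; r}, c("a", "b"),
                  alleles = data.frame(ea = c("A", "A"), oa = c("G", "G")))
  h <- heidi_test(harmonized_pair(df), ld = ld)
  expect_false(h$assessable)
  expect_match(h$reason, "eligible")
})

test_that("HEIDI keeps false rejection near nominal under a shared variant", {
  rej <- sapply(1:200, function(i) {
    s <- simulate_summary_stats(scenario_preset("H4", seed = 3000 + i))
    h <- heidi_test(harmonize_pair(s$exposure, s$outcome), ld = s$ld)
    if (!h$assessable) NA else h$pval < 0.05
  })
  rate <- mean(rej, na.rm = TRUE)
  expect_gte(rate, 0.01)
  expect_lte(rate, 0.10)
})

test_that("HEIDI rejects two distinct causal variants in strong LD", {
  rej <- sapply(1:100, function(i) {
    cfg <- sim_config(n_snps = 60, ld_model = list(model = "ar1", rho = 0.6),
                      n_x = 35559, n_case = 79495, n_control = 1259808,
                      causal_x = data.frame(index = 30, beta = 0.15),
                      causal_y = data.frame(index = 31, beta = 0.025),
                      seed = 5000 + i)
    s <- simulate_summary_stats(cfg)
    h <- heidi_test(harmonize_pair(s$exposure, s$outcome), ld = s$ld)
    if (!h$assessable) NA else h$pval < 0.05
  })
  expect_gte(mean(rej, na.rm = TRUE), 0.8)
})

test_that("HEIDI p is invariant to SNP relabeling and allele recoding", {
  s <- simulate_summary_stats(scenario_preset("H4", seed = 909))
  pair <- harmonize_pair(s$exposure, s$outcome)
  h1 <- heidi_test(pair, ld = s$ld)

  # shuffle non-top rows
  set.seed(45)
  ord <- order(pair$pval_x)
  idx <- c(ord[1], sample(ord[-1]))
  pair2 <- harmonized_pair(as.data.frame(pair)[idx, ])
  h2 <- heidi_test(pair2, ld = s$ld)
  expect_equal(h2$pval, h1$pval, tolerance = 1e-9)

  # recode some variants to the opposite allele orientation
  flipped <- s$exposure
  pick <- seq(1, 60, by = 3)
  flipped$records$beta[pick] <- -flipped$records$beta[pick]
  flipped$records$eaf[pick] <- 1 - flipped$records$eaf[pick]
  flipped$records$ea[pick] <- "G"; flipped$records$oa[pick] <- "A"
  h3 <- heidi_test(harmonize_pair(flipped, s$outcome), ld = s$ld)
  expect_equal(h3$pval, h1$pval, tolerance = 1e-9)
  expect_equal(h3$n_snps_used, h1$n_snps_used)
})

test_that("HEIDI caps the SNP count at the configured maximum", {
  cfg <- sim_config(n_snps = 80, ld_model = list(model = "ar1", rho = 0.8),
                    n_x = 100000, n_case = 79495, n_control = 1259808,
                    causal_x = data.frame(index = 40, beta = 0.2),
                    causal_beta = 1, seed = 321)
  s <- simulate_summary_stats(cfg)
  h <- heidi_test(harmonize_pair(s$exposure, s$outcome), ld = s$ld)
  if (h$assessable) {
    expect_gte(h$n_snps_used, 3)
    expect_lte(h$n_snps_used, 20)
  } else {
    succeed()
  }
})
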