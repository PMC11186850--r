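# The summary-data MR estimator family and its diagnostics.

test_that("Wald ratio arithmetic and sign symmetry", {
  w <- wald_ratio(0.5, 0.05, 0.02, 0.005)
  expect_equal(w$beta, 0.04)
  expect_equal(w$se, 0.01)
  expect_equal(w$odds_ratio, exp(0.04), tolerance = 1e-12)

  w2 <- wald_ratio(-0.5, 0.05, 0.02, 0.005)
  expect_equal(w2$beta, -0.04)
  expect_equal(w2$se, 0.01)   # SE stays positive
  expect_error(wald_ratio(0, 0.05, 0.02, 0.005), "b_x = 0")
})

test_that("second-order Wald SE matches Monte-Carlo ratio SE", {
  set.seed(31)
  b_x <- 0.5; se_x <- 0.04; b_y <- 0.05; se_y <- 0.01   # |b_x|/se_x > 10
  mc <- sd(rnorm(1e6, b_y, se_y) / rnorm(1e6, b_x, se_x))
  w <- wald_ratio(b_x, se_x, b_y, se_y, second_order = TRUE)
  expect_lt(abs(w$se - mc) / mc, 0.02)
})

test_that("IVW reproduces the weighted-regression hand calculation", {
  p <- toy_pair(c(1, 1), c(0.01, 0.01), c(0.1, 0.3), c(0.1, 0.1))
  r <- mr_ivw(p)
  expect_equal(r$beta, 0.2)
  expect_equal(r$Q, 2.0)
  expect_equal(r$se, 0.1)    # fixed 1/sqrt(200) inflated by sqrt(Q/(k-1))
  expect_equal(mr_ivw(p, method = "fixed")$se, 1 / sqrt(200))

  # homogeneous ratios: estimate is the common ratio, no inflation
  ph <- toy_pair(c(0.5, 1, 2), 0.01, 0.3 * c(0.5, 1, 2), 0.05)
  rh <- mr_ivw(ph)
  expect_equal(rh$beta, 0.3)
  expect_equal(rh$Q, 0)
  expect_equal(rh$se, mr_ivw(ph, method = "fixed")$se)
})

test_that("with one instrument the IVW path equals the Wald ratio exactly", {
  p <- toy_pair(0.4, 0.02, 0.03, 0.008)
  r <- mr_ivw(p)
  w <- wald_ratio(0.4, 0.02, 0.03, 0.008)
  expect_equal(r$beta, w$beta)
  expect_equal(r$se, w$se)
  expect_match(r$notes, "single instrument")
})

test_that("Cochran's Q is non-negative and zero iff ratios are equal", {
  set.seed(32)
  for (i in 1:20) {
    k <- sample(2:10, 1)
    p <- toy_pair(runif(k, 0.1, 1), 0.01, rnorm(k, 0, 0.1), runif(k, 0.02, 0.2))
    expect_gte(mr_ivw(p)$Q, 0)
  }
  peq <- toy_pair(c(1, 1, 1), 0.01, c(0.2, 0.2, 0.2), 0.05)
  expect_equal(mr_ivw(peq)$Q, 0)
})

test_that("estimators are equivariant to allele recoding and exposure scaling", {
  set.seed(33)
  k <- 8
  p <- toy_pair(rnorm(k, 0.3, 0.05), 0.02, rnorm(k, 0.03, 0.02), 0.05)
  flip <- rep(c(1, -1), length.out = k)
  p_flip <- toy_pair(p$beta_x * flip, p$se_x, p$beta_y * flip, p$se_y)
  expect_equal(mr_ivw(p)$beta, mr_ivw(p_flip)$beta, tolerance = 1e-10)
  expect_equal(mr_egger(p)$beta, mr_egger(p_flip)$beta, tolerance = 1e-10)
  expect_equal(weighted_median(p, seed = 1)$beta,
               weighted_median(p_flip, seed = 1)$beta, tolerance = 1e-10)

  cc <- 2.5   # exposure unit change scales the estimate by 1/c
  p_sc <- toy_pair(p$beta_x * cc, p$se_x * cc, p$beta_y, p$se_y)
  expect_equal(mr_ivw(p_sc)$beta, mr_ivw(p)$beta / cc, tolerance = 1e-10)
})

test_that("GLS IVW reduces to fixed-effect IVW under identity LD", {
  set.seed(34)
  k <- 6
  p <- toy_pair(rnorm(k, 0.3, 0.05), 0.02, rnorm(k, 0.03, 0.02), 0.05)
  ld <- toy_ld(diag(k), ids = p$variant_id)
  g <- ivw_correlated(p, ld, ridge = 0)
  f <- mr_ivw(p, method = "fixed")
  expect_equal(g$beta, f$beta, tolerance = 1e-10)
  expect_equal(g$se, f$se, tolerance = 1e-10)
})

test_that("duplicating a SNP at r = 1 collapses to the single-SNP result", {
  p1 <- toy_pair(0.5, 0.02, 0.05, 0.04)
  p2 <- toy_pair(c(0.5, 0.5), 0.02, c(0.05, 0.05), 0.04)
  p2$variant_id <- c("a", "b")
  ld <- ld_matrix(matrix(c(1, 1, 1, 1), 2), c("a", "b"))
  g <- ivw_correlated(harmonized_pair(as.data.frame(p2)), ld)
  w <- wald_ratio(0.5, 0.02, 0.05, 0.04)
  expect_equal(g$beta, w$beta, tolerance = 1e-6)
  expect_equal(g$se, w$se, tolerance = 1e-3)   # up to the ridge
})

test_that("GLS IVW attains nominal coverage under AR(1) LD", {
  covered <- sapply(1:200, function(i) {
    cfg <- sim_config(n_snps = 10, ld_model = list(model = "ar1", rho = 0.5),
                      n_x = 35559, n_case = 20000, n_control = 20000,
                      causal_x = data.frame(index = 1:10, beta = 0.12),
                      causal_beta = 0.1, seed = 7000 + i)
    s <- simulate_summary_stats(cfg)
    ci <- ivw_correlated(harmonize_pair(s$exposure, s$outcome), s$ld)
    ci$ci_low <= 0.1 && ci$ci_high >= 0.1
  })
  expect_gte(mean(covered), 0.92)
  expect_lte(mean(covered), 0.98)
})

test_that("Egger recovers an exact affine relation", {
  bx <- c(0.2, 0.4, 0.6, 0.8)
  p <- toy_pair(bx, 0.01, 0.1 + 0.2 * bx, 0.05)
  e <- mr_egger(p)
  expect_equal(e$beta, 0.2, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0.1, tolerance = 1e-10)
  expect_equal(e$Q, 0, tolerance = 1e-12)
  expect_error(mr_egger(toy_pair(c(1, 1), 0.01, c(0.1, 0.2), 0.05)), ">= 3")
})

test_that("Egger slope equals IVW slope when the intercept is exactly zero", {
  bx <- c(0.2, 0.4, 0.6)
  p <- toy_pair(bx, 0.01, 0.3 * bx, 0.05)   # line through the origin
  expect_equal(mr_egger(p)$beta, mr_ivw(p)$beta, tolerance = 1e-10)
  expect_equal(mr_egger(p)$egger_intercept, 0, tolerance = 1e-12)
})

test_that("Egger intercept recovers planted directional pleiotropy", {
  set.seed(35)
  delta <- 0.05
  k <- 20
  est <- replicate(300, {
    bx <- abs(rnorm(k, 0.15, 0.03))
    by <- delta + 0.1 * bx + rnorm(k, 0, 0.02)
    mr_egger(toy_pair(bx, 0.001, by, 0.02))$egger_intercept
  })
  mc_se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - delta), 3 * mc_se)
})

test_that("weighted median interpolates the weighted ratio order", {
  p <- toy_pair(c(1, 1, 1), 0.01, c(0.1, 0.2, 0.9), 0.05)
  r <- weighted_median(p, n_boot = 200, seed = 3)
  expect_equal(r$beta, 0.2)
  # seeded determinism of the bootstrap SE
  r2 <- weighted_median(p, n_boot = 200, seed = 3)
  expect_identical(r$se, r2$se)
  expect_error(weighted_median(p, n_boot = 10), "seed")
})

test_that("weighted median resists 40% invalid instruments better than IVW", {
  res <- sapply(1:150, function(i) {
    cfg <- sim_config(n_snps = 60, ld_model = list(model = "ar1", rho = 0.5),
                      n_x = 35559, n_case = 50000, n_control = 50000,
                      causal_x = data.frame(index = seq(3, 57, 6), beta = 0.12),
                      causal_beta = 0.1,
                      causal_y = data.frame(index = seq(3, 57, 6)[1:4],
                                            beta = 0.15),
                      seed = 40000 + i)
    s <- simulate_summary_stats(cfg)
    pr <- harmonize_pair(s$exposure, s$outcome)
    pr <- pr[pr$pval_x < 5e-8, ]
    pr <- harmonized_pair(as.data.frame(pr))
    c(ivw = mr_ivw(pr)$beta,
      wm = weighted_median(pr, n_boot = 1, seed = i)$beta)
  })
  bias_ivw <- abs(mean(res["ivw", ]) - 0.1)
  bias_wm <- abs(mean(res["wm", ]) - 0.1)
  expect_lt(bias_wm, 0.25 * bias_ivw)
})

test_that("weighted mode finds the majority cluster", {
  p <- toy_pair(rep(1, 9), 0.01, c(rep(0.1, 6), rep(0.5, 3)), 0.05)
  r <- weighted_mode(p, n_boot = 100, seed = 5)
  expect_lt(abs(r$beta - 0.1), 0.05)
  # halving the bandwidth stays on the majority cluster
  r2 <- weighted_mode(p, bandwidth_factor = 0.5, n_boot = 100, seed = 5)
  expect_lt(abs(r2$beta - 0.1), 0.05)
  # degenerate case: all ratios identical
  pd <- toy_pair(c(1, 2, 4), 0.01, 0.3 * c(1, 2, 4), 0.05)
  expect_equal(weighted_mode(pd, n_boot = 50, seed = 6)$beta, 0.3)
})

test_that("Steiger test evaluates direction from explained variance", {
  # z_x = 30 vs z_y = 2 at equal n: unambiguous exposure -> outcome
  p <- toy_pair(30 * 0.01, 0.01, 2 * 0.01, 0.01)
  st <- steiger_test(p, n_x = 10000, n_y = 10000)
  expect_equal(st$direction, "exposure->outcome")
  expect_lt(st$pval, 1e-10)

  # symmetric case: Z = 0, p = 1
  p2 <- toy_pair(0.05, 0.01, 0.05, 0.01)
  st2 <- steiger_test(p2, n_x = 5000, n_y = 5000)
  expect_equal(st2$Z, 0)
  expect_equal(st2$pval, 1)

  expect_false(steiger_test(p, n_x = 3, n_y = 1000)$assessable)
})

test_that("Steiger infers the correct direction in forward simulations", {
  ok <- sapply(1:200, function(i) {
    cfg <- sim_config(n_snps = 20, ld_model = list(model = "identity"),
                      n_x = 50000, n_case = 25000, n_control = 25000,
                      causal_x = data.frame(index = 1:10, beta = 0.1),
                      causal_beta = 0.15, seed = 6000 + i)
    s <- simulate_summary_stats(cfg)
    pr <- harmonize_pair(s$exposure, s$outcome)
    pr <- harmonized_pair(as.data.frame(pr[pr$pval_x < 5e-8, ]))
    steiger_test(pr, n_x = 50000, n_y = 50000)$direction == "exposure->outcome"
  })
  expect_gte(mean(ok), 0.99)
})
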