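# Summary-data MR estimators: Wald ratio, random-effects IVW, LD-aware
# (GLS) IVW, MR-Egger, weighted median, weighted mode, and the Steiger
# directionality test. All operate on a harmonized_pair whose betas share
# one effect allele; binary-outcome betas are log-odds throughout.

#' Construct an MR result
#'
#' @param method Estimator name.
#' @param beta,se Causal estimate (log-odds for binary outcomes) and SE.
#' @param n_snps Number of instruments used.
#' @param pval P-value; computed from `beta/se` (normal) when NULL.
#' @param Q,Q_pval Cochran heterogeneity statistic and p-value.
#' @param egger_intercept,intercept_se,intercept_pval Egger intercept terms.
#' @param outcome_type `"binary"` adds `odds_ratio = exp(beta)` and OR CI.
#' @param notes Free-text caveats.
#' @return A list of class `mr_result` with 95% CI and, for binary
#'   outcomes, the odds ratio.
#' @export
mr_result <- function(method, beta, se, n_snps, pval = NULL,
                      Q = NA_real_, Q_pval = NA_real_,
                      egger_intercept = NA_real_, intercept_se = NA_real_,
                      intercept_pval = NA_real_,
                      outcome_type = "binary", notes = "") {
  z <- beta / se
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(z))
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  res <- list(method = method, n_snps = n_snps, beta = beta, se = se,
              ci_low = ci[1], ci_high = ci[2], pval = pval,
              odds_ratio = if (identical(outcome_type, "binary")) exp(beta) else NA_real_,
              or_ci_low = if (identical(outcome_type, "binary")) exp(ci[1]) else NA_real_,
              or_ci_high = if (identical(outcome_type, "binary")) exp(ci[2]) else NA_real_,
              Q = Q, Q_pval = Q_pval,
              egger_intercept = egger_intercept, intercept_se = intercept_se,
              intercept_pval = intercept_pval,
              outcome_type = outcome_type, notes = notes)
  class(res) <- "mr_result"
  res
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("%s (k=%d): beta %.4g (95%% CI %.4g, %.4g), p = %.3g\n",
              x$method, x$n_snps, x$beta, x$ci_low, x$ci_high, x$pval))
  if (identical(x$outcome_type, "binary")) {
    cat(sprintf("  OR %.4g (%.4g, %.4g)\n", x$odds_ratio, x$or_ci_low, x$or_ci_high))
  }
  if (is.finite(x$Q)) cat(sprintf("  Q = %.4g (p = %.3g)\n", x$Q, x$Q_pval))
  if (is.finite(x$egger_intercept)) {
    cat(sprintf("  intercept %.4g (p = %.3g)\n", x$egger_intercept, x$intercept_pval))
  }
  if (nzchar(x$notes)) cat("  note:", x$notes, "\n")
  invisible(x)
}

#' @export
as.data.frame.mr_result <- function(x, ...) {
  data.frame(method = x$method, n_snps = x$n_snps, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, pval = x$pval,
             odds_ratio = x$odds_ratio, Q = x$Q, Q_pval = x$Q_pval,
             egger_intercept = x$egger_intercept,
             intercept_pval = x$intercept_pval, notes = x$notes,
             stringsAsFactors = FALSE)
}

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = b_y / b_x`. The default standard error is the first-order delta
#' method `se_y / |b_x|`, ignoring exposure-side noise (the weighting
#' convention of the IVW estimator here); `second_order = TRUE` adds the
#' exposure-variance term `sqrt(se_y^2/b_x^2 + b_y^2 se_x^2 / b_x^4)`.
#'
#' @param b_x,se_x Instrument-exposure effect and SE.
#' @param b_y,se_y Instrument-outcome effect and SE.
#' @param second_order Use the second-order delta SE.
#' @param outcome_type Passed to [mr_result()].
#' @return An `mr_result`.
#' @export
wald_ratio <- function(b_x, se_x, b_y, se_y, second_order = FALSE,
                       outcome_type = "binary") {
  if (b_x == 0) stop("wald_ratio: undefined ratio, b_x = 0", call. = FALSE)
  beta <- b_y / b_x
  se <- if (second_order) {
    sqrt(se_y^2 / b_x^2 + b_y^2 * se_x^2 / b_x^4)
  } else {
    se_y / abs(b_x)
  }
  mr_result("wald_ratio", beta, se, n_snps = 1L, outcome_type = outcome_type)
}

#' Inverse-variance-weighted MR
#'
#' Combines per-instrument Wald ratios weighted by the inverse variance of
#' the instrument-outcome effect: `beta = sum(w b_x b_y) / sum(w b_x^2)`
#' with `w = 1/se_y^2` (a zero-intercept weighted regression of `b_y` on
#' `b_x`). Fixed-effect SE is `(sum w b_x^2)^(-1/2)`; the random-effects SE
#' multiplies it by `max(1, sqrt(Q/(k-1)))` where Q is Cochran's Q about
#' the IVW slope (inflation floored at 1 — never below the fixed SE).
#' With a single instrument, falls through to [wald_ratio()] with a note.
#'
#' @param pair A [harmonized_pair()] (or data.frame with `beta_x`, `se_x`,
#'   `beta_y`, `se_y`).
#' @param method `"random"` (default) or `"fixed"` effects.
#' @return An `mr_result` carrying Q and its p-value.
#' @export
mr_ivw <- function(pair, method = c("random", "fixed")) {
  method <- match.arg(method)
  pair <- as_harmonized_pair(pair)
  otype <- attr(pair, "outcome_type") %||% "binary"
  k <- nrow(pair)
  if (k == 0) stop("mr_ivw: no instruments", call. = FALSE)
  if (k == 1) {
    res <- wald_ratio(pair$beta_x, pair$se_x, pair$beta_y, pair$se_y,
                      outcome_type = otype)
    res$notes <- "single instrument: Wald ratio used in place of IVW"
    return(res)
  }
  w <- 1 / pair$se_y^2
  beta <- sum(w * pair$beta_x * pair$beta_y) / sum(w * pair$beta_x^2)
  se_fixed <- 1 / sqrt(sum(w * pair$beta_x^2))
  Q <- sum(w * (pair$beta_y - beta * pair$beta_x)^2)
  Q_pval <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  se <- if (method == "random") se_fixed * max(1, sqrt(Q / (k - 1))) else se_fixed
  mr_result(paste0("ivw_", method), beta, se, n_snps = k,
            Q = Q, Q_pval = Q_pval, outcome_type = otype)
}

#' IVW allowing correlated (LD-linked) instruments
#'
#' Generalized least squares of `b_y` on `b_x` with outcome-effect
#' covariance `Omega_ij = se_yi se_yj r_ij` taken from the LD reference
#' (ridge-regularized before inversion). Reduces to fixed-effect
#' [mr_ivw()] when the LD matrix is the identity. Used as the confirmation
#' analysis when instruments are selected at a relaxed clumping threshold.
#'
#' @param pair A [harmonized_pair()]; all variants must be in `ld`.
#' @param ld An `ld_matrix`.
#' @param ridge Ridge constant for [ld_regularize()].
#' @return An `mr_result`.
#' @export
ivw_correlated <- function(pair, ld, ridge = 1e-3) {
  pair <- as_harmonized_pair(pair)
  otype <- attr(pair, "outcome_type") %||% "binary"
  k <- nrow(pair)
  if (k < 2) stop("ivw_correlated: need >= 2 instruments", call. = FALSE)
  r <- ld_regularize(ld_subset(ld, pair$variant_id), ridge)$r
  omega <- outer(pair$se_y, pair$se_y) * r
  oi <- tryCatch(solve(omega), error = function(e) {
    stop("ivw_correlated: outcome covariance numerically singular after ",
         "regularization", call. = FALSE)
  })
  x <- pair$beta_x
  denom <- drop(t(x) %*% oi %*% x)
  beta <- drop(t(x) %*% oi %*% pair$beta_y) / denom
  se <- 1 / sqrt(denom)
  resid <- pair$beta_y - beta * x
  Q <- drop(t(resid) %*% oi %*% resid)
  Q_pval <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  mr_result("ivw_correlated", beta, se, n_snps = k, Q = Q, Q_pval = Q_pval,
            outcome_type = otype)
}

#' MR-Egger regression
#'
#' Weighted least squares of `b_y` on `b_x` with an intercept, weights
#' `1/se_y^2`, after orienting all exposure effects non-negative (flipping
#' the paired outcome signs). The slope is the causal estimate; a nonzero
#' intercept indicates directional horizontal pleiotropy. Standard errors
#' are inflated by `max(1, sqrt(Q_egger/(k-2)))`; p-values use a t
#' distribution on k-2 df.
#'
#' @param pair A [harmonized_pair()] with at least 3 instruments.
#' @return An `mr_result` with intercept fields populated.
#' @export
mr_egger <- function(pair) {
  pair <- as_harmonized_pair(pair)
  otype <- attr(pair, "outcome_type") %||% "binary"
  k <- nrow(pair)
  if (k < 3) stop("mr_egger: need >= 3 instruments", call. = FALSE)
  flip <- sign(pair$beta_x)
  flip[flip == 0] <- 1
  bx <- pair$beta_x * flip
  by <- pair$beta_y * flip
  w <- 1 / pair$se_y^2
  X <- cbind(1, bx)
  XtWX <- crossprod(X, w * X)
  cov_un <- solve(XtWX)
  coef <- unname(drop(cov_un %*% crossprod(X, w * by)))
  resid <- by - drop(X %*% coef)
  Q <- sum(w * resid^2)
  Q_pval <- stats::pchisq(Q, df = k - 2, lower.tail = FALSE)
  infl <- max(1, sqrt(Q / (k - 2)))
  ses <- unname(sqrt(diag(cov_un))) * infl
  pvals <- 2 * stats::pt(-abs(coef / ses), df = k - 2)
  mr_result("mr_egger", beta = coef[2], se = ses[2], n_snps = k,
            pval = pvals[2], Q = Q, Q_pval = Q_pval,
            egger_intercept = coef[1], intercept_se = ses[1],
            intercept_pval = pvals[1], outcome_type = otype)
}

# draw parametric-bootstrap replicates of the per-SNP effects and return
# the sd of a per-replicate statistic; RNG state is restored afterwards
bootstrap_se <- function(pair, statistic, n_boot, seed) {
  with_seed(seed, {
    est <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(nrow(pair), pair$beta_x, pair$se_x)
      by <- stats::rnorm(nrow(pair), pair$beta_y, pair$se_y)
      statistic(bx, by)
    }, numeric(1))
    stats::sd(est)
  })
}

with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

wmedian_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(b)] <= 0.5) return(b[length(b)])
  stats::approx(cum, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted median MR
#'
#' The median of per-SNP Wald ratios under inverse-variance weights
#' (`b_x^2/se_y^2`, normalized): consistent when at least half the weight
#' comes from valid instruments. The point estimate interpolates linearly
#' between the ratios bracketing cumulative weight 0.5; the SE is a seeded
#' parametric bootstrap resampling `b_x` and `b_y` from their sampling
#' distributions.
#'
#' @param pair A [harmonized_pair()] with at least 3 instruments.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Mandatory RNG seed for the bootstrap.
#' @return An `mr_result`.
#' @export
weighted_median <- function(pair, n_boot = 1000, seed) {
  pair <- as_harmonized_pair(pair)
  otype <- attr(pair, "outcome_type") %||% "binary"
  if (nrow(pair) < 3) stop("weighted_median: need >= 3 instruments", call. = FALSE)
  if (missing(seed)) stop("weighted_median: seed is required", call. = FALSE)
  est <- wmedian_point(pair$beta_y / pair$beta_x, pair$beta_x^2 / pair$se_y^2)
  se <- bootstrap_se(pair, function(bx, by) {
    wmedian_point(by / bx, bx^2 / pair$se_y^2)
  }, n_boot, seed)
  mr_result("weighted_median", est, se, n_snps = nrow(pair), outcome_type = otype)
}

wmode_point <- function(ratios, weights, bandwidth_factor) {
  if (max(ratios) - min(ratios) < .Machine$double.eps^0.5) return(ratios[1])
  w <- weights / sum(weights)
  s <- min(stats::sd(ratios), stats::IQR(ratios) / 1.349)
  if (s <= 0) s <- stats::sd(ratios)
  h <- bandwidth_factor * 1.06 * s * length(ratios)^(-1 / 5)
  d <- stats::density(ratios, weights = w, bw = h, n = 1024)
  d$x[which.max(d$y)]
}

#' Weighted mode MR
#'
#' Kernel-smoothed weighted density over per-SNP Wald ratios (normal
#' kernel, bandwidth = `bandwidth_factor` times a weighted Silverman-type
#' rule); the estimate is the density argmax — consistent when the largest
#' group of instruments sharing a ratio is valid. SE by seeded parametric
#' bootstrap.
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor Multiplier on the reference bandwidth
#'   (default 1).
#' @return An `mr_result`.
#' @export
weighted_mode <- function(pair, bandwidth_factor = 1, n_boot = 1000, seed) {
  pair <- as_harmonized_pair(pair)
  otype <- attr(pair, "outcome_type") %||% "binary"
  if (nrow(pair) < 3) stop("weighted_mode: need >= 3 instruments", call. = FALSE)
  if (missing(seed)) stop("weighted_mode: seed is required", call. = FALSE)
  wts <- pair$beta_x^2 / pair$se_y^2
  est <- wmode_point(pair$beta_y / pair$beta_x, wts, bandwidth_factor)
  se <- bootstrap_se(pair, function(bx, by) {
    wmode_point(by / bx, wts, bandwidth_factor)
  }, n_boot, seed)
  mr_result("weighted_mode", est, se, n_snps = nrow(pair), outcome_type = otype)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome. Per SNP, `r2 = z^2 / (z^2 + n - 2)` (the z-score approximation;
#' for binary outcomes this uses the effective sample size and is an
#' observed-scale approximation). Trait-level `r = sqrt(min(1, sum r2))`
#' over independent instruments. The inferred direction is
#' exposure -> outcome iff `r_x > r_y`; the p-value compares
#' Fisher-transformed correlations,
#' `Z = (atanh(r_x) - atanh(r_y)) / sqrt(1/(n_x-3) + 1/(n_y-3))`.
#'
#' @param pair A [harmonized_pair()].
#' @param n_x,n_y Sample sizes (effective n for binary traits); taken from
#'   the pair's attributes when omitted.
#' @return List with `direction`, `pval`, `r_x`, `r_y`, `Z`, `assessable`,
#'   and `per_snp` (data.frame of single-SNP directions and p-values).
#' @export
steiger_test <- function(pair, n_x = NULL, n_y = NULL) {
  pair <- as_harmonized_pair(pair)
  n_x <- n_x %||% attr(pair, "n_x")
  n_y <- n_y %||% attr(pair, "n_y")
  if (is.null(n_x) || is.null(n_y) || is.na(n_x) || is.na(n_y) ||
      n_x <= 3 || n_y <= 3) {
    return(list(direction = NA_character_, pval = NA_real_, r_x = NA_real_,
                r_y = NA_real_, Z = NA_real_, assessable = FALSE,
                per_snp = NULL))
  }
  r2_of <- function(beta, se, n) {
    z2 <- (beta / se)^2
    z2 / (z2 + n - 2)
  }
  r2x <- r2_of(pair$beta_x, pair$se_x, n_x)
  r2y <- r2_of(pair$beta_y, pair$se_y, n_y)
  fisher_z <- function(rx, ry) {
    (atanh(pmin(rx, 1 - 1e-12)) - atanh(pmin(ry, 1 - 1e-12))) /
      sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  }
  r_x <- sqrt(min(1, sum(r2x)))
  r_y <- sqrt(min(1, sum(r2y)))
  Z <- fisher_z(r_x, r_y)
  zs <- fisher_z(sqrt(r2x), sqrt(r2y))
  per_snp <- data.frame(
    variant_id = pair$variant_id,
    r2_exposure = r2x, r2_outcome = r2y,
    direction = ifelse(r2x > r2y, "exposure->outcome", "outcome->exposure"),
    pval = 2 * stats::pnorm(-abs(zs)))
  list(direction = if (r_x > r_y) "exposure->outcome" else "outcome->exposure",
       pval = 2 * stats::pnorm(-abs(Z)), r_x = r_x, r_y = r_y, Z = Z,
       assessable = TRUE, per_snp = per_snp)
}

#' Primary MR estimate for a pair
#'
#' The discovery/validation convention: Wald ratio with a single
#' instrument, random-effects IVW with several.
#'
#' @param pair A [harmonized_pair()].
#' @return An `mr_result`.
#' @export
mr_primary <- function(pair) {
  pair <- as_harmonized_pair(pair)
  if (nrow(pair) == 1) {
    wald_ratio(pair$beta_x, pair$se_x, pair$beta_y, pair$se_y,
               outcome_type = attr(pair, "outcome_type") %||% "binary")
  } else {
    mr_ivw(pair, method = "random")
  }
}
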