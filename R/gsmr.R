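# GSMR: GLS combination of per-SNP Wald ratios under LD, with iterative
# outlier removal. Distinguished from plain IVW by (a) the exposure-side
# sampling variance in each ratio's variance and (b) the LD covariance.

#' GSMR causal estimate with outlier removal
#'
#' Per SNP, `b_xy_j = b_yj/b_xj` with delta-method variance
#' `v_j = (se_yj^2 + b_xy_j^2 se_xj^2) / b_xj^2`. The estimate is the GLS
#' combination `beta = (1' V^-1 b_xy) / (1' V^-1 1)` with
#' `V_ij = r_ij sqrt(v_i v_j)` built from the (ridge-regularized) LD
#' matrix. Outlier loop: each SNP's deviation `d_j = b_xy_j - beta` has
#' variance `v_j - var(beta)` (since `cov(b_xy_j, beta) = var(beta)` under
#' GLS); while the worst SNP's two-sided deviation p-value is below
#' `outlier_alpha` it is removed and the model refit. Intended for
#' instruments clumped at a relaxed threshold (r2 < 0.1).
#'
#' @param pair A [harmonized_pair()] with >= 2 variants.
#' @param ld An `ld_matrix` covering the pair.
#' @param outlier_alpha Removal threshold (default 0.01).
#' @param ridge Ridge constant for LD regularization.
#' @return List of class `gsmr_result`: `beta`, `se`, `pval`,
#'   `n_snps_used`, `removed_outliers` (data.frame id/pval), `used_ids`.
#' @export
gsmr_fit <- function(pair, ld, outlier_alpha = 0.01, ridge = 1e-3) {
  pair <- as_harmonized_pair(pair)
  if (nrow(pair) < 2) stop("gsmr_fit: need >= 2 instruments", call. = FALSE)
  if (any(pair$beta_x == 0)) stop("gsmr_fit: zero exposure effect", call. = FALSE)

  b_xy <- pair$beta_y / pair$beta_x
  v <- (pair$se_y^2 + b_xy^2 * pair$se_x^2) / pair$beta_x^2
  r_all <- ld_aligned_pair_r(ld, pair, ridge)

  active <- seq_len(nrow(pair))
  removed <- data.frame(variant_id = character(0), pval = numeric(0))
  repeat {
    fit <- gsmr_gls(b_xy[active], v[active], r_all[active, active, drop = FALSE])
    if (length(active) <= 1) break
    var_d <- pmax(v[active] - fit$var_beta, .Machine$double.eps)
    z_d <- (b_xy[active] - fit$beta) / sqrt(var_d)
    p_d <- 2 * stats::pnorm(-abs(z_d))
    worst <- which.min(p_d)
    if (p_d[worst] >= outlier_alpha) break
    if (length(active) == 1) break
    removed <- rbind(removed, data.frame(variant_id = pair$variant_id[active[worst]],
                                         pval = p_d[worst]))
    active <- active[-worst]
    if (length(active) == 0) {
      stop("gsmr_fit: all instruments removed as outliers", call. = FALSE)
    }
  }
  structure(list(beta = fit$beta, se = sqrt(fit$var_beta),
                 pval = 2 * stats::pnorm(-abs(fit$beta / sqrt(fit$var_beta))),
                 n_snps_used = length(active),
                 removed_outliers = removed,
                 used_ids = pair$variant_id[active]),
            class = "gsmr_result")
}

gsmr_gls <- function(b_xy, v, r) {
  V <- r * outer(sqrt(v), sqrt(v))
  Vi <- solve(V)
  one <- rep(1, length(b_xy))
  denom <- drop(t(one) %*% Vi %*% one)
  list(beta = drop(t(one) %*% Vi %*% b_xy) / denom, var_beta = 1 / denom)
}

#' @export
print.gsmr_result <- function(x, ...) {
  cat(sprintf("gsmr: beta %.4g (se %.4g), p = %.3g, %d SNP(s) used, %d outlier(s) removed\n",
              x$beta, x$se, x$pval, x$n_snps_used, nrow(x$removed_outliers)))
  invisible(x)
}

# signed LD for the pair's variants, aligned to the pair's effect alleles,
# ridge-regularized
ld_aligned_pair_r <- function(ld, pair, ridge = 1e-3) {
  ea <- if ("ea" %in% names(pair)) pair$ea else NULL
  oa <- if ("oa" %in% names(pair)) pair$oa else NULL
  r <- ld_aligned_r(ld, pair$variant_id, ea, oa)
  ld_regularize(ld_matrix(r, pair$variant_id), ridge)$r
}
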