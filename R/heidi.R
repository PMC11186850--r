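# HEIDI: heterogeneity in dependent instruments across a cis region.
# Under a single shared causal variant, the ratio b_y/b_x is constant
# across SNPs in LD with it; heterogeneity of the ratios (beyond their
# LD-induced sampling covariance) indicates distinct linked variants.

#' HEIDI test for a shared causal variant in a cis region
#'
#' Takes the region's harmonized exposure/outcome effects, anchors on the
#' top exposure SNP (smallest exposure p), and tests whether the other
#' eligible SNPs' Wald ratios deviate from the top SNP's. Eligibility:
#' exposure `p <= p_include`, LD with the top SNP neither too strong
#' (`r2 > r2_prune_high`, near-duplicates carry no information) nor too
#' weak (`r2 < r2_prune_low`, ratio too noisy), capped at `max_snps` by
#' exposure |z|. Deviations `d_j = b_xy(j) - b_xy(top)` get a delta-method
#' covariance from the LD structure of both traits; the statistic
#' `T = sum z_dj^2` is referred to its eigenvalue-weighted chi-square null
#' via [quadform_pval()].
#'
#' A p-value below `alpha` rejects the single-shared-variant model
#' (pattern consistent with distinct variants in linkage); `pass = TRUE`
#' means `pval >= alpha`.
#'
#' @param region_exposure,region_outcome `summary_stats` for the cis
#'   region, or a ready [harmonized_pair()] as the first argument.
#' @param ld An `ld_matrix` covering the region.
#' @param p_include Maximum exposure p for inclusion (default 1.57e-3).
#' @param min_snps,max_snps Bounds on the number of SNPs used (3 and 20).
#' @param r2_prune_high,r2_prune_low LD pruning bounds against the top SNP
#'   (defaults 0.9 and 0.05).
#' @param alpha Rejection threshold for the pass flag (default 0.05).
#' @param ridge Ridge constant for LD regularization.
#' @return List of class `heidi_result`: `top_snp`, `n_snps_used`,
#'   `T_heidi`, `pval`, `eligible_snp_count`, `pass`, `assessable`,
#'   `reason` (when not assessable), `settings`.
#' @export
heidi_test <- function(region_exposure, region_outcome = NULL, ld,
                       p_include = 1.57e-3, min_snps = 3, max_snps = 20,
                       r2_prune_high = 0.9, r2_prune_low = 0.05,
                       alpha = 0.05, ridge = 1e-3) {
  pair <- if (inherits(region_exposure, "harmonized_pair")) {
    region_exposure
  } else {
    harmonize_pair(region_exposure, region_outcome)
  }
  if (!"pval_x" %in% names(pair)) {
    pair$pval_x <- 2 * stats::pnorm(-abs(pair$beta_x / pair$se_x))
  }
  settings <- list(p_include = p_include, min_snps = min_snps,
                   max_snps = max_snps, r2_prune_high = r2_prune_high,
                   r2_prune_low = r2_prune_low, alpha = alpha)
  not_assessable <- function(reason, top = NA_character_, eligible = 0L) {
    structure(list(top_snp = top, n_snps_used = 0L, T_heidi = NA_real_,
                   pval = NA_real_, eligible_snp_count = eligible,
                   pass = NA, assessable = FALSE, reason = reason,
                   settings = settings),
              class = "heidi_result")
  }

  ord <- order(pair$pval_x, pair$variant_id)
  top_i <- ord[1]
  top_id <- pair$variant_id[top_i]
  if (!top_id %in% ld$variant_ids) {
    stop("heidi_test: top SNP absent from LD reference: ", top_id, call. = FALSE)
  }

  r_all <- ld_aligned_pair_r(ld, pair, ridge = 0)
  r2_top <- r_all[top_i, ]^2
  elig <- which(pair$pval_x <= p_include &
                  seq_len(nrow(pair)) != top_i &
                  r2_top <= r2_prune_high & r2_top >= r2_prune_low)
  n_elig <- length(elig) + 1L
  if (n_elig < min_snps) {
    return(not_assessable(sprintf("only %d eligible SNP(s), need >= %d",
                                  n_elig, min_snps), top_id, n_elig))
  }
  if (n_elig > max_snps) {
    zx <- abs(pair$beta_x[elig] / pair$se_x[elig])
    elig <- elig[order(-zx)][seq_len(max_snps - 1L)]
  }

  use <- c(top_i, elig)
  bx <- pair$beta_x[use]; sx <- pair$se_x[use]
  by <- pair$beta_y[use]; sy <- pair$se_y[use]
  r <- ld_regularize(ld_matrix(r_all[use, use, drop = FALSE],
                               pair$variant_id[use]), ridge)$r
  b_xy <- by / bx

  # cov(b_xy_j, b_xy_k) by the delta method with two-sample independence
  # between traits: outcome term + exposure term
  c_mat <- (r * outer(sy, sy) + outer(b_xy, b_xy) * r * outer(sx, sx)) /
    outer(bx, bx)
  m <- length(use)
  j <- 2:m
  d <- b_xy[j] - b_xy[1]
  cov_d <- c_mat[j, j, drop = FALSE] -
    matrix(c_mat[j, 1], m - 1, m - 1) -
    t(matrix(c_mat[j, 1], m - 1, m - 1)) + c_mat[1, 1]
  sd_d <- sqrt(pmax(diag(cov_d), .Machine$double.eps))
  z_d <- d / sd_d
  T_heidi <- sum(z_d^2)
  corr_d <- cov_d / outer(sd_d, sd_d)
  lam <- eigen(corr_d, symmetric = TRUE, only.values = TRUE)$values
  pval <- quadform_pval(T_heidi, pmax(lam, 0))

  structure(list(top_snp = top_id, n_snps_used = m, T_heidi = T_heidi,
                 pval = pval, eligible_snp_count = n_elig,
                 pass = pval >= alpha, assessable = TRUE, reason = NA_character_,
                 settings = settings),
            class = "heidi_result")
}

#' @export
print.heidi_result <- function(x, ...) {
  if (!x$assessable) {
    cat("heidi: not assessable —", x$reason, "\n")
  } else {
    cat(sprintf("heidi: top %s, %d SNPs, T = %.3g, p = %.3g (%s)\n",
                x$top_snp, x$n_snps_used, x$T_heidi, x$pval,
                if (isTRUE(x$pass)) "consistent with one shared causal variant"
                else "heterogeneous"))
  }
  invisible(x)
}
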