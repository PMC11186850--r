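# Single-causal-variant Bayesian colocalization via Wakefield approximate
# Bayes factors: do two traits' association signals in a region share one
# causal variant (H4) or carry distinct ones (H3)?

#' Colocalization priors
#'
#' Per-SNP prior probabilities: `p1` causal for trait 1 only, `p2` for
#' trait 2 only, `p12` for both. Defaults 1e-4, 1e-4, 1e-6.
#'
#' @param p1,p2,p12 Per-SNP priors, each in (0,1), `p1+p2+p12 < 1`.
#' @return List of class `coloc_priors`.
#' @export
coloc_priors <- function(p1 = 1e-4, p2 = 1e-4, p12 = 1e-6) {
  stopifnot(p1 > 0, p2 > 0, p12 >= 0, p1 < 1, p2 < 1, p12 < 1,
            p1 + p2 + p12 < 1)
  structure(list(p1 = p1, p2 = p2, p12 = p12), class = "coloc_priors")
}

#' Wakefield log approximate Bayes factor
#'
#' For an estimated effect `beta` with variance `V = se^2` and a normal
#' prior with variance `W = prior_sd^2` on the true effect:
#' `lABF = 0.5 log(1 - r) + 0.5 r z^2` with `r = W/(V+W)`, `z = beta/se` —
#' the log of `sqrt(V/(V+W)) exp(W z^2 / (2(V+W)))`.
#'
#' @param beta,se Effect estimate and standard error (`se > 0`).
#' @param prior_sd Prior standard deviation of the true effect
#'   (`W^0.5 > 0`).
#' @return Log approximate Bayes factor (vectorized).
#' @export
wakefield_labf <- function(beta, se, prior_sd) {
  stopifnot(all(se > 0), prior_sd > 0)
  V <- se^2
  r <- prior_sd^2 / (V + prior_sd^2)
  z <- beta / se
  0.5 * log1p(-r) + 0.5 * r * z^2
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

#' Bayesian colocalization of two traits in a region
#'
#' Computes per-SNP Wakefield log-ABFs for each trait and the posterior
#' probabilities of the five hypotheses: H0 no association, H1/H2 one
#' trait only, H3 both traits with distinct causal variants, H4 a shared
#' causal variant. Assumes at most one causal variant per trait in the
#' region. Log-scale accumulation uses log-sum-exp throughout; the H3 sum
#' over distinct-variant pairs is computed stably as
#' `exp(L1+L2) - exp(L12)`.
#'
#' `PP.H4 >= 0.80` is read as strong support for a shared causal variant,
#' `>= 0.50` as moderate.
#'
#' @param trait1,trait2 Region `summary_stats` (joined on `variant_id`),
#'   or data.frames with `variant_id`, `beta`, `se`.
#' @param priors A [coloc_priors()].
#' @param sd1,sd2 Prior effect SDs; defaults by trait type — 0.15 for
#'   quantitative traits, 0.2 (log-odds) for binary.
#' @return List of class `coloc_result`: `pp` (named H0..H4, sums to 1),
#'   `n_snps`, `per_snp_h4` (data.frame of each SNP's share of the H4
#'   weight), `priors`, `support` (strong/moderate/weak), `top_snp`.
#' @export
coloc_abf <- function(trait1, trait2, priors = coloc_priors(),
                      sd1 = NULL, sd2 = NULL) {
  default_sd <- function(tr, given) {
    if (!is.null(given)) return(given)
    if (inherits(tr, "summary_stats") && identical(tr$trait_type, "binary")) 0.2
    else 0.15
  }
  sd1 <- default_sd(trait1, sd1)
  sd2 <- default_sd(trait2, sd2)
  rec <- function(tr) if (inherits(tr, "summary_stats")) tr$records else tr
  t1 <- rec(trait1); t2 <- rec(trait2)
  shared <- intersect(t1$variant_id, t2$variant_id)
  if (length(shared) < 1) stop("coloc_abf: no shared variants", call. = FALSE)
  i1 <- match(shared, t1$variant_id); i2 <- match(shared, t2$variant_id)
  z_ok <- is.finite(t1$beta[i1] / t1$se[i1]) | is.finite(t2$beta[i2] / t2$se[i2])
  if (!any(z_ok)) stop("coloc_abf: all z-scores non-finite in region", call. = FALSE)

  l1 <- wakefield_labf(t1$beta[i1], t1$se[i1], sd1)
  l2 <- wakefield_labf(t2$beta[i2], t2$se[i2], sd2)
  L1 <- logsumexp(l1)
  L2 <- logsumexp(l2)
  L12 <- logsumexp(l1 + l2)

  # sum over ordered distinct pairs: exp(L1+L2) - exp(L12), stably
  diff_log <- if (L12 < L1 + L2) L1 + L2 + log1p(-exp(L12 - L1 - L2)) else -Inf
  lw <- c(H0 = 0,
          H1 = log(priors$p1) + L1,
          H2 = log(priors$p2) + L2,
          H3 = log(priors$p1) + log(priors$p2) + diff_log,
          H4 = if (priors$p12 > 0) log(priors$p12) + L12 else -Inf)
  pp <- exp(lw - logsumexp(lw))
  pp <- pp / sum(pp)

  h4_contrib <- exp(l1 + l2 - L12)
  support <- if (pp["H4"] >= 0.80) "strong" else if (pp["H4"] >= 0.50) "moderate" else "weak"
  structure(list(pp = pp, n_snps = length(shared),
                 per_snp_h4 = data.frame(variant_id = shared,
                                         h4_contribution = h4_contrib),
                 priors = priors, prior_sd = c(trait1 = sd1, trait2 = sd2),
                 support = support,
                 top_snp = shared[which.max(h4_contrib)]),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc (%d SNPs, single-causal-variant assumption):\n", x$n_snps))
  print(round(x$pp, 4))
  cat(sprintf("support: %s (top shared-signal SNP %s)\n", x$support, x$top_snp))
  invisible(x)
}
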