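# Tail probability of a positively weighted sum of independent 1-df
# chi-square variables, P(sum lambda_i X_i > q) — the null distribution of
# quadratic forms in correlated normals. Imhof-type numerical inversion of
# the characteristic function, with Satterthwaite moment matching as a
# fallback when the integral misbehaves.

#' Upper tail of a weighted chi-square sum
#'
#' @param q Observed statistic.
#' @param lambda Non-negative eigenvalue weights (zeros dropped).
#' @return `P(sum lambda_i chisq_1 > q)`, clamped to `[0, 1]`; falls back
#'   to a scaled chi-square (Satterthwaite) approximation if the numerical
#'   integration fails to converge.
#' @export
quadform_pval <- function(q, lambda) {
  lambda <- lambda[lambda > 1e-12]
  if (length(lambda) == 0) return(1)
  if (length(lambda) == 1) {
    return(stats::pchisq(q / lambda, df = 1, lower.tail = FALSE))
  }
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  # the integrand oscillates with asymptotic period 4*pi/q under an
  # envelope decaying like u^-(k/2+1); integrate period-aligned chunks and
  # stop when contributions vanish (asymptotically an alternating series,
  # so the truncation error is bounded by the last chunk)
  period <- 4 * pi / max(q, 1e-3)
  val <- tryCatch({
    acc <- 0
    u0 <- 0
    converged <- FALSE
    for (i in seq_len(2000L)) {
      chunk <- stats::integrate(integrand, u0, u0 + period,
                                rel.tol = 1e-9, abs.tol = 1e-13,
                                subdivisions = 200L)$value
      acc <- acc + chunk
      u0 <- u0 + period
      if (abs(chunk) < 1e-13 && i > 2) {
        converged <- TRUE
        break
      }
    }
    if (!converged && abs(chunk) > 1e-7) NA_real_ else 0.5 + acc / pi
  }, error = function(e) NA_real_)
  if (is.na(val) || val < -1e-4 || val > 1 + 1e-4) {
    val <- satterthwaite_pval(q, lambda)
  }
  min(max(val, 0), 1)
}

satterthwaite_pval <- function(q, lambda) {
  s1 <- sum(lambda); s2 <- sum(lambda^2)
  stats::pchisq(q * s1 / s2, df = s1^2 / s2, lower.tail = FALSE)
}
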