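# cis-pQTL instrument selection: cis-window filtering, significance, MAF,
# palindromic and HLA exclusions, greedy LD clumping, strength diagnostics.

#' Instrument-selection parameters
#'
#' Defaults follow common proteome-wide MR practice: genome-wide
#' significance `5e-8`, a 500 kb cis flank around the protein-coding gene,
#' MAF >= 0.01, clumping at r2 < 0.001 within a 10 Mb window, exclusion of
#' the extended HLA region (chr6:29-34 Mb, complex LD), and removal of
#' palindromic variants at intermediate allele frequency (0.4-0.6).
#'
#' @param p_threshold Association p-value threshold.
#' @param cis_flank_bp Flank added on each side of the gene (inclusive).
#' @param maf_min Minimum minor allele frequency, `min(eaf, 1-eaf)`.
#' @param clump_r2 LD r2 above which the weaker variant is removed.
#' @param clump_window_bp Physical clumping window in bp.
#' @param hla_region List `(chrom, start, end)` to exclude.
#' @param palindromic_af_window Intermediate-frequency window.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(p_threshold = 5e-8, cis_flank_bp = 5e5,
                             maf_min = 0.01, clump_r2 = 0.001,
                             clump_window_bp = 1e7,
                             hla_region = list(chrom = "6", start = 29e6, end = 34e6),
                             palindromic_af_window = c(0.4, 0.6)) {
  stopifnot(p_threshold > 0, p_threshold < 1, cis_flank_bp >= 0,
            maf_min >= 0, maf_min < 0.5, clump_r2 > 0, clump_r2 <= 1,
            clump_window_bp > 0,
            palindromic_af_window[1] <= palindromic_af_window[2])
  structure(list(p_threshold = p_threshold, cis_flank_bp = cis_flank_bp,
                 maf_min = maf_min, clump_r2 = clump_r2,
                 clump_window_bp = clump_window_bp, hla_region = hla_region,
                 palindromic_af_window = palindromic_af_window),
            class = "selection_params")
}

#' Define a gene's cis region
#'
#' @param gene_id Gene identifier.
#' @param chrom Chromosome (string, no "chr" prefix required).
#' @param start,end 1-based inclusive gene coordinates, `start <= end`.
#' @return A list of class `gene_region`.
#' @export
gene_region <- function(gene_id, chrom, start, end) {
  stopifnot(start <= end, start >= 1)
  structure(list(gene_id = gene_id, chrom = as.character(chrom),
                 start = as.numeric(start), end = as.numeric(end)),
            class = "gene_region")
}

#' Read a gene-annotation table
#'
#' TSV with columns `gene_id`, `chrom`, `start`, `end`.
#'
#' @param path File path.
#' @return A list of [gene_region()] objects, named by gene id.
#' @export
read_gene_regions <- function(path) {
  g <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "chrom", "start", "end") %in% names(g)))
  out <- lapply(seq_len(nrow(g)), function(i) {
    gene_region(g$gene_id[i], g$chrom[i], g$start[i], g$end[i])
  })
  names(out) <- g$gene_id
  out
}

#' Select independent cis-pQTL instruments for a protein
#'
#' Applies, in order: cis-window restriction (gene start/end +/- flank,
#' inclusive), the association p-value threshold, the MAF filter,
#' removal of palindromic variants at intermediate frequency, removal of
#' the HLA region, then greedy LD [clump()]ing. Every exclusion is recorded
#' in the audit trail with the rule that removed it.
#'
#' @param pqtl `summary_stats` for the protein.
#' @param region A [gene_region()].
#' @param ld An `ld_matrix` (used for clumping).
#' @param params A [selection_params()].
#' @return A list of class `instrument_set`: `gene_id`, `variants`
#'   (data.frame of retained records with per-variant `f_stat`), `audit`
#'   (data.frame variant_id/rule for every exclusion), `params`. Zero
#'   retained variants is a valid, flagged result, not an error.
#' @export
select_cis_instruments <- function(pqtl, region, ld, params = selection_params()) {
  stopifnot(inherits(pqtl, "summary_stats"), inherits(region, "gene_region"))
  rec <- pqtl$records
  audit <- data.frame(variant_id = character(0), rule = character(0))
  note <- function(ids, rule) {
    if (length(ids) > 0) {
      audit <<- rbind(audit, data.frame(variant_id = ids, rule = rule))
    }
  }

  keep <- rec$chrom == region$chrom &
    rec$pos >= region$start - params$cis_flank_bp &
    rec$pos <= region$end + params$cis_flank_bp
  note(rec$variant_id[!keep], "outside_cis_window")
  rec <- rec[keep, , drop = FALSE]

  keep <- rec$pval < params$p_threshold
  note(rec$variant_id[!keep], "above_p_threshold")
  rec <- rec[keep, , drop = FALSE]

  maf <- pmin(rec$eaf, 1 - rec$eaf)
  keep <- !is.na(maf) & maf >= params$maf_min
  note(rec$variant_id[!keep], "below_maf")
  rec <- rec[keep, , drop = FALSE]

  afw <- params$palindromic_af_window
  pal <- is_palindromic(rec$ea, rec$oa) & !is.na(rec$eaf) &
    rec$eaf >= afw[1] & rec$eaf <= afw[2]
  note(rec$variant_id[pal], "palindromic_intermediate_af")
  rec <- rec[!pal, , drop = FALSE]

  hla <- params$hla_region
  in_hla <- rec$chrom == as.character(hla$chrom) &
    rec$pos >= hla$start & rec$pos <= hla$end
  note(rec$variant_id[in_hla], "hla_region")
  rec <- rec[!in_hla, , drop = FALSE]

  if (nrow(rec) > 0) {
    kept_ids <- clump(rec, ld, r2 = params$clump_r2,
                      window_bp = params$clump_window_bp)
    note(setdiff(rec$variant_id, kept_ids), "clumped")
    rec <- rec[match(kept_ids, rec$variant_id), , drop = FALSE]
    rec$f_stat <- per_snp_f(rec$beta, rec$se)
  } else {
    rec$f_stat <- numeric(0)
  }
  rownames(rec) <- NULL
  structure(list(gene_id = region$gene_id, variants = rec, audit = audit,
                 params = params, empty = nrow(rec) == 0),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %s, %d instrument(s), %d exclusion(s)\n",
              x$gene_id, nrow(x$variants), nrow(x$audit)))
  invisible(x)
}

#' Greedy LD clumping
#'
#' Orders candidates by ascending p-value (ties broken on variant id), takes
#' the top variant as an index, removes all others within `window_bp` whose
#' squared correlation with it is `>= r2`, and repeats. Variants absent
#' from the LD reference are treated as correlated with nothing, retained,
#' and warned about.
#'
#' @param candidates data.frame with `variant_id`, `pos`, `pval` columns.
#' @param ld An `ld_matrix`.
#' @param r2 LD pruning threshold.
#' @param window_bp Physical window in bp.
#' @param warn_missing Warn about candidates absent from the LD reference
#'   (default TRUE; callers clumping across regions wider than the
#'   reference turn this off).
#' @return Character vector of retained variant ids, by ascending p.
#' @export
clump <- function(candidates, ld, r2 = 0.001, window_bp = 1e7,
                  warn_missing = TRUE) {
  stopifnot(is.data.frame(candidates),
            all(c("variant_id", "pos", "pval") %in% names(candidates)))
  cand <- candidates[order(candidates$pval, candidates$variant_id), , drop = FALSE]
  missing_ld <- setdiff(cand$variant_id, ld$variant_ids)
  if (length(missing_ld) > 0 && warn_missing) {
    warning("clump: variant(s) absent from LD reference retained as independent: ",
            paste(utils::head(missing_ld, 5), collapse = ", "))
  }
  kept <- character(0)
  active <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!active[i]) next
    idx <- cand$variant_id[i]
    kept <- c(kept, idx)
    active[i] <- FALSE
    if (!idx %in% ld$variant_ids) next
    others <- which(active)
    if (length(others) == 0) break
    in_window <- abs(cand$pos[others] - cand$pos[i]) <= window_bp
    in_ld <- cand$variant_id[others] %in% ld$variant_ids
    rr <- rep(0, length(others))
    rr[in_ld] <- ld$r[idx, cand$variant_id[others][in_ld]]^2
    active[others[in_window & rr >= r2]] <- FALSE
  }
  kept
}

#' Per-variant instrument strength (F statistic)
#'
#' Approximates the first-stage F as the squared z-score, `(beta/se)^2` —
#' the standard approximation when only marginal summary effects are
#' available. F >= 10 is the conventional weak-instrument gate.
#'
#' @param beta,se Per-allele effect and standard error (`se > 0`).
#' @return Numeric F statistics (vectorized).
#' @export
per_snp_f <- function(beta, se) {
  stopifnot(all(se > 0))
  (beta / se)^2
}

#' Cross-cohort heterogeneity of a variant's outcome effect
#'
#' Fixed-effect meta-analysis heterogeneity across outcome cohorts:
#' Cochran's `Q = sum w_k (b_k - b_bar)^2` with `w_k = 1/se_k^2`, p-value
#' from a chi-square on K-1 df, and `I2 = max(0, (Q - (K-1))/Q)`. A variant
#' passes the consistency screen when `p_Q > 0.05` and `I2 < 50%`.
#'
#' @param betas,ses Per-cohort effects and standard errors (length >= 2).
#' @param alpha Heterogeneity alpha for the pass flag (default 0.05).
#' @param i2_max Maximum admissible I2 (default 0.5).
#' @return List `Q`, `p`, `i2`, `pass`, `assessable`. With a single cohort,
#'   `assessable = FALSE` and the statistics are NA.
#' @export
cross_cohort_het <- function(betas, ses, alpha = 0.05, i2_max = 0.5) {
  ok <- is.finite(betas) & is.finite(ses) & ses > 0
  betas <- betas[ok]; ses <- ses[ok]
  k <- length(betas)
  if (k < 2) {
    return(list(Q = NA_real_, p = NA_real_, i2 = NA_real_,
                pass = NA, assessable = FALSE))
  }
  w <- 1 / ses^2
  bbar <- sum(w * betas) / sum(w)
  Q <- sum(w * (betas - bbar)^2)
  p <- stats::pchisq(Q, df = k - 1, lower.tail = FALSE)
  i2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) else 0
  list(Q = Q, p = p, i2 = i2, pass = (p > alpha) && (i2 < i2_max),
       assessable = TRUE)
}
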