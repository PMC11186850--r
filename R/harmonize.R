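# Allele harmonization between exposure and outcome summary statistics,
# and LD-proxy lookup for outcome variants missing from the outcome file.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  !is.na(ea) & !is.na(oa) & COMPLEMENT[ea] == oa
}

#' Construct a harmonized exposure/outcome pair
#'
#' Low-level constructor used by [harmonize_pair()] and the simulator. The
#' data.frame must carry at least `beta_x`, `se_x`, `beta_y`, `se_y`; the
#' estimators operate on these columns.
#'
#' @param df data.frame of per-variant harmonized effects.
#' @param exposure_id,outcome_id Trait identifiers.
#' @param outcome_type `"binary"` or `"quantitative"`.
#' @param n_x,n_y Sample sizes (effective n for binary outcomes), optional.
#' @param dropped data.frame describing variants removed during
#'   harmonization, with a `reason` column.
#' @return Object of classes `harmonized_pair` and `data.frame`.
#' @export
harmonized_pair <- function(df, exposure_id = "exposure", outcome_id = "outcome",
                            outcome_type = "binary", n_x = NA, n_y = NA,
                            dropped = NULL) {
  stopifnot(is.data.frame(df),
            all(c("beta_x", "se_x", "beta_y", "se_y") %in% names(df)))
  if (!"variant_id" %in% names(df)) df$variant_id <- paste0("v", seq_len(nrow(df)))
  if (any(df$se_x <= 0, na.rm = TRUE) || any(df$se_y <= 0, na.rm = TRUE)) {
    stop("harmonized_pair: standard errors must be positive", call. = FALSE)
  }
  structure(df,
            class = c("harmonized_pair", "data.frame"),
            exposure_id = exposure_id, outcome_id = outcome_id,
            outcome_type = outcome_type, n_x = n_x, n_y = n_y,
            dropped = dropped %||% data.frame(variant_id = character(0),
                                              reason = character(0)))
}

as_harmonized_pair <- function(x) {
  if (inherits(x, "harmonized_pair")) return(x)
  harmonized_pair(as.data.frame(x))
}

#' Harmonize exposure and outcome records to a shared effect allele
#'
#' Joins the two traits on `variant_id` and expresses both effects on the
#' exposure's effect allele. When the outcome's effect allele matches the
#' exposure's other allele (directly or after strand complement), the
#' outcome beta is negated and its frequency complemented. Palindromic
#' variants (A/T, G/C) whose exposure effect-allele frequency lies inside
#' `af_window` are removed — strand cannot be resolved from alleles at
#' intermediate frequency — and flagged `palindromic_dropped`. Variants
#' whose alleles match neither orientation are dropped with reason
#' `allele_mismatch`. Exposure variants absent from the outcome are
#' resolved through [find_proxy()] when an LD reference is supplied.
#'
#' @param exposure,outcome `summary_stats` objects.
#' @param af_window Intermediate-frequency window for the palindromic
#'   filter, default `c(0.4, 0.6)` (exposure-side frequency).
#' @param ld Optional `ld_matrix` used for proxy lookup.
#' @param proxy_r2 Minimum squared correlation for a proxy (default 0.8).
#' @return A [harmonized_pair()] with per-variant exposure and outcome
#'   effects, flags (`flipped`, `proxy_used`, `proxy_id`, `proxy_r2`), and
#'   a `dropped` attribute listing removals and reasons.
#' @export
harmonize_pair <- function(exposure, outcome, af_window = c(0.4, 0.6),
                           ld = NULL, proxy_r2 = 0.8) {
  stopifnot(inherits(exposure, "summary_stats"), inherits(outcome, "summary_stats"))
  ex <- exposure$records
  oc <- outcome$records
  oc_ix <- match(ex$variant_id, oc$variant_id)

  dropped <- data.frame(variant_id = character(0), reason = character(0))
  rows <- vector("list", nrow(ex))
  for (i in seq_len(nrow(ex))) {
    e <- ex[i, ]
    proxy_used <- FALSE; proxy_id <- NA_character_; proxy_r2_val <- NA_real_
    j <- oc_ix[i]
    if (is.na(j) && !is.null(ld) && e$variant_id %in% ld$variant_ids) {
      px <- find_proxy(e$variant_id, outcome, ld, r2_min = proxy_r2)
      if (is.null(px)) {
        dropped <- rbind(dropped, data.frame(variant_id = e$variant_id,
                                             reason = "no_proxy"))
        next
      }
      j <- match(px$proxy_id, oc$variant_id)
      o <- oc[j, ]
      # re-orient the proxy's effect to the query variant's LD-reference
      # orientation: allele matching against the reference when available,
      # otherwise the sign of r
      o <- reorient_proxy(o, e, ld, px)
      proxy_used <- TRUE; proxy_id <- px$proxy_id; proxy_r2_val <- px$r2
    } else if (is.na(j)) {
      dropped <- rbind(dropped, data.frame(variant_id = e$variant_id,
                                           reason = "absent_from_outcome"))
      next
    } else {
      o <- oc[j, ]
    }

    orient <- allele_orientation(e$ea, e$oa, o$ea, o$oa)
    if (is.na(orient)) {
      dropped <- rbind(dropped, data.frame(variant_id = e$variant_id,
                                           reason = "allele_mismatch"))
      next
    }
    pal <- is_palindromic(e$ea, e$oa)
    if (pal && !is.na(e$eaf) && e$eaf >= af_window[1] && e$eaf <= af_window[2]) {
      dropped <- rbind(dropped, data.frame(variant_id = e$variant_id,
                                           reason = "palindromic_dropped"))
      next
    }
    flipped <- orient < 0
    rows[[i]] <- data.frame(
      variant_id = e$variant_id, chrom = e$chrom, pos = e$pos,
      ea = e$ea, oa = e$oa,
      beta_x = e$beta, se_x = e$se, eaf_x = e$eaf, pval_x = e$pval,
      beta_y = orient * o$beta, se_y = o$se,
      eaf_y = if (flipped) 1 - o$eaf else o$eaf, pval_y = o$pval,
      flipped = flipped, proxy_used = proxy_used,
      proxy_id = proxy_id, proxy_r2 = proxy_r2_val,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0) {
    stop("harmonize_pair: no shared variants after harmonization", call. = FALSE)
  }
  rownames(out) <- NULL
  harmonized_pair(out,
                  exposure_id = exposure$trait_id, outcome_id = outcome$trait_id,
                  outcome_type = outcome$trait_type,
                  n_x = stats::median(ex$n, na.rm = TRUE),
                  n_y = stats::median(oc$n, na.rm = TRUE),
                  dropped = dropped)
}

# +1 same orientation, -1 swapped, NA mismatch; strand complement accepted
allele_orientation <- function(ea_x, oa_x, ea_y, oa_y) {
  if (ea_y == ea_x && oa_y == oa_x) return(1)
  if (ea_y == oa_x && oa_y == ea_x) return(-1)
  cea <- unname(COMPLEMENT[ea_y]); coa <- unname(COMPLEMENT[oa_y])
  if (!is.na(cea) && !is.na(coa)) {
    if (cea == ea_x && coa == oa_x) return(1)
    if (cea == oa_x && coa == ea_x) return(-1)
  }
  NA_real_
}

# Express a proxy record's outcome effect on the query variant's own
# effect/other alleles so downstream harmonization can treat it as if the
# query had been observed directly.
reorient_proxy <- function(o, e, ld, px) {
  if (!is.null(ld$alleles)) {
    qi <- match(e$variant_id, ld$variant_ids)
    pi <- match(px$proxy_id, ld$variant_ids)
    # align the proxy record to the reference orientation of the proxy
    # variant (allele matching, preferred when alleles are available)
    op <- allele_orientation(ld$alleles$ea[pi], ld$alleles$oa[pi], o$ea, o$oa)
    if (!is.na(op) && op < 0) {
      o$beta <- -o$beta
      o$eaf <- 1 - o$eaf
    }
    # the result is expressed on the query's reference alleles
    o$ea <- ld$alleles$ea[qi]; o$oa <- ld$alleles$oa[qi]
  } else {
    o$ea <- e$ea; o$oa <- e$oa
  }
  # negative LD: the query's effect allele travels with the proxy's other
  # allele, so the transferred effect changes sign
  if (px$sign < 0) {
    o$beta <- -o$beta
    o$eaf <- 1 - o$eaf
  }
  o
}

#' Find an LD proxy for a variant missing from the outcome data
#'
#' Returns the outcome-present variant with the highest squared correlation
#' `r2 >= r2_min` to the query, together with the sign of r so the proxy's
#' effect can be re-oriented to the query's effect allele. Ties on r2 break
#' lexicographically on variant id.
#'
#' @param variant_id Query variant (must be present in `ld`).
#' @param outcome A `summary_stats` object searched for candidates.
#' @param ld An `ld_matrix` containing the query.
#' @param r2_min Minimum r2 (default 0.8).
#' @return `NULL` if no candidate reaches `r2_min`; otherwise a list with
#'   `proxy_id`, `r`, `r2`, `sign`.
#' @export
find_proxy <- function(variant_id, outcome, ld, r2_min = 0.8) {
  stopifnot(inherits(outcome, "summary_stats"), inherits(ld, "ld_matrix"))
  if (!variant_id %in% ld$variant_ids) {
    stop("find_proxy: query variant absent from LD reference: ", variant_id,
         call. = FALSE)
  }
  if (variant_id %in% outcome$records$variant_id) {
    return(list(proxy_id = variant_id, r = 1, r2 = 1, sign = 1))
  }
  cand <- intersect(outcome$records$variant_id, ld$variant_ids)
  cand <- setdiff(cand, variant_id)
  if (length(cand) == 0) return(NULL)
  rvec <- ld$r[variant_id, cand]
  r2 <- rvec^2
  ok <- r2 >= r2_min
  if (!any(ok)) return(NULL)
  cand <- cand[ok]; rvec <- rvec[ok]; r2 <- r2[ok]
  ord <- order(-r2, cand)
  list(proxy_id = cand[ord[1]], r = unname(rvec[ord[1]]),
       r2 = unname(r2[ord[1]]), sign = unname(sign(rvec[ord[1]])))
}
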