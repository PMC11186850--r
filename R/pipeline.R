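# Discovery -> validation -> confirmation -> sensitivity -> HEIDI ->
# colocalization orchestration, FDR gating, and tier classification of
# protein-outcome associations.

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR q-values with monotonicity enforcement, input order
#' preserved. Thin wrapper over `stats::p.adjust(method = "BH")`.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return q-values in the input order; empty input gives empty output.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0) return(numeric(0))
  stopifnot(all(is.na(pvals) | (pvals > 0 & pvals <= 1)))
  stats::p.adjust(pvals, method = "BH")
}

#' Tier-classification thresholds
#'
#' @param fdr_alpha Discovery FDR threshold (0.05).
#' @param validation_alpha Validation p threshold (0.05).
#' @param aux_alpha Alpha for heterogeneity, pleiotropy and HEIDI
#'   diagnostics (0.05).
#' @param coloc_strong,coloc_moderate PP.H4 cutoffs (0.80, 0.50).
#' @param min_outcomes Minimum number of associated outcomes for tier 1 (2).
#' @param na_aux_passes Whether non-assessable heterogeneity/pleiotropy
#'   diagnostics count as passing for tier 1 (default TRUE; FALSE is the
#'   conservative alternative).
#' @return List of class `tier_criteria`.
#' @export
tier_criteria <- function(fdr_alpha = 0.05, validation_alpha = 0.05,
                          aux_alpha = 0.05, coloc_strong = 0.80,
                          coloc_moderate = 0.50, min_outcomes = 2,
                          na_aux_passes = TRUE) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, validation_alpha > 0,
            validation_alpha < 1, aux_alpha > 0, aux_alpha < 1,
            coloc_moderate < coloc_strong, min_outcomes >= 1)
  structure(list(fdr_alpha = fdr_alpha, validation_alpha = validation_alpha,
                 aux_alpha = aux_alpha, coloc_strong = coloc_strong,
                 coloc_moderate = coloc_moderate, min_outcomes = min_outcomes,
                 na_aux_passes = na_aux_passes),
            class = "tier_criteria")
}

#' Classify a significant association into evidence tiers
#'
#' Applies the three-tier evidence grading to records already significant
#' in discovery (FDR < `fdr_alpha`) and validation (p < `validation_alpha`
#' with the same direction); other records get `NA` (no tier).
#'
#' Tier 3: colocalization PP.H4 below `coloc_moderate`, or the
#' confounder-exclusion sensitivity analysis failed, or the GSMR/LD-aware
#' IVW confirmation failed. Otherwise tier 1 requires all of: PP.H4 >=
#' `coloc_strong`; HEIDI p >= `aux_alpha`; heterogeneity Q p >=
#' `aux_alpha` (or not assessable); Egger intercept p >= `aux_alpha` (or
#' not assessable); association with >= `min_outcomes` outcomes.
#' Everything else is tier 2.
#'
#' @param records data.frame with columns `significant` (logical),
#'   `pp_h4`, `sensitivity_pass` (logical, NA allowed), `confirmation_status`
#'   (`confirmed`/`failed`/`insufficient_snps`), `heidi_pval`, `Q_pval`,
#'   `intercept_pval`, `outcomes_associated_count`.
#' @param criteria A [tier_criteria()].
#' @return Integer vector of tiers (1, 2, 3, or NA), one per row.
#' @export
classify_tier <- function(records, criteria = tier_criteria()) {
  stopifnot(is.data.frame(records))
  need <- c("significant", "pp_h4", "sensitivity_pass", "confirmation_status",
            "heidi_pval", "Q_pval", "intercept_pval",
            "outcomes_associated_count")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0) {
    stop("classify_tier: missing field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  aux_ok <- function(p) {
    ifelse(is.na(p), criteria$na_aux_passes, p >= criteria$aux_alpha)
  }
  sens_fail <- !is.na(records$sensitivity_pass) & !records$sensitivity_pass
  conf_fail <- !is.na(records$confirmation_status) &
    records$confirmation_status == "failed"
  tier3 <- (!is.na(records$pp_h4) & records$pp_h4 < criteria$coloc_moderate) |
    sens_fail | conf_fail
  tier1 <- !tier3 &
    !is.na(records$pp_h4) & records$pp_h4 >= criteria$coloc_strong &
    !is.na(records$heidi_pval) & records$heidi_pval >= criteria$aux_alpha &
    aux_ok(records$Q_pval) & aux_ok(records$intercept_pval) &
    records$outcomes_associated_count >= criteria$min_outcomes
  tier <- ifelse(tier3, 3L, ifelse(tier1, 1L, 2L))
  tier[!records$significant %in% TRUE] <- NA_integer_
  tier
}

#' Published migraine association table bundled for classifier validation
#'
#' Loads the packaged table of 22 published plasma-protein/migraine MR
#' associations (odds ratios, heterogeneity/pleiotropy/HEIDI p-values,
#' colocalization PP.H4, sensitivity and confirmation flags, and the
#' reported evidence tier) used to validate [classify_tier()]. Printed
#' values below a reporting limit (e.g. "<0.01") are stored just under the
#' limit.
#'
#' @return data.frame with one row per association.
#' @export
load_tier_fixture <- function() {
  path <- system.file("extdata", "migraine_associations.tsv", package = "pwmr",
                      mustWork = TRUE)
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, na.strings = "NA")
  x$sensitivity_pass <- as.logical(x$sensitivity_pass)
  x
}

#' Confounder-exclusion sensitivity analysis
#'
#' Refits the MR estimate after removing instruments listed in a
#' confounder-association exclusion table (the offline stand-in for a
#' phenome-database query), optionally applying the pre-filters of the
#' screening stage — dropping variants whose outcome association is
#' genome-wide significant (`pval_y < outcome_p_max`) and variants failing
#' a cross-cohort heterogeneity screen (`het_pass` column, when present) —
#' then re-clumping at the strict threshold.
#'
#' @param pair A [harmonized_pair()] of candidate instruments (typically
#'   the unclumped cis candidates).
#' @param confounder_snps data.frame with a `variant_id` column (and
#'   optionally a `trait` column naming the confounder); may be empty.
#' @param ld An `ld_matrix` for re-clumping.
#' @param reference An `mr_result` whose direction the refit must match.
#' @param clump_r2,clump_window_bp Re-clumping parameters (0.001, 10 Mb).
#' @param alpha Pass threshold (p < alpha, same direction as `reference`).
#' @param outcome_p_max Outcome-association pre-filter (default 5e-8;
#'   `NULL` disables).
#' @return List: `result` (`mr_result` or NULL), `pass`, `n_excluded`,
#'   `reason` (on failure).
#' @export
sensitivity_confounder_filter <- function(pair, confounder_snps, ld, reference,
                                          clump_r2 = 0.001,
                                          clump_window_bp = 1e7,
                                          alpha = 0.05,
                                          outcome_p_max = 5e-8) {
  pair <- as_harmonized_pair(pair)
  excl <- character(0)
  if (!is.null(confounder_snps) && nrow(confounder_snps) > 0) {
    excl <- unique(as.character(confounder_snps$variant_id))
  }
  keep <- !pair$variant_id %in% excl
  if (!is.null(outcome_p_max) && "pval_y" %in% names(pair)) {
    keep <- keep & !(is.finite(pair$pval_y) & pair$pval_y < outcome_p_max)
  }
  if ("het_pass" %in% names(pair)) {
    keep <- keep & (is.na(pair$het_pass) | pair$het_pass)
  }
  sub <- pair[keep, , drop = FALSE]
  if (nrow(sub) == 0) {
    return(list(result = NULL, pass = FALSE, n_excluded = sum(!keep),
                reason = "no instruments after confounder exclusion"))
  }
  cand <- data.frame(variant_id = sub$variant_id, pos = sub$pos,
                     pval = sub$pval_x)
  kept_ids <- clump(cand, ld, r2 = clump_r2, window_bp = clump_window_bp)
  sub <- sub[match(kept_ids, sub$variant_id), , drop = FALSE]
  res <- mr_primary(harmonized_pair(as.data.frame(sub),
                                    outcome_type = attr(pair, "outcome_type") %||% "binary"))
  pass <- res$pval < alpha && sign(res$beta) == sign(reference$beta)
  list(result = res, pass = pass, n_excluded = sum(!keep), reason = NA_character_)
}

#' Reverse-direction MR (outcome as exposure)
#'
#' Selects genome-wide significant instruments from the outcome trait
#' (relaxing to `p_relaxed` when none reach `p_threshold`, as is needed for
#' sparse disease-subtype GWAS), clumps them, harmonizes against the
#' protein's summary statistics, and runs the standard forward machinery
#' with the roles swapped. A reverse p below `alpha` raises the
#' "potential reverse causality" flag.
#'
#' @param outcome_stats `summary_stats` of the disease trait (exposure
#'   role here).
#' @param pqtl `summary_stats` of the protein (outcome role here).
#' @param ld An `ld_matrix` for clumping (variants absent are kept).
#' @param p_threshold Primary instrument threshold (5e-8).
#' @param p_relaxed Fallback threshold (1e-5).
#' @param clump_r2,clump_window_bp Clumping parameters.
#' @param alpha Flag threshold (0.05).
#' @return List: `result` (`mr_result` or NULL), `pval`,
#'   `reverse_causality_flag`, `threshold_used`, `assessable`.
#' @export
reverse_mr <- function(outcome_stats, pqtl, ld, p_threshold = 5e-8,
                       p_relaxed = 1e-5, clump_r2 = 0.001,
                       clump_window_bp = 1e7, alpha = 0.05) {
  stopifnot(inherits(outcome_stats, "summary_stats"), inherits(pqtl, "summary_stats"))
  rec <- outcome_stats$records
  thr <- p_threshold
  iv <- rec[rec$pval < thr, , drop = FALSE]
  if (nrow(iv) == 0) {
    thr <- p_relaxed
    iv <- rec[rec$pval < thr, , drop = FALSE]
  }
  if (nrow(iv) == 0) {
    return(list(result = NULL, pval = NA_real_, reverse_causality_flag = NA,
                threshold_used = NA_real_, assessable = FALSE))
  }
  kept <- clump(iv, ld, r2 = clump_r2, window_bp = clump_window_bp,
                warn_missing = FALSE)
  iv_ss <- summary_stats(iv[match(kept, iv$variant_id), , drop = FALSE],
                         trait_id = outcome_stats$trait_id,
                         trait_type = outcome_stats$trait_type,
                         validate = FALSE)
  pair <- tryCatch(harmonize_pair(iv_ss, pqtl, ld = ld),
                   error = function(e) NULL)
  if (is.null(pair)) {
    return(list(result = NULL, pval = NA_real_, reverse_causality_flag = NA,
                threshold_used = thr, assessable = FALSE))
  }
  attr(pair, "outcome_type") <- pqtl$trait_type
  res <- mr_primary(pair)
  list(result = res, pval = res$pval,
       reverse_causality_flag = res$pval < alpha,
       threshold_used = thr, assessable = TRUE)
}

#' Run the discovery/validation MR pipeline over proteins and outcomes
#'
#' For every protein x outcome cell: select strict (r2 < 0.001) cis
#' instruments in the discovery pQTL study and estimate the causal effect
#' (Wald ratio for one instrument, random-effects IVW otherwise); repeat
#' in the validation study; confirm with GSMR on relaxed (r2 < 0.1)
#' instruments (LD-aware IVW when fewer than `gsmr_min_snps` remain,
#' `insufficient_snps` when fewer than 2); heterogeneity (Cochran Q) and
#' pleiotropy (Egger intercept) diagnostics on the relaxed set; HEIDI test
#' and colocalization across the cis region; confounder-exclusion
#' sensitivity refit; reverse MR. Discovery p-values are BH-adjusted
#' jointly across all cells; "significant" = discovery q below
#' `criteria$fdr_alpha` and validation p below `criteria$validation_alpha`
#' with the same direction; "suggestive" = nominal p < 0.05 in both pQTL
#' studies with the same direction. Each protein's associated-outcome
#' count (significant or suggestive) feeds [classify_tier()].
#'
#' @param proteins Named list of [gene_region()] objects.
#' @param discovery_pqtl,validation_pqtl Named lists of `summary_stats`
#'   per protein (names matching `proteins`).
#' @param outcome_stats Named list of `summary_stats` per outcome.
#' @param ld An `ld_matrix`, or a named list of per-protein `ld_matrix`.
#' @param selection A [selection_params()] for the strict track.
#' @param criteria A [tier_criteria()].
#' @param confounder_snps Optional exclusion table (`variant_id` column).
#' @param gsmr_clump_r2 Relaxed clumping threshold (0.1).
#' @param gsmr_min_snps Minimum SNPs for GSMR before falling back to
#'   LD-aware IVW (default 5).
#' @param outlier_alpha GSMR outlier threshold (0.01).
#' @param run_confirmation,run_heidi,run_coloc,run_sensitivity,run_reverse
#'   Stage toggles (all default TRUE); disabled stages leave their fields
#'   NA.
#' @return data.frame of class `association_table`, one row per
#'   protein x outcome with all stage results and the final `tier`.
#' @export
run_discovery_validation <- function(proteins, discovery_pqtl, validation_pqtl,
                                     outcome_stats, ld,
                                     selection = selection_params(),
                                     criteria = tier_criteria(),
                                     confounder_snps = NULL,
                                     gsmr_clump_r2 = 0.1, gsmr_min_snps = 5,
                                     outlier_alpha = 0.01,
                                     run_confirmation = TRUE, run_heidi = TRUE,
                                     run_coloc = TRUE, run_sensitivity = TRUE,
                                     run_reverse = TRUE) {
  stopifnot(length(proteins) >= 1, length(outcome_stats) >= 1)
  ld_for <- function(p) if (inherits(ld, "ld_matrix")) ld else ld[[p]]
  relaxed <- selection
  relaxed$clump_r2 <- gsmr_clump_r2

  rows <- list()
  for (p in names(proteins)) {
    region <- proteins[[p]]
    ldp <- ld_for(p)
    iv_disc <- select_cis_instruments(discovery_pqtl[[p]], region, ldp, selection)
    iv_val <- if (!is.null(validation_pqtl[[p]])) {
      select_cis_instruments(validation_pqtl[[p]], region, ldp, selection)
    } else NULL
    iv_relaxed <- if (run_confirmation) {
      select_cis_instruments(discovery_pqtl[[p]], region, ldp, relaxed)
    } else NULL

    for (o in names(outcome_stats)) {
      rows[[paste(p, o, sep = ".")]] <- evaluate_cell(
        p, o, region, discovery_pqtl[[p]], validation_pqtl[[p]],
        outcome_stats[[o]], ldp, iv_disc, iv_val, iv_relaxed,
        selection, confounder_snps, gsmr_min_snps, outlier_alpha,
        run_heidi, run_coloc, run_sensitivity, run_reverse)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL

  tab$discovery_q <- NA_real_
  ok <- !is.na(tab$discovery_pval)
  tab$discovery_q[ok] <- bh_fdr(tab$discovery_pval[ok])
  same_dir <- !is.na(tab$validation_beta) & !is.na(tab$discovery_beta) &
    sign(tab$validation_beta) == sign(tab$discovery_beta)
  tab$significant <- !is.na(tab$discovery_q) &
    tab$discovery_q < criteria$fdr_alpha &
    !is.na(tab$validation_pval) &
    tab$validation_pval < criteria$validation_alpha & same_dir
  tab$suggestive <- !tab$significant & !is.na(tab$discovery_pval) &
    tab$discovery_pval < 0.05 & !is.na(tab$validation_pval) &
    tab$validation_pval < 0.05 & same_dir

  assoc <- tab$significant | tab$suggestive
  cnt <- tapply(assoc, tab$protein, sum)
  tab$outcomes_associated_count <- as.integer(cnt[tab$protein])

  tab$tier <- classify_tier(tab, criteria)
  class(tab) <- c("association_table", "data.frame")
  tab
}

evaluate_cell <- function(p, o, region, disc_ss, val_ss, out_ss, ldp,
                          iv_disc, iv_val, iv_relaxed, selection,
                          confounder_snps, gsmr_min_snps, outlier_alpha,
                          run_heidi, run_coloc, run_sensitivity,
                          run_reverse) {
  na_res <- list(beta = NA_real_, se = NA_real_, pval = NA_real_,
                 odds_ratio = NA_real_, n_snps = 0L, method = NA_character_)
  cell <- data.frame(protein = p, outcome = o, stringsAsFactors = FALSE)
  notes <- character(0)

  pair_of <- function(iv, ss) {
    if (is.null(iv) || iv$empty) return(NULL)
    iv_ss <- summary_stats(iv$variants[names(iv$variants) != "f_stat"],
                           trait_id = p, trait_type = ss$trait_type,
                           validate = FALSE)
    pr <- tryCatch(harmonize_pair(iv_ss, out_ss, ld = ldp),
                   error = function(e) NULL)
    if (!is.null(pr)) {
      attr(pr, "n_x") <- stats::median(iv$variants$n, na.rm = TRUE)
      attr(pr, "n_y") <- stats::median(out_ss$records$n, na.rm = TRUE)
    }
    pr
  }

  disc_pair <- pair_of(iv_disc, disc_ss)
  disc <- if (!is.null(disc_pair)) mr_primary(disc_pair) else na_res
  if (is.null(disc_pair)) notes <- c(notes, "no discovery instruments")

  val_pair <- if (!is.null(val_ss)) pair_of(iv_val, val_ss) else NULL
  val <- if (!is.null(val_pair)) mr_primary(val_pair) else na_res

  # confirmation on the relaxed instrument track
  rel_pair <- pair_of(iv_relaxed, disc_ss)
  conf_status <- "insufficient_snps"
  conf <- na_res; conf_method <- NA_character_
  Q_pval <- NA_real_; intercept_pval <- NA_real_
  if (!is.null(rel_pair) && nrow(rel_pair) >= 2) {
    if (nrow(rel_pair) >= gsmr_min_snps) {
      g <- tryCatch(gsmr_fit(rel_pair, ldp, outlier_alpha = outlier_alpha),
                    error = function(e) NULL)
      if (!is.null(g)) {
        conf <- list(beta = g$beta, se = g$se, pval = g$pval,
                     n_snps = g$n_snps_used)
        conf_method <- "gsmr"
      }
    }
    if (is.na(conf_method)) {
      ci <- tryCatch(ivw_correlated(rel_pair, ldp), error = function(e) NULL)
      if (!is.null(ci)) {
        conf <- list(beta = ci$beta, se = ci$se, pval = ci$pval,
                     n_snps = ci$n_snps)
        conf_method <- "ivw_correlated"
      }
    }
    if (!is.na(conf_method) && !is.na(disc$beta)) {
      conf_status <- if (conf$pval < 0.05 && sign(conf$beta) == sign(disc$beta)) {
        "confirmed"
      } else "failed"
    }
    ivw_rel <- tryCatch(mr_ivw(rel_pair), error = function(e) NULL)
    if (!is.null(ivw_rel)) Q_pval <- ivw_rel$Q_pval
    if (nrow(rel_pair) >= 3) {
      eg <- tryCatch(mr_egger(rel_pair), error = function(e) NULL)
      if (!is.null(eg)) intercept_pval <- eg$intercept_pval
    }
  }

  # region-wide pair (all cis variants, no instrument filtering) for
  # HEIDI and colocalization
  region_pair <- if (!run_heidi && !run_coloc && !run_sensitivity) NULL else tryCatch({
    cis <- disc_ss$records[disc_ss$records$chrom == region$chrom &
                             disc_ss$records$pos >= region$start - selection$cis_flank_bp &
                             disc_ss$records$pos <= region$end + selection$cis_flank_bp, ]
    harmonize_pair(summary_stats(cis, p, disc_ss$trait_type, validate = FALSE),
                   out_ss)
  }, error = function(e) NULL)

  heidi_pval <- NA_real_
  pp_h4 <- NA_real_
  if (!is.null(region_pair) && run_heidi) {
    hd <- tryCatch(heidi_test(region_pair, ld = ldp), error = function(e) NULL)
    if (!is.null(hd) && hd$assessable) heidi_pval <- hd$pval
  }
  if (!is.null(region_pair) && run_coloc) {
    cl <- tryCatch(coloc_abf(
      data.frame(variant_id = region_pair$variant_id,
                 beta = region_pair$beta_x, se = region_pair$se_x),
      data.frame(variant_id = region_pair$variant_id,
                 beta = region_pair$beta_y, se = region_pair$se_y),
      sd1 = if (disc_ss$trait_type == "binary") 0.2 else 0.15,
      sd2 = if (out_ss$trait_type == "binary") 0.2 else 0.15),
      error = function(e) NULL)
    if (!is.null(cl)) pp_h4 <- unname(cl$pp["H4"])
  }

  sens_pass <- NA; sens_pval <- NA_real_
  if (run_sensitivity && !is.null(region_pair) && !is.na(disc$beta)) {
    cand <- region_pair[!is.na(region_pair$pval_x) &
                          region_pair$pval_x < selection$p_threshold, ,
                        drop = FALSE]
    if (nrow(cand) > 0) {
      sf <- sensitivity_confounder_filter(
        harmonized_pair(as.data.frame(cand), outcome_type = out_ss$trait_type),
        confounder_snps, ldp, disc,
        clump_r2 = selection$clump_r2,
        clump_window_bp = selection$clump_window_bp)
      sens_pass <- sf$pass
      if (!is.null(sf$result)) sens_pval <- sf$result$pval
      if (!is.na(sf$reason)) notes <- c(notes, sf$reason)
    }
  }

  rev_pval <- NA_real_; rev_flag <- NA
  if (run_reverse && !is.null(disc_ss)) {
    rv <- reverse_mr(out_ss, disc_ss, ldp)
    if (rv$assessable) {
      rev_pval <- rv$pval; rev_flag <- rv$reverse_causality_flag
    }
  }

  steiger <- if (!is.null(disc_pair)) steiger_test(disc_pair) else NULL

  cbind(cell, data.frame(
    discovery_method = if (!is.null(disc_pair)) disc$method else NA_character_,
    discovery_n_snps = if (!is.null(disc_pair)) disc$n_snps else 0L,
    discovery_beta = disc$beta, discovery_se = disc$se,
    discovery_pval = disc$pval,
    discovery_or = if (!is.null(disc$odds_ratio)) disc$odds_ratio else NA_real_,
    validation_beta = val$beta, validation_se = val$se,
    validation_pval = val$pval,
    confirmation_method = conf_method, confirmation_beta = conf$beta,
    confirmation_pval = conf$pval, confirmation_status = conf_status,
    Q_pval = Q_pval, intercept_pval = intercept_pval,
    heidi_pval = heidi_pval, pp_h4 = pp_h4,
    sensitivity_pass = sens_pass, sensitivity_pval = sens_pval,
    steiger_direction = if (!is.null(steiger)) steiger$direction else NA_character_,
    steiger_pval = if (!is.null(steiger)) steiger$pval else NA_real_,
    reverse_pval = rev_pval, reverse_flag = rev_flag,
    notes = paste(notes, collapse = "; "),
    stringsAsFactors = FALSE))
}

#' Run the full pipeline from a configuration file
#'
#' Reads a YAML configuration naming the input files, thresholds, seed and
#' output directory, executes [run_discovery_validation()], and writes
#' `associations.tsv` plus a JSON run manifest. Identical configuration and
#' seed give byte-identical outputs.
#'
#' Configuration keys: `genes` (annotation TSV), `discovery`/`validation`
#' (maps protein id -> summary-stats TSV), `outcomes` (map outcome id ->
#' TSV), `ld_matrix`/`ld_variants` (LD reference files), optional
#' `confounder_snps` TSV, optional `selection`/`criteria` overrides
#' (field = value), `seed`, `outdir`.
#'
#' @param config Path to a YAML file, or an equivalent named list.
#' @return The association table, invisibly; side effect: files in
#'   `outdir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$outdir), !is.null(config$seed))
  set.seed(as.integer(config$seed))

  regions <- read_gene_regions(config$genes)
  read_map <- function(m, type) {
    out <- lapply(m, read_summary_stats, trait_type = type)
    names(out) <- names(m)
    out
  }
  disc <- read_map(config$discovery, "quantitative")
  val <- if (!is.null(config$validation)) read_map(config$validation, "quantitative") else NULL
  outs <- read_map(config$outcomes, config$outcome_type %||% "binary")
  ld <- read_ld_matrix(config$ld_matrix, config$ld_variants)
  conf_snps <- if (!is.null(config$confounder_snps)) {
    utils::read.table(config$confounder_snps, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else NULL

  sel <- do.call(selection_params, config$selection %||% list())
  crit <- do.call(tier_criteria, config$criteria %||% list())

  tab <- run_discovery_validation(regions[names(disc)], disc, val, outs, ld,
                                  selection = sel, criteria = crit,
                                  confounder_snps = conf_snps)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out_tsv <- file.path(config$outdir, "associations.tsv")
  df <- as.data.frame(tab)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 10))
  utils::write.table(df, out_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  manifest <- list(
    package = "pwmr",
    seed = as.integer(config$seed),
    n_proteins = length(disc), n_outcomes = length(outs),
    n_cells = nrow(tab),
    n_significant = sum(tab$significant, na.rm = TRUE),
    tier_counts = as.list(table(factor(tab$tier, levels = 1:3))),
    selection = unclass(sel), criteria = unclass(crit))
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(tab)
}
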