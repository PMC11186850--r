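# Synthetic GWAS/pQTL summary statistics with known causal architecture.
# Effects live on the standardized-genotype scale internally; emitted
# betas are per-allele (scaled by 1/sqrt(2 maf (1-maf))) so the files look
# like real GWAS output. Marginal standardized effects are R %*% joint
# effects; observed z-scores are MVN around the true z with covariance R.

#' Simulation configuration
#'
#' @param n_snps Number of variants in the region.
#' @param ld_model List describing LD: `list(model = "identity")`,
#'   `list(model = "ar1", rho = ...)`, or
#'   `list(model = "blocks", sizes = c(...), rhos = c(...))`.
#' @param maf_range Uniform MAF sampling range (default `c(0.01, 0.5)`).
#' @param n_x Exposure (quantitative trait) sample size.
#' @param n_x_val Optional sample size of an independent validation
#'   exposure study measuring the same protein (same true effects, fresh
#'   sampling noise); `NULL` to skip.
#' @param n_case,n_control Outcome case/control counts; effective
#'   `n = 4/(1/n_case + 1/n_control)`.
#' @param causal_x data.frame `index`, `beta`: joint standardized effects
#'   on the exposure.
#' @param causal_y data.frame `index`, `beta`: direct (not exposure-
#'   mediated) joint effects on the outcome log-odds — distinct causal
#'   variants, horizontal pleiotropy, or the outcome's own genetics.
#' @param causal_beta Causal effect of exposure on outcome, log-odds per
#'   SD of exposure.
#' @param reverse_beta Causal effect of outcome liability on exposure (for
#'   reverse-causation scenarios); exposure joint effects become
#'   `causal_x + reverse_beta * causal_y`.
#' @param chrom,pos_start,pos_step Variant coordinates.
#' @param label Scenario label carried into the truth record.
#' @param seed Mandatory RNG seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps, ld_model = list(model = "ar1", rho = 0.5),
                       maf_range = c(0.01, 0.5),
                       n_x = 35559, n_x_val = NULL,
                       n_case = 2000, n_control = 20000,
                       causal_x = data.frame(index = integer(0), beta = numeric(0)),
                       causal_y = data.frame(index = integer(0), beta = numeric(0)),
                       causal_beta = 0, reverse_beta = 0,
                       chrom = "1", pos_start = 1e6, pos_step = 2000,
                       label = "custom", seed) {
  if (missing(seed) || length(seed) != 1 || is.na(seed)) {
    stop("sim_config: seed is mandatory", call. = FALSE)
  }
  stopifnot(n_snps >= 1, n_x > 3, n_case > 0, n_control > 0,
            maf_range[1] > 0, maf_range[2] <= 0.5)
  rhos <- c(ld_model$rho, ld_model$rhos)
  if (length(rhos) > 0 && any(abs(rhos) >= 1)) {
    stop("sim_config: LD rho must be in (-1, 1)", call. = FALSE)
  }
  check_idx <- function(df, what) {
    if (nrow(df) > 0 && (any(df$index < 1) || any(df$index > n_snps))) {
      stop("sim_config: ", what, " causal index outside region", call. = FALSE)
    }
  }
  check_idx(causal_x, "exposure"); check_idx(causal_y, "outcome")
  if (reverse_beta != 0 && causal_beta != 0) {
    stop("sim_config: forward and reverse causal effects are mutually exclusive",
         call. = FALSE)
  }
  structure(list(n_snps = as.integer(n_snps), ld_model = ld_model,
                 maf_range = maf_range, n_x = n_x, n_x_val = n_x_val,
                 n_case = n_case,
                 n_control = n_control, causal_x = causal_x,
                 causal_y = causal_y, causal_beta = causal_beta,
                 reverse_beta = reverse_beta, chrom = as.character(chrom),
                 pos_start = pos_start, pos_step = pos_step,
                 label = label, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an LD correlation matrix
#'
#' `identity`; `ar1` with `r_ij = rho^|i-j|`; or constant-correlation
#' `blocks`. All are positive semi-definite by construction.
#'
#' @param config A [sim_config()] (or a bare `ld_model` list plus
#'   `n_snps`).
#' @param n_snps Required when `config` is a bare model list.
#' @return An `ld_matrix` with variant ids `rs1..rsN` and A/G alleles.
#' @export
simulate_ld <- function(config, n_snps = NULL) {
  if (inherits(config, "sim_config")) {
    model <- config$ld_model; m <- config$n_snps
  } else {
    model <- config; m <- n_snps
  }
  r <- switch(model$model,
    identity = diag(m),
    ar1 = model$rho^abs(outer(seq_len(m), seq_len(m), "-")),
    blocks = {
      stopifnot(sum(model$sizes) == m, length(model$sizes) == length(model$rhos))
      blocks <- mapply(function(s, rho) {
        b <- matrix(rho, s, s); diag(b) <- 1; b
      }, model$sizes, model$rhos, SIMPLIFY = FALSE)
      out <- matrix(0, m, m)
      at <- 0
      for (b in blocks) {
        idx <- at + seq_len(nrow(b))
        out[idx, idx] <- b
        at <- at + nrow(b)
      }
      out
    },
    stop("simulate_ld: unknown LD model '", model$model, "'", call. = FALSE))
  ids <- paste0("rs", seq_len(m))
  ld_matrix(r, ids, alleles = data.frame(ea = rep("A", m), oa = rep("G", m)))
}

joint_effects <- function(config) {
  bx <- numeric(config$n_snps)
  byd <- numeric(config$n_snps)
  if (nrow(config$causal_x) > 0) bx[config$causal_x$index] <- config$causal_x$beta
  if (nrow(config$causal_y) > 0) byd[config$causal_y$index] <- config$causal_y$beta
  bx_joint <- bx + config$reverse_beta * byd
  by_joint <- config$causal_beta * bx_joint + byd
  list(bx = bx_joint, by = by_joint)
}

#' Simulate exposure and outcome summary statistics
#'
#' Generates LD-correlated marginal summary statistics for a quantitative
#' exposure (pQTL-like) and a binary outcome (log-odds scale) in one cis
#' region, under the configured causal architecture. True marginal
#' standardized effects are `R %*% joint`; observed z-scores are drawn
#' `MVN(z_true, R)`; betas/SEs are reconstructed on the per-allele scale
#' from the sampled allele frequencies. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return List: `exposure` and `outcome` (`summary_stats`), `ld`
#'   (`ld_matrix`), `truth` (joint and true marginal standardized effects,
#'   MAFs, scenario label, effective outcome n).
#' @export
simulate_summary_stats <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    m <- config$n_snps
    ld <- simulate_ld(config)
    R <- ld$r
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    eff <- joint_effects(config)
    mx <- drop(R %*% eff$bx)
    my <- drop(R %*% eff$by)

    n_eff <- 4 / (1 / config$n_case + 1 / config$n_control)
    se_x_std <- 1 / sqrt(config$n_x)
    se_y_std <- 2 / sqrt(n_eff)

    L <- chol_psd(R)
    z_x <- mx / se_x_std + drop(crossprod(L, stats::rnorm(m)))
    z_y <- my / se_y_std + drop(crossprod(L, stats::rnorm(m)))

    allele_scale <- 1 / sqrt(2 * maf * (1 - maf))
    mk <- function(z, se_std, n, n_case = NA, n_control = NA, trait_id, type) {
      se <- se_std * allele_scale
      records <- data.frame(
        variant_id = ld$variant_ids, chrom = config$chrom,
        pos = config$pos_start + (seq_len(m) - 1) * config$pos_step,
        ea = "A", oa = "G", eaf = maf,
        beta = z * se, se = se,
        pval = pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin), n = n,
        n_case = n_case, n_control = n_control)
      summary_stats(records, trait_id = trait_id, trait_type = type,
                    provenance = paste0("simulated scenario ", config$label,
                                        ", seed ", config$seed))
    }
    exposure_val <- NULL
    if (!is.null(config$n_x_val)) {
      se_val_std <- 1 / sqrt(config$n_x_val)
      z_val <- mx / se_val_std + drop(crossprod(L, stats::rnorm(m)))
      exposure_val <- mk(z_val, se_val_std, config$n_x_val,
                         trait_id = "exposure_validation", type = "quantitative")
    }
    list(
      exposure = mk(z_x, se_x_std, config$n_x,
                    trait_id = "exposure", type = "quantitative"),
      exposure_validation = exposure_val,
      outcome = mk(z_y, se_y_std, config$n_case + config$n_control,
                   config$n_case, config$n_control,
                   trait_id = "outcome", type = "binary"),
      ld = ld,
      truth = list(label = config$label, maf = maf,
                   joint_x = eff$bx, joint_y = eff$by,
                   marginal_x = mx, marginal_y = my,
                   n_eff_outcome = n_eff, se_x_std = se_x_std,
                   se_y_std = se_y_std, causal_beta = config$causal_beta))
  })
}

chol_psd <- function(R, jitter = 1e-8) {
  tryCatch(chol(R), error = function(e) {
    chol(R + diag(jitter * nrow(R), nrow(R)))
  })
}

#' Named scenario presets
#'
#' Fully populated [sim_config()]s for the canonical colocalization
#' hypotheses and the MR failure modes:
#' `H0` no association; `H1` exposure-only causal variant; `H2`
#' outcome-only; `H3` two distinct causal variants in LD; `H4` one shared
#' causal variant; `pleiotropy` a valid causal effect plus a directional
#' direct-effect variant; `invalid_instruments` 40% of instruments given
#' direct outcome effects; `reverse` outcome liability drives the
#' exposure; `confounded` one variant acting on both traits through a
#' confounder.
#'
#' `scale = "paper_like"` uses a 35,559-sample exposure study and
#' 79,495 cases / 1,259,808 controls; `"small"` keeps the exposure study
#' and scales the case/control counts 40x down (2,000 / 20,000), with
#' shared-variant outcome effects enlarged so the region retains a
#' genome-wide-significant outcome signal at desk scale.
#'
#' @param name Preset name (see above).
#' @param scale `"small"` (default) or `"paper_like"`.
#' @param seed RNG seed.
#' @return A [sim_config()].
#' @export
scenario_preset <- function(name = c("H0", "H1", "H2", "H3", "H4",
                                     "pleiotropy", "invalid_instruments",
                                     "reverse", "confounded"),
                            scale = c("small", "paper_like"), seed) {
  name <- match.arg(name)
  scale <- match.arg(scale)
  if (missing(seed)) stop("scenario_preset: seed is mandatory", call. = FALSE)
  sizes <- if (scale == "paper_like") {
    list(n_x = 35559, n_case = 79495, n_control = 1259808, b_out = 0.025)
  } else {
    # case/control 40x down; direct outcome effects enlarged to keep the
    # causal variant's outcome z-score near its full-scale value (~6)
    list(n_x = 35559, n_case = 2000, n_control = 20000, b_out = 0.16)
  }
  m <- 60
  base <- function(...) {
    sim_config(n_snps = m, ld_model = list(model = "ar1", rho = 0.5),
               n_x = sizes$n_x, n_case = sizes$n_case,
               n_control = sizes$n_control, seed = seed, label = name, ...)
  }
  bx <- 0.15   # shared causal variant: ~2% of exposure variance
  mid <- 30L
  iv_idx <- seq(3L, 57L, by = 6L)   # 10 well-separated instruments
  switch(name,
    H0 = base(),
    H1 = base(causal_x = data.frame(index = mid, beta = bx)),
    H2 = base(causal_y = data.frame(index = mid, beta = sizes$b_out)),
    H3 = base(causal_x = data.frame(index = mid, beta = bx),
              causal_y = data.frame(index = mid + 2L, beta = sizes$b_out)),
    H4 = base(causal_x = data.frame(index = mid, beta = bx),
              causal_beta = sizes$b_out / bx),
    pleiotropy = base(causal_x = data.frame(index = iv_idx, beta = 0.12),
                      causal_beta = 0.1,
                      causal_y = data.frame(index = 15L, beta = 0.05)),
    invalid_instruments = base(
      causal_x = data.frame(index = iv_idx, beta = 0.12),
      causal_beta = 0.1,
      causal_y = data.frame(index = iv_idx[1:4], beta = 0.08)),
    reverse = base(causal_y = data.frame(index = iv_idx, beta = sizes$b_out),
                   reverse_beta = 0.3),
    confounded = base(causal_x = data.frame(index = iv_idx, beta = 0.12),
                      causal_beta = 0.1,
                      causal_y = data.frame(index = iv_idx[5], beta = 0.12)))
}

#' Simulate individual-level genotypes and phenotypes
#'
#' Validation oracle for the summary-level generator: latent-Gaussian
#' haplotypes with the configured LD are thresholded at the MAF quantile
#' to give 0/1/2 dosages; the quantitative exposure follows the linear
#' model on standardized dosages, the binary outcome a logistic model.
#'
#' @param config A [sim_config()].
#' @param n_samples Number of individuals (>= 100).
#' @return List: `dosages` (variants x samples), `maf`, `exposure`
#'   (numeric), `outcome` (0/1), `ld` (the generating `ld_matrix`).
#' @export
simulate_individual_level <- function(config, n_samples) {
  stopifnot(inherits(config, "sim_config"), n_samples >= 100)
  with_seed(config$seed + 1L, {
    m <- config$n_snps
    ld <- simulate_ld(config)
    L <- chol_psd(ld$r)
    maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
    hap <- function() {
      z <- crossprod(L, matrix(stats::rnorm(m * n_samples), m, n_samples))
      (z < stats::qnorm(maf)) * 1
    }
    g <- hap() + hap()
    rownames(g) <- ld$variant_ids

    gs <- (g - 2 * maf) / sqrt(2 * maf * (1 - maf))
    eff <- joint_effects(config)
    eta_x <- drop(crossprod(gs, eff$bx))
    var_g <- stats::var(eta_x)
    exposure <- eta_x + stats::rnorm(n_samples, 0, sqrt(max(1 - var_g, 0.05)))

    case_frac <- config$n_case / (config$n_case + config$n_control)
    # the causal path acts through the exposure phenotype (including its
    # noise), the direct path through the genotypes alone
    eta_y <- drop(crossprod(gs, eff$by - config$causal_beta * eff$bx)) +
      config$causal_beta * exposure
    intercept <- stats::qlogis(case_frac)
    outcome <- stats::rbinom(n_samples, 1, stats::plogis(intercept + eta_y))
    list(dosages = g, maf = maf, exposure = exposure, outcome = outcome, ld = ld)
  })
}

#' Per-SNP marginal summary statistics from individual-level data
#'
#' Runs one marginal regression per variant (linear for quantitative,
#' logistic for binary phenotypes) on per-allele dosages.
#'
#' @param dosages Variant x sample dosage matrix.
#' @param phenotype Numeric vector (0/1 for binary).
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param chrom,pos_start,pos_step Coordinates for the emitted records.
#' @return A `summary_stats` object.
#' @export
marginal_summary_stats <- function(dosages, phenotype,
                                   trait_type = c("quantitative", "binary"),
                                   chrom = "1", pos_start = 1e6,
                                   pos_step = 2000) {
  trait_type <- match.arg(trait_type)
  m <- nrow(dosages)
  n <- ncol(dosages)
  est <- matrix(NA_real_, m, 2)
  for (i in seq_len(m)) {
    g <- dosages[i, ]
    fit <- if (trait_type == "quantitative") {
      stats::lm(phenotype ~ g)
    } else {
      stats::glm(phenotype ~ g, family = stats::binomial())
    }
    est[i, ] <- summary(fit)$coefficients["g", 1:2]
  }
  maf <- rowMeans(dosages) / 2
  records <- data.frame(
    variant_id = rownames(dosages) %||% paste0("rs", seq_len(m)),
    chrom = chrom, pos = pos_start + (seq_len(m) - 1) * pos_step,
    ea = "A", oa = "G", eaf = maf, beta = est[, 1], se = est[, 2],
    pval = 2 * stats::pnorm(-abs(est[, 1] / est[, 2])), n = n,
    n_case = if (trait_type == "binary") sum(phenotype) else NA,
    n_control = if (trait_type == "binary") sum(phenotype == 0) else NA)
  summary_stats(records, trait_id = "individual_level", trait_type = trait_type,
                provenance = "marginal regressions on simulated dosages")
}

#' Simulate a multi-protein study for pipeline testing
#'
#' Builds pipeline-ready inputs for a set of proteins, one cis region per
#' protein (each on its own chromosome with its own LD block), a discovery
#' and an independent validation pQTL study per protein, and a single
#' binary-outcome GWAS covering all regions. Discovery and validation
#' study sizes default to the two-study design the package targets
#' (7,213 and 35,559).
#'
#' @param scenarios Named character vector mapping protein id to a
#'   [scenario_preset()] name.
#' @param scale Preset scale (`"small"` or `"paper_like"`).
#' @param seed Base seed; protein k uses `seed + k`.
#' @param n_x_discovery,n_x_validation Exposure study sizes.
#' @return List with `proteins` (named [gene_region()] list), `discovery`,
#'   `validation` (named `summary_stats` lists), `outcome`
#'   (single combined `summary_stats`), `ld` (named `ld_matrix` list),
#'   `truth` (per-protein truth records).
#' @export
simulate_proteome <- function(scenarios, scale = "small", seed,
                              n_x_discovery = 7213, n_x_validation = 35559) {
  if (missing(seed)) stop("simulate_proteome: seed is mandatory", call. = FALSE)
  stopifnot(!is.null(names(scenarios)), all(nzchar(names(scenarios))))
  proteins <- list(); discovery <- list(); validation <- list()
  ld <- list(); truth <- list(); outcome_recs <- list()
  for (k in seq_along(scenarios)) {
    p <- names(scenarios)[k]
    cfg <- scenario_preset(scenarios[[k]], scale = scale, seed = seed + k)
    cfg$n_x <- n_x_discovery
    cfg$n_x_val <- n_x_validation
    cfg$chrom <- as.character(k)
    s <- simulate_summary_stats(cfg)

    prefix <- function(ss) {
      ss$records$variant_id <- paste0(p, "_", ss$records$variant_id)
      ss
    }
    discovery[[p]] <- prefix(s$exposure)
    discovery[[p]]$trait_id <- p
    validation[[p]] <- prefix(s$exposure_validation)
    validation[[p]]$trait_id <- p
    oc <- prefix(s$outcome)
    outcome_recs[[p]] <- oc$records
    ldp <- s$ld
    ldp$variant_ids <- paste0(p, "_", ldp$variant_ids)
    dimnames(ldp$r) <- list(ldp$variant_ids, ldp$variant_ids)
    ld[[p]] <- ldp
    span <- range(s$exposure$records$pos)
    proteins[[p]] <- gene_region(p, cfg$chrom, span[1] + 20000, span[2] - 20000)
    truth[[p]] <- s$truth
  }
  outcome <- summary_stats(do.call(rbind, outcome_recs), trait_id = "disease",
                           trait_type = "binary",
                           provenance = "simulated multi-region outcome GWAS",
                           validate = FALSE)
  list(proteins = proteins, discovery = discovery, validation = validation,
       outcome = outcome, ld = ld, truth = truth)
}

#' Write a simulated proteome study to disk as pipeline input files
#'
#' Emits the tab-delimited file set [run_pipeline()] consumes: a gene
#' annotation table, per-protein discovery/validation summary statistics,
#' the combined outcome GWAS, and a block-diagonal LD reference, and
#' returns a ready configuration list.
#'
#' @param sim Output of [simulate_proteome()].
#' @param dir Output directory (created if needed).
#' @param seed Seed to record in the configuration.
#' @return A configuration list for [run_pipeline()] (without `outdir`).
#' @export
write_proteome_files <- function(sim, dir, seed = 1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  genes <- do.call(rbind, lapply(sim$proteins, function(g) {
    data.frame(gene_id = g$gene_id, chrom = g$chrom, start = g$start,
               end = g$end)
  }))
  genes_path <- file.path(dir, "genes.tsv")
  utils::write.table(genes, genes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  disc <- list(); val <- list()
  for (p in names(sim$discovery)) {
    disc[[p]] <- file.path(dir, paste0(p, "_discovery.tsv"))
    write_summary_stats(sim$discovery[[p]], disc[[p]])
    val[[p]] <- file.path(dir, paste0(p, "_validation.tsv"))
    write_summary_stats(sim$validation[[p]], val[[p]])
  }
  outcome_path <- file.path(dir, "outcome.tsv")
  write_summary_stats(sim$outcome, outcome_path)
  ld_path <- file.path(dir, "ld.tsv")
  ldvar_path <- file.path(dir, "ld_variants.tsv")
  write_ld_matrix(ld_block_diag(sim$ld), ld_path, ldvar_path)
  list(genes = genes_path, discovery = disc, validation = val,
       outcomes = list(disease = outcome_path),
       ld_matrix = ld_path, ld_variants = ldvar_path, seed = seed)
}
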