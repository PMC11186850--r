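# Small builders shared across tests. Everything is generated in code; no
# stored fixtures beyond the packaged published-association table.

toy_records <- function(n = 3, chrom = "1", pos = NULL, ea = "A", oa = "G",
                        eaf = 0.3, beta = 0.1, se = 0.02, pval = NULL,
                        nn = 10000, ids = NULL) {
  pos <- pos %||% (1e6 + (seq_len(n) - 1) * 1000)
  df <- data.frame(
    variant_id = ids %||% paste0("rs", seq_len(n)),
    chrom = chrom, pos = pos,
    ea = rep_len(ea, n), oa = rep_len(oa, n),
    eaf = rep_len(eaf, n), beta = rep_len(beta, n), se = rep_len(se, n),
    pval = NA, n = nn, stringsAsFactors = FALSE)
  df$pval <- pval %||% pmax(2 * pnorm(-abs(df$beta / df$se)), 1e-300)
  df
}

toy_stats <- function(..., trait_id = "trait", trait_type = "quantitative") {
  summary_stats(toy_records(...), trait_id = trait_id, trait_type = trait_type)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_ld <- function(r, ids = NULL, ea = "A", oa = "G") {
  n <- nrow(r)
  ids <- ids %||% paste0("rs", seq_len(n))
  ld_matrix(r, ids, alleles = data.frame(ea = rep_len(ea, n),
                                         oa = rep_len(oa, n)))
}

# exposure/outcome pair with exact per-SNP effects, bypassing file plumbing
toy_pair <- function(beta_x, se_x, beta_y, se_y, ...) {
  harmonized_pair(data.frame(beta_x = beta_x, se_x = se_x,
                             beta_y = beta_y, se_y = se_y), ...)
}
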