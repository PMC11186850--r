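# Summary-statistic containers and TSV I/O.

#' Canonical summary-statistic columns
#'
#' Column names used internally for per-variant GWAS/pQTL association
#' records: `variant_id`, `chrom`, `pos` (1-based), `ea` (effect allele),
#' `oa` (other allele), `eaf` (effect-allele frequency), `beta` (per-allele
#' effect, log-odds for binary traits), `se`, `pval`, `n`, and the optional
#' `n_case`/`n_control` for binary traits.
#'
#' @return Character vector of required column names.
#' @export
ss_required_columns <- function() {
  c("variant_id", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "pval", "n")
}

ss_optional_columns <- function() c("n_case", "n_control")

#' Construct a summary_stats object
#'
#' Validates per-variant association records for one trait and bundles them
#' with trait metadata. Rows violating basic invariants (missing beta/se or
#' alleles, `se <= 0`, non-SNP alleles, `eaf` outside (0,1), `pval` outside
#' (0,1]) are dropped and counted in the attached load report. Records are
#' sorted by chromosome and position; `variant_id` must be unique.
#'
#' @param records data.frame with the columns of [ss_required_columns()]
#'   (plus optional `n_case`, `n_control`).
#' @param trait_id Trait identifier string.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param provenance Free-text metadata string.
#' @param validate Drop invalid rows and build a load report (default TRUE).
#' @return An object of class `summary_stats`: a list with elements
#'   `trait_id`, `trait_type`, `records` (validated data.frame),
#'   `provenance`, `load_report` (data.frame of rejection counts by rule).
#' @export
summary_stats <- function(records, trait_id, trait_type = c("quantitative", "binary"),
                          provenance = "", validate = TRUE) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(ss_required_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop("summary_stats: missing required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in ss_optional_columns()) {
    if (!col %in% names(records)) records[[col]] <- NA_integer_
  }
  records <- records[c(ss_required_columns(), ss_optional_columns())]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$ea <- toupper(as.character(records$ea))
  records$oa <- toupper(as.character(records$oa))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n", "n_case", "n_control")) {
    records[[col]] <- suppressWarnings(as.numeric(records[[col]]))
  }

  report <- data.frame(rule = character(0), n_dropped = integer(0))
  if (validate) {
    drop_rule <- function(df, keep, rule) {
      keep[is.na(keep)] <- FALSE
      if (any(!keep)) {
        report <<- rbind(report, data.frame(rule = rule, n_dropped = sum(!keep)))
      }
      df[keep, , drop = FALSE]
    }
    snp_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
    records <- drop_rule(records, !is.na(records$beta) & !is.na(records$se),
                         "missing_beta_or_se")
    records <- drop_rule(records, records$se > 0, "nonpositive_se")
    records <- drop_rule(records, snp_allele(records$ea) & snp_allele(records$oa) &
                           records$ea != records$oa, "non_snp_alleles")
    records <- drop_rule(records, is.na(records$eaf) |
                           (records$eaf > 0 & records$eaf < 1), "eaf_out_of_range")
    records <- drop_rule(records, is.na(records$pval) |
                           (records$pval >= 0 & records$pval <= 1), "pval_out_of_range")
    # underflowed p-values (printed as 0) are clamped, not rejected
    records$pval[!is.na(records$pval) & records$pval == 0] <- .Machine$double.xmin
  }
  if (nrow(records) == 0) {
    stop("summary_stats: zero valid rows for trait '", trait_id, "'", call. = FALSE)
  }
  if (anyDuplicated(records$variant_id)) {
    stop("summary_stats: duplicate variant_id in trait '", trait_id, "'", call. = FALSE)
  }
  records <- records[order(records$chrom, records$pos, records$variant_id), ,
                     drop = FALSE]
  rownames(records) <- NULL
  structure(
    list(trait_id = trait_id, trait_type = trait_type, records = records,
         provenance = provenance, load_report = report),
    class = "summary_stats"
  )
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: trait '%s' (%s), %d variants\n",
              x$trait_id, x$trait_type, nrow(x$records)))
  if (nrow(x$load_report) > 0) {
    cat("rows dropped at load:\n")
    print(x$load_report, row.names = FALSE)
  }
  invisible(x)
}

#' Read GWAS/pQTL summary statistics from a delimited file
#'
#' Reads a tab- or comma-delimited file with a header into a
#' [summary_stats()] object. Non-canonical column names are resolved through
#' `column_map`; rows failing validation are dropped and counted in the load
#' report.
#'
#' @param path File path. The delimiter is taken from the header line
#'   (tab if present, else comma).
#' @param column_map Named character vector mapping canonical names (see
#'   [ss_required_columns()]) to the file's column names, e.g.
#'   `c(variant_id = "SNP", ea = "A1")`. Unmapped canonical names are looked
#'   up verbatim.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @param trait_id Trait identifier; defaults to the file base name.
#' @return A `summary_stats` object.
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("quantitative", "binary"),
                               trait_id = NULL) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("summary-statistics file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, na.strings = c("NA", "."),
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  wanted <- c(ss_required_columns(), ss_optional_columns())
  resolved <- stats::setNames(wanted, wanted)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), wanted)
    if (length(bad) > 0) {
      stop("read_summary_stats: unknown canonical names in column_map: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    resolved[names(column_map)] <- column_map
  }
  missing_req <- ss_required_columns()[!resolved[ss_required_columns()] %in% names(raw)]
  if (length(missing_req) > 0) {
    stop("read_summary_stats: cannot resolve required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in wanted) {
    src <- resolved[[canon]]
    out[[canon]] <- if (src %in% names(raw)) raw[[src]] else NA
  }
  summary_stats(out, trait_id = trait_id %||% sub("\\.[^.]*$", "", basename(path)),
                trait_type = trait_type,
                provenance = paste0("read from ", path))
}

#' Write summary statistics as tab-delimited text
#'
#' Emits the same dialect [read_summary_stats()] accepts: UTF-8,
#' tab-separated, `.` for missing values, canonical column names.
#'
#' @param x A `summary_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  stopifnot(inherits(x, "summary_stats"))
  utils::write.table(x$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
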