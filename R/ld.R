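# Signed LD correlation matrices: construction, regularization, I/O.

#' Construct an ld_matrix object
#'
#' A signed pairwise correlation matrix among variants, with the allele pair
#' the signs refer to. The matrix must be symmetric with unit diagonal.
#'
#' @param r Square numeric matrix of correlations in `[-1, 1]`.
#' @param variant_ids Character vector of variant ids (row/column order).
#' @param alleles Optional data.frame with columns `ea`, `oa` giving the
#'   effect/other allele orientation the correlation signs refer to.
#' @return An object of class `ld_matrix`.
#' @export
ld_matrix <- function(r, variant_ids, alleles = NULL) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == ncol(r), length(variant_ids) == nrow(r))
  variant_ids <- as.character(variant_ids)
  if (anyDuplicated(variant_ids)) stop("ld_matrix: duplicate variant ids", call. = FALSE)
  if (max(abs(r - t(r))) > 1e-8) stop("ld_matrix: r is not symmetric", call. = FALSE)
  if (max(abs(diag(r) - 1)) > 1e-8) stop("ld_matrix: diagonal must be 1", call. = FALSE)
  if (any(abs(r) > 1 + 1e-8)) stop("ld_matrix: |r| > 1", call. = FALSE)
  r <- (r + t(r)) / 2
  dimnames(r) <- list(variant_ids, variant_ids)
  if (!is.null(alleles)) {
    stopifnot(is.data.frame(alleles), nrow(alleles) == nrow(r),
              all(c("ea", "oa") %in% names(alleles)))
    alleles <- data.frame(ea = toupper(alleles$ea), oa = toupper(alleles$oa))
  }
  structure(list(variant_ids = variant_ids, alleles = alleles, r = r),
            class = "ld_matrix")
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("ld_matrix: %d variants\n", length(x$variant_ids)))
  invisible(x)
}

#' Compute LD from a dosage table
#'
#' Pearson correlation of allele dosages across reference samples.
#' Monomorphic variants (zero dosage variance) are excluded with a warning.
#'
#' @param genotypes Numeric matrix, variants x samples; rownames are variant
#'   ids. At least 2 samples.
#' @param alleles Optional allele orientation data.frame (`ea`, `oa`) per
#'   variant, carried into the result.
#' @return An `ld_matrix`.
#' @export
compute_ld <- function(genotypes, alleles = NULL) {
  genotypes <- as.matrix(genotypes)
  if (ncol(genotypes) < 2) stop("compute_ld: need >= 2 samples", call. = FALSE)
  if (is.null(rownames(genotypes))) {
    rownames(genotypes) <- paste0("v", seq_len(nrow(genotypes)))
  }
  v <- apply(genotypes, 1, stats::var)
  mono <- v <= 0 | is.na(v)
  if (any(mono)) {
    warning("compute_ld: excluding ", sum(mono), " monomorphic variant(s): ",
            paste(utils::head(rownames(genotypes)[mono], 5), collapse = ", "))
    genotypes <- genotypes[!mono, , drop = FALSE]
    if (!is.null(alleles)) alleles <- alleles[!mono, , drop = FALSE]
  }
  if (nrow(genotypes) == 0) stop("compute_ld: no polymorphic variants", call. = FALSE)
  r <- stats::cor(t(genotypes))
  diag(r) <- 1
  ld_matrix(r, rownames(genotypes), alleles = alleles)
}

#' Ridge-regularize an LD matrix
#'
#' Adds `lambda` to the diagonal and renormalizes back to unit diagonal,
#' i.e. `r' = (r + lambda I) / (1 + lambda)`. Reference-panel LD matrices
#' are frequently near-singular; every internal inversion works on the
#' regularized matrix.
#'
#' @param ld An `ld_matrix`.
#' @param lambda Ridge constant (default `1e-3`).
#' @return A regularized `ld_matrix`.
#' @export
ld_regularize <- function(ld, lambda = 1e-3) {
  stopifnot(inherits(ld, "ld_matrix"), lambda >= 0)
  r <- (ld$r + diag(lambda, nrow(ld$r))) / (1 + lambda)
  ld_matrix(r, ld$variant_ids, ld$alleles)
}

#' Extract the LD submatrix for a set of variants
#'
#' @param ld An `ld_matrix`.
#' @param ids Variant ids, all present in `ld`.
#' @return An `ld_matrix` restricted to `ids`, in that order.
#' @export
ld_subset <- function(ld, ids) {
  stopifnot(inherits(ld, "ld_matrix"))
  ids <- as.character(ids)
  missing <- setdiff(ids, ld$variant_ids)
  if (length(missing) > 0) {
    stop("ld_subset: variant(s) absent from LD reference: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  idx <- match(ids, ld$variant_ids)
  al <- if (!is.null(ld$alleles)) ld$alleles[idx, , drop = FALSE] else NULL
  ld_matrix(ld$r[idx, idx, drop = FALSE], ids, alleles = al)
}

#' Signed LD r between variants and a harmonized effect-allele orientation
#'
#' Correlation signs in an LD reference refer to that reference's allele
#' orientation. When a caller's effect alleles disagree with the
#' reference's, the corresponding rows/columns of r change sign. Returns
#' the r matrix aligned to the caller's orientation; without stored alleles
#' the reference orientation is assumed to match.
#'
#' @param ld An `ld_matrix`.
#' @param ids Variant ids to extract.
#' @param ea,oa Caller's effect/other alleles for `ids` (optional).
#' @return Numeric matrix of signed correlations.
#' @keywords internal
ld_aligned_r <- function(ld, ids, ea = NULL, oa = NULL) {
  sub <- ld_subset(ld, ids)
  r <- sub$r
  if (!is.null(ea) && !is.null(sub$alleles)) {
    flip <- ifelse(toupper(ea) == sub$alleles$ea, 1,
                   ifelse(toupper(ea) == sub$alleles$oa, -1, NA_real_))
    if (anyNA(flip)) {
      stop("ld_aligned_r: allele mismatch with LD reference for ",
           paste(ids[is.na(flip)], collapse = ", "), call. = FALSE)
    }
    r <- r * tcrossprod(flip)
  }
  r
}

#' Read an LD reference from text files
#'
#' Expects a square matrix TSV (no header, or header of variant ids) plus a
#' sidecar variant list TSV with columns `variant_id`, `ea`, `oa`.
#'
#' @param matrix_path Path to the square correlation matrix TSV.
#' @param variants_path Path to the sidecar variant/allele list.
#' @return An `ld_matrix`.
#' @export
read_ld_matrix <- function(matrix_path, variants_path) {
  vr <- utils::read.table(variants_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(c("variant_id", "ea", "oa") %in% names(vr)))
  r <- as.matrix(utils::read.table(matrix_path, header = FALSE, sep = "\t"))
  dimnames(r) <- NULL
  ld_matrix(r, vr$variant_id, alleles = vr[c("ea", "oa")])
}

#' Write an LD reference as text files
#'
#' @param ld An `ld_matrix` (must carry alleles).
#' @param matrix_path,variants_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_ld_matrix <- function(ld, matrix_path, variants_path) {
  stopifnot(inherits(ld, "ld_matrix"))
  utils::write.table(ld$r, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  al <- ld$alleles %||% data.frame(ea = rep(NA_character_, length(ld$variant_ids)),
                                   oa = NA_character_)
  utils::write.table(data.frame(variant_id = ld$variant_ids, al),
                     variants_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrix_path)
}

#' Combine per-region LD matrices into one block-diagonal reference
#'
#' Regions on different chromosomes are uncorrelated, so a genome-wide
#' reference for multi-region analyses is the block-diagonal assembly of
#' the per-region matrices.
#'
#' @param ld_list List of `ld_matrix` objects with disjoint variant ids.
#' @return A single `ld_matrix`.
#' @export
ld_block_diag <- function(ld_list) {
  stopifnot(length(ld_list) >= 1)
  ids <- unlist(lapply(ld_list, function(l) l$variant_ids), use.names = FALSE)
  if (anyDuplicated(ids)) stop("ld_block_diag: duplicate variant ids", call. = FALSE)
  n <- length(ids)
  r <- matrix(0, n, n)
  at <- 0
  for (l in ld_list) {
    k <- length(l$variant_ids)
    r[at + seq_len(k), at + seq_len(k)] <- l$r
    at <- at + k
  }
  alleles <- do.call(rbind, lapply(ld_list, function(l) {
    l$alleles %||% data.frame(ea = rep(NA_character_, length(l$variant_ids)),
                              oa = NA_character_)
  }))
  ld_matrix(r, ids, alleles = alleles)
}
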