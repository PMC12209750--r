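# LD-corrected multivariable weights: within each clump the vector of
# univariate per-SNP betas is multiplied by the (pseudo)inverse of the SNP
# genotype correlation matrix from the reference panel, converting marginal
# effects into joint, LD-corrected weights. A pseudoinverse handles
# ill-conditioned clumps of highly correlated SNPs.

#' SNP genotype correlation matrix from the reference panel
#'
#' Pearson correlation of dosages, computed on centered (not variance-
#' standardized beyond the correlation itself) genotypes, so downstream
#' weights stay on the per-allele scale of the input betas.
#'
#' @param panel A `reference_panel`.
#' @param snp_ids Character vector of SNP ids present in the panel.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
snp_correlation <- function(panel, snp_ids) {
  missing_ids <- setdiff(snp_ids, colnames(panel$dosages))
  assert_that(length(missing_ids) == 0,
              "SNP(s) absent from panel: ", paste(missing_ids, collapse = ", "))
  X <- panel$dosages[, snp_ids, drop = FALSE]
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stop("constant dosage column(s) in panel: ",
         paste(snp_ids[sds == 0], collapse = ", "),
         " (correlation undefined)", call. = FALSE)
  }
  R <- cor(X)
  dimnames(R) <- list(snp_ids, snp_ids)
  R
}

#' LD-adjust univariate betas to multivariable weights
#'
#' Computes `weights = pinv(R) %*% betas` via the singular value
#' decomposition, discarding singular values below `svd_rtol` times the
#' largest. For full-rank R this equals the exact inverse; for rank-deficient
#' clumps (e.g. duplicated SNPs) the minimum-norm solution splits weight
#' across the collinear SNPs, leaving the implied locus score unchanged.
#'
#' @param betas Numeric vector of univariate regression coefficients.
#' @param R SNP correlation matrix (symmetric, same dimension as `betas`).
#' @param svd_rtol Relative singular-value cutoff (default 1e-6).
#' @param gene_id,clump_id Optional labels carried on the result.
#' @return Object of class `weight_vector`: snp_ids, weights,
#'   condition_number (largest/smallest singular value), rank_used.
#' @export
adjust_weights <- function(betas, R, svd_rtol = 1e-6,
                           gene_id = NA_character_, clump_id = NA_character_) {
  assert_that(is.matrix(R) && nrow(R) == ncol(R), "R must be a square matrix")
  assert_that(length(betas) == nrow(R), "dim(betas) must equal dim(R)")
  if (max(abs(R - t(R))) > 1e-8) stop("R must be symmetric", call. = FALSE)
  sv <- svd(R)
  keep <- sv$d >= svd_rtol * sv$d[1]
  rank_used <- sum(keep)
  w <- sv$v[, keep, drop = FALSE] %*%
    ((crossprod(sv$u[, keep, drop = FALSE], betas)) / sv$d[keep])
  structure(list(gene_id = gene_id, clump_id = clump_id,
                 snp_ids = colnames(R) %||% paste0("snp", seq_along(betas)),
                 weights = as.numeric(w),
                 condition_number = sv$d[1] / sv$d[length(sv$d)],
                 rank_used = rank_used),
            class = "weight_vector")
}

#' LD-corrected weights for one clump
#'
#' Convenience wrapper: builds the clump's correlation matrix from the panel
#' and calls [adjust_weights()] on its member betas.
#'
#' @param clump A `gate_clump` from [clump_associations()].
#' @param panel A `reference_panel`.
#' @param svd_rtol Relative singular-value cutoff.
#' @return A `weight_vector` carrying the clump's gene and clump ids and its
#'   cis/trans flag as attribute `is_cis`.
#' @export
clump_weights <- function(clump, panel, svd_rtol = 1e-6) {
  R <- snp_correlation(panel, clump$members$snp_id)
  wv <- adjust_weights(clump$members$beta, R, svd_rtol = svd_rtol,
                       gene_id = clump$gene_id, clump_id = clump$clump_id)
  attr(wv, "is_cis") <- clump$is_cis
  wv
}

#' Tabulate weight vectors
#'
#' @param wvs List of `weight_vector` objects.
#' @return Data frame: gene_id, clump_id, snp_id, weight, condition_number,
#'   rank_used.
#' @export
weight_table <- function(wvs) {
  do.call(rbind, lapply(wvs, function(w) data.frame(
    gene_id = w$gene_id, clump_id = w$clump_id, snp_id = w$snp_ids,
    weight = w$weights, condition_number = w$condition_number,
    rank_used = w$rank_used, stringsAsFactors = FALSE)))
}
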