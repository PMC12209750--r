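# GATE scoring: per-individual locus-specific scores (adjusted weights times
# target-cohort genotypes), genome-wide aggregation over trans loci, and the
# Hill-number effective number of trans-QTLs.

#' Per-individual locus-specific score
#'
#' Multiplies the clump's LD-adjusted weight vector by the cohort's dosage
#' matrix. Missing dosages are mean-imputed per SNP and genotypes are
#' centered at twice the cohort allele frequency, so scores are mean-zero;
#' with an intercept in the null model, association results are invariant to
#' this centering.
#'
#' @param cohort A `gate_cohort` (or any list with a `dosages` matrix whose
#'   columns are named by SNP id).
#' @param wv A `weight_vector`.
#' @param is_cis Logical flag stored on the result; defaults to the weight
#'   vector's own flag (FALSE if unset).
#' @return Object of class `locus_score`: gene_id, clump_id, values,
#'   variance, is_cis.
#' @export
locus_score <- function(cohort, wv, is_cis = NULL) {
  is_cis <- is_cis %||% attr(wv, "is_cis") %||% FALSE
  if (is.na(is_cis)) is_cis <- FALSE
  present <- wv$snp_ids %in% colnames(cohort$dosages)
  if (!any(present)) {
    stop("none of the weight vector's SNPs are present in the cohort",
         call. = FALSE)
  }
  if (any(!present)) {
    warning(sprintf("%d of %d SNP(s) missing from cohort (%.0f%%); scoring on the intersection",
                    sum(!present), length(present), 100 * mean(!present)),
            call. = FALSE)
  }
  ids <- wv$snp_ids[present]
  w <- wv$weights[present]
  X <- cohort$dosages[, ids, drop = FALSE]
  storage.mode(X) <- "double"
  if (anyNA(X)) {
    for (j in seq_len(ncol(X))) {
      nas <- is.na(X[, j])
      if (any(nas)) X[nas, j] <- mean(X[, j], na.rm = TRUE)
    }
  }
  freq <- colMeans(X) / 2
  values <- as.numeric(X %*% w) - sum(2 * freq * w)
  structure(list(gene_id = wv$gene_id, clump_id = wv$clump_id,
                 values = values, variance = var(values), is_cis = is_cis),
            class = "locus_score")
}

#' Cis score for one gene
#'
#' Same computation as [locus_score()], flagged cis; cis scores are kept out
#' of the aggregated trans score and tested for disease association
#' separately.
#'
#' @inheritParams locus_score
#' @return A `locus_score` with `is_cis = TRUE`.
#' @export
cis_score <- function(cohort, wv) {
  locus_score(cohort, wv, is_cis = TRUE)
}

#' Hill-number effective number of trans-QTLs
#'
#' The diversity index of the locus-score variances: with
#' `p_i = sigma_i^2 / sum_j sigma_j^2`, returns `2^(-sum p_i log2 p_i)`
#' (2 to the Shannon entropy in bits), treating `0 log 0` as 0. Ranges from
#' 1 when a single locus dominates to K when all K variances are equal.
#'
#' @param variances Non-negative locus-score variances, at least one > 0.
#' @return Effective number in `[1, K]`.
#' @export
diversity_index <- function(variances) {
  assert_that(all(variances >= 0), "variances must be non-negative")
  tot <- sum(variances)
  assert_that(tot > 0, "all variances are zero; diversity index undefined")
  p <- variances / tot
  p <- p[p > 0]
  2^(-sum(p * log2(p)))
}

#' Aggregate trans locus scores into a genome-wide GATE score
#'
#' Element-wise sum of the per-individual locus scores over trans loci (cis
#' loci are excluded), with the Hill-number effective number of trans-QTLs
#' computed from the locus-score variances measured in the target cohort.
#'
#' @param locus_scores List of `locus_score` objects for one gene.
#' @param study Study label carried on the result.
#' @return Object of class `gate_score`: gene_id, values, n_loci,
#'   locus_variances, effective_n, score_sd, study — or `NULL` (with a
#'   message) when the gene has no trans locus.
#' @export
aggregate_trans <- function(locus_scores, study = NA_character_) {
  trans <- Filter(function(l) !isTRUE(l$is_cis), locus_scores)
  if (!length(trans)) {
    msg("gene skipped: no trans locus scores to aggregate")
    return(NULL)
  }
  gene_id <- trans[[1]]$gene_id
  values <- Reduce(`+`, lapply(trans, `[[`, "values"))
  vars <- vapply(trans, `[[`, numeric(1), "variance")
  structure(list(gene_id = gene_id, values = values, n_loci = length(trans),
                 locus_variances = vars,
                 effective_n = diversity_index(vars),
                 score_sd = sd(values), study = study),
            class = "gate_score")
}

#' Score a cohort for many genes
#'
#' Runs [clump_weights()], [locus_score()] and [aggregate_trans()] over a
#' list of clumps grouped by gene, returning the per-gene GATE scores, the
#' per-gene cis scores and the underlying trans locus scores.
#'
#' @param cohort A `gate_cohort`.
#' @param clumps List of `gate_clump` objects (any genes, cis and trans).
#' @param panel A `reference_panel` for the correlation matrices.
#' @param svd_rtol Relative singular-value cutoff for [adjust_weights()].
#' @param study Study label.
#' @return List with `gate` (named list of `gate_score`), `cis` (named list
#'   of per-gene summed cis `locus_score`s), `locus` (named list of lists of
#'   trans `locus_score`s per gene), and `weights` (list of `weight_vector`).
#' @export
score_cohort <- function(cohort, clumps, panel, svd_rtol = 1e-6,
                         study = NA_character_) {
  wvs <- lapply(clumps, clump_weights, panel = panel, svd_rtol = svd_rtol)
  ls <- lapply(wvs, function(w) locus_score(cohort, w))
  genes <- unique(vapply(ls, `[[`, character(1), "gene_id"))
  gate <- list(); cis <- list(); locus <- list()
  for (g in genes) {
    mine <- Filter(function(l) identical(l$gene_id, g), ls)
    gs <- aggregate_trans(mine, study = study)
    if (!is.null(gs)) {
      gate[[g]] <- gs
      locus[[g]] <- Filter(function(l) !isTRUE(l$is_cis), mine)
    }
    cis_l <- Filter(function(l) isTRUE(l$is_cis), mine)
    if (length(cis_l)) {
      values <- Reduce(`+`, lapply(cis_l, `[[`, "values"))
      cis[[g]] <- structure(list(gene_id = g, clump_id = "cis_combined",
                                 values = values, variance = var(values),
                                 is_cis = TRUE), class = "locus_score")
    }
  }
  list(gate = gate, cis = cis, locus = locus, weights = wvs)
}

#' Score matrix and per-gene metadata
#'
#' @param gate Named list of `gate_score` objects (e.g. from
#'   [score_cohort()]`$gate`).
#' @param sample_ids Optional row names for the matrix.
#' @return List with `matrix` (individuals x genes) and `meta` data frame
#'   (gene_id, study, n_loci, effective_n, score_sd).
#' @export
gate_score_matrix <- function(gate, sample_ids = NULL) {
  m <- do.call(cbind, lapply(gate, `[[`, "values"))
  colnames(m) <- names(gate)
  if (!is.null(sample_ids)) rownames(m) <- sample_ids
  meta <- do.call(rbind, lapply(gate, function(g) data.frame(
    gene_id = g$gene_id, study = g$study, n_loci = g$n_loci,
    effective_n = g$effective_n, score_sd = g$score_sd,
    stringsAsFactors = FALSE)))
  rownames(meta) <- NULL
  list(matrix = m, meta = meta)
}
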