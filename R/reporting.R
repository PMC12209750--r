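# Filtering and validation of putative core genes: the effective-number and
# p-value filters, GWAS-hit proximity, the measured-protein direction and
# magnitude criterion, the attenuation prediction, and assembly of the
# validation table.

#' Primary core-gene filter
#'
#' Retains trans-score associations with effective number of trans-QTLs
#' strictly greater than `min_effective_n` and p-value strictly below
#' `max_p`. Both inequalities are strict: effective_n = 5 exactly or
#' p = 1e-5 exactly are excluded.
#'
#' @param results Association results with `effective_n` and `pvalue`.
#' @param min_effective_n Effective-number threshold (default 5).
#' @param max_p P-value threshold (default 1e-5).
#' @return Filtered data frame.
#' @export
filter_core_genes <- function(results, min_effective_n = 5, max_p = 1e-5) {
  keep <- results$effective_n > min_effective_n & results$pvalue < max_p
  keep[is.na(keep)] <- FALSE
  msg(sum(keep), " of ", nrow(results), " scores pass effective_n > ",
      min_effective_n, " and p < ", format(max_p))
  results[keep, , drop = FALSE]
}

#' Secondary candidates near GWAS hits
#'
#' Genes whose trans score associates with disease at the relaxed threshold
#' `max_p` (strictly) and whose transcription site lies within the GWAS
#' window of a reported hit — a nearby hit raises the prior probability of a
#' causal effect.
#'
#' @param results Association results with `gene_id` and `pvalue`.
#' @param proximity Data frame from [gwas_proximity()] (gene_id,
#'   gwas_hit_within_window, hit_labels).
#' @param max_p Relaxed p threshold (default 1e-3).
#' @return Filtered data frame with proximity columns merged in.
#' @export
secondary_candidates <- function(results, proximity, max_p = 1e-3) {
  m <- merge(results, proximity, by = "gene_id", all.x = TRUE)
  keep <- m$pvalue < max_p & m$gwas_hit_within_window %in% TRUE
  m[keep, , drop = FALSE]
}

#' GWAS-hit proximity to transcription sites
#'
#' TRUE for a gene when some hit lies on the same chromosome within `window`
#' base pairs (closed interval) of its transcription start site. The default
#' 200-kb window reflects the typical distance from protein-QTL variants to
#' the transcription start site.
#'
#' @param genes Gene annotation (gene_id, chrom, tss_pos).
#' @param hits Data frame of GWAS hits (chrom, pos, optionally
#'   attributed_genes).
#' @param window Base-pair window (default 200,000).
#' @return Data frame: gene_id, gwas_hit_within_window, hit_labels.
#' @export
gwas_proximity <- function(genes, hits, window = 2e5) {
  res <- lapply(seq_len(nrow(genes)), function(i) {
    near <- as.character(hits$chrom) == as.character(genes$chrom[i]) &
      abs(hits$pos - genes$tss_pos[i]) <= window
    labels <- if (any(near) && !is.null(hits$attributed_genes)) {
      paste(unique(hits$attributed_genes[near]), collapse = ";")
    } else ""
    data.frame(gene_id = genes$gene_id[i], gwas_hit_within_window = any(near),
               hit_labels = labels, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Measured-protein validation criterion
#'
#' Passes when the measured-protein association is in the same direction as
#' the aggregated trans-score association and its magnitude (standardized
#' log odds ratio) is at least `ratio` times that of the trans score.
#'
#' @param trans_log_or,protein_log_or Standardized log odds ratios.
#' @param ratio Magnitude multiple required (default 2).
#' @return Logical.
#' @export
protein_validation <- function(trans_log_or, protein_log_or, ratio = 2) {
  sign(trans_log_or) == sign(protein_log_or) &
    abs(protein_log_or) >= ratio * abs(trans_log_or)
}

#' Attenuation prediction for score vs measured-level effects
#'
#' If the measured level is causal and the genotypic score is a noisy proxy
#' explaining a fraction `r2` of its variance, the ratio of standardized
#' effect sizes (measured : score) should be about `1/sqrt(r2)` — the ratio
#' of effect sizes scales with the correlation of the score with the
#' measured value. At the typical r2 of about 2% this predicts a ratio of
#' about 7.
#'
#' @param r2 Squared correlation of the score with the measured level, in
#'   (0, 1].
#' @param trans_log_or,protein_log_or Standardized log odds ratios (trans
#'   effect must be nonzero).
#' @param factor_range Observed/predicted ratio band counted as consistent
#'   (default 0.5 to 2).
#' @return List: predicted_ratio, observed_ratio, consistent.
#' @export
attenuation_check <- function(r2, trans_log_or, protein_log_or,
                              factor_range = c(0.5, 2)) {
  assert_that(r2 > 0 && r2 <= 1, "r2 must be in (0, 1]")
  assert_that(trans_log_or != 0, "trans effect must be nonzero")
  predicted <- 1 / sqrt(r2)
  observed <- protein_log_or / trans_log_or
  list(predicted_ratio = predicted, observed_ratio = observed,
       consistent = observed >= factor_range[1] * predicted &
         observed <= factor_range[2] * predicted)
}

#' Assemble the core-gene validation table
#'
#' One row per candidate gene with the computable criteria (GWAS-hit
#' proximity, MR support, measured-protein direction/magnitude) and the
#' curated literature criteria (mouse-model perturbation, drug evidence,
#' monogenic disease) taken from a user-supplied annotation table. Curated
#' criteria that are absent from the annotation are reported as NA
#' (unknown), never as FALSE. The MR column is populated only for eligible
#' genes (>= 10 instruments).
#'
#' @param candidates Association results for candidate genes (gene_id,
#'   effective_n, pvalue, log_or_std).
#' @param proximity Output of [gwas_proximity()].
#' @param mr_results Data frame from [mr_table()], or NULL.
#' @param protein_results Data frame (gene_id, log_or_std, pvalue) of
#'   measured-protein associations, or NULL.
#' @param curated Data frame (gene_id, mouse_model, drug, monogenic) of
#'   curated booleans, or NULL.
#' @param mr_p MR significance threshold (default 0.01).
#' @param protein_ratio Magnitude multiple for the protein criterion
#'   (default 2).
#' @return Data frame, one row per candidate.
#' @export
assemble_validation_table <- function(candidates, proximity = NULL,
                                      mr_results = NULL,
                                      protein_results = NULL, curated = NULL,
                                      mr_p = 0.01, protein_ratio = 2) {
  if (!nrow(candidates)) {
    return(data.frame(gene_id = character(), trans_log_or_std = numeric(),
                      trans_p = numeric(), effective_n = numeric(),
                      gwas_hit_within_200kb = logical(), hit_labels = character(),
                      mr_pass = logical(), protein_log_or_std = numeric(),
                      protein_p = numeric(), protein_pass = logical(),
                      mouse_model = logical(), drug = logical(),
                      monogenic = logical()))
  }
  out <- data.frame(gene_id = candidates$gene_id,
                    trans_log_or_std = candidates$log_or_std,
                    trans_p = candidates$pvalue,
                    effective_n = candidates$effective_n,
                    stringsAsFactors = FALSE)
  hit <- rep(NA, nrow(out)); labels <- rep(NA_character_, nrow(out))
  if (!is.null(proximity)) {
    i <- match(out$gene_id, proximity$gene_id)
    hit <- proximity$gwas_hit_within_window[i]
    labels <- proximity$hit_labels[i]
  }
  out$gwas_hit_within_200kb <- hit
  out$hit_labels <- labels
  out$mr_pass <- NA
  if (!is.null(mr_results)) {
    i <- match(out$gene_id, mr_results$gene_id)
    ok <- !is.na(i) & mr_results$eligible[i]
    out$mr_pass[ok] <- mr_results$pvalue[i][ok] < mr_p
  }
  out$protein_log_or_std <- NA_real_
  out$protein_p <- NA_real_
  out$protein_pass <- NA
  if (!is.null(protein_results)) {
    i <- match(out$gene_id, protein_results$gene_id)
    ok <- !is.na(i)
    out$protein_log_or_std[ok] <- protein_results$log_or_std[i][ok]
    out$protein_p[ok] <- protein_results$pvalue[i][ok]
    out$protein_pass[ok] <- protein_validation(out$trans_log_or_std[ok],
                                               out$protein_log_or_std[ok],
                                               ratio = protein_ratio)
  }
  for (col in c("mouse_model", "drug", "monogenic")) {
    out[[col]] <- NA
    if (!is.null(curated) && col %in% names(curated)) {
      i <- match(out$gene_id, curated$gene_id)
      out[[col]][!is.na(i)] <- curated[[col]][i[!is.na(i)]]
    }
  }
  rownames(out) <- NULL
  out
}

#' Score correlation matrix ordered by hierarchical clustering
#'
#' Pearson correlations between per-individual GATE scores, with rows and
#' columns reordered by average-linkage hierarchical clustering on
#' 1 - |correlation|; the diagonal is 1.
#'
#' @param score_matrix Individuals x genes matrix of GATE score values.
#' @return Reordered correlation matrix.
#' @export
score_correlation <- function(score_matrix) {
  C <- cor(score_matrix)
  if (ncol(C) > 2) {
    hc <- stats::hclust(stats::as.dist(1 - abs(C)), method = "average")
    C <- C[hc$order, hc$order]
  }
  C
}
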