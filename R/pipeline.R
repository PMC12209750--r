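#' Run the aggregated-trans-score pipeline end to end
#'
#' From QTL summary statistics to per-gene association results: extraction
#' p-filter, HLA mask, allele harmonization against the panel, per-gene
#' clumping with cis/trans classification, LD-corrected weights, locus and
#' aggregated trans scores in the cohort, covariate-adjusted efficient score
#' tests, and the Hill-number effective number per gene.
#'
#' @param assocs QTL association data frame (as from [simulate_qtl_study()]
#'   or [load_summary_stats()]).
#' @param panel A `reference_panel`.
#' @param cohort A `gate_cohort`.
#' @param genes Gene annotation (gene_id, chrom, tss_pos).
#' @param config A [gate_config()].
#' @param study Study label.
#' @return List: `associations` (per-gene results), `scored` (scores and
#'   weights from [score_cohort()]), `clumps`, `null` (the fitted null
#'   model), `filtered_assocs`.
#' @export
gate_pipeline <- function(assocs, panel, cohort, genes,
                          config = gate_config(), study = NA_character_) {
  a <- filter_by_pvalue(assocs, config$extraction_p)
  a <- mask_hla(a, config$hla_chrom, config$hla_start, config$hla_end)
  a <- harmonize_alleles(a, panel$snps)
  clumps <- list()
  for (g in unique(a$gene_id)) {
    cl <- clump_associations(a[a$gene_id == g, , drop = FALSE], panel,
                             anchor_p = config$anchor_p,
                             r2_threshold = config$r2_threshold,
                             window = config$clump_window,
                             genes = genes, cis_window = config$cis_window)
    clumps <- c(clumps, cl)
  }
  scored <- score_cohort(cohort, clumps, panel, svd_rtol = config$svd_rtol,
                         study = study)
  null <- fit_null(cohort$outcome, cohort$covariates)
  res <- gate_association_table(null, scored)
  list(associations = res, scored = scored, clumps = clumps, null = null,
       filtered_assocs = a)
}
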