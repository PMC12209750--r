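#!/usr/bin/env Rscript
# Step 2 — ingest the QTL summary statistics, apply the extraction filter
# (p < 1e-5), mask the HLA region, harmonize alleles to the panel, and form
# per-gene clumps of associated SNPs (anchor p < 1e-6, r2 >= 0.1, 1 Mb).

source("analysis/_common.R")

assocs <- load_summary_stats(file.path(RESULTS, "qtl_sumstats.tsv"),
                             study = "synthetic_eqtl")
cat(sprintf("loaded %d associations\n", nrow(assocs)))

cfg <- gate_config()
a <- filter_by_pvalue(assocs, cfg$extraction_p)
a <- mask_hla(a, cfg$hla_chrom, cfg$hla_start, cfg$hla_end)
panel <- panel_obj()
a <- harmonize_alleles(a, panel$snps)

genes <- gene_annotation(ARCH)
clumps <- list()
for (g in unique(a$gene_id)) {
  clumps <- c(clumps, clump_associations(a[a$gene_id == g, ], panel,
                                         anchor_p = cfg$anchor_p,
                                         r2_threshold = cfg$r2_threshold,
                                         window = cfg$clump_window,
                                         genes = genes,
                                         cis_window = cfg$cis_window))
}
tab <- clump_table(clumps)
data.table::fwrite(tab, file.path(RESULTS, "clumps.tsv"), sep = "\t")
cat(sprintf("%d clumps over %d genes (%d cis, %d trans); median SNPs/clump %d\n",
            nrow(tab), length(unique(tab$gene_id)), sum(tab$is_cis),
            sum(!tab$is_cis), as.integer(median(tab$n_snps))))
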