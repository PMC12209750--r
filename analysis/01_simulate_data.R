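#!/usr/bin/env Rscript
# Step 1 — simulate the study inputs: an LD reference panel, a QTL study's
# summary statistics, and a genotyped disease cohort with three designated
# core genes mediating risk. Writes the plain-text interchange files that
# the ingestion step consumes.

source("analysis/_common.R")

panel <- panel_obj()
qtl <- qtl_obj()
cohort <- cohort_obj()

write_architecture(ARCH, file.path(RESULTS, "architecture.yaml"))
write_panel_traw(panel, file.path(RESULTS, "panel.traw"))
write_panel_vcf(panel, file.path(RESULTS, "panel.vcf"))
write_summary_stats(qtl, file.path(RESULTS, "qtl_sumstats.tsv"))
write_phenotypes(cohort, file.path(RESULTS, "phenotypes.tsv"))

cat(sprintf("panel: %d individuals x %d SNPs in %d LD blocks\n",
            nrow(panel$dosages), nrow(panel$snps), length(panel$model)))
cat(sprintf("QTL study: %d summary rows over %d genes (n = %d)\n",
            nrow(qtl), length(unique(qtl$gene_id)), N_STUDY))
cat(sprintf("cohort: %d individuals, %d cases (prevalence %.4f, target %.2f)\n",
            length(cohort$outcome), sum(cohort$outcome), mean(cohort$outcome),
            ARCH$prevalence))
cat(sprintf("core genes: %s (log OR %.2f per SD of expression)\n",
            paste(ARCH$core_genes$gene_id, collapse = ", "),
            ARCH$core_genes$coef[1]))
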