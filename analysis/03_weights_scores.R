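#!/usr/bin/env Rscript
# Step 3 — convert univariate betas to LD-corrected multivariable weights
# (pseudoinverse of the panel correlation matrix per clump), score the
# cohort per locus, and aggregate trans loci into genome-wide GATE scores
# with the Hill-number effective number of trans-QTLs.

source("analysis/_common.R")

run <- pipeline_obj()

wt <- weight_table(run$scored$weights)
data.table::fwrite(wt, file.path(RESULTS, "weights.tsv"), sep = "\t")

sm <- gate_score_matrix(run$scored$gate, cohort_obj()$sample_ids)
data.table::fwrite(sm$meta, file.path(RESULTS, "score_meta.tsv"), sep = "\t")

cat(sprintf("weights for %d clumps (%d SNPs); max condition number %.2g\n",
            length(run$scored$weights), nrow(wt), max(wt$condition_number)))
cat(sprintf("GATE scores for %d genes; effective_n range %.2f-%.2f (of %d loci)\n",
            nrow(sm$meta), min(sm$meta$effective_n), max(sm$meta$effective_n),
            max(sm$meta$n_loci)))
cat(sprintf("genes with effective_n > 5: %d of %d\n",
            sum(sm$meta$effective_n > 5), nrow(sm$meta)))
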