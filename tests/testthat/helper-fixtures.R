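# Shared fixture builders. All fixtures are generated in code under fixed
# seeds; nothing is read from disk except files the tests themselves write.

# Test-sized view of the package's reference architecture.
make_test_arch <- function(n_genes = 8, n_core = 2, n_trans = 6,
                           snps_per_block = 2, coef = 0.5, eff = 0.12,
                           noise = 1, prevalence = 0.01, rho = 0.4,
                           maf_range = c(0.25, 0.45), cis = TRUE) {
  synthetic_architecture(n_genes = n_genes, n_core = n_core,
                         n_trans = n_trans, snps_per_block = snps_per_block,
                         coef = coef, eff = eff, noise = noise,
                         prevalence = prevalence, rho = rho,
                         maf_range = maf_range, cis = cis)
}

# Small panel with independent SNPs at given MAFs (one 1-SNP block each).
make_indep_panel <- function(mafs, n, seed = 1, chrom = "1", spacing = 5e6) {
  blocks <- lapply(seq_along(mafs), function(i)
    ld_block_spec(chrom, 1e6 + (i - 1) * spacing, 1, rho = 0,
                  maf_range = rep(mafs[i], 2)))
  simulate_ld_panel(blocks, n, seed)
}

# Minimal cohort-like object for scoring tests: just a dosage matrix.
make_dosage_cohort <- function(dosages) {
  structure(list(dosages = dosages,
                 sample_ids = sprintf("S%d", seq_len(nrow(dosages)))),
            class = "gate_cohort")
}

# A valid summary-statistic data frame for ingestion tests.
make_sumstats <- function(n = 3, gene_id = "G1", study = "fix") {
  beta <- seq(0.1, by = 0.05, length.out = n)
  se <- rep(0.02, n)
  data.frame(snp_id = sprintf("chr1_%d", 1e6 + (seq_len(n) - 1) * 1000),
             chrom = "1", pos = 1e6 + (seq_len(n) - 1) * 1000,
             effect_allele = "A", other_allele = "G", gene_id = gene_id,
             beta = beta, se = se, pvalue = 2 * pnorm(-abs(beta / se)),
             n = 10000L, study = study, stringsAsFactors = FALSE)
}
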