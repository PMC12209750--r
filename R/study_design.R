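#' Synthetic core-gene study architecture
#'
#' A ready-made [architecture_spec()] emulating the omnigenic sparse-effector
#' design the scoring pipeline assumes: many genes each regulated by several
#' unlinked trans LD blocks (plus one cis block near the TSS), of which a
#' small designated subset of core genes carries a log-odds effect on a
#' low-prevalence binary disease through their standardized expression.
#'
#' Defaults define the package's reference simulation: 50 genes, 3 core
#' genes, 7 two-SNP trans blocks per gene with per-SNP effects 0.25 and
#' 0.175 expression SD per allele (within-block dosage correlation 0.4, MAF
#' 0.25-0.45), unit expression noise, core coefficient 0.6 per expression
#' SD, and 1% disease prevalence. With these choices each trans anchor is
#' essentially always genome-wide significant in a 20,000-sample QTL study
#' (see [qtl_power()]) and the genetic signal explains roughly a quarter of
#' expression variance, so a 50,000-sample cohort has high power to detect
#' core genes while null genes stay null.
#'
#' @param n_genes Total number of genes.
#' @param n_core Number of core genes (the first `n_core` gene ids).
#' @param n_trans Trans LD blocks per gene.
#' @param snps_per_block SNPs per LD block.
#' @param coef Core-gene log odds ratio per SD of expression.
#' @param eff Lead per-SNP effect on expression (decays by 0.7 per SNP
#'   within a block).
#' @param noise Expression noise SD.
#' @param prevalence Disease prevalence target.
#' @param rho Within-block adjacent dosage correlation.
#' @param maf_range Minor-allele-frequency range for all blocks.
#' @param cis Include a cis block (effects 0.15 decaying) per gene.
#' @return An `architecture_spec`.
#' @export
synthetic_architecture <- function(n_genes = 50, n_core = 3, n_trans = 7,
                                   snps_per_block = 2, coef = 0.6,
                                   eff = 0.25, noise = 1, prevalence = 0.01,
                                   rho = 0.4, maf_range = c(0.25, 0.45),
                                   cis = TRUE) {
  genes <- vector("list", n_genes)
  pos0 <- 1e6
  for (i in seq_len(n_genes)) {
    chrom_g <- as.character((i %% 4) + 10)
    tb <- vector("list", n_trans); te <- vector("list", n_trans)
    for (l in seq_len(n_trans)) {
      chrom_b <- as.character(((i * 7 + l) %% 5) + 1)
      start <- 1e6 + (i * 50 + l * 7) * 1e5
      tb[[l]] <- ld_block_spec(chrom_b, start, snps_per_block, rho = rho,
                               maf_range = maf_range)
      te[[l]] <- eff * 0.7^(seq_len(snps_per_block) - 1)
    }
    tss <- pos0 + i * 3e6 + 5e4
    cis_block <- NULL; cis_eff <- NULL
    if (cis) {
      cis_block <- ld_block_spec(chrom_g, pos0 + i * 3e6, snps_per_block,
                                 rho = rho, maf_range = maf_range)
      cis_eff <- 0.15 * 0.7^(seq_len(snps_per_block) - 1)
    }
    genes[[i]] <- gene_spec(sprintf("G%02d", i), chrom_g, tss,
                            cis_block = cis_block, cis_effects = cis_eff,
                            trans_blocks = tb, trans_effects = te,
                            expression_noise_sd = noise)
  }
  core <- if (n_core > 0) {
    data.frame(gene_id = sprintf("G%02d", seq_len(n_core)), coef = coef)
  }
  architecture_spec(genes, core_genes = core, prevalence = prevalence)
}
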