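# Simulated QTL study: fresh individuals from the panel's population, gene
# expression as a linear genetic signal plus Gaussian noise, and univariate
# per-SNP regressions of expression on dosage -- the summary-statistic form
# in which large eQTL/pQTL studies publish their results.

simulate_expression <- function(G, gene) {
  eff <- gene_effect_table(gene)
  y <- if (nrow(eff)) {
    as.numeric(G[, eff$snp_id, drop = FALSE] %*% eff$effect)
  } else numeric(nrow(G))
  y + rnorm(nrow(G), 0, gene$expression_noise_sd)
}

#' Simulate a QTL study's summary statistics
#'
#' Draws `n_study` fresh individuals from the panel's generative model,
#' simulates each gene's expression (or protein level), regresses it
#' univariately on every SNP, and returns the per-SNP coefficients, standard
#' errors and p-values -- one row per (SNP, gene) pair, as a QTL study would
#' publish. If the architecture designates `trait_associated_snps`, only
#' those SNPs are tested, emulating trans designs restricted to a preselected
#' trait-associated set.
#'
#' @param panel A `reference_panel`.
#' @param arch An [architecture_spec()].
#' @param n_study Study sample size.
#' @param seed Integer seed.
#' @param study Study label recorded on each row.
#' @param qtl_type `"transcript"` or `"protein"`.
#' @return Data frame of associations with columns snp_id, chrom, pos,
#'   effect_allele, other_allele, gene_id, beta, se, pvalue, n, study,
#'   qtl_type.
#' @export
simulate_qtl_study <- function(panel, arch, n_study, seed,
                               study = "synthetic", qtl_type = "transcript") {
  assert_that(length(arch$genes) > 0, "architecture has no genes")
  qtl_type <- match.arg(qtl_type, c("transcript", "protein"))
  G <- draw_genotypes(panel, n_study, sub_seed(seed, 11L))
  set.seed(sub_seed(seed, 12L))
  keep <- panel$snps$snp_id
  if (!is.null(arch$trait_associated_snps)) {
    keep <- intersect(keep, arch$trait_associated_snps)
  }
  X <- G[, keep, drop = FALSE]
  Xc <- scale(X, center = TRUE, scale = FALSE)
  Sxx <- colSums(Xc^2)
  snp_meta <- panel$snps[match(keep, panel$snps$snp_id), ]
  out <- vector("list", length(arch$genes))
  for (i in seq_along(arch$genes)) {
    g <- arch$genes[[i]]
    y <- simulate_expression(G, g)
    yc <- y - mean(y)
    Syy <- sum(yc^2)
    beta <- as.numeric(crossprod(Xc, yc)) / Sxx
    rss <- pmax(Syy - beta^2 * Sxx, 0)
    se <- sqrt(rss / (n_study - 2) / Sxx)
    # normal approximation, as large-sample QTL studies publish
    pval <- 2 * pnorm(-abs(beta / se))
    out[[i]] <- data.frame(snp_id = snp_meta$snp_id, chrom = snp_meta$chrom,
                           pos = snp_meta$pos,
                           effect_allele = snp_meta$effect_allele,
                           other_allele = snp_meta$other_allele,
                           gene_id = g$gene_id, beta = beta, se = se,
                           pvalue = pval, n = n_study, study = study,
                           qtl_type = qtl_type, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Power of a univariate QTL test under the generative model
#'
#' Closed-form power of the two-sided Wald test of a single SNP's effect on
#' expression, from the non-central chi-square distribution of the squared
#' t statistic at large n.
#'
#' @param beta Per-allele effect size (expression units).
#' @param maf Minor allele frequency.
#' @param noise_sd Residual SD of expression.
#' @param n Study sample size.
#' @param alpha Significance threshold.
#' @return Power (probability of p < alpha).
#' @export
qtl_power <- function(beta, maf, noise_sd, n, alpha = 1e-6) {
  vx <- 2 * maf * (1 - maf)
  vy <- beta^2 * vx + noise_sd^2
  r2 <- beta^2 * vx / vy
  ncp <- n * r2 / (1 - r2)
  crit <- qchisq(alpha, df = 1, lower.tail = FALSE)
  pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
}
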