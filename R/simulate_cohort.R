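#' Simulate a disease cohort under core-gene-mediated risk
#'
#' Draws `n` individuals from the panel's population, computes each core
#' gene's expression (genetic signal plus noise, standardized to unit
#' variance), and assigns a binary disease outcome from a logistic liability:
#' intercept + sum over core genes of coef x standardized expression + any
#' direct per-SNP (pleiotropic) effects. The intercept is solved numerically
#' so the expected prevalence equals the architecture's target. Covariates
#' (sex, 20 genotypic principal components) are simulated independent of
#' genotype: they play the role of nuisance adjustments, not confounders.
#'
#' @param panel A `reference_panel`.
#' @param arch An [architecture_spec()].
#' @param n Cohort size.
#' @param seed Integer seed.
#' @param n_pcs Number of principal-component covariates (default 20).
#' @param incident_fraction Fraction of cases flagged as incident (diagnosed
#'   during follow-up rather than at baseline).
#' @param proteomics_fraction Fraction of individuals flagged as members of a
#'   proteomics substudy (used to test the exclusion rule for genotypic
#'   scores derived from that substudy).
#' @return An object of class `gate_cohort`: sample_ids, dosages, snps,
#'   outcome (0/1), covariates (sex + PCs), expression (true per-gene
#'   expression of the architecture's genes, standardized; kept for oracle
#'   checks), incident_flag, proteomics_subset_flag.
#' @export
simulate_cohort <- function(panel, arch, n, seed, n_pcs = 20L,
                            incident_fraction = 0.3,
                            proteomics_fraction = 0) {
  G <- draw_genotypes(panel, n, sub_seed(seed, 21L))
  set.seed(sub_seed(seed, 22L))
  genes <- arch$genes
  expr <- matrix(0, n, length(genes),
                 dimnames = list(NULL, vapply(genes, `[[`, character(1), "gene_id")))
  for (i in seq_along(genes)) {
    e <- simulate_expression(G, genes[[i]])
    s <- sd(e)
    expr[, i] <- if (s > 0) (e - mean(e)) / s else e - mean(e)
  }
  eta <- numeric(n)
  if (nrow(arch$core_genes)) {
    eta <- eta + as.numeric(expr[, arch$core_genes$gene_id, drop = FALSE] %*%
                              arch$core_genes$coef)
  }
  if (!is.null(arch$direct_snp_effects)) {
    eta <- eta + as.numeric(G[, names(arch$direct_snp_effects), drop = FALSE] %*%
                              arch$direct_snp_effects)
  }
  intercept <- solve_prevalence_intercept(eta, arch$prevalence)
  p <- plogis(intercept + eta)
  outcome <- rbinom(n, 1L, p)
  covariates <- data.frame(sex = rbinom(n, 1L, 0.5))
  pcs <- matrix(rnorm(n * n_pcs), n, n_pcs,
                dimnames = list(NULL, paste0("pc", seq_len(n_pcs))))
  covariates <- cbind(covariates, as.data.frame(pcs))
  incident <- integer(n)
  cases <- which(outcome == 1L)
  incident[cases] <- rbinom(length(cases), 1L, incident_fraction)
  proteo <- rbinom(n, 1L, proteomics_fraction)
  structure(list(sample_ids = sprintf("S%06d", seq_len(n)),
                 dosages = G, snps = panel$snps, outcome = outcome,
                 covariates = covariates, expression = expr,
                 liability = intercept + eta,
                 incident_flag = incident,
                 proteomics_subset_flag = proteo),
            class = "gate_cohort")
}

# Solve E[plogis(c + eta)] = prevalence for the intercept c.
solve_prevalence_intercept <- function(eta, prevalence) {
  f <- function(c) mean(plogis(c + eta)) - prevalence
  lo <- -35; hi <- 35
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf(paste0("prevalence target %.4g unreachable: achievable range ",
                        "[%.4g, %.4g] given the configured liability effects"),
                 prevalence, mean(plogis(lo + eta)), mean(plogis(hi + eta))),
         call. = FALSE)
  }
  uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' @export
print.gate_cohort <- function(x, ...) {
  cat("gate_cohort:", length(x$outcome), "individuals,",
      sum(x$outcome), "cases,", ncol(x$dosages), "SNPs\n")
  invisible(x)
}
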