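# Mendelian randomization with Gaussian pleiotropy marginalized: IVW
# closed-form oracle, generative slope recovery, eligibility rule, and
# invariances of the marginal likelihood.

sim_instruments <- function(n_inst, theta, tau, seed, se_G = 0.02,
                            se_g = 0, gene = "G") {
  set.seed(seed)
  gamma <- rnorm(n_inst, 0, 0.3)
  alpha <- if (tau > 0) rnorm(n_inst, 0, tau) else numeric(n_inst)
  Gamma <- theta * gamma + alpha + rnorm(n_inst, 0, se_G)
  out <- data.frame(gene_id = gene, clump_id = paste0("c", seq_len(n_inst)),
                    gamma = gamma, se_gamma = se_g, Gamma = Gamma,
                    se_Gamma = se_G, stringsAsFactors = FALSE)
  class(out) <- c("instrument_summary", class(out))
  out
}

test_that("with tau = 0 and exact gamma the MLE equals the IVW closed form", {
  inst <- sim_instruments(20, theta = 0.25, tau = 0, seed = 71)
  ivw <- sum(inst$gamma * inst$Gamma / inst$se_Gamma^2) /
    sum(inst$gamma^2 / inst$se_Gamma^2)
  # profile the marginal likelihood at tau fixed to 0
  th_hat <- optimize(function(th) marginal_loglik(th, 0, inst),
                     interval = c(-2, 2), maximum = TRUE, tol = 1e-10)$maximum
  expect_equal(th_hat, ivw, tolerance = 1e-5)
  # the full fit drives tau to ~0 here and lands on the same estimate
  fit <- fit_causal_effect(inst)
  expect_equal(fit$theta_hat, ivw, tolerance = 0.02 / abs(ivw))
  expect_lt(fit$tau_hat, 0.01)
})

test_that("exactly null instruments put the pleiotropy scale at zero", {
  inst <- sim_instruments(15, theta = 0, tau = 0, seed = 72)
  inst$Gamma <- 0
  ll0 <- marginal_loglik(0, 0, inst)
  expect_gt(ll0, marginal_loglik(0, 0.05, inst))
  expect_gt(ll0, marginal_loglik(0, 0.5, inst))
})

test_that("a shared offset in the outcome coefficients lowers the likelihood", {
  # no intercept term: directional pleiotropy is penalized, not fitted away
  inst <- sim_instruments(20, theta = 0.3, tau = 0, seed = 73)
  best <- fit_causal_effect(inst)
  shifted <- inst; shifted$Gamma <- shifted$Gamma + 0.2
  expect_lt(marginal_loglik(best$theta_hat, best$tau_hat, shifted),
            best$loglik)
})

test_that("marginal likelihood is invariant to instrument relabeling", {
  inst <- sim_instruments(12, theta = 0.2, tau = 0.05, seed = 74)
  perm <- inst[sample(nrow(inst)), ]
  expect_equal(marginal_loglik(0.2, 0.05, perm),
               marginal_loglik(0.2, 0.05, inst))
  f1 <- fit_causal_effect(inst); f2 <- fit_causal_effect(perm)
  expect_equal(f2$theta_hat, f1$theta_hat, tolerance = 1e-5)
  expect_equal(f2$pvalue, f1$pvalue, tolerance = 1e-5)
})

test_that("gamma measurement error is propagated into the variance", {
  inst <- sim_instruments(10, theta = 0.5, tau = 0, seed = 75, se_g = 0.1)
  v_expected <- inst$se_Gamma^2 + 0.5^2 * inst$se_gamma^2 + 0.02^2
  ll <- marginal_loglik(0.5, 0.02, inst)
  manual <- sum(dnorm(inst$Gamma, 0.5 * inst$gamma, sqrt(v_expected), log = TRUE))
  expect_equal(ll, manual, tolerance = 1e-12)
  expect_error(marginal_loglik(0.5, -0.1, inst), "tau")
  expect_error(marginal_loglik(Inf, 0, inst), "finite")
})

test_that("the likelihood-ratio statistic is non-negative and CI covers the MLE", {
  for (s in 76:78) {
    inst <- sim_instruments(15, theta = 0.15, tau = 0.03, seed = s)
    fit <- fit_causal_effect(inst)
    expect_gte(fit$loglik,
               optimize(function(tau) marginal_loglik(0, tau, inst),
                        c(0, 1), maximum = TRUE)$objective - 1e-6)
    expect_true(fit$ci_95[1] <= fit$theta_hat && fit$theta_hat <= fit$ci_95[2])
    expect_true(fit$converged)
  }
})

test_that("fewer than 10 instruments flags the result ineligible", {
  inst9 <- sim_instruments(9, theta = 0.3, tau = 0, seed = 79)
  expect_false(fit_causal_effect(inst9)$eligible)
  inst10 <- sim_instruments(10, theta = 0.3, tau = 0, seed = 79)
  expect_true(fit_causal_effect(inst10)$eligible)
  expect_error(fit_causal_effect(inst9[1, , drop = FALSE]), "at least 2")
})

test_that("instruments built from locus scores recover the generative slope", {
  # a gene whose standardized expression causes disease with theta = 0.2;
  # instruments are per-locus scores, no pleiotropy
  arch <- make_test_arch(n_genes = 1, n_core = 1, n_trans = 8, coef = 0.2,
                         eff = 0.3, noise = 1, prevalence = 0.2, cis = FALSE)
  panel <- simulate_ld_panel(arch_blocks(arch), 2000, seed = 80)
  qtl <- simulate_qtl_study(panel, arch, 15000, seed = 81)
  cohort <- simulate_cohort(panel, arch, 40000, seed = 82)
  cfg <- gate_config(anchor_p = 1e-5)
  run <- suppressMessages(suppressWarnings(
    gate_pipeline(qtl, panel, cohort, gene_annotation(arch), config = cfg)))
  cohort_scores <- run$scored$locus[["G01"]]
  expect_gte(length(cohort_scores), 6)
  # exposure study: fresh individuals, measured expression
  Gq <- draw_genotypes(panel, 15000, seed = 83)
  set.seed(84)
  expo_raw <- gatescores:::simulate_expression(Gq, arch$genes[[1]])
  expo <- (expo_raw - mean(expo_raw)) / sd(expo_raw)
  qcoh <- make_dosage_cohort(Gq)
  wv_by_clump <- setNames(run$scored$weights,
                          vapply(run$scored$weights, `[[`, character(1), "clump_id"))
  qtl_scores <- lapply(cohort_scores, function(l)
    locus_score(qcoh, wv_by_clump[[l$clump_id]]))
  inst <- build_instruments(qtl_scores, expo, cohort_scores, run$null,
                            gene_id = "G01")
  expect_equal(nrow(inst), length(cohort_scores))
  # points (gamma, Gamma) fall on the slope-theta line within noise
  fit <- fit_causal_effect(inst, min_instruments = 5L)
  expect_equal(fit$theta_hat, 0.2, tolerance = 0.5)
  expect_true(fit$ci_95[1] <= 0.2 && 0.2 <= fit$ci_95[2])
})

test_that("cis loci and zero-variance scores are rejected from instruments", {
  n <- 200
  mk <- function(values, cis = FALSE, id = "c1")
    structure(list(gene_id = "G", clump_id = id, values = values,
                   variance = var(values), is_cis = cis), class = "locus_score")
  set.seed(85)
  y <- rbinom(n, 1, 0.3)
  null <- fit_null(y)
  s1 <- mk(rnorm(n), id = "c1"); s2 <- mk(rnorm(n), id = "c2")
  cis <- mk(rnorm(n), cis = TRUE, id = "c3")
  expo <- rnorm(n)
  expect_error(build_instruments(list(s1, cis), expo, list(s1, cis), null),
               "cis loci")
  flat <- mk(rep(0, n), id = "c4")
  expect_warning(inst <- build_instruments(list(s1, s2, flat), expo,
                                           list(s1, s2, flat), null),
                 "zero-variance")
  expect_equal(nrow(inst), 2)
})
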