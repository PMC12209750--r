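# Efficient score tests under the covariate-only logistic null: closed-form
# oracles, Pearson chi-square equivalence, Monte-Carlo calibration, and the
# SD-standardized one-step log odds ratio against a full ML refit.

test_that("intercept-only and saturated nulls reproduce closed-form fits", {
  y <- rep(c(1, 0), c(25, 75))
  null <- fit_null(y)
  expect_equal(unique(round(null$mu, 10)), 0.25)
  # one binary covariate, strata rates 30/100 and 10/100
  y2 <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  x2 <- data.frame(g = rep(c(1, 0), each = 100))
  null2 <- fit_null(y2, x2)
  expect_equal(sort(unique(round(null2$mu, 8))), c(0.1, 0.3))
})

test_that("degenerate null inputs are rejected", {
  expect_error(fit_null(rep(1, 10)), "both classes")
  expect_error(fit_null(c(0.5, 1, 0)), "binary")
  y <- rep(c(0, 1), 50)
  covs <- data.frame(a = 1:100, b = 2 * (1:100))
  expect_error(fit_null(y, covs), "rank-deficient")
  # complete separation
  ys <- rep(c(0, 1), each = 50)
  xs <- data.frame(z = c(rnorm(50, -10), rnorm(50, 10)))
  expect_error(fit_null(ys, xs), "separation")
})

test_that("score test equals Pearson chi-square on a 2x2 table", {
  # printed fixture: outcome x binary score counts 20/80, 35/65
  y <- c(rep(1, 20), rep(0, 80), rep(1, 35), rep(0, 65))
  s <- rep(c(0, 1), each = 100)
  null <- fit_null(y)
  res <- efficient_score_test(null, s)
  pear <- suppressWarnings(chisq.test(table(s, y), correct = FALSE))
  expect_equal(res$chi2, unname(pear$statistic), tolerance = 1e-10)
  expect_equal(res$pvalue, pear$p.value, tolerance = 1e-10)
})

test_that("a score orthogonal to the residuals gives chi2 = 0, p = 1", {
  y <- rep(c(1, 0), 50)
  null <- fit_null(y)
  s <- rep(c(1, -1), each = 50)  # balanced across cases and controls
  res <- efficient_score_test(null, s)
  expect_equal(res$U, 0)
  expect_equal(res$chi2, 0)
  expect_equal(res$pvalue, 1)
  expect_equal(res$log_or_std, 0)
})

test_that("constant or collinear scores error", {
  y <- rep(c(1, 0), 50)
  covs <- data.frame(x = rnorm(100))
  null <- fit_null(y, covs)
  expect_error(efficient_score_test(null, rep(2, 100)), "constant")
  expect_error(efficient_score_test(null, 3 * covs$x + 1), "collinear")
})

test_that("null simulations reject at the nominal 5% rate", {
  set.seed(61)
  n <- 800
  covs <- data.frame(sex = rbinom(n, 1, 0.5), pc1 = rnorm(n))
  rejections <- vapply(1:2000, function(i) {
    y <- rbinom(n, 1, 0.15)
    null <- fit_null(y, covs)
    efficient_score_test(null, rnorm(n))$pvalue < 0.05
  }, logical(1))
  ci <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
  expect_gte(mean(rejections), ci[1])
  expect_lte(mean(rejections), ci[2])
})

test_that("score-test and LRT p-values agree within 10% for moderate effects", {
  set.seed(62)
  n <- 5000
  checked <- 0
  for (i in 1:30) {
    covs <- data.frame(sex = rbinom(n, 1, 0.5))
    s <- rnorm(n)
    beta <- runif(1, 0.02, 0.09)
    y <- rbinom(n, 1, plogis(-1.5 + 0.3 * covs$sex + beta * s))
    null <- fit_null(y, covs)
    p_score <- efficient_score_test(null, s)$pvalue
    full <- glm(y ~ sex + s, data = cbind(covs, s = s), family = binomial())
    reduced <- glm(y ~ sex, data = covs, family = binomial())
    p_lrt <- pchisq(reduced$deviance - full$deviance, 1, lower.tail = FALSE)
    if (p_lrt >= 0.001 && p_lrt <= 0.5) {
      checked <- checked + 1
      expect_equal(p_score, p_lrt, tolerance = 0.1)
    }
  }
  expect_gte(checked, 5)
})

test_that("standardized log OR is unit-invariant and tracks the ML estimate", {
  set.seed(63)
  n <- 20000
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(-2 + 0.08 * s))
  null <- fit_null(y)
  r1 <- efficient_score_test(null, s)
  r2 <- efficient_score_test(null, 2 * s)
  expect_equal(r2$log_or_std, r1$log_or_std, tolerance = 1e-10)
  expect_equal(r2$U / r2$V, (r1$U / r1$V) / 2, tolerance = 1e-10)
  # weak-effect regime: one-step U/V vs full ML refit within 5% relative
  ml <- unname(coef(glm(y ~ s, family = binomial()))[2])
  expect_equal(r1$U / r1$V, ml, tolerance = 0.05)
})

test_that("adding a covariate orthogonal to residuals and score leaves chi2 unchanged", {
  set.seed(64)
  n <- 4000
  covs <- data.frame(sex = rbinom(n, 1, 0.5))
  s <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 0.5 * covs$sex))
  null1 <- fit_null(y, covs)
  r1 <- efficient_score_test(null1, s)
  # build a covariate numerically orthogonal to both the null residuals and
  # the weighted score direction
  z <- rnorm(n)
  M <- cbind(null1$residuals, s * null1$weights, null1$X * null1$weights)
  z_orth <- z - M %*% solve(crossprod(M), crossprod(M, z))
  null2 <- fit_null(y, cbind(covs, z = as.numeric(z_orth)))
  r2 <- efficient_score_test(null2, s)
  expect_equal(r2$chi2, r1$chi2, tolerance = 1e-6)
})

test_that("measured-level association supports incident-only restriction", {
  set.seed(65)
  n <- 30000
  prot <- rnorm(n)
  y <- rbinom(n, 1, plogis(-3 + 0.5 * prot))
  covs <- data.frame(age = rnorm(n, 55, 8), sex = rbinom(n, 1, 0.5))
  incident <- integer(n)
  incident[y == 1] <- rbinom(sum(y), 1, 0.5)
  r_all <- measured_level_association(prot, y, covs, gene_id = "P1")
  expect_equal(r_all$score_type, "measured_protein")
  expect_equal(r_all$log_or_std, 0.5, tolerance = 0.15)
  r_inc <- measured_level_association(prot, y, covs, incident_flag = incident,
                                      incident_only = TRUE)
  expect_equal(r_inc$n_cases, sum(y == 1 & incident == 1))
  expect_equal(r_inc$n_noncases, sum(y == 0))
  expect_gt(r_inc$log_or_std, 0.2)
})

test_that("proteomics-substudy members are excluded from genotypic-score tests", {
  set.seed(66)
  n <- 2000
  y <- rbinom(n, 1, 0.2)
  covs <- data.frame(sex = rbinom(n, 1, 0.5))
  flag <- rbinom(n, 1, 0.3) == 1
  scored <- list(gate = list(G1 = structure(
    list(gene_id = "G1", values = rnorm(n), n_loci = 2,
         locus_variances = c(1, 1), effective_n = 2, score_sd = 1,
         study = "proteomics_panel"), class = "gate_score")), cis = list())
  null <- fit_null(y, covs)
  res <- gate_association_table(null, scored, exclude = flag,
                                outcome = y, covariates = covs)
  expect_equal(res$n_cases + res$n_noncases, sum(!flag))
})
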