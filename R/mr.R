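# Mendelian randomization with pleiotropy marginalized out. Each trans-QTL
# locus contributes one scalar instrument: its locus score. gamma is the
# instrument's effect on the exposure (the measured transcript/protein),
# Gamma its log-odds effect on disease. Direct (pleiotropic) instrument
# effects alpha_j ~ N(0, tau^2) are integrated analytically, giving the
# marginal likelihood
#   Gamma_j ~ N(theta * gamma_j, se_Gamma_j^2 + theta^2 se_gamma_j^2 + tau^2)
# maximized jointly over the causal effect theta and the pleiotropy scale
# tau; inference on theta is by profile likelihood.

#' Build scalar instruments from trans locus scores
#'
#' One instrument per trans-QTL locus: `gamma` is the univariate regression
#' coefficient of the exposure on the locus score (in exposure-study
#' individuals), and `Gamma` is the one-step log-odds coefficient of disease
#' on the cohort locus score, with standard error `1/sqrt(V)` from the
#' efficient-score machinery. Cis loci are rejected — cis SNPs frequently
#' alter splicing, so their effect on measured levels need not reflect an
#' effect on function.
#'
#' @param qtl_scores List of `locus_score` objects evaluated on the
#'   exposure-study individuals.
#' @param exposure Exposure values (measured expression/protein) for those
#'   individuals.
#' @param cohort_scores List of `locus_score` objects for the same clumps
#'   evaluated on the disease cohort, aligned with `qtl_scores`.
#' @param null A `gate_null_model` for the disease cohort.
#' @param gene_id Gene label.
#' @return Data frame of class `instrument_summary`: gene_id, clump_id,
#'   gamma, se_gamma, Gamma, se_Gamma.
#' @export
build_instruments <- function(qtl_scores, exposure, cohort_scores, null,
                              gene_id = NA_character_) {
  assert_that(length(qtl_scores) == length(cohort_scores),
              "qtl_scores and cohort_scores must align")
  assert_that(length(qtl_scores) >= 2, "at least 2 trans loci are required")
  if (any(vapply(qtl_scores, function(l) isTRUE(l$is_cis), logical(1))) ||
      any(vapply(cohort_scores, function(l) isTRUE(l$is_cis), logical(1)))) {
    stop("cis loci must be excluded from Mendelian randomization", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(qtl_scores)) {
    s <- qtl_scores[[i]]$values
    if (var(s) == 0 || var(cohort_scores[[i]]$values) == 0) {
      warning("zero-variance locus score excluded: ",
              qtl_scores[[i]]$clump_id, call. = FALSE)
      next
    }
    sc <- s - mean(s)
    yc <- exposure - mean(exposure)
    sxx <- sum(sc^2)
    gamma <- sum(sc * yc) / sxx
    df <- length(s) - 2
    se_gamma <- sqrt(max(sum(yc^2) - gamma^2 * sxx, 0) / df / sxx)
    tst <- efficient_score_test(null, cohort_scores[[i]]$values)
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = gene_id, clump_id = qtl_scores[[i]]$clump_id,
      gamma = gamma, se_gamma = se_gamma,
      Gamma = tst$U / tst$V, se_Gamma = 1 / sqrt(tst$V),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("instrument_summary", class(out))
  out
}

#' Marginal log-likelihood of the causal effect
#'
#' Log-likelihood of `(theta, tau)` given instrument summaries, with the
#' Gaussian pleiotropy distribution integrated analytically and the
#' measurement error of `gamma` propagated. There is no intercept term: a
#' shared offset in the outcome coefficients is evidence of directional
#' pleiotropy and is absorbed into tau, not fitted away.
#'
#' @param theta Causal effect of the exposure on disease (log-odds per
#'   exposure unit).
#' @param tau Pleiotropy scale (SD of direct instrument effects), >= 0.
#' @param instruments An `instrument_summary` data frame.
#' @return Scalar log-likelihood.
#' @export
marginal_loglik <- function(theta, tau, instruments) {
  assert_that(is.finite(theta) && is.finite(tau), "theta and tau must be finite")
  assert_that(tau >= 0, "tau must be >= 0")
  v <- instruments$se_Gamma^2 + theta^2 * instruments$se_gamma^2 + tau^2
  sum(dnorm(instruments$Gamma, mean = theta * instruments$gamma,
            sd = sqrt(v), log = TRUE))
}

ivw_estimate <- function(instruments) {
  w <- instruments$gamma^2 / instruments$se_Gamma^2
  theta <- sum(instruments$gamma * instruments$Gamma / instruments$se_Gamma^2) /
    sum(w)
  list(theta = theta, se = 1 / sqrt(sum(w)))
}

#' Fit the causal effect by marginal maximum likelihood
#'
#' Maximizes [marginal_loglik()] over `(theta, tau)` by a bounded tau grid
#' with per-tau profile optimization in theta, followed by local refinement.
#' The p-value is the likelihood-ratio test of `theta = 0` with tau free
#' under both hypotheses; the 95% CI is the profile-likelihood interval. A
#' gene is flagged eligible only with at least `min_instruments` (default
#' 10) trans-QTLs: with fewer there is not enough information to learn the
#' pleiotropy distribution, and results are advisory only.
#'
#' @param instruments An `instrument_summary` data frame (>= 2 rows).
#' @param min_instruments Eligibility threshold (default 10).
#' @param tau_grid_n Number of grid points for the tau profile (default 25).
#' @return Object of class `mr_result`: gene_id, theta_hat, ci_95, pvalue,
#'   tau_hat, n_instruments, eligible, converged, loglik.
#' @export
fit_causal_effect <- function(instruments, min_instruments = 10L,
                              tau_grid_n = 25L) {
  n_inst <- nrow(instruments)
  assert_that(n_inst >= 2, "at least 2 instruments are required")
  assert_that(all(is.finite(instruments$gamma)) &&
                all(is.finite(instruments$Gamma)) &&
                all(instruments$se_gamma > 0 | instruments$se_gamma == 0) &&
                all(instruments$se_Gamma > 0),
              "instrument summaries must be finite with positive se_Gamma")
  tau_max <- 3 * max(sd(instruments$Gamma), max(instruments$se_Gamma))
  taus <- seq(0, tau_max, length.out = tau_grid_n)
  ivw <- ivw_estimate(instruments)
  half <- max(10 * ivw$se, 3 * tau_max / max(abs(instruments$gamma)),
              2 * abs(ivw$theta))
  th_int <- ivw$theta + c(-1, 1) * half

  prof_theta <- function(tau) {
    o <- optimize(function(th) marginal_loglik(th, tau, instruments),
                  interval = th_int, maximum = TRUE, tol = 1e-8)
    c(theta = o$maximum, ll = o$objective)
  }
  grid <- vapply(taus, prof_theta, numeric(2))
  best <- which.max(grid["ll", ])
  start <- c(grid["theta", best], taus[best])
  opt <- optim(start, function(p) -marginal_loglik(p[1], p[2], instruments),
               method = "L-BFGS-B",
               lower = c(th_int[1], 0), upper = c(th_int[2], 2 * tau_max))
  converged <- opt$convergence == 0
  theta_hat <- unname(opt$par[1]); tau_hat <- unname(opt$par[2])
  ll1 <- -opt$value
  ll0 <- optimize(function(tau) marginal_loglik(0, tau, instruments),
                  interval = c(0, 2 * tau_max), maximum = TRUE,
                  tol = 1e-8)$objective
  lr <- max(0, 2 * (ll1 - ll0))
  pvalue <- pchisq(lr, df = 1, lower.tail = FALSE)

  # Profile-likelihood 95% CI for theta.
  prof <- function(th) optimize(function(tau) marginal_loglik(th, tau, instruments),
                                interval = c(0, 2 * tau_max), maximum = TRUE,
                                tol = 1e-8)$objective
  cut <- ll1 - qchisq(0.95, 1) / 2
  ci <- c(NA_real_, NA_real_)
  step <- max(abs(theta_hat) + 4 * ivw$se, 8 * ivw$se, 1e-3)
  for (side in 1:2) {
    dir <- if (side == 1) -1 else 1
    lo <- theta_hat; hi <- theta_hat + dir * step
    for (k in 1:40) {
      if (prof(hi) < cut) break
      hi <- theta_hat + dir * step * 2^k
    }
    if (prof(hi) < cut) {
      r <- uniroot(function(th) prof(th) - cut, sort(c(lo, hi)), tol = 1e-7)
      ci[side] <- r$root
    }
  }
  structure(list(gene_id = instruments$gene_id[1] %||% NA_character_,
                 theta_hat = theta_hat, ci_95 = ci, pvalue = pvalue,
                 tau_hat = tau_hat, n_instruments = n_inst,
                 eligible = n_inst >= min_instruments,
                 converged = converged, loglik = ll1),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR fit for %s: theta = %.4f [%.4f, %.4f], tau = %.4f, p = %.3g (%d instruments%s)\n",
              x$gene_id, x$theta_hat, x$ci_95[1], x$ci_95[2], x$tau_hat,
              x$pvalue, x$n_instruments,
              if (x$eligible) "" else "; ineligible, advisory only"))
  invisible(x)
}

#' Tabulate MR results
#'
#' @param results List of `mr_result` objects.
#' @return Data frame: gene_id, theta_hat, ci_lo, ci_hi, pvalue, tau_hat,
#'   n_instruments, eligible.
#' @export
mr_table <- function(results) {
  do.call(rbind, lapply(results, function(r) data.frame(
    gene_id = r$gene_id, theta_hat = r$theta_hat, ci_lo = r$ci_95[1],
    ci_hi = r$ci_95[2], pvalue = r$pvalue, tau_hat = r$tau_hat,
    n_instruments = r$n_instruments, eligible = r$eligible,
    stringsAsFactors = FALSE)))
}
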