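# Efficient score tests under the covariate-only logistic null. The null
# model (outcome ~ sex + PCs) is fitted once and reused across thousands of
# scores: for a tested score s, U = s'(y - mu) is the gradient of the
# log-likelihood in the score's coefficient at the null, and
# V = s'Ws - s'WX (X'WX)^-1 X'Ws is the efficient information, i.e. the
# second-derivative term with the covariate directions projected out
# (W = diag(mu(1-mu))). chi2 = U^2/V is compared with a 1-df chi-square.

#' Fit the covariate-only logistic null model
#'
#' Maximum-likelihood logistic regression of the binary outcome on the
#' covariates (an intercept is added). The fitted probabilities and the
#' projection machinery are cached so that every subsequent score test is a
#' few vector operations.
#'
#' @param outcome Binary 0/1 vector with both classes present.
#' @param covariates Data frame or matrix of covariates (no intercept
#'   column; one is added).
#' @return Object of class `gate_null_model`: mu (fitted probabilities),
#'   weights mu(1-mu), residuals y - mu, the covariate matrix, a QR
#'   factorization of sqrt(W) X, n_cases, n_noncases, convergence flag.
#' @export
fit_null <- function(outcome, covariates = NULL) {
  y <- as.numeric(outcome)
  assert_that(all(y %in% c(0, 1)), "outcome must be binary 0/1")
  assert_that(length(unique(y)) == 2, "outcome must contain both classes")
  X <- if (is.null(covariates)) {
    matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    stats::model.matrix(~ ., data = as.data.frame(covariates))
  }
  assert_that(nrow(X) == length(y), "covariate rows must align with outcome")
  if (qr(X)$rank < ncol(X)) {
    stop("covariate matrix is rank-deficient; drop collinear columns",
         call. = FALSE)
  }
  # separation is detected explicitly below; muffle glm.fit's own warning
  fit <- withCallingHandlers(
    glm.fit(X, y, family = binomial(),
            control = list(epsilon = 1e-12, maxit = 50)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  mu <- fit$fitted.values
  if (!fit$converged || min(mu) < 1e-10 || max(mu) > 1 - 1e-10) {
    stop("logistic null fit did not converge cleanly (possible separation); ",
         "consider a penalized fit or fewer covariates", call. = FALSE)
  }
  grad <- crossprod(X, y - mu)
  if (max(abs(grad)) > 1e-6) {
    stop("null-model gradient not at zero (max |grad| = ",
         format(max(abs(grad))), ")", call. = FALSE)
  }
  w <- mu * (1 - mu)
  structure(list(mu = mu, weights = w, residuals = y - mu, X = X,
                 qr_sw = qr(X * sqrt(w)), n = length(y),
                 n_cases = sum(y == 1), n_noncases = sum(y == 0),
                 converged = fit$converged),
            class = "gate_null_model")
}

#' Efficient score test of one score against the null model
#'
#' Tests association of a per-individual score with the outcome using the
#' gradient and efficient information of the logistic log-likelihood at the
#' covariate-only null. Reports the 1-df chi-square p-value and the
#' SD-standardized log odds ratio: the one-step estimator U/V times the SD
#' of the score, i.e. the log odds ratio per one-SD increase of the score.
#'
#' @param null A `gate_null_model` from [fit_null()].
#' @param score_values Numeric per-individual score, aligned with the
#'   cohort; must not be constant.
#' @param gene_id,score_type,effective_n,n_loci Metadata carried through to
#'   the result row.
#' @return One-row data frame (class `association_result`): gene_id,
#'   score_type, n_loci, effective_n, U, V, chi2, pvalue, log_or_std,
#'   score_sd, n_cases, n_noncases.
#' @export
efficient_score_test <- function(null, score_values, gene_id = NA_character_,
                                 score_type = "trans", effective_n = NA_real_,
                                 n_loci = NA_integer_) {
  assert_that(inherits(null, "gate_null_model"), "null must be a gate_null_model")
  s <- as.numeric(score_values)
  assert_that(length(s) == null$n, "score length must match the cohort")
  s_sd <- sd(s)
  if (!is.finite(s_sd) || s_sd == 0) {
    stop("score is constant; nothing to test", call. = FALSE)
  }
  U <- sum(s * null$residuals)
  sw <- s * sqrt(null$weights)
  proj <- qr.fitted(null$qr_sw, sw)
  V <- sum(sw^2) - sum(proj^2)
  if (V <= 1e-10 * sum(sw^2)) {
    stop("efficient information is numerically zero: score collinear with covariates",
         call. = FALSE)
  }
  chi2 <- U^2 / V
  res <- data.frame(gene_id = gene_id, score_type = score_type,
                    n_loci = n_loci, effective_n = effective_n,
                    U = U, V = V, chi2 = chi2,
                    pvalue = pchisq(chi2, df = 1, lower.tail = FALSE),
                    log_or_std = (U / V) * s_sd, score_sd = s_sd,
                    n_cases = null$n_cases, n_noncases = null$n_noncases,
                    stringsAsFactors = FALSE)
  class(res) <- c("association_result", class(res))
  res
}

#' Test all GATE (and cis) scores of a cohort
#'
#' @param null A `gate_null_model`.
#' @param scored Output of [score_cohort()].
#' @param exclude Optional logical vector of individuals to exclude (e.g.
#'   proteomics-substudy members when testing genotypic scores derived from
#'   that substudy); a fresh null model is fitted on the remainder.
#' @param outcome,covariates Required when `exclude` is used, to refit the
#'   null on the retained subset.
#' @return Data frame of association results, one row per gene x score type.
#' @export
gate_association_table <- function(null, scored, exclude = NULL,
                                   outcome = NULL, covariates = NULL) {
  if (!is.null(exclude) && any(exclude)) {
    assert_that(!is.null(outcome), "outcome needed to refit the null on a subset")
    keep <- !exclude
    null <- fit_null(outcome[keep],
                     if (!is.null(covariates)) covariates[keep, , drop = FALSE])
    subset_values <- function(v) v[keep]
  } else {
    subset_values <- identity
  }
  rows <- list()
  for (g in names(scored$gate)) {
    gs <- scored$gate[[g]]
    rows[[length(rows) + 1L]] <-
      efficient_score_test(null, subset_values(gs$values), gene_id = g,
                           score_type = "trans", effective_n = gs$effective_n,
                           n_loci = gs$n_loci)
  }
  for (g in names(scored$cis)) {
    rows[[length(rows) + 1L]] <-
      efficient_score_test(null, subset_values(scored$cis[[g]]$values),
                           gene_id = g, score_type = "cis")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Association of a measured level with disease
#'
#' Applies the same efficient-score machinery to a measured (not genotypic)
#' predictor, standardized to unit SD so the reported log odds ratio is per
#' SD of the measured level. Supports restriction to incident cases:
#' individuals who were already cases at baseline are dropped, so the tested
#' contrast is incident disease versus non-cases.
#'
#' @param values Measured per-individual level (e.g. a plasma protein).
#' @param outcome Binary outcome vector.
#' @param covariates Covariate data frame (e.g. age, sex, ancestry).
#' @param incident_flag Optional 0/1 vector; with `incident_only = TRUE`,
#'   prevalent cases (outcome 1, incident_flag 0) are excluded.
#' @param incident_only Restrict cases to incident ones.
#' @param gene_id Label for the result row.
#' @return One-row association result with `score_type = "measured_protein"`.
#' @export
measured_level_association <- function(values, outcome, covariates = NULL,
                                       incident_flag = NULL,
                                       incident_only = FALSE,
                                       gene_id = NA_character_) {
  keep <- rep(TRUE, length(outcome))
  if (incident_only) {
    assert_that(!is.null(incident_flag), "incident_flag needed for incident_only")
    keep <- !(outcome == 1 & incident_flag == 0)
  }
  v <- values[keep]
  v <- (v - mean(v)) / sd(v)
  null <- fit_null(outcome[keep],
                   if (!is.null(covariates)) covariates[keep, , drop = FALSE])
  efficient_score_test(null, v, gene_id = gene_id,
                       score_type = "measured_protein")
}
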