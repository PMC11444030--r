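#' Quasi-Bayesian causal mediation for a single mediator
#'
#' Estimates the average causal mediation effect (ACME) and average direct
#' effect (ADE) on the prevalence-difference scale from a fitted mediator
#' model and a fitted outcome model, using quasi-Bayesian Monte Carlo:
#' `n_sims` parameter vectors are drawn from a multivariate normal centred at
#' the estimates with the cluster-robust covariance (clustered on the study
#' block by default), and for each draw the counterfactual quantities
#' `ACME(t) = mean[Y(t, M(1)) - Y(t, M(0))]` and
#' `ADE(t) = mean[Y(1, M(t)) - Y(0, M(t))]` are computed over the analysis
#' rows. Reported averages are the conditional estimates weighted by the arm
#' proportions; confidence intervals are draw percentiles and the two-sided
#' p-value is the tail fraction of the draw distribution.
#'
#' For binary and ordinal mediators the expectation over the mediator's
#' simulated distribution is computed exactly (the support is finite), which
#' leaves the estimand unchanged while removing Monte-Carlo noise from the
#' mediator draw; count mediators are drawn Poisson and gaussian mediators
#' use their conditional mean. Potential outcomes are expected probabilities,
#' not Bernoulli draws.
#'
#' A negative ACME means the pathway through the mediator was protective.
#'
#' @param records data.frame on which both models were fit (used for row-set
#'   validation and arm weights).
#' @param mediator_spec a [mediator_spec()] naming the mediator and its type.
#' @param mediator_fit converged [fit_model()] result for mediator ~
#'   treatment (+ block, covariates).
#' @param outcome_fit converged [fit_model()] result for outcome ~ treatment
#'   + mediator (+ interaction, block, covariates), fit on the identical
#'   row set.
#' @param treat treatment column name (0/1).
#' @param n_sims number of quasi-Bayesian draws (the published analysis used
#'   1000).
#' @param cluster_var column for the parameter-draw covariance clustering
#'   (default `"block_id"`).
#' @param seed RNG seed; fixing it reproduces the result exactly.
#' @param vcov_type `"cluster"` (default), `"model"`, or `"zero"`
#'   (degenerate covariance; draws collapse to the point estimates, used by
#'   closed-form oracles).
#' @return object of class `crt_mediation`.
#' @export
mediate_single <- function(records, mediator_spec, mediator_fit, outcome_fit,
                           treat = "arm", n_sims = 1000,
                           cluster_var = "block_id", seed = NULL,
                           vcov_type = c("cluster", "model", "zero")) {
  vcov_type <- match.arg(vcov_type)
  stopifnot(inherits(mediator_fit, "crt_fit"), inherits(outcome_fit, "crt_fit"))
  if (!mediator_fit$converged) stopf("mediator model did not converge")
  if (!outcome_fit$converged) stopf("outcome model did not converge")
  if (mediator_fit$n_obs != outcome_fit$n_obs ||
      !identical(mediator_fit$rows_used, outcome_fit$rows_used)) {
    stopf("mediator and outcome models were not fit on the identical row set (n = %d vs %d)",
          mediator_fit$n_obs, outcome_fit$n_obs)
  }
  med <- mediator_spec$name
  if (!treat %in% names(outcome_fit$coefficients) &&
      !any(grepl(treat, names(outcome_fit$coefficients), fixed = TRUE))) {
    stopf("outcome model has no treatment term '%s'", treat)
  }
  dat <- mediator_fit$data
  w1 <- mean(dat[[treat]] == 1)
  w0 <- 1 - w1

  if (!is.null(seed)) set.seed(seed)
  theta_m <- param_draws(mediator_fit, n_sims, cluster_var, vcov_type)
  theta_y <- param_draws(outcome_fit, n_sims, cluster_var, vcov_type)

  kind <- mediator_kind(mediator_spec, mediator_fit)
  draws <- switch(kind,
    binary = mediate_draws_discrete(dat, med, mediator_fit, outcome_fit,
                                    treat, theta_m, theta_y, values = c(0, 1)),
    ordinal = mediate_draws_discrete(dat, med, mediator_fit, outcome_fit,
                                     treat, theta_m, theta_y, values = NULL),
    count = mediate_draws_numeric(dat, med, mediator_fit, outcome_fit,
                                  treat, theta_m, theta_y, stochastic = TRUE),
    gaussian = mediate_draws_numeric(dat, med, mediator_fit, outcome_fit,
                                     treat, theta_m, theta_y, stochastic = FALSE)
  )
  new_crt_mediation(draws, w0, w1, method = "quasi-bayes",
                    mediator = med, n_obs = nrow(dat), n_sims = n_sims,
                    seed = seed)
}

mediator_kind <- function(mediator_spec, mediator_fit) {
  if (mediator_fit$family == "gaussian") return("gaussian")
  switch(mediator_spec$type,
         binary = "binary", ordinal = "ordinal", count = "count")
}

param_draws <- function(fit, n_sims, cluster_var, vcov_type) {
  mu <- fit$coefficients
  V <- switch(vcov_type,
    cluster = cluster_robust_vcov(fit, cluster_var),
    model = fit$vcov_model,
    zero = matrix(0, length(mu), length(mu)))
  if (all(V == 0)) {
    return(matrix(mu, nrow = n_sims, ncol = length(mu), byrow = TRUE,
                  dimnames = list(NULL, names(mu))))
  }
  # Eigen sampler tolerant of positive semi-definite covariance (the
  # block-clustered sandwich is rank-deficient when parameters outnumber
  # blocks); negative rounding-error eigenvalues are clipped at zero.
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  A <- e$vectors %*% (t(e$vectors) * sqrt(lam))
  z <- matrix(stats::rnorm(n_sims * length(mu)), nrow = n_sims)
  d <- sweep(z %*% t(A), 2, mu, "+")
  colnames(d) <- names(mu)
  d
}

# Design matrix for counterfactual data under stored terms/xlevels.
cf_model_matrix <- function(fit, dat, assign_cols) {
  m <- fit$model
  tt <- stats::delete.response(stats::terms(m))
  nd <- dat
  for (nm in names(assign_cols)) nd[[nm]] <- assign_cols[[nm]]
  xlev <- fit$xlevels
  stats::model.matrix(tt, data = nd, xlev = xlev)
}

outcome_linkinv <- function(fit) {
  fam <- fit$family
  switch(fam,
    "binomial-log" = , "modified-poisson" = , "poisson" =
      function(eta) pmin(exp(eta), 1),
    "binomial-logit" = stats::plogis,
    "gaussian" = identity,
    stopf("unsupported outcome family '%s'", fam))
}

mediator_linkinv <- function(fit) {
  switch(fit$family,
    "binomial-log" = , "modified-poisson" = function(eta) clamp01(exp(eta)),
    "binomial-logit" = stats::plogis,
    "poisson" = exp,
    "gaussian" = identity,
    stopf("unsupported mediator family '%s'", fit$family))
}

# Exact-expectation path for mediators with finite support (binary levels
# c(0,1), or the ordinal factor levels of the outcome model).
mediate_draws_discrete <- function(dat, med, mfit, yfit, treat,
                                   theta_m, theta_y, values) {
  n_sims <- nrow(theta_m)
  n <- nrow(dat)
  ordinal <- is.null(values)
  if (ordinal) {
    lev <- levels(factor(mfit$data[[med]]))
    K <- length(lev)
  } else {
    lev <- values
    K <- length(values)
  }
  # Outcome design matrices for every (t, mediator level) combination.
  Xy <- vector("list", 2L * K)
  dim(Xy) <- c(2L, K)
  for (ti in 1:2) {
    for (k in seq_len(K)) {
      mval <- if (ordinal) factor(lev[k], levels = lev) else lev[k]
      Xy[[ti, k]] <- cf_model_matrix(yfit, dat,
                                     stats::setNames(list(ti - 1L, mval),
                                                     c(treat, med)))
    }
  }
  linkinv_y <- outcome_linkinv(yfit)

  if (ordinal) {
    Xm <- stats::model.matrix(stats::delete.response(stats::terms(mfit$model)),
                              data = transform_treat(dat, treat, 0L),
                              xlev = mfit$xlevels)
    Xm1 <- stats::model.matrix(stats::delete.response(stats::terms(mfit$model)),
                               data = transform_treat(dat, treat, 1L),
                               xlev = mfit$xlevels)
    p_beta <- length(mfit$coefficients) - length(mfit$cutpoints)
    Xm <- Xm[, -1, drop = FALSE]; Xm1 <- Xm1[, -1, drop = FALSE]
  } else {
    Xm0b <- cf_model_matrix(mfit, dat, stats::setNames(list(0L), treat))
    Xm1b <- cf_model_matrix(mfit, dat, stats::setNames(list(1L), treat))
    linkinv_m <- mediator_linkinv(mfit)
  }

  acme0 <- acme1 <- ade0 <- ade1 <- total <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    thy <- theta_y[s, ]
    mu <- array(0, dim = c(2L, K, n))
    for (ti in 1:2) for (k in seq_len(K)) {
      mu[ti, k, ] <- linkinv_y(drop(Xy[[ti, k]] %*% thy))
    }
    if (ordinal) {
      thm <- theta_m[s, ]
      beta <- thm[seq_len(p_beta)]
      zeta <- thm[-seq_len(p_beta)]
      P0 <- ordinal_probs(drop(Xm %*% beta), zeta)
      P1 <- ordinal_probs(drop(Xm1 %*% beta), zeta)
    } else {
      p0 <- linkinv_m(drop(Xm0b %*% theta_m[s, ]))
      p1 <- linkinv_m(drop(Xm1b %*% theta_m[s, ]))
      P0 <- cbind(1 - p0, p0)
      P1 <- cbind(1 - p1, p1)
    }
    # Ybar(t, M ~ P) = sum_k P_k * mu[t, k, ]
    ybar <- function(ti, P) {
      out <- numeric(n)
      for (k in seq_len(K)) out <- out + P[, k] * mu[ti, k, ]
      out
    }
    y_0_M0 <- ybar(1L, P0); y_0_M1 <- ybar(1L, P1)
    y_1_M0 <- ybar(2L, P0); y_1_M1 <- ybar(2L, P1)
    acme0[s] <- mean(y_0_M1 - y_0_M0)
    acme1[s] <- mean(y_1_M1 - y_1_M0)
    ade0[s] <- mean(y_1_M0 - y_0_M0)
    ade1[s] <- mean(y_1_M1 - y_0_M1)
    total[s] <- mean(y_1_M1 - y_0_M0)
  }
  list(acme0 = acme0, acme1 = acme1, ade0 = ade0, ade1 = ade1, total = total)
}

transform_treat <- function(dat, treat, value) {
  dat[[treat]] <- value
  dat
}

# Category probabilities under a proportional-odds model.
ordinal_probs <- function(eta, zeta) {
  K <- length(zeta) + 1L
  cum <- vapply(zeta, function(z) stats::plogis(z - eta), numeric(length(eta)))
  cum <- cbind(cum, 1)
  P <- cum
  for (k in K:2) P[, k] <- cum[, k] - cum[, k - 1]
  P
}

# Simulated-value path for count (Poisson draws) and gaussian (conditional
# mean) mediators.
mediate_draws_numeric <- function(dat, med, mfit, yfit, treat,
                                  theta_m, theta_y, stochastic) {
  n_sims <- nrow(theta_m)
  n <- nrow(dat)
  Xm0 <- cf_model_matrix(mfit, dat, stats::setNames(list(0L), treat))
  Xm1 <- cf_model_matrix(mfit, dat, stats::setNames(list(1L), treat))
  linkinv_m <- mediator_linkinv(mfit)
  linkinv_y <- outcome_linkinv(yfit)
  acme0 <- acme1 <- ade0 <- ade1 <- total <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    em0 <- linkinv_m(drop(Xm0 %*% theta_m[s, ]))
    em1 <- linkinv_m(drop(Xm1 %*% theta_m[s, ]))
    if (stochastic) {
      M0 <- stats::rpois(n, em0)
      M1 <- stats::rpois(n, em1)
    } else {
      M0 <- em0
      M1 <- em1
    }
    thy <- theta_y[s, ]
    mu <- function(ti, Mv) {
      X <- cf_model_matrix(yfit, dat,
                           stats::setNames(list(ti, Mv), c(treat, med)))
      linkinv_y(drop(X %*% thy))
    }
    y_0_M0 <- mu(0L, M0); y_0_M1 <- mu(0L, M1)
    y_1_M0 <- mu(1L, M0); y_1_M1 <- mu(1L, M1)
    acme0[s] <- mean(y_0_M1 - y_0_M0)
    acme1[s] <- mean(y_1_M1 - y_1_M0)
    ade0[s] <- mean(y_1_M0 - y_0_M0)
    ade1[s] <- mean(y_1_M1 - y_0_M1)
    total[s] <- mean(y_1_M1 - y_0_M0)
  }
  list(acme0 = acme0, acme1 = acme1, ade0 = ade0, ade1 = ade1, total = total)
}

new_crt_mediation <- function(draws, w0, w1, method, mediator, n_obs,
                              n_sims, seed) {
  acme_avg <- avg_conditional(draws$acme0, draws$acme1, w0, w1)
  ade_avg <- avg_conditional(draws$ade0, draws$ade1, w0, w1)
  comp <- list(acme_avg = acme_avg, ade_avg = ade_avg, total = draws$total,
               acme_0 = draws$acme0, acme_1 = draws$acme1,
               ade_0 = draws$ade0, ade_1 = draws$ade1)
  est <- data.frame(
    effect = names(comp),
    estimate = vapply(comp, mean, 0),
    ci_low = vapply(comp, function(d) pct_ci(d)[1], 0),
    ci_high = vapply(comp, function(d) pct_ci(d)[2], 0),
    p = vapply(comp, tail_pvalue, 0),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(estimates = est, draws = draws, weights = c(w0 = w0, w1 = w1),
                 method = method, mediator = mediator, n_obs = n_obs,
                 n_sims = n_sims, seed = seed),
            class = "crt_mediation")
}

#' Extract a single effect estimate from a mediation result
#'
#' @param x `crt_mediation` object.
#' @param effect one of `"acme_avg"`, `"ade_avg"`, `"total"`, `"acme_0"`,
#'   `"acme_1"`, `"ade_0"`, `"ade_1"`.
#' @return one-row data.frame with estimate, CI, p.
#' @export
mediation_effect <- function(x, effect = "acme_avg") {
  stopifnot(inherits(x, "crt_mediation"))
  row <- x$estimates[x$estimates$effect == effect, ]
  if (!nrow(row)) stopf("unknown effect '%s'", effect)
  row
}

#' @export
print.crt_mediation <- function(x, digits = 4, ...) {
  cat("<crt_mediation>", x$method, " mediator:", x$mediator, "\n")
  cat(sprintf("  n = %d, sims = %d, weights (control, treated) = (%.3f, %.3f)\n",
              x$n_obs, x$n_sims, x$weights["w0"], x$weights["w1"]))
  est <- x$estimates
  est[, 2:5] <- round(est[, 2:5], digits)
  print(est, row.names = FALSE)
  invisible(x)
}
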