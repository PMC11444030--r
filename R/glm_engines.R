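#' Model specification for pipeline regressions
#'
#' @param outcome name of the outcome column.
#' @param terms character vector of predictor terms (formula syntax allowed,
#'   e.g. `"arm"`, `"arm:mediator"`, `"factor(block_id)"`).
#' @param family one of `"binomial-log"` (log-binomial with automatic
#'   modified-Poisson fallback), `"modified-poisson"` (Poisson/log on a
#'   binary outcome), `"poisson"` (counts), `"ordinal-logit"`
#'   (proportional odds), `"gaussian"` (identity-link linear model, used by
#'   the linear-probability mediation estimators), or `"binomial-logit"`.
#' @param cluster_var column used to group score contributions in the
#'   cluster-robust sandwich (default `"cluster_id"`).
#' @return list of class `crt_model_spec`.
#' @export
model_spec <- function(outcome, terms,
                       family = c("binomial-log", "modified-poisson",
                                  "poisson", "ordinal-logit", "gaussian",
                                  "binomial-logit"),
                       cluster_var = "cluster_id") {
  family <- match.arg(family)
  stopifnot(is.character(outcome), length(outcome) == 1L,
            is.character(terms), length(terms) >= 1L)
  structure(list(outcome = outcome, terms = terms, family = family,
                 cluster_var = cluster_var),
            class = "crt_model_spec")
}

spec_formula <- function(spec) {
  stats::as.formula(paste(spec$outcome, "~", paste(spec$terms, collapse = " + ")))
}

#' Fit a pipeline regression with cluster-robust variance
#'
#' Fits the family-appropriate model for a mediator or outcome regression:
#' log-binomial for binary variables (falling back to modified Poisson when
#' the log-binomial fit does not converge or produces fitted probabilities at
#' the boundary), Poisson for counts, and proportional-odds logistic for
#' ordinal variables. Robust standard errors are computed with the CR1
#' cluster sandwich to account for cluster randomization and repeated
#' measures.
#'
#' Degenerate outcomes (no variation) yield a non-converged [crt_fit] rather
#' than an error, so screening loops can record the failure and move on.
#'
#' @param records data.frame of survey records.
#' @param spec a [model_spec()].
#' @return object of class `crt_fit` with elements `coefficients`,
#'   `vcov_robust`, `vcov_model`, `n_obs`, `n_clusters`, `converged`,
#'   `family` (the family actually used), `fallback` (TRUE when a
#'   log-binomial was refit as modified Poisson), `cutpoints` (ordinal
#'   only), and internal fitting state used by the mediation estimators.
#' @export
fit_model <- function(records, spec) {
  stopifnot(inherits(spec, "crt_model_spec"))
  f <- spec_formula(spec)
  vars <- all.vars(f)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols)) {
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (!spec$cluster_var %in% names(records)) {
    stopf("cluster variable '%s' not in records", spec$cluster_var)
  }
  keep <- stats::complete.cases(records[, vars, drop = FALSE])
  dat <- records[keep, , drop = FALSE]
  rows_used <- which(keep)
  cl <- dat[[spec$cluster_var]]
  n_clusters <- length(unique(cl))
  if (n_clusters < 2) stopf("need >= 2 clusters, got %d", n_clusters)

  y <- dat[[spec$outcome]]
  degenerate <- length(unique(y[!is.na(y)])) < 2
  if (degenerate) {
    return(new_crt_fit(NULL, spec, dat, rows_used, n_clusters,
                       converged = FALSE, fallback = FALSE,
                       reason = "degenerate outcome (no variation)"))
  }

  if (spec$family == "ordinal-logit") {
    return(fit_ordinal(f, spec, dat, rows_used, n_clusters))
  }

  fam_used <- spec$family
  fallback <- FALSE
  fit <- switch(spec$family,
    "binomial-log" = try_log_binomial(f, dat),
    "modified-poisson" = quiet_glm(f, dat, stats::poisson(link = "log")),
    "poisson" = quiet_glm(f, dat, stats::poisson(link = "log")),
    "binomial-logit" = quiet_glm(f, dat, stats::binomial(link = "logit")),
    "gaussian" = quiet_glm(f, dat, stats::gaussian())
  )
  if (spec$family == "binomial-log" && is.null(fit)) {
    # Modified Poisson: Poisson regression with log link on the binary
    # outcome; robust variance restores valid inference.
    fit <- quiet_glm(f, dat, stats::poisson(link = "log"))
    fam_used <- "modified-poisson"
    fallback <- TRUE
  }
  if (is.null(fit) || !fit$converged) {
    return(new_crt_fit(NULL, spec, dat, rows_used, n_clusters,
                       converged = FALSE, fallback = fallback,
                       reason = "optimizer did not converge"))
  }
  if (anyNA(stats::coef(fit))) {
    return(new_crt_fit(NULL, spec, dat, rows_used, n_clusters,
                       converged = FALSE, fallback = fallback,
                       reason = "aliased (collinear) terms"))
  }
  out <- new_crt_fit(fit, spec, dat, rows_used, n_clusters,
                     converged = TRUE, fallback = fallback)
  out$family <- fam_used
  out
}

quiet_glm <- function(f, dat, family) {
  fit <- suppressWarnings(tryCatch(
    stats::glm(f, data = dat, family = family),
    error = function(e) NULL))
  fit
}

# Log-binomial fits are fragile; start at the null model and declare failure
# on non-convergence or boundary fitted probabilities (>= 1 - 1e-8).
try_log_binomial <- function(f, dat) {
  y <- stats::model.response(stats::model.frame(f, dat))
  p0 <- mean(y)
  nterms <- ncol(stats::model.matrix(f, dat))
  start <- c(log(max(p0, 1e-6)), rep(0, nterms - 1))
  fit <- suppressWarnings(tryCatch(
    stats::glm(f, data = dat, family = stats::binomial(link = "log"),
               start = start),
    error = function(e) NULL))
  if (is.null(fit) || !fit$converged) return(NULL)
  if (any(fit$fitted.values >= 1 - 1e-8)) return(NULL)
  fit
}

fit_ordinal <- function(f, spec, dat, rows_used, n_clusters) {
  yname <- spec$outcome
  yfac <- dat[[yname]]
  if (!is.factor(yfac)) yfac <- factor(yfac)
  yfac <- droplevels(yfac)
  dat[[yname]] <- yfac
  if (nlevels(yfac) < 2) {
    return(new_crt_fit(NULL, spec, dat, rows_used, n_clusters,
                       converged = FALSE, fallback = FALSE,
                       reason = "degenerate outcome (single level)"))
  }
  if (nlevels(yfac) == 2L) {
    # polr needs >= 3 levels; a two-level proportional-odds model IS binary
    # logistic regression, re-expressed with cutpoint = -intercept.
    return(fit_ordinal_binary(f, spec, dat, rows_used, n_clusters, yfac))
  }
  fit <- suppressWarnings(tryCatch(
    MASS::polr(f, data = dat, Hess = TRUE, method = "logistic"),
    error = function(e) NULL))
  if (is.null(fit)) {
    return(new_crt_fit(NULL, spec, dat, rows_used, n_clusters,
                       converged = FALSE, fallback = FALSE,
                       reason = "polr failed"))
  }
  out <- new_crt_fit(fit, spec, dat, rows_used, n_clusters,
                     converged = TRUE, fallback = FALSE)
  out$cutpoints <- fit$zeta
  out
}

# Two-level "ordinal" fit via logistic regression, presented in polr
# parameterisation: P(Y = 2) = plogis(x'beta - zeta), so beta is the glm slope
# vector and zeta = -(glm intercept). The signed permutation is kept so that
# re-clustered sandwich covariances stay in polr order.
fit_ordinal_binary <- function(f, spec, dat, rows_used, n_clusters, yfac) {
  dat$.ybin <- as.integer(yfac == levels(yfac)[2])
  rhs <- paste(deparse(f[[3]]), collapse = " ")
  f2 <- stats::as.formula(paste(".ybin ~", rhs))
  glmfit <- quiet_glm(f2, dat, stats::binomial(link = "logit"))
  if (is.null(glmfit) || !glmfit$converged || anyNA(stats::coef(glmfit))) {
    return(new_crt_fit(NULL, spec, dat, rows_used, n_clusters,
                       converged = FALSE, fallback = FALSE,
                       reason = "two-level logistic fit failed"))
  }
  out <- new_crt_fit(glmfit, spec, dat, rows_used, n_clusters,
                     converged = TRUE, fallback = FALSE)
  p <- length(out$coefficients)
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) P[i, i + 1] <- 1
  P[p, 1] <- -1
  cut_name <- paste(levels(yfac), collapse = "|")
  nms <- c(names(out$coefficients)[-1], cut_name)
  out$param_transform <- P
  out$coefficients <- stats::setNames(drop(P %*% out$coefficients), nms)
  out$vcov_model <- relabel_vcov(P %*% out$vcov_model %*% t(P), nms)
  out$vcov_robust <- relabel_vcov(P %*% out$vcov_robust %*% t(P), nms)
  out$cutpoints <- out$coefficients[cut_name]
  out$family <- "ordinal-logit"
  out
}

relabel_vcov <- function(V, nms) {
  dimnames(V) <- list(nms, nms)
  V
}

new_crt_fit <- function(fit, spec, dat, rows_used, n_clusters,
                        converged, fallback, reason = NULL) {
  coefs <- if (is.null(fit)) NULL else full_coefs(fit)
  vc_model <- if (is.null(fit)) NULL else model_vcov(fit)
  vc_robust <- NULL
  if (!is.null(fit)) {
    vc_robust <- cluster_sandwich(fit, dat[[spec$cluster_var]])
  }
  structure(list(
    coefficients = coefs,
    vcov_robust = vc_robust,
    vcov_model = vc_model,
    n_obs = nrow(dat),
    n_clusters = n_clusters,
    converged = converged,
    family = spec$family,
    fallback = fallback,
    cutpoints = NULL,
    reason = reason,
    spec = spec,
    model = fit,
    data = dat,
    rows_used = rows_used,
    xlevels = fit_xlevels(fit)
  ), class = "crt_fit")
}

fit_xlevels <- function(fit) {
  if (is.null(fit)) return(NULL)
  if (!is.null(fit$xlevels)) return(fit$xlevels)
  stats::.getXlevels(stats::terms(fit), stats::model.frame(fit))
}

# Full parameter vector: glm coefficients, or c(beta, zeta) for polr, in the
# order matching the sandwich/vcov.
full_coefs <- function(fit) {
  if (inherits(fit, "polr")) c(fit$coefficients, fit$zeta) else stats::coef(fit)
}

model_vcov <- function(fit) {
  if (inherits(fit, "polr")) return(stats::vcov(fit))
  # unscaled: Poisson/binomial have dispersion 1; gaussian uses the usual
  # sigma^2 (X'X)^-1 from summary.
  suppressWarnings(stats::vcov(fit))
}

#' Cluster-robust (CR1) sandwich covariance
#'
#' Sandwich estimator with score contributions summed within cluster and the
#' small-sample factor G/(G-1), G the number of clusters. Works for `glm`
#' fits (any family here) and `MASS::polr` proportional-odds fits, for which
#' per-observation scores are derived analytically.
#'
#' @param fit a `crt_fit` (or raw `glm`/`polr` object).
#' @param cluster vector of cluster ids, one per observation used in the fit;
#'   for a `crt_fit`, defaults to the fitting cluster variable. Pass a column
#'   name to re-cluster a `crt_fit` on another identifier (e.g., study block
#'   for the mediation step).
#' @param cr1 apply the G/(G-1) correction (default TRUE).
#' @return symmetric covariance matrix.
#' @export
cluster_robust_vcov <- function(fit, cluster = NULL, cr1 = TRUE) {
  if (inherits(fit, "crt_fit")) {
    if (!fit$converged) stopf("cannot compute robust vcov for a non-converged fit")
    if (is.null(cluster)) {
      cluster <- fit$data[[fit$spec$cluster_var]]
    } else if (is.character(cluster) && length(cluster) == 1L) {
      if (!cluster %in% names(fit$data)) stopf("no column '%s' in fit data", cluster)
      cluster <- fit$data[[cluster]]
    }
    V <- cluster_sandwich(fit$model, cluster, cr1)
    if (!is.null(fit$param_transform)) {
      P <- fit$param_transform
      V <- relabel_vcov(P %*% V %*% t(P), names(fit$coefficients))
    }
    return(V)
  }
  cluster_sandwich(fit, cluster, cr1)
}

cluster_sandwich <- function(fit, cluster, cr1 = TRUE) {
  if (length(unique(cluster)) < 2) {
    stopf("cluster-robust variance needs >= 2 clusters; supply more clusters or use model-based vcov")
  }
  ef <- score_contributions(fit)
  if (length(cluster) != nrow(ef)) {
    stopf("cluster vector length (%d) does not match observations used (%d)",
          length(cluster), nrow(ef))
  }
  G <- length(unique(cluster))
  efc <- rowsum(ef, group = as.character(cluster))
  meat <- crossprod(as.matrix(efc))
  if (cr1) meat <- meat * G / (G - 1)
  bread <- model_vcov(fit)
  if (inherits(fit, "glm")) {
    # bread must be the unscaled (X'WX)^-1 for quasi families; vcov() of a
    # gaussian glm is sigma^2-scaled, so rebuild from the qr decomposition.
    bread <- summary_cov_unscaled(fit)
  }
  v <- bread %*% meat %*% bread
  (v + t(v)) / 2
}

summary_cov_unscaled <- function(fit) {
  s <- suppressWarnings(stats::summary.glm(fit))
  s$cov.unscaled
}

# Per-observation score (estimating-function) contributions, scaled so that
# bread = cov.unscaled gives the standard sandwich: x_i (y_i - mu_i)
# (dmu/deta)_i / V(mu_i). For gaussian this reduces to x_i e_i, pairing with
# the (X'X)^-1 bread to give the usual lm sandwich.
score_contributions <- function(fit) {
  if (inherits(fit, "polr")) return(polr_scores(fit))
  if (!inherits(fit, "glm")) stopf("unsupported model class")
  X <- stats::model.matrix(fit)
  r <- stats::residuals(fit, type = "working")
  w <- fit$weights   # IRLS weights: (dmu/deta)^2 / V(mu)
  X * (w * r)
}

# Analytic per-observation scores of the proportional-odds log-likelihood,
# parameter order c(beta, zeta) to match vcov(polr).
polr_scores <- function(fit) {
  X <- stats::model.matrix(fit)[, -1, drop = FALSE]  # polr drops intercept
  y <- as.integer(stats::model.response(stats::model.frame(fit)))
  zeta <- fit$zeta
  beta <- fit$coefficients
  K <- length(zeta) + 1L
  eta <- drop(X %*% beta)
  zlo <- c(-Inf, zeta)[y]        # zeta_{j-1}
  zhi <- c(zeta, Inf)[y]         # zeta_j
  Fhi <- stats::plogis(zhi - eta)
  Flo <- stats::plogis(zlo - eta)
  fhi <- stats::dlogis(zhi - eta)
  flo <- stats::dlogis(zlo - eta)
  P <- pmax(Fhi - Flo, 1e-12)
  sc_beta <- X * ((flo - fhi) / P)
  sc_zeta <- matrix(0, nrow = length(y), ncol = K - 1L)
  for (k in seq_len(K - 1L)) {
    sc_zeta[, k] <- (fhi * (y == k) - flo * (y == k + 1L)) / P
  }
  cbind(sc_beta, sc_zeta)
}

#' Wald test and CI for a fitted term
#'
#' Normal-approximation confidence interval and two-sided p-value on the link
#' scale, with the exponentiated estimate for ratio-scale reporting
#' (prevalence ratio for binary outcomes, count ratio for counts, odds ratio
#' for ordinal outcomes).
#'
#' @param fit a converged `crt_fit`.
#' @param term coefficient name.
#' @param level confidence level (default 0.95).
#' @param exponentiate report on the ratio scale (default TRUE).
#' @return named list: `estimate`, `ci_low`, `ci_high`, `p`, `se` (link
#'   scale), `term`.
#' @export
wald_test <- function(fit, term, level = 0.95, exponentiate = TRUE) {
  stopifnot(inherits(fit, "crt_fit"))
  if (!fit$converged) stopf("fit did not converge")
  if (!term %in% names(fit$coefficients)) {
    stopf("term '%s' not in fit (have: %s)", term,
          paste(names(fit$coefficients), collapse = ", "))
  }
  b <- fit$coefficients[[term]]
  se <- sqrt(fit$vcov_robust[term, term])
  z <- b / se
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::qnorm(1 - (1 - level) / 2)
  lo <- b - q * se
  hi <- b + q * se
  if (exponentiate) {
    list(estimate = exp(b), ci_low = exp(lo), ci_high = exp(hi),
         p = p, se = se, term = term)
  } else {
    list(estimate = b, ci_low = lo, ci_high = hi, p = p, se = se, term = term)
  }
}

#' @export
print.crt_fit <- function(x, ...) {
  cat("<crt_fit>", x$family,
      if (isTRUE(x$fallback)) "(modified-Poisson fallback)" else "", "\n")
  cat("  n =", x$n_obs, " clusters =", x$n_clusters,
      " converged =", x$converged, "\n")
  if (!x$converged && !is.null(x$reason)) cat("  reason:", x$reason, "\n")
  if (!is.null(x$coefficients)) {
    est <- x$coefficients
    se <- sqrt(diag(x$vcov_robust))
    print(round(cbind(estimate = est, robust_se = se), 4))
  }
  invisible(x)
}
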