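#' Mediation under post-treatment confounding (dependent mediators)
#'
#' Latrine-use mediators are hypothesised to be causally downstream of
#' latrine-quality indicators, so the treatment affects both the mediator and
#' a confounder of the mediator-outcome relation. This estimator follows the
#' varying-coefficient linear structural-equation approach: a
#' linear-probability mediator equation on treatment, the upstream
#' confounders and covariates, and a linear-probability outcome equation on
#' treatment, the mediator, their interaction (the varying coefficient), the
#' upstream confounders and covariates. ACME(t) and ADE(t) are composed from
#' the path coefficients evaluated at the sample distribution of the
#' confounders. Because the confounders are themselves affected by treatment,
#' the counterfactual mediator shift includes the indirect
#' treatment-confounder-mediator path
#' (`delta_M = a1 + sum_u a2_u delta_W_u`, with `delta_W_u` the arm
#' difference in confounder `u`), giving `ACME(t) = (b2 + b3 t) delta_M` and
#' `ADE(t) = b1 + sum_u b4_u delta_W_u + b3 E[M(t)]`. Uncertainty comes from
#' a nonparametric bootstrap that resamples whole study blocks, keeping each
#' matched pair together.
#'
#' @param records data.frame of survey records.
#' @param mediator_spec a [mediator_spec()]; ordinal mediators enter the
#'   linear system through their integer level.
#' @param upstream_confounders names of the retained upstream (latrine
#'   quality) mediators; must be non-empty, otherwise use [mediate_single()].
#' @param treat treatment column (0/1).
#' @param covariates names of pre-treatment covariates to adjust for.
#' @param n_boot bootstrap resamples (the published analysis used 1000); 0
#'   returns point estimates only.
#' @param cluster_var bootstrap resampling unit (default `"block_id"`).
#' @param seed RNG seed.
#' @param outcome outcome column (default `"diarrhea"`).
#' @return object of class `crt_mediation` (`method = "dependent-bootstrap"`).
#'   Attribute `n_redrawn` counts bootstrap resamples redrawn because a
#'   single arm was present.
#' @export
mediate_dependent <- function(records, mediator_spec, upstream_confounders,
                              treat = "arm", covariates = character(),
                              n_boot = 1000, cluster_var = "block_id",
                              seed = NULL, outcome = "diarrhea") {
  stopifnot(inherits(mediator_spec, "crt_mediator_spec"))
  if (!length(upstream_confounders)) {
    stopf("no upstream confounders supplied; use mediate_single() for causally independent mediators")
  }
  med <- mediator_spec$name
  vars <- c(outcome, treat, med, upstream_confounders, covariates, cluster_var)
  missing_cols <- setdiff(vars, names(records))
  if (length(missing_cols)) {
    stopf("records lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  dat <- records[stats::complete.cases(records[, vars, drop = FALSE]),
                 vars, drop = FALSE]
  dat[[med]] <- as.numeric(dat[[med]])
  dat[[outcome]] <- as.numeric(dat[[outcome]])
  if (length(unique(dat[[treat]])) < 2) stopf("treatment does not vary")

  w1 <- mean(dat[[treat]] == 1)
  w0 <- 1 - w1

  est_fun <- function(d) lsem_effects(d, med, outcome, treat,
                                      upstream_confounders, covariates)
  point <- est_fun(dat)

  n_redrawn <- 0L
  boot <- NULL
  if (n_boot > 0) {
    if (!is.null(seed)) set.seed(seed)
    blocks <- unique(dat[[cluster_var]])
    split_idx <- split(seq_len(nrow(dat)), dat[[cluster_var]])
    boot <- matrix(NA_real_, nrow = n_boot, ncol = 5,
                   dimnames = list(NULL, c("acme0", "acme1", "ade0", "ade1",
                                           "total")))
    for (b in seq_len(n_boot)) {
      for (try in 1:100) {
        take <- sample(blocks, length(blocks), replace = TRUE)
        idx <- unlist(split_idx[as.character(take)], use.names = FALSE)
        db <- dat[idx, , drop = FALSE]
        if (length(unique(db[[treat]])) == 2) break
        n_redrawn <- n_redrawn + 1L
        if (try == 100) stopf("could not draw a bootstrap resample with both arms")
      }
      e <- est_fun(db)
      boot[b, ] <- c(e$acme0, e$acme1, e$ade0, e$ade1, e$total)
    }
  }

  draws <- if (is.null(boot)) {
    list(acme0 = point$acme0, acme1 = point$acme1,
         ade0 = point$ade0, ade1 = point$ade1, total = point$total)
  } else {
    list(acme0 = boot[, "acme0"], acme1 = boot[, "acme1"],
         ade0 = boot[, "ade0"], ade1 = boot[, "ade1"], total = boot[, "total"])
  }
  res <- new_crt_mediation(draws, w0, w1, method = "dependent-bootstrap",
                           mediator = med, n_obs = nrow(dat),
                           n_sims = n_boot, seed = seed)
  # point estimates come from the full data, CIs/p from the bootstrap
  pt <- c(acme_avg = avg_conditional(point$acme0, point$acme1, w0, w1),
          ade_avg = avg_conditional(point$ade0, point$ade1, w0, w1),
          total = point$total, acme_0 = point$acme0, acme_1 = point$acme1,
          ade_0 = point$ade0, ade_1 = point$ade1)
  res$estimates$estimate <- unname(pt[res$estimates$effect])
  attr(res, "n_redrawn") <- n_redrawn
  res
}

# Two-equation linear-probability structural system. The upstream
# confounders are themselves post-treatment, so the counterfactual mediator
# shift includes the treatment -> confounder -> mediator path, and the direct
# effect includes the treatment -> confounder -> outcome path:
#   delta_M = a1 + sum_u a2_u * delta_W_u   (delta_W_u = arm difference in W_u)
#   ACME(t) = (b2 + b3 t) * delta_M
#   ADE(t)  = b1 + sum_u b4_u * delta_W_u + b3 * E[M(t)]
# with E[M(0)] evaluated at the control-arm confounder distribution and the
# pre-treatment covariate sample means.
lsem_effects <- function(d, med, outcome, treat, upstream, covariates) {
  rhs_m <- paste(c(treat, upstream, covariates), collapse = " + ")
  rhs_y <- paste(c(sprintf("%s * %s", treat, med), upstream, covariates),
                 collapse = " + ")
  m_eq <- stats::lm(stats::as.formula(paste(med, "~", rhs_m)), data = d)
  y_eq <- stats::lm(stats::as.formula(paste(outcome, "~", rhs_y)), data = d)
  cm <- stats::coef(m_eq)
  cy <- stats::coef(y_eq)
  inter_name <- paste0(treat, ":", med)
  if (!inter_name %in% names(cy)) inter_name <- paste0(med, ":", treat)
  getc <- function(co, nm) {
    if (nm %in% names(co) && !is.na(co[[nm]])) unname(co[[nm]]) else 0
  }
  a1 <- getc(cm, treat)
  b1 <- getc(cy, treat)
  b2 <- getc(cy, med)
  b3 <- getc(cy, inter_name)

  tr1 <- d[[treat]] == 1
  wbar0 <- vapply(upstream, function(u) mean(as.numeric(d[[u]][!tr1])), 0)
  wbar1 <- vapply(upstream, function(u) mean(as.numeric(d[[u]][tr1])), 0)
  delta_w <- wbar1 - wbar0
  a2 <- vapply(upstream, function(u) getc(cm, u), 0)
  b4 <- vapply(upstream, function(u) getc(cy, u), 0)

  delta_m <- a1 + sum(a2 * delta_w)
  # E[M(0)]: control-arm confounder means, overall covariate means
  m0bar <- getc(cm, "(Intercept)") + sum(a2 * wbar0) +
    sum(vapply(covariates, function(x) {
      getc(cm, x) * mean(as.numeric(d[[x]]))
    }, 0))
  acme0 <- b2 * delta_m
  acme1 <- (b2 + b3) * delta_m
  ade0 <- b1 + sum(b4 * delta_w) + b3 * m0bar
  ade1 <- b1 + sum(b4 * delta_w) + b3 * (m0bar + delta_m)
  list(acme0 = acme0, acme1 = acme1, ade0 = ade0, ade1 = ade1,
       total = acme1 + ade0)
}
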