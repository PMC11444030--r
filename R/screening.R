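#' Mediator catalog
#'
#' Bundles the mediator specifications screened by the pipeline, mirroring
#' the three-panel taxonomy (latrine quality indicators, latrine use
#' practices, feces management practices).
#'
#' @param ... [mediator_spec()] objects (or a single list of them).
#' @return list of class `crt_mediator_catalog`.
#' @export
mediator_catalog <- function(...) {
  specs <- list(...)
  if (length(specs) == 1L && !inherits(specs[[1]], "crt_mediator_spec")) {
    specs <- specs[[1]]
  }
  for (s in specs) stopifnot(inherits(s, "crt_mediator_spec"))
  nm <- vapply(specs, function(s) s$name, "")
  if (anyDuplicated(nm)) stopf("duplicate mediator names in catalog")
  structure(specs, names = nm, class = "crt_mediator_catalog")
}

#' Catalog matching the default synthetic trial
#' @return `crt_mediator_catalog` for [default_mediator_models()].
#' @export
default_catalog <- function() {
  mediator_catalog(lapply(default_mediator_models(), function(g) g$spec))
}

screen_family <- function(type) {
  switch(type, binary = "binomial-log", count = "poisson",
         ordinal = "ordinal-logit")
}

# Rows eligible for a mediator's three steps: the season's records, complete
# on outcome and step-two covariates, non-missing on the mediator, within the
# mediator's availability window. The same row set is reused across steps
# (the "consistent number of observations" rule).
mediator_rows <- function(records, spec, season, covariates, outcome) {
  keep <- records$season == season &
    stats::complete.cases(records[, c(outcome, covariates), drop = FALSE]) &
    !is.na(records[[spec$name]])
  if (!is.null(spec$rounds)) keep <- keep & records$round %in% spec$rounds
  records[keep, , drop = FALSE]
}

#' Step one: screen mediators on treatment assignment
#'
#' Regresses each potential mediator on intervention assignment with block
#' fixed effects and cluster-robust standard errors, using the
#' family-appropriate model (log-binomial with modified-Poisson fallback for
#' binary, Poisson for counts, proportional odds for ordinal). Mediators are
#' retained when the treatment term is significant at `alpha`. Degenerate
#' mediators are reported as not retained with a reason, not an error.
#'
#' @param records survey records (all seasons; restricted internally).
#' @param catalog a [mediator_catalog()].
#' @param season `"monsoon"` or `"dry"`.
#' @param covariates step-two covariate names defining the complete-case row
#'   set (may be empty).
#' @param treat,outcome,block_var,cluster_var column names.
#' @param alpha retention threshold (default 0.05).
#' @return data.frame of class `crt_screen_report`: one row per mediator with
#'   arm summaries (`n (%)` for binary, `median (range)` otherwise), the
#'   ratio-scale effect estimate with CI and p, the model family used, `n`,
#'   and the `retained` flag.
#' @export
step1_screen <- function(records, catalog, season, covariates = character(),
                         treat = "arm", outcome = "diarrhea",
                         block_var = "block_id", cluster_var = "block_id",
                         alpha = 0.05) {
  stopifnot(inherits(catalog, "crt_mediator_catalog"))
  rows <- lapply(catalog, function(spec) {
    dat <- mediator_rows(records, spec, season, covariates, outcome)
    summ <- arm_summary_string(dat, spec, treat)
    base <- data.frame(
      mediator = spec$name, category = spec$category, type = spec$type,
      season = season, n = nrow(dat),
      sanitation_summary = summ[2], control_summary = summ[1],
      family = NA_character_, estimate = NA_real_, ci_low = NA_real_,
      ci_high = NA_real_, p = NA_real_, retained = FALSE,
      reason = NA_character_, stringsAsFactors = FALSE)
    if (nrow(dat) == 0) {
      base$reason <- "no eligible rows"
      return(base)
    }
    if (length(unique(dat[[spec$name]])) < 2) {
      base$reason <- "degenerate"
      return(base)
    }
    sp <- model_spec(spec$name, c(treat, sprintf("factor(%s)", block_var)),
                     family = screen_family(spec$type),
                     cluster_var = cluster_var)
    fit <- fit_model(dat, sp)
    base$family <- fit$family
    if (!fit$converged) {
      base$reason <- fit$reason %||% "did not converge"
      return(base)
    }
    wt <- wald_test(fit, treat)
    base$estimate <- wt$estimate
    base$ci_low <- wt$ci_low
    base$ci_high <- wt$ci_high
    base$p <- wt$p
    base$retained <- wt$p < alpha
    base
  })
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("crt_screen_report", "data.frame")
  attr(rep, "alpha") <- alpha
  rep
}

arm_summary_string <- function(dat, spec, treat) {
  vapply(c(0, 1), function(a) {
    x <- dat[[spec$name]][dat[[treat]] == a]
    x <- x[!is.na(x)]
    if (!length(x)) return("-")
    if (spec$type == "binary") {
      sprintf("%d (%.1f%%)", sum(x == 1), 100 * mean(x == 1))
    } else {
      sprintf("%g (%g, %g)", stats::median(x), min(x), max(x))
    }
  }, "")
}

#' Covariate prescreen against the outcome
#'
#' One bivariate outcome regression per candidate covariate, run separately
#' by season; candidates associated with the outcome at `alpha` (default
#' 0.20) are retained as mediator-outcome confounders for steps two and
#' three. Child age is the only candidate expected to vary by round; the
#' rest are baseline variables.
#'
#' @param records survey records.
#' @param candidates character vector of numeric/binary covariate columns.
#' @param season season to restrict to.
#' @param outcome,treat,cluster_var column names.
#' @param alpha retention threshold (default 0.20).
#' @param robust use cluster-robust SEs (default TRUE).
#' @return data.frame: `candidate`, `estimate` (prevalence ratio per unit),
#'   `p`, `retained`.
#' @export
screen_covariates <- function(records, candidates, season,
                              outcome = "diarrhea", treat = "arm",
                              cluster_var = "block_id", alpha = 0.20,
                              robust = TRUE) {
  if (!length(candidates)) {
    return(data.frame(candidate = character(), estimate = numeric(),
                      p = numeric(), retained = logical()))
  }
  sub <- records[records$season == season, , drop = FALSE]
  rows <- lapply(candidates, function(cv) {
    dat <- sub[stats::complete.cases(sub[, c(outcome, cv), drop = FALSE]), ,
               drop = FALSE]
    out <- data.frame(candidate = cv, estimate = NA_real_, p = NA_real_,
                      retained = FALSE, stringsAsFactors = FALSE)
    if (nrow(dat) < 10 || length(unique(dat[[cv]])) < 2) return(out)
    sp <- model_spec(outcome, cv, family = "binomial-log",
                     cluster_var = cluster_var)
    fit <- fit_model(dat, sp)
    if (!fit$converged) return(out)
    if (robust) {
      wt <- wald_test(fit, cv)
    } else {
      se <- sqrt(fit$vcov_model[cv, cv])
      b <- fit$coefficients[[cv]]
      wt <- list(estimate = exp(b), p = 2 * stats::pnorm(-abs(b / se)))
    }
    out$estimate <- wt$estimate
    out$p <- wt$p
    out$retained <- wt$p < alpha
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

# Mediator term as it enters the outcome model: ordinal mediators as category
# indicators, binary/count as-is.
mediator_term <- function(spec) {
  if (spec$type == "ordinal") sprintf("factor(%s)", spec$name) else spec$name
}

#' Step two: outcome regressed on treatment controlling for the mediator
#'
#' Diarrheal disease is regressed on intervention assignment, the retained
#' mediator, the prescreened covariates and block fixed effects
#' (log-binomial with modified-Poisson fallback, cluster-robust SEs). The
#' adjusted mediator association (the supplementary-table analog) is
#' attached as attribute `"mediator_assoc"`. Ordinal mediators enter as a
#' numeric level trend here so the association is a single coefficient; the
#' step-three outcome model uses category indicators instead.
#'
#' @param records survey records.
#' @param spec the mediator's [mediator_spec()].
#' @param covariates retained covariate names.
#' @param season season to restrict to.
#' @param screen optional `crt_screen_report`; if given, passing a mediator
#'   that step one did not retain is an error.
#' @param treat,outcome,block_var,cluster_var column names.
#' @return a `crt_fit` for the outcome model.
#' @export
step2_fit <- function(records, spec, covariates, season, screen = NULL,
                      treat = "arm", outcome = "diarrhea",
                      block_var = "block_id", cluster_var = "block_id") {
  stopifnot(inherits(spec, "crt_mediator_spec"))
  if (!is.null(screen)) {
    row <- screen[screen$mediator == spec$name & screen$season == season, ]
    if (!nrow(row) || !isTRUE(row$retained[1])) {
      stopf("mediator '%s' was not retained by step one in season '%s'",
            spec$name, season)
    }
  }
  dat <- mediator_rows(records, spec, season, covariates, outcome)
  med_term <- if (spec$type == "ordinal") {
    sprintf("as.numeric(%s)", spec$name)
  } else spec$name
  sp <- model_spec(outcome,
                   c(treat, med_term, covariates,
                     sprintf("factor(%s)", block_var)),
                   family = "binomial-log", cluster_var = cluster_var)
  fit <- fit_model(dat, sp)
  if (fit$converged) {
    term <- grep(spec$name, names(fit$coefficients), fixed = TRUE,
                 value = TRUE)[1]
    attr(fit, "mediator_assoc") <- wald_test(fit, term)
  }
  fit
}

#' Default analysis configuration
#'
#' @param n_sims quasi-Bayesian draws for [mediate_single()] (default 1000).
#' @param n_boot block-bootstrap resamples for [mediate_dependent()]
#'   (default 1000).
#' @param alpha_mediator step-one retention threshold (default 0.05).
#' @param alpha_covariate covariate prescreen threshold (default 0.20).
#' @param treat,outcome,block_var,cluster_var column names.
#' @param mediation_cluster_var clustering unit for the mediation-step
#'   covariance (default the study block).
#' @param include_partial_mediators include mediators with restricted
#'   availability windows in step three (default FALSE: screened only).
#' @param seed integer seed.
#' @return list of class `crt_analysis_config`.
#' @export
analysis_config <- function(n_sims = 1000, n_boot = 1000,
                            alpha_mediator = 0.05, alpha_covariate = 0.20,
                            treat = "arm", outcome = "diarrhea",
                            block_var = "block_id",
                            cluster_var = "block_id",
                            mediation_cluster_var = "block_id",
                            include_partial_mediators = FALSE,
                            seed = 1L) {
  structure(list(n_sims = n_sims, n_boot = n_boot,
                 alpha_mediator = alpha_mediator,
                 alpha_covariate = alpha_covariate,
                 treat = treat, outcome = outcome, block_var = block_var,
                 cluster_var = cluster_var,
                 mediation_cluster_var = mediation_cluster_var,
                 include_partial_mediators = include_partial_mediators,
                 seed = as.integer(seed)),
            class = "crt_analysis_config")
}

#' Run the full three-step mediation analysis by season
#'
#' Executes, separately for monsoon and dry seasons: the covariate prescreen
#' (alpha 0.20), step one mediator screening (alpha 0.05), step two adjusted
#' outcome models, and step three causal mediation. Latrine-quality and
#' feces-management mediators are analysed with the quasi-Bayesian
#' single-mediator estimator; latrine-use mediators are routed to the
#' dependent-mediator estimator with the latrine-quality mediators that had
#' statistically significant ACMEs as upstream confounders (falling back to
#' the single-mediator estimator when none qualify). Row counts are held
#' identical across a mediator's three steps.
#'
#' @param records survey records with `season` assigned.
#' @param catalog a [mediator_catalog()].
#' @param covariate_candidates candidate covariate columns.
#' @param config an [analysis_config()].
#' @return list of class `crt_analysis`: per-season covariate screens, screen
#'   reports, `crt_mediation` objects, and a combined tidy `table` ordered by
#'   descending `|ACME|` within season.
#' @export
run_full_analysis <- function(records, catalog, covariate_candidates,
                              config = analysis_config()) {
  stopifnot(inherits(config, "crt_analysis_config"))
  if (!"season" %in% names(records)) {
    stopf("records need a 'season' column (see assign_season)")
  }
  seasons <- intersect(c("monsoon", "dry"), unique(records$season))
  out <- list(config = config, seasons = list())
  for (season in seasons) {
    res <- run_season(records, catalog, covariate_candidates, config, season)
    out$seasons[[season]] <- res
  }
  tabs <- lapply(out$seasons, function(s) s$table)
  tabs <- tabs[!vapply(tabs, is.null, TRUE)]
  out$table <- if (length(tabs)) do.call(rbind, tabs) else NULL
  if (!is.null(out$table)) rownames(out$table) <- NULL
  class(out) <- "crt_analysis"
  out
}

run_season <- function(records, catalog, covariate_candidates, config,
                       season) {
  covs <- screen_covariates(records, covariate_candidates, season,
                            outcome = config$outcome, treat = config$treat,
                            cluster_var = config$cluster_var,
                            alpha = config$alpha_covariate)
  retained_covs <- covs$candidate[covs$retained]
  screen <- step1_screen(records, catalog, season,
                         covariates = retained_covs, treat = config$treat,
                         outcome = config$outcome,
                         block_var = config$block_var,
                         cluster_var = config$cluster_var,
                         alpha = config$alpha_mediator)
  retained <- screen$mediator[screen$retained]
  if (config$include_partial_mediators) {
    step3_specs <- catalog[retained]
  } else {
    step3_specs <- Filter(function(s) is.null(s$rounds), catalog[retained])
  }
  res <- list(season = season, covariate_screen = covs,
              retained_covariates = retained_covs, screen = screen,
              mediations = list(), table = NULL)
  if (!length(step3_specs)) {
    message(sprintf("season '%s': no mediators retained for step three", season))
    return(res)
  }
  # Independent categories first: their significant latrine-quality ACMEs
  # feed the dependent-mediator models for latrine use.
  cats <- vapply(step3_specs, function(s) s$category, "")
  order_idx <- order(match(cats, c("latrine_quality", "feces_management",
                                   "latrine_use")))
  step3_specs <- step3_specs[order_idx]
  sig_quality <- character(0)
  k <- 0L
  for (spec in step3_specs) {
    k <- k + 1L
    med_res <- tryCatch(
      mediate_one(records, spec, retained_covs, config, season, sig_quality,
                  seed = child_seed(config$seed, 1000L + k)),
      error = function(e) {
        message(sprintf("mediation failed for '%s' (%s): %s",
                        spec$name, season, conditionMessage(e)))
        NULL
      })
    if (is.null(med_res)) next
    res$mediations[[spec$name]] <- med_res
    if (spec$category == "latrine_quality") {
      acme_p <- mediation_effect(med_res, "acme_avg")$p
      if (!is.na(acme_p) && acme_p < config$alpha_mediator) {
        sig_quality <- c(sig_quality, spec$name)
      }
    }
  }
  res$table <- mediation_table(res$mediations, catalog, season)
  res
}

# Step 2/3 for one mediator on its consistent row set.
mediate_one <- function(records, spec, covariates, config, season,
                        sig_quality, seed) {
  dat <- mediator_rows(records, spec, season, covariates, config$outcome)
  # step one refit on this exact row set (same rows by construction)
  m_sp <- model_spec(spec$name,
                     c(config$treat, sprintf("factor(%s)", config$block_var)),
                     family = screen_family(spec$type),
                     cluster_var = config$cluster_var)
  m_fit <- fit_model(dat, m_sp)
  if (!m_fit$converged) stopf("mediator model did not converge")

  if (spec$category == "latrine_use" && length(sig_quality)) {
    return(mediate_dependent(dat, spec, upstream_confounders = sig_quality,
                             treat = config$treat, covariates = covariates,
                             n_boot = config$n_boot,
                             cluster_var = config$mediation_cluster_var,
                             seed = seed, outcome = config$outcome))
  }
  y_sp <- model_spec(config$outcome,
                     c(sprintf("%s * %s", config$treat, mediator_term(spec)),
                       covariates, sprintf("factor(%s)", config$block_var)),
                     family = "binomial-log",
                     cluster_var = config$cluster_var)
  y_fit <- fit_model(dat, y_sp)
  if (!y_fit$converged) stopf("outcome model did not converge")
  stopifnot(m_fit$n_obs == y_fit$n_obs)
  mediate_single(dat, spec, m_fit, y_fit, treat = config$treat,
                 n_sims = config$n_sims,
                 cluster_var = config$mediation_cluster_var, seed = seed)
}

mediation_table <- function(mediations, catalog, season) {
  if (!length(mediations)) return(NULL)
  rows <- lapply(names(mediations), function(nm) {
    m <- mediations[[nm]]
    acme <- mediation_effect(m, "acme_avg")
    ade <- mediation_effect(m, "ade_avg")
    tot <- mediation_effect(m, "total")
    data.frame(mediator = nm, category = catalog[[nm]]$category,
               season = season, method = m$method, n = m$n_obs,
               acme = acme$estimate, acme_ci_low = acme$ci_low,
               acme_ci_high = acme$ci_high, acme_p = acme$p,
               ade = ade$estimate, ade_ci_low = ade$ci_low,
               ade_ci_high = ade$ci_high, ade_p = ade$p,
               total = tot$estimate, total_ci_low = tot$ci_low,
               total_ci_high = tot$ci_high, total_p = tot$p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-abs(tab$acme)), ]
  rownames(tab) <- NULL
  tab
}

#' @export
print.crt_analysis <- function(x, ...) {
  cat("<crt_analysis> seasons:", paste(names(x$seasons), collapse = ", "), "\n")
  for (s in names(x$seasons)) {
    sc <- x$seasons[[s]]$screen
    cat(sprintf("  %s: %d mediators screened, %d retained, %d mediated\n",
                s, nrow(sc), sum(sc$retained),
                length(x$seasons[[s]]$mediations)))
  }
  if (!is.null(x$table)) {
    tab <- x$table[, c("mediator", "season", "method", "n", "acme", "ade",
                       "total", "acme_p")]
    tab[, 5:8] <- round(tab[, 5:8], 4)
    print(tab, row.names = FALSE)
  }
  invisible(x)
}

#' Lagged-mediator sensitivity analysis
#'
#' For mediators recorded over a short recall window, concurrent measurement
#' of mediator and diarrhea can pick up reverse causation (practices changing
#' in response to a child's illness). This re-estimates the step-two adjusted
#' association using the mediator value from the previous survey round
#' (approximately 3 months earlier), keeping only child-round pairs whose
#' season matches the previous round's season, and reports concurrent and
#' lagged estimates side by side.
#'
#' @param records survey records with `season`.
#' @param specs list of [mediator_spec()] for the short-recall mediators.
#' @param covariates adjustment covariates.
#' @param treat,outcome,block_var,cluster_var,child_var,round_var column
#'   names.
#' @return data.frame: one row per mediator and season with `n_pairs` and
#'   concurrent/lagged estimate, CI and p. Zero qualifying pairs yields an
#'   empty table with a message.
#' @export
lagged_sensitivity <- function(records, specs, covariates = character(),
                               treat = "arm", outcome = "diarrhea",
                               block_var = "block_id",
                               cluster_var = "block_id",
                               child_var = "child_id", round_var = "round") {
  if (inherits(specs, "crt_mediator_spec")) specs <- list(specs)
  empty <- data.frame(mediator = character(), season = character(),
                      n_pairs = integer(),
                      est_concurrent = numeric(), p_concurrent = numeric(),
                      est_lagged = numeric(), p_lagged = numeric())
  rec <- records[order(records[[child_var]], records[[round_var]]), ]
  prev_idx <- match(paste(rec[[child_var]], rec[[round_var]] - 1L),
                    paste(rec[[child_var]], rec[[round_var]]))
  rec$season_prev <- rec$season[prev_idx]
  qualifying <- !is.na(prev_idx) & rec$season_prev == rec$season
  if (!any(qualifying)) {
    message("no consecutive same-season round pairs; empty sensitivity table")
    return(empty)
  }
  out <- list()
  for (spec in specs) {
    med <- spec$name
    lag_col <- paste0(med, "_lag1")
    rec[[lag_col]] <- rec[[med]][prev_idx]
    for (season in intersect(c("monsoon", "dry"), unique(rec$season))) {
      keep <- qualifying & rec$season == season &
        !is.na(rec[[med]]) & !is.na(rec[[lag_col]]) &
        stats::complete.cases(rec[, c(outcome, covariates), drop = FALSE])
      dat <- rec[keep, , drop = FALSE]
      row <- data.frame(mediator = med, season = season, n_pairs = nrow(dat),
                        est_concurrent = NA_real_, p_concurrent = NA_real_,
                        est_lagged = NA_real_, p_lagged = NA_real_,
                        stringsAsFactors = FALSE)
      if (nrow(dat) >= 20) {
        wt_c <- lag_assoc(dat, med, covariates, treat, outcome, block_var,
                          cluster_var)
        wt_l <- lag_assoc(dat, lag_col, covariates, treat, outcome, block_var,
                          cluster_var)
        if (!is.null(wt_c)) {
          row$est_concurrent <- wt_c$estimate; row$p_concurrent <- wt_c$p
        }
        if (!is.null(wt_l)) {
          row$est_lagged <- wt_l$estimate; row$p_lagged <- wt_l$p
        }
      }
      out[[paste(med, season)]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

lag_assoc <- function(dat, med_col, covariates, treat, outcome, block_var,
                      cluster_var) {
  if (length(unique(dat[[med_col]])) < 2) return(NULL)
  term <- if (is.numeric(dat[[med_col]]) &&
              length(unique(dat[[med_col]])) > 2) {
    sprintf("as.numeric(%s)", med_col)
  } else med_col
  sp <- model_spec(outcome, c(treat, term, covariates,
                              sprintf("factor(%s)", block_var)),
                   family = "binomial-log", cluster_var = cluster_var)
  fit <- tryCatch(fit_model(dat, sp), error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(NULL)
  tname <- grep(med_col, names(fit$coefficients), fixed = TRUE, value = TRUE)[1]
  wald_test(fit, tname)
}
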