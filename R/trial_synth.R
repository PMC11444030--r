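#' Mediator specification
#'
#' Describes one potential mediator: its name, the category it belongs to in
#' the latrine-quality / latrine-use / feces-management taxonomy, its
#' measurement type, and the direction in which the intervention is expected
#' to move it.
#'
#' @param name column name.
#' @param category `"latrine_quality"`, `"latrine_use"`, or
#'   `"feces_management"`.
#' @param type `"binary"`, `"count"`, or `"ordinal"`.
#' @param direction `"increase"` or `"decrease"` (desired direction under
#'   intervention; informational).
#' @param rounds integer vector of survey rounds in which the mediator is
#'   recorded (default all); mediators recorded in early rounds only (e.g.,
#'   latrine age) are screened on available rounds.
#' @return list of class `crt_mediator_spec`.
#' @export
mediator_spec <- function(name,
                          category = c("latrine_quality", "latrine_use",
                                       "feces_management"),
                          type = c("binary", "count", "ordinal"),
                          direction = c("increase", "decrease"),
                          rounds = NULL) {
  category <- match.arg(category)
  type <- match.arg(type)
  direction <- match.arg(direction)
  structure(list(name = name, category = category, type = type,
                 direction = direction, rounds = rounds),
            class = "crt_mediator_spec")
}

#' Generating model for one synthetic mediator
#'
#' @param spec a [mediator_spec()].
#' @param intercept linear-predictor intercept.
#' @param beta_treat treatment-to-mediator path coefficient.
#' @param beta_upstream named list: upstream mediator name -> coefficient
#'   (latrine-use mediators depending on latrine-quality mediators).
#' @param beta_covariates named list: covariate name -> coefficient.
#' @param link `"logit"`, `"log"`, or `"identity"` for binary mediators;
#'   `"log-count"` for counts; `"cumulative-logit"` for ordinal.
#' @param cutpoints strictly increasing cutpoints (ordinal; length K-1 for K
#'   levels, K >= 3).
#' @return list of class `crt_mediator_gen`.
#' @export
mediator_gen <- function(spec, intercept, beta_treat,
                         beta_upstream = list(), beta_covariates = list(),
                         link = c("logit", "log", "identity",
                                  "log-count", "cumulative-logit"),
                         cutpoints = NULL) {
  link <- match.arg(link)
  stopifnot(inherits(spec, "crt_mediator_spec"))
  if (spec$type == "ordinal") {
    if (link != "cumulative-logit") stopf("ordinal mediators use link 'cumulative-logit'")
    if (is.null(cutpoints) || length(cutpoints) < 2 ||
        any(diff(cutpoints) <= 0)) {
      stopf("ordinal mediator '%s' needs >= 3 levels with strictly increasing cutpoints",
            spec$name)
    }
  }
  if (spec$type == "count" && link != "log-count") {
    stopf("count mediators use link 'log-count'")
  }
  structure(list(spec = spec, intercept = intercept, beta_treat = beta_treat,
                 beta_upstream = beta_upstream,
                 beta_covariates = beta_covariates,
                 link = link, cutpoints = cutpoints),
            class = "crt_mediator_gen")
}

#' Generating model for the synthetic outcome
#'
#' @param intercept linear-predictor intercept.
#' @param beta_treat direct treatment path.
#' @param beta_mediators named list mediator -> coefficient (ordinal
#'   mediators enter through their integer level).
#' @param beta_interaction named list mediator -> treatment-by-mediator
#'   interaction coefficient.
#' @param beta_covariates named list covariate -> coefficient.
#' @param link `"logit"`, `"log"`, or `"identity"` (linear probability).
#' @param season_shift additive linear-predictor offset applied during
#'   monsoon rounds.
#' @return list of class `crt_outcome_gen`.
#' @export
outcome_gen <- function(intercept, beta_treat, beta_mediators = list(),
                        beta_interaction = list(), beta_covariates = list(),
                        link = c("logit", "log", "identity"),
                        season_shift = 0) {
  link <- match.arg(link)
  structure(list(intercept = intercept, beta_treat = beta_treat,
                 beta_mediators = beta_mediators,
                 beta_interaction = beta_interaction,
                 beta_covariates = beta_covariates,
                 link = link, season_shift = season_shift),
            class = "crt_outcome_gen")
}

#' Synthetic cluster-randomized trial configuration
#'
#' The defaults emulate the trial whose structure the package targets:
#' geographically matched blocks each containing one sanitation and one
#' control cluster, 6-8 compounds per cluster with one index child each,
#' eight survey rounds roughly four months apart spanning monsoon and dry
#' windows, a binary 7-day diarrhea outcome with 10-15% prevalence, and
#' mediators causally downstream of treatment (a latrine-use mediator also
#' depends on a latrine-quality mediator, creating post-treatment
#' confounding).
#'
#' @param n_blocks number of matched blocks (>= 2).
#' @param clusters_per_arm_per_block clusters per arm per block (default 1).
#' @param compounds_per_cluster compounds per cluster (6-8 typical).
#' @param children_per_compound index children per compound (default 1).
#' @param rounds number of survey rounds.
#' @param round_dates Date vector of round dates (default: alternating
#'   mid-January / mid-July starting 2014, so both seasons are populated).
#' @param season_windows a [season_windows()] table (default: April 1 -
#'   September 30 monsoon each covered year).
#' @param mediator_models list of [mediator_gen()] in topological order.
#' @param outcome_model an [outcome_gen()].
#' @param missingness named list of per-column missing-completely-at-random
#'   probabilities.
#' @param seed integer RNG seed.
#' @return list of class `crt_synth_config`.
#' @export
synth_config <- function(n_blocks = 50,
                         clusters_per_arm_per_block = 1,
                         compounds_per_cluster = 7,
                         children_per_compound = 1,
                         rounds = 8,
                         round_dates = NULL,
                         season_windows = NULL,
                         mediator_models = default_mediator_models(),
                         outcome_model = default_outcome_model(),
                         missingness = list(diarrhea = 0.002),
                         seed = 1L) {
  stopifnot(is_count(n_blocks), n_blocks >= 2,
            is_count(clusters_per_arm_per_block),
            is_count(compounds_per_cluster),
            is_count(children_per_compound),
            is_count(rounds))
  if (is.null(round_dates)) {
    start <- as.Date("2014-01-15")
    round_dates <- as.Date(vapply(seq_len(rounds) - 1L, function(k) {
      yr <- 2014L + k %/% 2L
      mo <- if (k %% 2L == 0L) "01" else "07"
      sprintf("%d-%s-15", yr, mo)
    }, character(1)))
  }
  round_dates <- as.Date(round_dates)
  if (length(round_dates) != rounds) stopf("need %d round dates", rounds)
  if (is.null(season_windows)) {
    yrs <- sort(unique(as.integer(format(round_dates, "%Y"))))
    season_windows <- season_windows(
      yrs, as.Date(sprintf("%d-04-01", yrs)), as.Date(sprintf("%d-09-30", yrs)))
  }
  if (any(unlist(missingness) < 0) || any(unlist(missingness) > 1)) {
    stopf("missingness probabilities must lie in [0,1]")
  }
  validate_mediator_order(mediator_models)
  structure(list(
    n_blocks = as.integer(n_blocks),
    clusters_per_arm_per_block = as.integer(clusters_per_arm_per_block),
    compounds_per_cluster = as.integer(compounds_per_cluster),
    children_per_compound = as.integer(children_per_compound),
    rounds = as.integer(rounds),
    round_dates = round_dates,
    season_windows = season_windows,
    mediator_models = mediator_models,
    outcome_model = outcome_model,
    missingness = missingness,
    seed = as.integer(seed)
  ), class = "crt_synth_config")
}

validate_mediator_order <- function(gens) {
  seen <- character(0)
  for (g in gens) {
    stopifnot(inherits(g, "crt_mediator_gen"))
    ups <- names(g$beta_upstream)
    bad <- setdiff(ups, seen)
    if (length(bad)) {
      stopf("mediator '%s' references upstream mediator(s) not generated earlier: %s",
            g$spec$name, paste(bad, collapse = ", "))
    }
    seen <- c(seen, g$spec$name)
  }
  if (anyDuplicated(seen)) stopf("duplicate mediator names")
  invisible(TRUE)
}

#' Default synthetic mediator set
#'
#' One latrine-quality indicator (hygienic latrine), one latrine-use
#' practice downstream of it (open defecation by children under 3, reduced
#' by treatment), one binary feces-management practice (child feces disposed
#' into latrine) and one ordinal practice (potty-use frequency, 5 levels).
#' Intercepts and treatment paths are set so arm-specific prevalences match
#' the trial's published step-one table to first order.
#'
#' @return list of [mediator_gen()] objects.
#' @export
default_mediator_models <- function() {
  list(
    mediator_gen(
      mediator_spec("hygienic_latrine", "latrine_quality", "binary", "increase"),
      intercept = stats::qlogis(0.76), beta_treat = 2.36,
      beta_covariates = list(wealth = 0.3), link = "logit"),
    mediator_gen(
      mediator_spec("child_od_u3", "latrine_use", "binary", "decrease"),
      intercept = 2.97, beta_treat = -1.10,
      beta_upstream = list(hygienic_latrine = -0.5), link = "logit"),
    mediator_gen(
      mediator_spec("feces_disposed_latrine", "feces_management", "binary",
                    "increase"),
      intercept = stats::qlogis(0.239), beta_treat = 2.32, link = "logit"),
    mediator_gen(
      mediator_spec("potty_use", "feces_management", "ordinal", "increase"),
      intercept = 0, beta_treat = 3.6,
      cutpoints = c(1.63, 1.68, 1.90, 2.92), link = "cumulative-logit")
  )
}

#' Default synthetic outcome model
#'
#' Logit-link diarrhea model producing roughly 14-15% control and 10%
#' intervention prevalence, with protective paths through reduced child open
#' defecation, safe feces disposal and potty use, and a modest direct
#' effect.
#'
#' @return an [outcome_gen()].
#' @export
default_outcome_model <- function() {
  outcome_gen(
    intercept = -1.75,
    beta_treat = -0.15,
    beta_mediators = list(hygienic_latrine = -0.15, child_od_u3 = 0.45,
                          feces_disposed_latrine = -0.35, potty_use = -0.06),
    beta_covariates = list(age_months = -0.004, wealth = -0.10),
    link = "logit", season_shift = 0)
}

# ---- generation internals ---------------------------------------------------

# Covariate draws shared by the trial generator and the oracle: child age in
# months (baseline uniform 0-30, aged by calendar time per round), sex, and a
# compound-level standard-normal wealth score.
draw_baseline_covariates <- function(n) {
  data.frame(age0 = stats::runif(n, 0, 30),
             sex = stats::rbinom(n, 1, 0.5),
             wealth = stats::rnorm(n))
}

months_elapsed <- function(config) {
  as.numeric(config$round_dates - config$round_dates[1]) / 30.44
}

mediator_eta <- function(gen, tr, mediators, covs) {
  eta <- rep(gen$intercept, length(tr)) + gen$beta_treat * tr
  for (nm in names(gen$beta_upstream)) {
    eta <- eta + gen$beta_upstream[[nm]] * mediators[[nm]]
  }
  for (nm in names(gen$beta_covariates)) {
    eta <- eta + gen$beta_covariates[[nm]] * covs[[nm]]
  }
  eta
}

draw_mediator_value <- function(gen, eta) {
  switch(gen$link,
    "logit" = stats::rbinom(length(eta), 1, stats::plogis(eta)),
    "log" = {
      if (any(eta > 0)) {
        stopf("mediator '%s': log-link linear predictor exceeds 0 (probability > 1)",
              gen$spec$name)
      }
      stats::rbinom(length(eta), 1, exp(eta))
    },
    "identity" = {
      if (any(eta < 0 | eta > 1)) {
        stopf("mediator '%s': identity-link probability outside [0,1]",
              gen$spec$name)
      }
      stats::rbinom(length(eta), 1, eta)
    },
    "log-count" = stats::rpois(length(eta), exp(eta)),
    "cumulative-logit" = {
      K <- length(gen$cutpoints) + 1L
      cum <- vapply(gen$cutpoints, function(z) stats::plogis(z - eta),
                    numeric(length(eta)))
      u <- stats::runif(length(eta))
      1L + rowSums(u > cum)
    })
}

# Coupled potential-mediator draws for the oracle: the same uniform is
# thresholded under both treatment levels (monotone coupling), so zero-path
# configurations give exactly M(0) == M(1) and the Monte-Carlo error of
# contrasts shrinks. The marginal law of each draw is unchanged.
draw_mediator_pair <- function(gen, eta0, eta1) {
  n <- length(eta0)
  u <- stats::runif(n)
  prob_of <- function(eta) {
    switch(gen$link,
      "logit" = stats::plogis(eta),
      "log" = {
        if (any(eta > 0)) {
          stopf("mediator '%s': log-link linear predictor exceeds 0 (probability > 1)",
                gen$spec$name)
        }
        exp(eta)
      },
      "identity" = {
        if (any(eta < 0 | eta > 1)) {
          stopf("mediator '%s': identity-link probability outside [0,1]",
                gen$spec$name)
        }
        eta
      })
  }
  switch(gen$link,
    "logit" = , "log" = , "identity" = {
      list(m0 = as.integer(u < prob_of(eta0)),
           m1 = as.integer(u < prob_of(eta1)))
    },
    "log-count" = list(m0 = stats::qpois(u, exp(eta0)),
                       m1 = stats::qpois(u, exp(eta1))),
    "cumulative-logit" = {
      cat_of <- function(eta) {
        cum <- vapply(gen$cutpoints, function(z) stats::plogis(z - eta),
                      numeric(n))
        1L + rowSums(u > cum)
      }
      list(m0 = cat_of(eta0), m1 = cat_of(eta1))
    })
}

outcome_prob <- function(om, tr, mediators, covs, monsoon, label = "outcome") {
  eta <- rep(om$intercept, length(tr)) + om$beta_treat * tr
  for (nm in names(om$beta_mediators)) {
    eta <- eta + om$beta_mediators[[nm]] * mediators[[nm]]
  }
  for (nm in names(om$beta_interaction)) {
    eta <- eta + om$beta_interaction[[nm]] * tr * mediators[[nm]]
  }
  for (nm in names(om$beta_covariates)) {
    eta <- eta + om$beta_covariates[[nm]] * covs[[nm]]
  }
  eta <- eta + om$season_shift * monsoon
  switch(om$link,
    "logit" = stats::plogis(eta),
    "log" = {
      if (any(eta > 0)) {
        stopf("%s: log-link linear predictor exceeds 0 under the configured model",
              label)
      }
      exp(eta)
    },
    "identity" = {
      if (any(eta < 0 | eta > 1)) {
        stopf("%s: identity-link probability outside [0,1] under the configured model",
              label)
      }
      eta
    })
}

#' Generate a synthetic cluster-randomized trial
#'
#' Draws one row per child-by-round with exactly balanced arm assignment
#' within every block, mediators drawn from their generating models given
#' treatment, upstream mediators and covariates, the binary outcome drawn
#' from the outcome model, and missingness injected afterwards. When
#' `compute_truth` is TRUE the returned `truth` carries the Monte-Carlo
#' counterfactual oracle's true ACME/ADE/total per mediator and season.
#'
#' @param config a [synth_config()].
#' @param compute_truth compute the oracle truth table (default TRUE; turn
#'   off inside replication loops and call [true_acme_oracle()] once on the
#'   shared config instead).
#' @param oracle_mc_n Monte-Carlo size for the oracle (default 1e5).
#' @return list with elements `records` (data.frame) and `truth`
#'   (`crt_synth_truth` or NULL).
#' @export
generate_trial <- function(config, compute_truth = TRUE, oracle_mc_n = 1e5) {
  stopifnot(inherits(config, "crt_synth_config"))
  set.seed(config$seed)
  B <- config$n_blocks
  cpb <- config$clusters_per_arm_per_block
  cpc <- config$compounds_per_cluster
  kpc <- config$children_per_compound

  # Unit frame: block -> (treated cluster(s), control cluster(s)) -> compounds
  # -> children. Arm assignment is balanced within block by construction;
  # which physical cluster gets treatment is randomized.
  units <- expand.grid(child = seq_len(kpc), compound = seq_len(cpc),
                       cl = seq_len(2L * cpb), block = seq_len(B))
  flip <- stats::rbinom(B, 1, 0.5)  # randomize treatment label within block
  arm_of <- function(block, cl) {
    as.integer((cl <= cpb) != (flip[block] == 1L))
  }
  units$arm <- arm_of(units$block, units$cl)
  units$block_id <- sprintf("B%03d", units$block)
  units$cluster_id <- sprintf("B%03d_C%d", units$block, units$cl)
  units$compound_id <- sprintf("%s_H%02d", units$cluster_id, units$compound)
  units$child_id <- sprintf("%s_K%d", units$compound_id, units$child)
  n_children <- nrow(units)

  base <- draw_baseline_covariates(n_children)
  # wealth is a compound-level score: share within compound
  base$wealth <- stats::ave(base$wealth, units$compound_id, FUN = function(x) x[1])

  elapsed <- months_elapsed(config)
  seasons <- assign_season(config$round_dates, config$season_windows)

  rows <- vector("list", config$rounds)
  for (r in seq_len(config$rounds)) {
    covs <- data.frame(age_months = base$age0 + elapsed[r],
                       sex = base$sex, wealth = base$wealth)
    tr <- units$arm
    med_vals <- list()
    for (g in config$mediator_models) {
      sp <- g$spec
      eta <- mediator_eta(g, tr, med_vals, covs)
      med_vals[[sp$name]] <- draw_mediator_value(g, eta)
    }
    monsoon <- as.integer(seasons[r] == "monsoon")
    p <- outcome_prob(config$outcome_model, tr, med_vals, covs,
                      monsoon, label = "outcome model")
    y <- stats::rbinom(n_children, 1, p)
    df <- data.frame(block_id = units$block_id, cluster_id = units$cluster_id,
                     compound_id = units$compound_id, child_id = units$child_id,
                     round = r, date = config$round_dates[r], arm = tr,
                     season = seasons[r], covs,
                     as.data.frame(med_vals), diarrhea = y,
                     stringsAsFactors = FALSE)
    rows[[r]] <- df
  }
  records <- do.call(rbind, rows)
  records <- records[order(records$child_id, records$round), ]
  rownames(records) <- NULL
  records <- inject_missingness(records, config$missingness,
                                seed = child_seed(config$seed, 99L))

  truth <- NULL
  if (compute_truth) {
    truth <- synth_truth(config, mc_n = oracle_mc_n)
  }
  list(records = records, truth = truth)
}

#' Brute-force counterfactual oracle for the true ACME
#'
#' Simulates `mc_n` units directly from the generating models: potential
#' mediator values M(0) and M(1) for every mediator (upstream mediators
#' evaluated at the same treatment level), and expected potential outcomes
#' Y(t, M(t')) with the non-target mediators held at their treatment-t
#' values. Returns the arm-proportion-weighted (0.5/0.5 under balanced
#' assignment) mean of Y(t, M(1)) - Y(t, M(0)) and its Monte-Carlo standard
#' error, plus the matching ADE and total effect.
#'
#' @param config a [synth_config()].
#' @param mediator mediator name.
#' @param mc_n Monte-Carlo size (>= 1e5 recommended).
#' @param season `"monsoon"` or `"dry"` (fixes the season offset).
#' @param seed RNG seed (default derived from the config seed).
#' @return list: `acme`, `acme_se`, `ade`, `ade_se`, `total`, `total_se`,
#'   `mc_n`.
#' @export
true_acme_oracle <- function(config, mediator, mc_n = 1e5,
                             season = c("monsoon", "dry"), seed = NULL) {
  stopifnot(inherits(config, "crt_synth_config"))
  season <- match.arg(season)
  med_names <- vapply(config$mediator_models, function(g) g$spec$name, "")
  if (!mediator %in% med_names) stopf("unknown mediator '%s'", mediator)
  set.seed(seed %||% child_seed(config$seed, 7L + match(mediator, med_names)))

  elapsed <- months_elapsed(config)
  seas <- assign_season(config$round_dates, config$season_windows)
  rounds_in <- which(seas == season)
  if (!length(rounds_in)) stopf("no rounds fall in season '%s'", season)

  base <- draw_baseline_covariates(mc_n)
  r <- sample(rounds_in, mc_n, replace = TRUE)
  covs <- data.frame(age_months = base$age0 + elapsed[r],
                     sex = base$sex, wealth = base$wealth)
  # Potential mediators under both treatment levels, in topological order,
  # with coupled draws (common random numbers across treatment levels).
  M0 <- list(); M1 <- list()
  for (g in config$mediator_models) {
    nm <- g$spec$name
    pair <- draw_mediator_pair(g,
                               mediator_eta(g, rep(0L, mc_n), M0, covs),
                               mediator_eta(g, rep(1L, mc_n), M1, covs))
    M0[[nm]] <- pair$m0
    M1[[nm]] <- pair$m1
  }
  monsoon <- as.integer(season == "monsoon")
  om <- config$outcome_model
  # Y(t, m-value) with non-target mediators at their level-t values; expected
  # probabilities, not Bernoulli draws, to cut Monte-Carlo noise.
  pY <- function(t, m_arg) {
    med <- if (t == 1) M1 else M0
    med[[mediator]] <- (if (m_arg == 1) M1 else M0)[[mediator]]
    outcome_prob(om, rep(t, mc_n), med, covs, monsoon, label = "outcome model")
  }
  y00 <- pY(0, 0); y01 <- pY(0, 1); y10 <- pY(1, 0); y11 <- pY(1, 1)
  acme_i <- 0.5 * (y01 - y00) + 0.5 * (y11 - y10)
  ade_i <- 0.5 * (y10 - y00) + 0.5 * (y11 - y01)
  tot_i <- y11 - y00
  msd <- function(x) stats::sd(x) / sqrt(mc_n)
  list(acme = mean(acme_i), acme_se = msd(acme_i),
       ade = mean(ade_i), ade_se = msd(ade_i),
       total = mean(tot_i), total_se = msd(tot_i), mc_n = mc_n)
}

# Truth table for all mediators x seasons.
synth_truth <- function(config, mc_n = 1e5) {
  med_names <- vapply(config$mediator_models, function(g) g$spec$name, "")
  seas_avail <- unique(assign_season(config$round_dates, config$season_windows))
  tab <- do.call(rbind, lapply(med_names, function(m) {
    do.call(rbind, lapply(seas_avail, function(s) {
      o <- true_acme_oracle(config, m, mc_n = mc_n, season = s)
      data.frame(mediator = m, season = s, true_acme = o$acme,
                 true_ade = o$ade, true_total = o$total,
                 oracle_se = o$acme_se, oracle_ade_se = o$ade_se,
                 oracle_total_se = o$total_se, stringsAsFactors = FALSE)
    }))
  }))
  structure(list(config = config, table = tab, oracle_mc_n = mc_n),
            class = "crt_synth_truth")
}

#' @export
print.crt_synth_truth <- function(x, ...) {
  cat("<crt_synth_truth> oracle mc_n =", x$oracle_mc_n, "\n")
  tab <- x$table[, c("mediator", "season", "true_acme", "true_ade",
                     "true_total", "oracle_se")]
  tab$true_acme <- round(tab$true_acme, 4)
  tab$true_ade <- round(tab$true_ade, 4)
  tab$true_total <- round(tab$true_total, 4)
  tab$oracle_se <- signif(tab$oracle_se, 2)
  print(tab)
  invisible(x)
}

#' Inject missing-completely-at-random values
#'
#' @param records data.frame.
#' @param missingness named list of per-column missing probabilities in
#'   `[0,1]`.
#' @param seed RNG seed.
#' @return records with selected cells set to NA; row count unchanged.
#' @export
inject_missingness <- function(records, missingness, seed = NULL) {
  if (!length(missingness)) return(records)
  probs <- unlist(missingness)
  if (any(probs < 0 | probs > 1)) stopf("missingness probabilities must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  for (col in names(missingness)) {
    if (!col %in% names(records)) stopf("missingness names unknown column '%s'", col)
    rate <- missingness[[col]]
    if (rate == 0) next
    hit <- stats::runif(nrow(records)) < rate
    records[[col]][hit] <- NA
  }
  records
}
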