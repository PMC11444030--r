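# Shared synthetic-trial configurations and small data builders.

# Saturated two-group data with k successes of n per arm; one row per child,
# clusters nested in arm.
two_group_data <- function(k1, n1, k0, n0, n_clusters = 40) {
  d <- data.frame(
    arm = rep(c(0L, 1L), c(n0, n1)),
    y = c(rep(c(1L, 0L), c(k0, n0 - k0)), rep(c(1L, 0L), c(k1, n1 - k1)))
  )
  d$cluster_id <- rep_len(seq_len(n_clusters), nrow(d))
  d$block_id <- d$cluster_id
  d
}

# Single-mediator logit trial used for parameter-recovery checks: all rounds
# fall in the monsoon window so the analysed season holds ~3000 records, and
# models without covariates are correctly specified.
recovery_config <- function(seed, beta_m = -0.45) {
  synth_config(
    n_blocks = 27, compounds_per_cluster = 7, rounds = 8,
    round_dates = as.Date(sprintf("%d-07-15", 2014:2021)),
    mediator_models = list(
      mediator_gen(
        mediator_spec("feces_disposed_latrine", "feces_management", "binary",
                      "increase"),
        intercept = stats::qlogis(0.239), beta_treat = 2.32, link = "logit")),
    outcome_model = outcome_gen(
      intercept = -1.9, beta_treat = -0.15,
      beta_mediators = list(feces_disposed_latrine = beta_m), link = "logit"),
    missingness = list(), seed = seed)
}

recovery_spec <- function() {
  mediator_spec("feces_disposed_latrine", "feces_management", "binary",
                "increase")
}

# One recovery-trial replicate: fit the (correctly specified) logit mediator
# and outcome models and run the quasi-Bayesian estimator.
recovery_replicate <- function(seed, beta_m = -0.45, n_sims = 200) {
  cfg <- recovery_config(seed, beta_m = beta_m)
  rec <- generate_trial(cfg, compute_truth = FALSE)$records
  mfit <- fit_model(rec, model_spec("feces_disposed_latrine", "arm",
                                    family = "binomial-logit",
                                    cluster_var = "cluster_id"))
  yfit <- fit_model(rec, model_spec("diarrhea", "arm * feces_disposed_latrine",
                                    family = "binomial-logit",
                                    cluster_var = "cluster_id"))
  res <- mediate_single(rec, recovery_spec(), mfit, yfit, treat = "arm",
                        n_sims = n_sims, cluster_var = "block_id",
                        seed = seed + 50000)
  mediation_effect(res, "acme_avg")
}

# Post-treatment confounding: treatment improves latrine quality (W), which
# reduces child open defecation (M) and independently affects diarrhea.
confounded_config <- function(seed) {
  synth_config(
    n_blocks = 25, compounds_per_cluster = 5, rounds = 4,
    round_dates = as.Date(sprintf("%d-07-15", 2014:2017)),
    mediator_models = list(
      mediator_gen(
        mediator_spec("hygienic_latrine", "latrine_quality", "binary"),
        intercept = -0.5, beta_treat = 1.5, link = "logit"),
      mediator_gen(
        mediator_spec("child_od_u3", "latrine_use", "binary", "decrease"),
        intercept = 0.8, beta_treat = -0.8,
        beta_upstream = list(hygienic_latrine = -1.0), link = "logit")),
    outcome_model = outcome_gen(
      intercept = -2.2, beta_treat = -0.2,
      beta_mediators = list(child_od_u3 = 0.6, hygienic_latrine = 0.8),
      link = "logit"),
    missingness = list(), seed = seed)
}

confounded_spec <- function() {
  mediator_spec("child_od_u3", "latrine_use", "binary", "decrease")
}

# Identity-link (linear probability) single-mediator config for closed-form
# oracles.
linear_config <- function(seed, beta_treat_m = 0.25, beta_m = -0.2) {
  synth_config(
    n_blocks = 5,
    mediator_models = list(
      mediator_gen(mediator_spec("m1", "latrine_quality", "binary"),
                   intercept = 0.3, beta_treat = beta_treat_m,
                   link = "identity")),
    outcome_model = outcome_gen(0.3, -0.03, beta_mediators = list(m1 = beta_m),
                                link = "identity"),
    missingness = list(), seed = seed)
}
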