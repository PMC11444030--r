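test_that("arm assignment is exactly balanced within every block", {
  cfg <- synth_config(n_blocks = 12, seed = 21)
  rec <- generate_trial(cfg, compute_truth = FALSE)$records
  by_block <- split(rec, rec$block_id)
  for (b in by_block) {
    arms <- tapply(b$arm, b$cluster_id, unique)
    expect_equal(sort(as.integer(unlist(arms))), c(0L, 1L))
  }
  # one row per child x round
  expect_equal(nrow(rec), 12 * 2 * 7 * 8)
  expect_equal(unname(table(rec$round)), rep(12 * 2 * 7, 8),
               ignore_attr = TRUE)
})

test_that("regenerating with the same seed reproduces the table bit-for-bit", {
  cfg <- synth_config(n_blocks = 6, seed = 99)
  a <- generate_trial(cfg, compute_truth = FALSE)$records
  b <- generate_trial(cfg, compute_truth = FALSE)$records
  expect_identical(a, b)
  c <- generate_trial(synth_config(n_blocks = 6, seed = 100),
                      compute_truth = FALSE)$records
  expect_false(identical(a$diarrhea, c$diarrhea))
})

test_that("empirical mediator prevalence matches the model-implied probability", {
  p0 <- 0.3; bt <- 1.1
  cfg <- synth_config(
    n_blocks = 60, rounds = 4,
    round_dates = as.Date(sprintf("%d-07-15", 2014:2017)),
    mediator_models = list(
      mediator_gen(mediator_spec("m1", "latrine_quality", "binary"),
                   intercept = qlogis(p0), beta_treat = bt, link = "logit")),
    outcome_model = outcome_gen(-2, 0, beta_mediators = list(m1 = 0),
                                link = "logit"),
    missingness = list(), seed = 31)
  rec <- generate_trial(cfg, compute_truth = FALSE)$records
  for (a in 0:1) {
    x <- rec$m1[rec$arm == a]
    p_model <- plogis(qlogis(p0) + bt * a)
    se <- sqrt(p_model * (1 - p_model) / length(x))
    expect_lt(abs(mean(x) - p_model), 3 * se)
  }
})

test_that("oracle truth satisfies the decomposition within Monte-Carlo error", {
  cfg <- recovery_config(5)
  o <- true_acme_oracle(cfg, "feces_disposed_latrine", mc_n = 1e5,
                        season = "monsoon")
  comb_se <- 3 * (o$acme_se + o$ade_se + o$total_se)
  expect_lt(abs(o$acme + o$ade - o$total), comb_se)
  expect_true(all(abs(c(o$acme, o$ade, o$total)) <= 1))
})

test_that("severed paths give exactly zero true ACME", {
  # no treatment -> mediator path
  cfg1 <- synth_config(
    n_blocks = 4,
    mediator_models = list(
      mediator_gen(mediator_spec("m1", "latrine_quality", "binary"),
                   intercept = 0, beta_treat = 0, link = "logit")),
    outcome_model = outcome_gen(-2, -0.2, beta_mediators = list(m1 = 0.5),
                                link = "logit"),
    missingness = list(), seed = 3)
  o1 <- true_acme_oracle(cfg1, "m1", mc_n = 1e5, season = "monsoon")
  expect_identical(o1$acme, 0)

  # no mediator -> outcome path (coefficient and interaction both zero)
  cfg2 <- synth_config(
    n_blocks = 4,
    mediator_models = list(
      mediator_gen(mediator_spec("m1", "latrine_quality", "binary"),
                   intercept = 0, beta_treat = 1, link = "logit")),
    outcome_model = outcome_gen(-2, -0.2, beta_mediators = list(m1 = 0),
                                beta_interaction = list(m1 = 0),
                                link = "logit"),
    missingness = list(), seed = 3)
  o2 <- true_acme_oracle(cfg2, "m1", mc_n = 1e5, season = "monsoon")
  expect_identical(o2$acme, 0)
})

test_that("linear-probability oracle matches the product of path coefficients", {
  cfg <- linear_config(3, beta_treat_m = 0.25, beta_m = -0.2)
  o <- true_acme_oracle(cfg, "m1", mc_n = 4e5, season = "monsoon")
  expect_lt(abs(o$acme - 0.25 * (-0.2)), 3 * o$acme_se)

  # doubling the mediator -> outcome coefficient doubles the ACME exactly
  # (same seed, coupled draws)
  a1 <- true_acme_oracle(linear_config(3, beta_m = -0.1), "m1",
                         mc_n = 1e5, season = "monsoon")$acme
  a2 <- true_acme_oracle(linear_config(3, beta_m = -0.2), "m1",
                         mc_n = 1e5, season = "monsoon")$acme
  expect_equal(a2, 2 * a1, tolerance = 1e-12)
})

test_that("oracle value is stable across independent seeds", {
  cfg <- recovery_config(5)
  o1 <- true_acme_oracle(cfg, "feces_disposed_latrine", mc_n = 1e5,
                         season = "monsoon", seed = 101)
  o2 <- true_acme_oracle(cfg, "feces_disposed_latrine", mc_n = 1e5,
                         season = "monsoon", seed = 202)
  expect_lt(abs(o1$acme - o2$acme), 3 * (o1$acme_se + o2$acme_se))
})

test_that("unreachable log-link probabilities error, naming the culprit", {
  cfg <- synth_config(
    n_blocks = 4,
    mediator_models = list(
      mediator_gen(mediator_spec("m1", "latrine_quality", "binary"),
                   intercept = -0.2, beta_treat = 0.5, link = "log")),
    outcome_model = outcome_gen(-2, 0, beta_mediators = list(m1 = 0.1),
                                link = "logit"),
    missingness = list(), seed = 3)
  expect_error(generate_trial(cfg, compute_truth = FALSE),
               "m1.*log-link")
})

test_that("inject_missingness behaves at the rate boundaries", {
  cfg <- synth_config(n_blocks = 10, missingness = list(), seed = 8)
  rec <- generate_trial(cfg, compute_truth = FALSE)$records

  expect_identical(inject_missingness(rec, list(diarrhea = 0), seed = 1), rec)

  all_na <- inject_missingness(rec, list(diarrhea = 1), seed = 1)
  expect_true(all(is.na(all_na$diarrhea)))
  expect_equal(nrow(all_na), nrow(rec))

  # rate 0.01 over n rows: count within the central 99% binomial interval
  n <- nrow(rec)
  some <- inject_missingness(rec, list(diarrhea = 0.01), seed = 2)
  n_miss <- sum(is.na(some$diarrhea))
  expect_gte(n_miss, qbinom(0.005, n, 0.01))
  expect_lte(n_miss, qbinom(0.995, n, 0.01))

  expect_error(inject_missingness(rec, list(diarrhea = 1.5)), "\\[0,1\\]")
  expect_error(inject_missingness(rec, list(nope = 0.1)), "unknown column")
})

test_that("ordinal mediators respect their cumulative-logit cutpoints", {
  cuts <- c(-0.5, 0.5, 1.5)
  cfg <- synth_config(
    n_blocks = 40, rounds = 2,
    round_dates = as.Date(c("2014-07-15", "2015-07-15")),
    mediator_models = list(
      mediator_gen(mediator_spec("po", "feces_management", "ordinal"),
                   intercept = 0, beta_treat = 0, cutpoints = cuts,
                   link = "cumulative-logit")),
    outcome_model = outcome_gen(-2, 0, link = "logit"),
    missingness = list(), seed = 13)
  rec <- generate_trial(cfg, compute_truth = FALSE)$records
  expect_setequal(unique(rec$po), 1:4)
  emp_cum <- cumsum(prop.table(table(rec$po)))[1:3]
  se <- sqrt(plogis(cuts) * (1 - plogis(cuts)) / nrow(rec))
  expect_true(all(abs(emp_cum - plogis(cuts)) < 4 * se))

  # invalid cutpoints are rejected at construction
  expect_error(
    mediator_gen(mediator_spec("po", "feces_management", "ordinal"),
                 0, 1, cutpoints = c(1, 0.5), link = "cumulative-logit"),
    "strictly increasing")
})
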