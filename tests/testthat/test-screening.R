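screen_trial <- function(seed = 51, n_blocks = 15) {
  cfg <- synth_config(n_blocks = n_blocks, seed = seed)
  generate_trial(cfg, compute_truth = FALSE)$records
}

test_that("step one emits the screening table and retains strong mediators", {
  rec <- screen_trial()
  rep1 <- step1_screen(rec, default_catalog(), "monsoon",
                       covariates = c("age_months", "sex"))
  expect_s3_class(rep1, "crt_screen_report")
  expect_setequal(rep1$mediator,
                  c("hygienic_latrine", "child_od_u3",
                    "feces_disposed_latrine", "potty_use"))
  # strong generated treatment effects on all four default mediators
  expect_true(all(rep1$retained))
  # binary mediators report prevalence-ratio-scale estimates in the
  # generated direction
  hyg <- rep1[rep1$mediator == "hygienic_latrine", ]
  expect_gt(hyg$estimate, 1)
  od <- rep1[rep1$mediator == "child_od_u3", ]
  expect_lt(od$estimate, 1)
  # ordinal mediator screened with proportional odds
  expect_equal(rep1$family[rep1$mediator == "potty_use"], "ordinal-logit")
  # arm summaries recompute from the raw records
  dat <- rec[rec$season == "monsoon" & !is.na(rec$diarrhea) &
               !is.na(rec$age_months) & !is.na(rec$sex), ]
  expect_equal(hyg$n, nrow(dat))
})

test_that("degenerate mediators are reported, not thrown", {
  rec <- screen_trial()
  rec$constant_med <- 1L
  cat <- mediator_catalog(c(
    default_catalog(),
    list(constant_med = mediator_spec("constant_med", "latrine_quality",
                                      "binary"))))
  rep1 <- step1_screen(rec, cat, "dry")
  row <- rep1[rep1$mediator == "constant_med", ]
  expect_false(row$retained)
  expect_equal(row$reason, "degenerate")
})

test_that("covariate prescreen retains true predictors and handles edge cases", {
  rec <- screen_trial()
  # empty candidate list
  empty <- screen_covariates(rec, character(0), "monsoon")
  expect_equal(nrow(empty), 0)
  # a covariate equal to the outcome's linear-predictor driver is always
  # retained
  rec$strong <- rec$diarrhea + rnorm(nrow(rec), 0, 0.05)
  scr <- screen_covariates(rec, c("strong", "sex"), "monsoon")
  expect_true(scr$retained[scr$candidate == "strong"])
  expect_lt(scr$p[scr$candidate == "strong"], 1e-6)
})

test_that("step two enforces step-one retention and reuses the row set", {
  rec <- screen_trial()
  rep1 <- step1_screen(rec, default_catalog(), "monsoon")
  fake_screen <- rep1
  fake_screen$retained[fake_screen$mediator == "hygienic_latrine"] <- FALSE
  expect_error(
    step2_fit(rec, default_catalog()[["hygienic_latrine"]], character(0),
              "monsoon", screen = fake_screen),
    "not retained")

  fit2 <- step2_fit(rec, default_catalog()[["feces_disposed_latrine"]],
                    character(0), "monsoon", screen = rep1)
  expect_true(fit2$converged)
  # identical n as step one (the consistent-observations rule)
  expect_equal(fit2$n_obs,
               rep1$n[rep1$mediator == "feces_disposed_latrine"])
  assoc <- attr(fit2, "mediator_assoc")
  expect_true(is.list(assoc) && !is.null(assoc$p))
})

test_that("the full pipeline is deterministic and row-consistent", {
  rec <- screen_trial(seed = 77, n_blocks = 12)
  cfgA <- analysis_config(n_sims = 40, n_boot = 20, seed = 9)
  a1 <- run_full_analysis(rec, default_catalog(),
                          c("age_months", "sex", "wealth"), cfgA)
  a2 <- run_full_analysis(rec, default_catalog(),
                          c("age_months", "sex", "wealth"), cfgA)
  expect_identical(a1$table, a2$table)

  # season-stratified analyses partition the season-taggable records
  expect_equal(sum(rec$season == "monsoon") + sum(rec$season == "dry"),
               nrow(rec))

  # every mediation's n matches its screen row (consistent observations)
  for (s in names(a1$seasons)) {
    scr <- a1$seasons[[s]]$screen
    for (nm in names(a1$seasons[[s]]$mediations)) {
      expect_equal(a1$seasons[[s]]$mediations[[nm]]$n_obs,
                   scr$n[scr$mediator == nm])
    }
  }

  # table ordered by descending |ACME| within season
  for (s in unique(a1$table$season)) {
    acmes <- abs(a1$table$acme[a1$table$season == s])
    expect_true(all(diff(acmes) <= 1e-12))
  }
})

test_that("mediators with availability windows are screened but not mediated", {
  rec <- screen_trial(seed = 31, n_blocks = 10)
  # a latrine-age-like mediator recorded in rounds 1-2 only
  rec$latrine_age <- ifelse(rec$round <= 2,
                            rpois(nrow(rec), exp(1 - 0.5 * rec$arm)), NA)
  cat <- mediator_catalog(c(
    default_catalog(),
    list(latrine_age = mediator_spec("latrine_age", "latrine_quality",
                                     "count", "decrease", rounds = 1:2))))
  cfgA <- analysis_config(n_sims = 20, n_boot = 10, seed = 2)
  a <- run_full_analysis(rec, cat, character(0), cfgA)
  scr <- a$seasons$monsoon$screen
  expect_true("latrine_age" %in% scr$mediator)
  expect_false("latrine_age" %in% names(a$seasons$monsoon$mediations))
})

test_that("lagged sensitivity handles alternating seasons and stable mediators", {
  # default round dates strictly alternate seasons: no qualifying pairs
  rec <- screen_trial(seed = 61, n_blocks = 8)
  expect_message(
    out <- lagged_sensitivity(rec, default_catalog()[["feces_disposed_latrine"]]),
    "no consecutive same-season")
  expect_equal(nrow(out), 0)

  # all-monsoon rounds with a mediator constant within child: lagged and
  # concurrent estimates coincide exactly
  cfg <- synth_config(
    n_blocks = 12, rounds = 4,
    round_dates = as.Date(sprintf("%d-07-15", 2014:2017)),
    missingness = list(), seed = 62)
  rec2 <- generate_trial(cfg, compute_truth = FALSE)$records
  first <- !duplicated(rec2$child_id)
  stable <- rec2$feces_disposed_latrine[first][match(rec2$child_id,
                                                     rec2$child_id[first])]
  rec2$stable_med <- stable
  out2 <- lagged_sensitivity(rec2,
                             mediator_spec("stable_med", "feces_management",
                                           "binary"))
  mon <- out2[out2$season == "monsoon", ]
  expect_gt(mon$n_pairs, 0)
  expect_equal(mon$est_lagged, mon$est_concurrent, tolerance = 1e-10)
})

test_that("reverse causation shows up as concurrent-vs-lagged divergence", {
  # mediator responds to the current outcome (caregivers change disposal
  # behaviour when the child is ill): the concurrent association is biased
  # away from the lagged one
  set.seed(63)
  cfg <- synth_config(
    n_blocks = 25, rounds = 6,
    round_dates = as.Date(sprintf("2014-0%d-15", 4:9)),
    missingness = list(), seed = 63)
  rec <- generate_trial(cfg, compute_truth = FALSE)$records
  rec$reactive <- rbinom(nrow(rec), 1,
                         ifelse(rec$diarrhea == 1, 0.85, 0.35))
  out <- lagged_sensitivity(rec,
                            mediator_spec("reactive", "feces_management",
                                          "binary"))
  mon <- out[out$season == "monsoon", ]
  expect_gt(mon$est_concurrent, mon$est_lagged)
  expect_gt(mon$est_concurrent, 1.5)   # strong spurious concurrent signal
  expect_lt(abs(log(mon$est_lagged)), log(1.5))  # lagged near the null
})
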