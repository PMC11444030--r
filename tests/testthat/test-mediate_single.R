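make_fits <- function(n = 800, seed = 3, interaction = TRUE) {
  set.seed(seed)
  d <- data.frame(arm = rep(c(0L, 1L), n / 2),
                  cluster_id = rep(seq_len(20), each = n / 20))
  d$block_id <- d$cluster_id
  d$m <- rbinom(n, 1, plogis(-1 + 1.2 * d$arm))
  d$y <- rbinom(n, 1, plogis(-2 + 0.3 * d$arm + 0.5 * d$m -
                               0.2 * d$arm * d$m))
  yterms <- if (interaction) "arm * m" else c("arm", "m")
  list(
    d = d,
    spec = mediator_spec("m", "latrine_use", "binary"),
    mfit = fit_model(d, model_spec("m", "arm", family = "binomial-logit")),
    yfit = fit_model(d, model_spec("y", yterms, family = "binomial-logit"))
  )
}

test_that("severing the mediator-outcome path zeroes the ACME exactly", {
  fx <- make_fits()
  yfit <- fx$yfit
  yfit$coefficients[c("m", "arm:m")] <- 0
  res <- mediate_single(fx$d, fx$spec, fx$mfit, yfit, n_sims = 20,
                        seed = 1, cluster_var = "cluster_id",
                        vcov_type = "zero")
  expect_identical(mediation_effect(res, "acme_avg")$estimate, 0)
  expect_identical(mediation_effect(res, "ade_avg")$estimate,
                   mediation_effect(res, "total")$estimate)
})

test_that("linear identity-link case returns the product of coefficients", {
  set.seed(5)
  n <- 600
  d <- data.frame(arm = rep(c(0L, 1L), n / 2),
                  cluster_id = rep(1:20, each = n / 20))
  d$m <- rbinom(n, 1, 0.25 + 0.3 * d$arm)
  d$y <- 0.12 + 0.04 * d$arm + 0.18 * d$m + rnorm(n, 0, 0.05)
  mfit <- fit_model(d, model_spec("m", "arm", family = "gaussian"))
  yfit <- fit_model(d, model_spec("y", c("arm", "m"), family = "gaussian"))
  spec <- mediator_spec("m", "latrine_use", "binary")
  res <- mediate_single(d, spec, mfit, yfit, n_sims = 10, seed = 2,
                        cluster_var = "cluster_id", vcov_type = "zero")
  expected <- mfit$coefficients[["arm"]] * yfit$coefficients[["m"]]
  expect_lt(abs(mediation_effect(res, "acme_avg")$estimate - expected), 1e-10)

  # with exactly balanced arms (w = 0.5/0.5) the averages decompose exactly
  est <- res$estimates
  expect_lt(abs(est$estimate[est$effect == "acme_avg"] +
                est$estimate[est$effect == "ade_avg"] -
                est$estimate[est$effect == "total"]), 1e-12)
  # no interaction term: the conditional ACMEs coincide, so the proportion-
  # weighted discrepancy vanishes draw by draw
  expect_equal(res$draws$acme0, res$draws$acme1, tolerance = 1e-12)
})

test_that("the decomposition identity holds exactly within every draw", {
  fx <- make_fits()
  res <- mediate_single(fx$d, fx$spec, fx$mfit, fx$yfit, n_sims = 100,
                        seed = 11, cluster_var = "block_id")
  dr <- res$draws
  expect_lt(max(abs(dr$acme1 + dr$ade0 - dr$total)), 1e-12)
  expect_lt(max(abs(dr$acme0 + dr$ade1 - dr$total)), 1e-12)
})

test_that("fixing the seed reproduces the result exactly", {
  fx <- make_fits()
  r1 <- mediate_single(fx$d, fx$spec, fx$mfit, fx$yfit, n_sims = 50,
                       seed = 4, cluster_var = "block_id")
  r2 <- mediate_single(fx$d, fx$spec, fx$mfit, fx$yfit, n_sims = 50,
                       seed = 4, cluster_var = "block_id")
  expect_identical(r1$estimates, r2$estimates)
  r3 <- mediate_single(fx$d, fx$spec, fx$mfit, fx$yfit, n_sims = 50,
                       seed = 5, cluster_var = "block_id")
  expect_false(identical(r1$estimates$estimate, r3$estimates$estimate))
})

test_that("mismatched row sets and non-converged fits are rejected", {
  fx <- make_fits()
  d2 <- fx$d[-(1:10), ]
  mfit2 <- fit_model(d2, model_spec("m", "arm", family = "binomial-logit"))
  expect_error(
    mediate_single(fx$d, fx$spec, mfit2, fx$yfit, n_sims = 5, seed = 1),
    "identical row set")

  bad <- fx$mfit
  bad$converged <- FALSE
  expect_error(
    mediate_single(fx$d, fx$spec, bad, fx$yfit, n_sims = 5, seed = 1),
    "did not converge")
})

test_that("a protective generated pathway yields a negative ACME", {
  # treatment raises safe-disposal prevalence, which lowers diarrhea risk
  set.seed(17)
  n <- 4000
  d <- data.frame(arm = rep(c(0L, 1L), n / 2),
                  cluster_id = rep(1:40, each = n / 40))
  d$block_id <- d$cluster_id
  d$m <- rbinom(n, 1, plogis(-1.2 + 2.3 * d$arm))
  d$y <- rbinom(n, 1, plogis(-1.6 - 0.1 * d$arm - 0.5 * d$m))
  spec <- mediator_spec("m", "feces_management", "binary", "increase")
  mfit <- fit_model(d, model_spec("m", "arm", family = "binomial-logit"))
  yfit <- fit_model(d, model_spec("y", "arm * m", family = "binomial-logit"))
  res <- mediate_single(d, spec, mfit, yfit, n_sims = 200, seed = 6,
                        cluster_var = "cluster_id")
  acme <- mediation_effect(res, "acme_avg")
  expect_lt(acme$estimate, 0)
  expect_lt(acme$ci_high, 0)
})

test_that("scaling the mediator-outcome coefficient scales the ACME", {
  gen <- function(b, seed) {
    set.seed(seed)
    n <- 8000
    d <- data.frame(arm = rep(c(0L, 1L), n / 2),
                    cluster_id = rep(1:40, each = n / 40))
    d$m <- rbinom(n, 1, 0.25 + 0.3 * d$arm)
    d$y <- 0.15 + 0.02 * d$arm + b * d$m + rnorm(n, 0, 0.08)
    mfit <- fit_model(d, model_spec("m", "arm", family = "gaussian"))
    yfit <- fit_model(d, model_spec("y", c("arm", "m"), family = "gaussian"))
    res <- mediate_single(d, mediator_spec("m", "latrine_use", "binary"),
                          mfit, yfit, n_sims = 50, seed = 7,
                          cluster_var = "cluster_id")
    mediation_effect(res, "acme_avg")$estimate
  }
  a1 <- gen(0.1, 23)
  a2 <- gen(0.2, 24)
  expect_gt(a2 / a1, 1.6)
  expect_lt(a2 / a1, 2.4)
})

test_that("ordinal mediators run through the exact-expectation path", {
  set.seed(19)
  n <- 2000
  d <- data.frame(arm = rep(c(0L, 1L), n / 2),
                  cluster_id = rep(1:20, each = n / 20))
  d$block_id <- d$cluster_id
  z <- rlogis(n) + 1.5 * d$arm
  d$po <- cut(z, c(-Inf, 0.8, 1.8, 2.8, Inf), labels = FALSE)
  d$y <- rbinom(n, 1, plogis(-1.4 + 0.1 * d$arm - 0.12 * d$po))
  spec <- mediator_spec("po", "feces_management", "ordinal", "increase")
  mfit <- fit_model(d, model_spec("po", "arm", family = "ordinal-logit"))
  yfit <- fit_model(d, model_spec("y", "arm * factor(po)",
                                  family = "binomial-logit"))
  res <- mediate_single(d, spec, mfit, yfit, n_sims = 100, seed = 8,
                        cluster_var = "cluster_id")
  dr <- res$draws
  expect_lt(max(abs(dr$acme1 + dr$ade0 - dr$total)), 1e-12)
  expect_lt(mediation_effect(res, "acme_avg")$estimate, 0)
})

test_that("count mediators are simulated Poisson and decompose exactly", {
  set.seed(20)
  n <- 1500
  d <- data.frame(arm = rep(c(0L, 1L), n / 2),
                  cluster_id = rep(1:30, each = n / 30))
  d$cnt <- rpois(n, exp(0.4 - 0.5 * d$arm))
  d$y <- rbinom(n, 1, plogis(-1.8 + 0.1 * d$arm + 0.15 * d$cnt))
  spec <- mediator_spec("cnt", "latrine_use", "count", "decrease")
  mfit <- fit_model(d, model_spec("cnt", "arm", family = "poisson"))
  yfit <- fit_model(d, model_spec("y", "arm * cnt",
                                  family = "binomial-logit"))
  res <- mediate_single(d, spec, mfit, yfit, n_sims = 60, seed = 9,
                        cluster_var = "cluster_id")
  dr <- res$draws
  expect_lt(max(abs(dr$acme1 + dr$ade0 - dr$total)), 1e-12)
  expect_lt(mediation_effect(res, "acme_avg")$estimate, 0)
})
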