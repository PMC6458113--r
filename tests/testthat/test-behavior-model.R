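test_that("AICc reproduces its closed form and published table rows", {
  expect_equal(aicc(-82.33, 5, 55), 175.88, tolerance = 0.005)
  expect_equal(aicc(-74.47, 5, 53), 160.21, tolerance = 0.005)
  expect_equal(aicc(-31.62, 5, 33), 75.46, tolerance = 0.005)
  expect_equal(aicc(0, 1, 1e6), 2 + 4 / (1e6 - 2), tolerance = 1e-12)
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("Akaike weights normalize relative likelihoods", {
  w <- akaike_weights(c(112.34, 113.77, 115.11, 122.46, 123.95))
  expect_equal(round(w[1], 2), 0.57)
  expect_equal(sum(w), 1)
  expect_equal(akaike_weights(42), 1)
  expect_equal(akaike_weights(c(0, 2)),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_error(akaike_weights(numeric()), "empty")
})

test_that("parameter counts match the mixed-model bookkeeping", {
  dat <- simulate_behavior(behavior_sim_config(seed = 21))
  selb <- suppressWarnings(suppressMessages(
    fit_candidate_set(dat, "ejaculation")))
  kb <- setNames(selb$table$k, selb$table$model)
  expect_equal(unname(kb["Null"]), 2L)
  expect_equal(unname(kb["CE"]), 3L)
  expect_equal(unname(kb["F"]), 3L)
  expect_equal(unname(kb["CE + F"]), 4L)
  expect_equal(unname(kb["CE + F + CE x F"]), 5L)
  selg <- suppressWarnings(suppressMessages(fit_candidate_set(dat, "sperm")))
  kg <- setNames(selg$table$k, selg$table$model)
  expect_equal(unname(kg["Null"]), 3L)
  expect_equal(unname(kg["CE + F + CE x F"]), 6L)
  # gaussian responses use only opportunities with an ejaculate
  expect_equal(selg$n_obs, sum(dat$ejaculated == 1L))
  # table AICc always reproduces the closed form from its own (l, k, n)
  expect_equal(selg$table$aicc,
               aicc(selg$table$loglik, selg$table$k, selg$n_obs))
  expect_equal(selg$table$delta, selg$table$aicc - min(selg$table$aicc))
  expect_equal(sum(selg$table$weight), 1)
})

test_that("with no male-level variance the mixed fit matches the fixed fit", {
  # the generator shares one trajectory across males, so the true random
  # intercept variance is 0
  dat <- simulate_behavior(behavior_sim_config(seed = 22))
  sel <- suppressWarnings(suppressMessages(fit_candidate_set(dat, "sperm")))
  mf <- ejacdyn:::build_model_frame(dat, "sperm")
  for (i in seq_len(nrow(sel$table))) {
    terms <- sel$terms[[i]]
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    ols <- lm(stats::as.formula(paste("y ~", rhs)), data = mf)
    expect_lt(abs(sel$table$loglik[i] - as.numeric(logLik(ols))), 0.01)
    # OLS profile log-likelihood closed form
    rss <- sum(stats::residuals(ols)^2)
    n <- nrow(mf)
    ll_closed <- -n / 2 * (log(2 * pi * rss / n) + 1)
    expect_equal(as.numeric(logLik(ols)), ll_closed, tolerance = 1e-6)
  }
  selb <- suppressWarnings(suppressMessages(
    fit_candidate_set(dat, "ejaculation")))
  mfb <- ejacdyn:::build_model_frame(dat, "ejaculation")
  glm0 <- stats::glm(y ~ CE + F, family = stats::binomial(), data = mfb)
  row <- which(selb$table$model == "CE + F")
  expect_lt(abs(selb$table$loglik[row] - as.numeric(logLik(glm0))), 0.01)
})

test_that("binomial marginal likelihood is stable under quadrature doubling", {
  dat <- simulate_behavior(behavior_sim_config(seed = 23))
  a <- suppressWarnings(suppressMessages(
    fit_candidate_set(dat, "ejaculation", nAGQ = 25L)))
  b <- suppressWarnings(suppressMessages(
    fit_candidate_set(dat, "ejaculation", nAGQ = 50L)))
  expect_true(all(abs(a$table$loglik -
                        b$table$loglik[match(a$table$model,
                                             b$table$model)]) < 0.01))
})

test_that("noiseless data recover the depletion slope to numerical precision", {
  cfg <- behavior_sim_config(
    n_males = 12, noise_sd = 0, intercept_log1p = 20, depletion_slope = -0.3,
    novelty_boost = 0, ejaculation_logit_intercept = 50,
    ejaculation_logit_slope = 0, seed = 31)
  dat <- simulate_behavior(cfg)
  sel <- suppressWarnings(suppressMessages(fit_candidate_set(dat, "sperm")))
  ce_row <- which(sel$table$model == "CE")
  b <- coef(sel, model = ce_row)
  # log(y) and log1p(y) agree to ~1e-8 at these magnitudes
  expect_equal(unname(b["CE"]), -0.3, tolerance = 1e-6)
})

test_that("model averaging weights, substitutes zeros and matches refits", {
  dat <- simulate_behavior(behavior_sim_config(seed = 24))
  sel <- suppressWarnings(suppressMessages(fit_candidate_set(dat, "sperm")))
  av <- model_average(sel)
  top <- which(sel$table$in_top_set)
  w <- sel$table$weight[top] / sum(sel$table$weight[top])
  # independent refits on the standardized frame, model by model
  mf <- ejacdyn:::build_model_frame(dat, "sperm", standardize = TRUE)
  beta <- lapply(sel$terms[top], function(tm) {
    rhs <- if (length(tm)) paste(tm, collapse = " + ") else "1"
    lme4::fixef(suppressWarnings(suppressMessages(
      lme4::lmer(stats::as.formula(paste("y ~", rhs, "+ (1 | male_id)")),
                 data = mf, REML = FALSE))))
  })
  for (term in av$term) {
    contrib <- vapply(beta, function(b) {
      if (term %in% names(b)) b[[term]] else 0
    }, numeric(1))
    expect_equal(av$estimate[av$term == term], sum(w * contrib),
                 tolerance = 1e-6)
    present <- vapply(beta, function(b) term %in% names(b), logical(1))
    expect_equal(av$estimate_conditional[av$term == term],
                 sum(w[present] * contrib[present]) / sum(w[present]),
                 tolerance = 1e-6)
  }
  # singleton top set collapses to that model's coefficients
  sel1 <- sel
  sel1$table$in_top_set <- seq_len(nrow(sel$table)) == 1L
  av1 <- model_average(sel1)
  b1 <- lme4::fixef(suppressWarnings(suppressMessages(
    lme4::lmer(stats::as.formula(paste(
      "y ~", paste(sel$terms[[1]], collapse = " + "), "+ (1 | male_id)")),
      data = mf, REML = FALSE))))
  for (term in names(b1)) {
    expect_equal(av1$estimate_conditional[av1$term == term],
                 unname(b1[term]), tolerance = 1e-6)
  }
})

test_that("standardization records mean-zero, half-SD predictor coding", {
  dat <- simulate_behavior(behavior_sim_config(seed = 25))
  mf <- ejacdyn:::build_model_frame(dat, "sperm", standardize = TRUE)
  expect_equal(mean(mf$CE), 0, tolerance = 1e-12)
  expect_equal(sd(mf$CE), 0.5, tolerance = 1e-12)
  expect_equal(sd(mf$F), 0.5, tolerance = 1e-12)
})

test_that("a positive novelty boost yields a positive averaged F effect", {
  pos <- 0
  for (s in 1:15) {
    dat <- simulate_behavior(behavior_sim_config(novelty_boost = 0.7,
                                                 seed = 400 + s))
    sel <- suppressWarnings(suppressMessages(fit_candidate_set(dat, "sperm")))
    av <- model_average(sel)
    fb <- av$estimate[av$term == "F"]
    if (length(fb) == 1 && fb > 0) pos <- pos + 1
  }
  expect_gte(pos, 13)
})
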