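test_that("the per-male depletion line and prediction follow the closed form", {
  rec <- male_records("m1", expm1(c(1.5, 1.0, 0.5)), f2_value = 9)
  res <- fit_depletion_predict(rec, "sperm")
  expect_equal(res$fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(res$fit$intercept, 2.0, tolerance = 1e-12)
  expect_equal(res$predicted, 0) # exp(0) - 1 at exposure 4
  expect_equal(res$observed, 9)
})

test_that("negative back-transformed predictions are clamped to zero", {
  rec <- male_records("m2", expm1(c(1.0, 0.4)), f2_value = 5)
  res <- fit_depletion_predict(rec, "sperm")
  # two-point line predicts log1p = -0.2 at exposure 3
  expect_equal(res$fit$slope, -0.6, tolerance = 1e-12)
  expect_equal(res$predicted, 0)
})

test_that("an all-zero male gives a flat line at zero", {
  rec <- male_records("m3", c(NA, NA, NA), f2_value = 4)
  res <- fit_depletion_predict(rec, "sperm")
  expect_equal(res$fit$slope, 0)
  expect_equal(res$predicted, 0)
})

test_that("insufficient records raise informative errors", {
  one_f1 <- male_records("m4", 10, f2_value = 3)
  expect_error(fit_depletion_predict(one_f1, "sperm"), "fewer than 2")
  no_f2 <- male_records("m5", c(10, 5), f2_value = 3)
  no_f2 <- no_f2[no_f2$female_order == 1L, ]
  expect_error(fit_depletion_predict(no_f2, "sperm"), "female-2")
})

test_that("a strong novelty boost drives V to its maximum", {
  dat <- simulate_behavior(behavior_sim_config(
    novelty_boost = 3, noise_sd = 0.05, ejaculation_logit_intercept = 50,
    ejaculation_logit_slope = 0, seed = 41))
  co <- coolidge_analysis(dat, "sperm")
  expect_equal(co$V, co$n_used * (co$n_used + 1) / 2)
  expect_lt(co$p_greater, 0.01)
})

test_that("V is invariant to common positive rescaling of both columns", {
  dat <- simulate_behavior(behavior_sim_config(seed = 42))
  co <- coolidge_analysis(dat, "sperm")
  scaled <- signed_rank_test(co$pairs$observed * 3.7, co$pairs$predicted * 3.7)
  expect_equal(scaled$V, co$V)
  expect_equal(scaled$p_two_sided, co$p_two_sided)
})

test_that("the analysis repeats identically for the SF responses", {
  dat <- simulate_behavior(behavior_sim_config(seed = 43))
  for (resp in c("sperm", "volume", "protein")) {
    co <- coolidge_analysis(dat, resp)
    expect_true(co$V >= 0 && co$V <= co$n_used * (co$n_used + 1) / 2)
    # dual route: the same pairs through stats::wilcox.test
    ref <- suppressWarnings(stats::wilcox.test(
      co$pairs$observed, co$pairs$predicted, paired = TRUE))
    expect_equal(unname(ref$statistic), co$V)
  }
})

test_that("rejection rate increases with the novelty boost on a fixed seed set", {
  rate <- vapply(c(0, 1.2), function(boost) {
    rej <- 0
    for (s in 1:40) {
      dat <- simulate_behavior(behavior_sim_config(
        novelty_boost = boost, ejaculation_logit_intercept = 30,
        ejaculation_logit_slope = 0, seed = 500 + s))
      co <- coolidge_analysis(dat, "sperm")
      if (co$p_greater < 0.05) rej <- rej + 1
    }
    rej / 40
  }, numeric(1))
  expect_gte(rate[2], rate[1])
  expect_gt(rate[2], 0.5)
})

test_that("status ratios compare dominant and subdominant investment", {
  dom1 <- male_records("d1", c(10, 5), 10, status = "dominant")
  dom2 <- male_records("d2", c(10, 5), 9, status = "dominant")
  sub1 <- male_records("s1", c(10, 6), 3, status = "subdominant")
  sub2 <- male_records("s2", c(10, 5), 3, status = "subdominant")
  dat <- rbind(dom1, dom2, sub1, sub2)
  res <- status_ratio_compare(dat, "sperm")
  expect_equal(res$test$p_greater, 1 / 6) # complete separation, 2 vs 2
  # identical ratios give p = 1 under midranks
  same <- rbind(male_records("d1", c(8, 4), 4, "dominant"),
                male_records("d2", c(8, 4), 4, "dominant"),
                male_records("s1", c(8, 4), 4, "subdominant"),
                male_records("s2", c(8, 4), 4, "subdominant"))
  expect_equal(status_ratio_compare(same, "sperm")$test$p_two_sided, 1)
  # undefined ratios skip the male, empty group errors
  onlydom <- rbind(dom1, dom2)
  expect_error(status_ratio_compare(onlydom, "sperm"), "empty")
})

test_that("males without a usable line are skipped and reported", {
  good <- male_records("g1", c(9, 4, 2), 6)
  good2 <- male_records("g2", c(8, 5, 2), 7)
  short <- male_records("s9", 7, 3)
  dat <- rbind(good, good2, short)
  co <- coolidge_analysis(dat, "sperm")
  expect_equal(nrow(co$pairs), 2L)
  expect_equal(co$skipped, "s9")
})
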