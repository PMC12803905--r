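test_that("window aggregation counts and rates follow the two-block rule", {
  cfg <- generator_config(n_subjects = 3, seed = 41)
  trials <- cohort_trial_records(simulate_cohort(cfg))
  agg <- aggregate_windows(trials)
  expect_equal(sort(unique(agg$window)), 1:15)
  expect_equal(nrow(agg), 3 * 15)
  expect_true(all(agg$n_trials == 6))
  expect_true(all(agg$accuracy >= 0 & agg$accuracy <= 1))
  # hand-built window: 2 of 6 trials are EIt-2nd
  tr <- data.frame(subject = "A", block = rep(1:2, each = 3), trial = rep(1:3, 2),
                   cue_time_s = 1:6, press_time_s = 2:7,
                   rt_s = c(1, 2, 3, 4, 5, 6),
                   correct = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
                   is_match = TRUE,
                   condition = c("EIt", "EXH", "IEt", "EXH", "EIt", "INH"),
                   not_flag = FALSE,
                   eit_half = c("2nd", "none", "none", "none", "2nd", "none"),
                   iet_half = c("none", "none", "1st", "none", "none", "none"),
                   delta_rri = c(0.1, NA, 0.2, 0, -0.1, 0.3),
                   delta_rri_b = 0,
                   delta_rri_bin = factor("low_pos",
                     levels = c("high_neg", "low_neg", "low_pos", "high_pos")),
                   rt_robust_z = 0)
  a1 <- aggregate_windows(tr)
  expect_equal(nrow(a1), 1)
  expect_equal(a1$eit2nd_rate, 2 / 6)
  expect_equal(a1$mean_rt, mean(c(1, 2, 4, 5, 6)))
  expect_equal(a1$accuracy, 5 / 6)
  expect_equal(a1$mean_drri, mean(c(0.1, 0.2, 0, -0.1, 0.3)))
})

test_that("window aggregation matches the brute-force oracle", {
  cfg <- generator_config(n_subjects = 4, seed = 43)
  trials <- cohort_trial_records(simulate_cohort(cfg))
  got <- aggregate_windows(trials)
  want <- oracle_aggregate(trials)
  for (col in c("mean_rt", "accuracy", "eit2nd_rate", "iet2nd_rate", "mean_drri"))
    expect_equal(got[[col]], want[[col]], tolerance = 1e-12, label = col)
})

test_that("normalization and centering satisfy their contracts", {
  cfg <- generator_config(n_subjects = 5, seed = 47)
  agg <- aggregate_windows(cohort_trial_records(simulate_cohort(cfg)))
  nc <- normalize_and_center(agg)
  for (col in c("rt_n", "eit2nd_n", "iet2nd_n", "acc_n", "drri_n")) {
    expect_equal(mean(nc[[col]]), 0, tolerance = 1e-12)
    expect_equal(stats::sd(nc[[col]]), 1, tolerance = 1e-12)
  }
  # per-subject predictor means are exactly zero
  for (col in c("eit2nd_c", "iet2nd_c", "acc_c", "drri_c"))
    expect_true(all(abs(tapply(nc[[col]], nc$subject, mean)) < 1e-12))
  # the response is grand-normalized but not subject-centered
  expect_gt(max(abs(tapply(nc$rt_n, nc$subject, mean))), 1e-6)
  # an exactly standard-normal column passes through unchanged
  agg2 <- agg
  agg2$mean_rt <- as.numeric(scale(stats::rnorm(nrow(agg2))))
  nc2 <- normalize_and_center(agg2)
  expect_equal(nc2$rt_n, agg2$mean_rt, tolerance = 1e-9)
  # constant column is a named error
  agg3 <- agg
  agg3$accuracy <- 1
  expect_error(normalize_and_center(agg3), "accuracy")
})

test_that("random-intercept fit degenerates to OLS without subject effects", {
  d <- simulate_model_cohort(beta = c(0.3, 0.1, -0.2), sigma_subject = 0,
                             seed = 51)
  m <- suppressMessages(fit_random_intercept(d, model = 1))
  ols <- stats::lm(rt_n ~ eit2nd_c + drri_c + acc_c, data = d)
  expect_equal(unname(coef(m)), unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("model machinery is symmetric in the transition-rate predictor", {
  d <- simulate_model_cohort(seed = 53)
  d$iet2nd_c <- -99  # poison: model 1 must not touch it
  m1 <- fit_random_intercept(d, model = 1)
  d2 <- d
  d2$iet2nd_c <- d$eit2nd_c
  m2 <- fit_random_intercept(d2, model = 2)
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate,
               tolerance = 1e-10)
  expect_error(fit_random_intercept(d[, c("subject", "rt_n")], 1), "missing")
})

test_that("fitted decomposition reproduces the observed response", {
  d <- simulate_model_cohort(seed = 57)
  m <- fit_random_intercept(d, model = 1)
  co <- coef(m)
  fixed <- co["(Intercept)"] + co["eit2nd_c"] * d$eit2nd_c +
    co["drri_c"] * d$drri_c + co["acc_c"] * d$acc_c
  re <- ranef_cr_mlm(m)[d$subject]
  expect_equal(unname(fixed + re + residuals(m)), d$rt_n, tolerance = 1e-8)
  expect_equal(unname(fixed + re), unname(fitted(m)), tolerance = 1e-8)
  expect_gt(m$var_intercept, 0)
  expect_s3_class(m, "cr_mlm")
  expect_output(print(m), "Random-intercept")
})

test_that("fit is invariant to subject relabeling and row order", {
  d <- simulate_model_cohort(seed = 59)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  d2$subject <- paste0("X", d2$subject)
  m1 <- fit_random_intercept(d, 1)
  m2 <- fit_random_intercept(d2, 1)
  expect_equal(m1$coefficients$estimate, m2$coefficients$estimate,
               tolerance = 1e-8)
})

test_that("coefficients recover injected truth in a short recovery run", {
  truth <- c(0.21, 0.145, -0.118)
  set.seed(63)
  hits <- replicate(8, {
    d <- simulate_model_cohort(beta = truth,
                               seed = sample.int(1e6, 1))
    m <- fit_random_intercept(d, 1)
    co <- m$coefficients[m$coefficients$term != "(Intercept)", ]
    all(abs(co$estimate - truth) <= 2 * co$se)
  })
  expect_gte(mean(hits), 0.5)  # joint coverage; per-coefficient ~95 %
})

test_that("shrinking subject heterogeneity shrinks the intercept variance", {
  d_big <- simulate_model_cohort(sigma_subject = 1, seed = 61)
  d_none <- simulate_model_cohort(sigma_subject = 0.001, seed = 61)
  m_big <- fit_random_intercept(d_big, 1)
  m_none <- suppressMessages(fit_random_intercept(d_none, 1))
  expect_gt(m_big$var_intercept, 0.5)
  expect_lt(m_none$var_intercept, 0.05)
})
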