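test_that("trial classification follows the condition definitions", {
  ph <- phase_series(ei = c(0, 4, 8), ie = c(1.6, 5.6, 9.6))
  # wholly inside an exhalation interval
  r <- classify_trial(2.0, 3.0, ph)
  expect_equal(r$condition, "EXH")
  expect_equal(r$eit_half, "none")
  # one EI transition in the second half
  ph2 <- phase_series(ei = c(9, 10.7, 14), ie = c(9.5, 12, 15))
  r2 <- classify_trial(10.0, 11.0, ph2)
  expect_equal(r2$condition, "EIt")
  expect_equal(r2$eit_half, "2nd")
  # transition exactly at the midpoint goes to the second half
  ph3 <- phase_series(ei = c(0, 10.5, 20), ie = c(5, 15, 25))
  r3 <- classify_trial(10.0, 11.0, ph3)
  expect_equal(r3$eit_half, "2nd")
  # both types inside -> DOUBLE
  r4 <- classify_trial(9.4, 11.0, ph2)
  expect_equal(r4$condition, "DOUBLE")
  # outside coverage -> NA
  expect_true(is.na(classify_trial(-5, -4, ph)$condition))
})

test_that("classification agrees with the brute-force oracle on random trials", {
  set.seed(11)
  for (rep in 1:40) {
    ph <- random_phase_series(30)
    lo <- min(ph$ei, ph$ie); hi <- max(ph$ei, ph$ie)
    cue <- stats::runif(50, lo, hi - 4)
    press <- cue + stats::runif(50, 0.2, 3.5)
    for (i in 1:50) {
      got <- classify_trial(cue[i], press[i], ph)
      want <- oracle_classify(cue[i], press[i], ph$ei, ph$ie)
      expect_identical(got, want)
    }
  }
})

test_that("RRI velocity matches direct subtraction and the generator truth", {
  rri <- build_rri_series(c(0, 0.8, 1.8, 2.6))
  # same interval -> 0
  expect_equal(compute_delta_rri(rri, 0.3, 0.5), 0)
  # press RRI 1.0, cue RRI 0.8 -> +0.2
  expect_equal(compute_delta_rri(rri, 0.5, 1.2), 0.2, tolerance = 1e-12)
  # uncovered events are missing
  expect_true(is.na(compute_delta_rri(rri, 0.5, 3)))
  cfg <- generator_config(seed = 13)
  s <- simulate_subject(cfg, 55)
  got <- compute_delta_rri(s$rri, s$events$cue_time_s, s$events$press_time_s)
  expect_equal(got, s$truth$delta_rri, tolerance = 1e-12)
  want <- vapply(seq_len(20), function(i)
    oracle_delta_rri(s$rri$r_times, s$events$cue_time_s[i],
                     s$events$press_time_s[i]), numeric(1))
  expect_equal(got[1:20], want, tolerance = 1e-12)
})

test_that("RRI velocity is antisymmetric in its two events", {
  set.seed(5)
  r <- cumsum(stats::runif(200, 0.6, 1.2))
  rri <- build_rri_series(r)
  a <- stats::runif(100, r[2], r[199])
  b <- stats::runif(100, r[2], r[199])
  expect_equal(compute_delta_rri(rri, a, b), -compute_delta_rri(rri, b, a))
})

test_that("baseline-referenced RRI velocity uses the last interval before cue", {
  rri <- build_rri_series(c(0, 0.8, 1.75, 2.6))
  # stationary RRIs give zero
  st <- build_rri_series(seq(0, 8.5, by = 0.85))
  expect_equal(compute_delta_rri_b(st, 3, 4), 0)
  # prior interval 0.8 (ends at 0.8 <= cue), press interval 0.95
  expect_equal(compute_delta_rri_b(rri, 0.9, 1.2), 0.15, tolerance = 1e-12)
  expect_true(is.na(compute_delta_rri_b(rri, 0.5, 1.2)))  # no complete prior RRI
  set.seed(7)
  r <- cumsum(stats::runif(100, 0.5, 1.3))
  rr <- build_rri_series(r)
  cue <- stats::runif(30, r[3], r[60]); press <- cue + stats::runif(30, 0.1, 5)
  got <- compute_delta_rri_b(rr, cue, press)
  want <- vapply(seq_len(30), function(i)
    oracle_delta_rri_b(r, cue[i], press[i]), numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("RRI-velocity binning applies the per-sign maximum-fraction rule", {
  b <- bin_delta_rri(c(0.2, 0.08, -0.1))
  expect_equal(as.character(b), c("high_pos", "low_pos", "high_neg"))
  # a lone positive value is its own maximum
  expect_equal(as.character(bin_delta_rri(c(0.03))), "high_pos")
  # boundary value goes to the high bin
  expect_equal(as.character(bin_delta_rri(c(0.1, 0.05)))[2], "high_pos")
  expect_equal(as.character(bin_delta_rri(c(0.1, 0.0499)))[2], "low_pos")
  # zero goes to low_pos
  expect_equal(as.character(bin_delta_rri(c(0.1, 0)))[2], "low_pos")
  expect_warning(bz <- bin_delta_rri(c(0, 0)), "zero")
  expect_equal(as.character(bz), c("low_pos", "low_pos"))
})

test_that("binning is scale invariant and matches the brute-force oracle", {
  set.seed(17)
  for (rep in 1:50) {
    v <- round(stats::rnorm(40, 0, 0.05), 4)
    expect_equal(as.character(bin_delta_rri(v)), oracle_bin(v))
    expect_identical(bin_delta_rri(v), bin_delta_rri(3.7 * v))
  }
})

test_that("robust z has exact median 0 and IQR 1 over correct trials", {
  z <- robust_z_rt(c(1, 2, 3, 4, 5), rep(TRUE, 5))
  expect_equal(z$z, c(-1, -0.5, 0, 0.5, 1))
  expect_equal(z$median_s, 3)
  expect_equal(z$iqr_s, 2)
  set.seed(23)
  rt <- stats::rlnorm(90, log(1.1), 0.25)
  corr <- stats::runif(90) < 0.9
  z2 <- robust_z_rt(rt, corr)
  expect_equal(stats::median(z2$z[corr]), 0)
  expect_equal(stats::IQR(z2$z[corr]), 1)
  # brute-force recomputation from sorted values
  expect_equal(z2$z, (rt - stats::median(rt[corr])) / stats::IQR(rt[corr]))
  # affine invariance: a*RT + b leaves z unchanged (a > 0)
  z3 <- robust_z_rt(2.5 * rt + 0.3, corr)
  expect_equal(z3$z, z2$z, tolerance = 1e-12)
  expect_warning(zf <- robust_z_rt(c(1, 1, 1, 1, 2), c(T, T, T, T, F)), "distinct")
  expect_false(zf$ok)
})

test_that("condition means average per subject and pool NOt correctly", {
  tr <- data.frame(subject = "A", block = 1, trial = 1:6,
                   cue_time_s = 1:6, press_time_s = 2:7, rt_s = 1,
                   correct = TRUE, is_match = TRUE,
                   condition = c("INH", "EXH", "IEt", "EIt", "EXH", "EIt"),
                   not_flag = c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE),
                   eit_half = c("none", "none", "none", "1st", "none", "2nd"),
                   iet_half = c("none", "none", "2nd", "none", "none", "none"),
                   delta_rri = 0.01, delta_rri_b = 0.01,
                   delta_rri_bin = factor("low_pos",
                     levels = c("high_neg", "low_neg", "low_pos", "high_pos")),
                   rt_robust_z = c(2, 2, 5, 7, 2, 7))
  cm <- condition_means(tr, "phase")
  expect_equal(cm$mean_value[cm$condition == "NOt"], 2)
  expect_equal(cm$mean_value[cm$condition == "EIt"], 7)
  expect_equal(cm$accuracy[cm$condition == "NOt"], 1)
  cmh <- condition_means(tr, "half")
  expect_setequal(cmh$condition, c("EIt-1st", "EIt-2nd", "IEt-2nd"))
})

test_that("DOUBLE sub-classification is the cross-product of half labels", {
  cfg <- generator_config(n_subjects = 6, seed = 19)
  trials <- cohort_trial_records(simulate_cohort(cfg))
  dd <- trials[trials$condition == "DOUBLE", ]
  expect_true(all(dd$eit_half != "none" & dd$iet_half != "none"))
  cross <- table(paste(dd$iet_half, dd$eit_half))
  expect_equal(sum(cross), nrow(dd))
  # eit_half is none exactly outside EIt/DOUBLE
  expect_true(all((trials$eit_half != "none") ==
                    (trials$condition %in% c("EIt", "DOUBLE"))))
})
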