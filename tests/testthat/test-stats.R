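test_that("sphericity screening matches the multivariate reference", {
  set.seed(31)
  mat <- matrix(stats::rnorm(36 * 4), 36, 4,
                dimnames = list(NULL, paste0("c", 1:4)))
  mat[, 3] <- mat[, 3] * 2 + mat[, 1]          # break sphericity
  scr <- normality_and_sphericity(mat)
  # cross-check the F and the Greenhouse-Geisser-corrected p against the
  # multivariate reference (anova.mlm with the sphericity test)
  fit <- stats::lm(mat ~ 1)
  ref <- stats::anova(fit, X = ~1, test = "Spherical")
  mine <- rm_anova_gg(mat, gg = "always")
  expect_equal(mine$F, ref$F[1], tolerance = 1e-10)
  expect_equal(mine$p, ref$`G-G Pr`[1], tolerance = 1e-10)
  expect_lt(scr$mauchly$p, 0.05)
  expect_false(scr$spherical)
  # compound-symmetric data has epsilon near 1 (sample epsilon is biased
  # down, hence the loose bound)
  set.seed(32)
  sub <- stats::rnorm(36)
  cs <- sapply(1:4, function(j) sub + stats::rnorm(36, sd = 1))
  scr2 <- normality_and_sphericity(cs)
  expect_gt(scr2$gg_epsilon, 0.8)
  expect_true(scr2$spherical)
})

test_that("Shapiro-Wilk screening is calibrated and detects heavy tails", {
  set.seed(33)
  rej <- mean(replicate(1000, stats::shapiro.test(stats::rnorm(36))$p.value < 0.05))
  expect_gt(rej, 0.03); expect_lt(rej, 0.07)
  rej_ln <- mean(replicate(200, stats::shapiro.test(stats::rlnorm(36))$p.value < 0.05))
  expect_gt(rej_ln, 0.5)
})

test_that("Friedman branch matches a rank-based oracle and handles ties", {
  cst <- matrix(rep(c(1, 2, 3), each = 8), 8, 3)
  cst <- cst * 0 + 5
  r <- friedman_with_wilcoxon_posthoc(cst)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  set.seed(34)
  for (i in 1:20) {
    m <- matrix(stats::rnorm(24), 8, 3, dimnames = list(NULL, c("a", "b", "c")))
    r2 <- friedman_with_wilcoxon_posthoc(m)
    expect_equal(r2$statistic, oracle_friedman(m), tolerance = 1e-10)
    expect_equal(r2$df, 2)
  }
  # significant omnibus triggers k(k-1)/2 Bonferroni-corrected post hocs
  m3 <- matrix(stats::rnorm(36 * 3), 36, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  m3[, 2] <- m3[, 2] + 2
  r3 <- friedman_with_wilcoxon_posthoc(m3)
  expect_lt(r3$p, 0.01)
  expect_equal(nrow(r3$posthoc), 3)
  expect_true(all(r3$posthoc$p_bonf <= 1))
  expect_true(all(r3$posthoc$p_bonf >= r3$posthoc$p_raw))
})

test_that("Friedman null rejection rate is calibrated", {
  set.seed(35)
  rej <- mean(replicate(1000, {
    stats::friedman.test(matrix(stats::rnorm(36 * 3), 36, 3))$p.value < 0.05
  }))
  expect_gte(rej, 0.03); expect_lte(rej, 0.07)
})

test_that("repeated-measures ANOVA reduces correctly in known cases", {
  # identical columns -> F = 0
  m0 <- matrix(rep(stats::rnorm(10), 3), 10, 3)
  expect_equal(rm_anova_gg(m0)$F, 0)
  # two conditions: F equals the squared paired-t statistic
  set.seed(36)
  m2 <- matrix(stats::rnorm(24), 12, 2)
  r2 <- rm_anova_gg(m2, gg = "never")
  tt <- stats::t.test(m2[, 1], m2[, 2], paired = TRUE)
  expect_equal(r2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
  expect_error(rm_anova_gg(matrix(1:6, 2, 3)), "fewer subjects")
})

test_that("Greenhouse-Geisser-corrected RM-ANOVA keeps type-I error in check", {
  set.seed(37)
  rej <- mean(replicate(400, {
    m <- matrix(stats::rnorm(12 * 4), 12, 4)
    rm_anova_gg(m, gg = "always")$p < 0.05
  }))
  expect_lte(rej, 0.07)
  expect_gte(rej, 0.01)
})

test_that("two-way trial ANOVA matches the balanced closed form", {
  # all-equal responses: both F = 0
  d0 <- expand.grid(A = c("1st", "2nd"), B = c("1st", "2nd"), r = 1:3)
  r0 <- two_way_anova_trials(rep(1, 12), d0$A, d0$B)
  expect_equal(r0$anova$F[1:2], c(0, 0))
  # additive shift d on factor A in a balanced 2x2 with within-cell
  # pattern {0, 1}: F_A = N d^2 / (4 s^2) with s^2 = 0.5
  d <- 2
  z <- c(0, 1, 0, 1, 0 + d, 1 + d, 0 + d, 1 + d)
  A <- rep(c("1st", "2nd"), each = 4)
  B <- rep(c("1st", "1st", "2nd", "2nd"), 2)
  r1 <- two_way_anova_trials(z, A, B)
  expect_equal(r1$anova$F[r1$anova$effect == "iet_half"],
               8 * d^2 / (4 * 0.5), tolerance = 1e-10)
  expect_error(two_way_anova_trials(c(1, 2), c("1st", "1st"), c("1st", "2nd")),
               "empty")
})

test_that("two-way trial ANOVA per-factor type-I error is near nominal", {
  set.seed(38)
  rej <- rowMeans(replicate(400, {
    z <- stats::rnorm(40)
    A <- sample(rep(c("1st", "2nd"), 10 * 2))
    B <- sample(rep(c("1st", "2nd"), 10 * 2))
    p <- two_way_anova_trials(z, A, B)$anova$p[1:2]
    p < 0.05
  }))
  expect_true(all(rej >= 0.02 & rej <= 0.09))
})

test_that("Kruskal-Wallis first-trial branch returns calibrated results", {
  set.seed(39)
  v <- c(stats::rnorm(30), stats::rnorm(30) + 2)
  g <- rep(c("a", "b"), each = 30)
  r <- kruskal_with_ranksum_posthoc(v, g)
  expect_lt(r$p, 0.001)
  expect_equal(r$df, 1)
  # matches base kruskal.test directly
  expect_equal(r$statistic, unname(stats::kruskal.test(v, factor(g))$statistic))
})

test_that("frequency tables match hand-counted fractions", {
  lv <- c("high_neg", "low_neg", "low_pos", "high_pos")
  tr <- data.frame(
    subject = "A", block = 1, trial = 1:6, cue_time_s = 1, press_time_s = 2,
    rt_s = 1, correct = TRUE, is_match = TRUE,
    condition = c("IEt", "IEt", "EIt", "EIt", "IEt", "EIt"),
    not_flag = FALSE,
    eit_half = c("none", "none", "2nd", "1st", "none", "2nd"),
    iet_half = c("1st", "1st", "none", "none", "2nd", "none"),
    delta_rri = 1, delta_rri_b = 1,
    delta_rri_bin = factor(c("high_pos", "low_pos", "high_neg", "high_pos",
                             "high_pos", "low_neg"), levels = lv),
    rt_robust_z = 0)
  fr <- suppressWarnings(frequency_analysis(tr))
  a <- fr$high_pos_by_half
  expect_equal(a$rate[a$condition == "IEt-1st"], 1 / 2)  # 1 of 2 IEt-1st trials
  expect_equal(a$rate[a$condition == "EIt-2nd"], 0)
  b <- fr$eit2nd_by_bin
  # high_pos trials are 1, 4, 5 with eit_half none/1st/none
  expect_equal(b$rate[b$condition == "high_pos"], 0)
  expect_equal(b$rate[b$condition == "high_neg"], 1)  # trial 3, eit_half 2nd
})

test_that("group tests are invariant to subject ordering", {
  set.seed(40)
  m <- matrix(stats::rnorm(36 * 3), 36, 3, dimnames = list(NULL, c("a", "b", "c")))
  p <- sample(36)
  expect_equal(friedman_with_wilcoxon_posthoc(m)$statistic,
               friedman_with_wilcoxon_posthoc(m[p, ])$statistic)
  expect_equal(rm_anova_gg(m)$F, rm_anova_gg(m[p, ])$F)
})
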