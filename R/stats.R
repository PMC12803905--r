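## Group-level statistical battery: normality/sphericity screening,
## Friedman + Wilcoxon post hocs, repeated-measures ANOVA with
## Greenhouse-Geisser correction, two-way ANOVA on trial-level values,
## Kruskal-Wallis for first-trial restrictions, and the transition-by-RRI
## velocity frequency analyses.

#' Greenhouse-Geisser epsilon of a subjects x conditions matrix
#'
#' Computed from the double-centered covariance of the repeated measures;
#' equals 1 under perfect sphericity and has lower bound 1/(k-1).
#'
#' @param mat numeric matrix, subjects in rows, conditions in columns.
#' @return epsilon in [1/(k-1), 1].
#' @export
gg_epsilon <- function(mat) {
  k <- ncol(mat)
  S <- stats::cov(mat)
  C <- diag(k) - 1 / k
  Sc <- C %*% S %*% C
  sum(diag(Sc))^2 / ((k - 1) * sum(Sc^2))
}

#' Normality and sphericity screening
#'
#' Shapiro-Wilk per condition and Mauchly's test over the repeated factor;
#' the flags drive the downstream branch (parametric repeated-measures ANOVA
#' versus Friedman; Greenhouse-Geisser correction when sphericity is
#' violated).
#'
#' @param mat numeric matrix, subjects x conditions (>= 3 rows).
#' @param alpha screening level.
#' @return list with \code{shapiro} (data.frame condition/W/p),
#'   \code{mauchly} (statistic, p, or NULL when k < 3 or n <= k),
#'   \code{gg_epsilon}, and flags \code{normal}, \code{spherical}.
#' @export
normality_and_sphericity <- function(mat, alpha = 0.05) {
  stopifnot(nrow(mat) >= 3)
  sw <- lapply(seq_len(ncol(mat)), function(j) {
    x <- mat[, j]
    if (length(unique(x)) < 3) return(c(W = NA_real_, p = NA_real_))
    r <- stats::shapiro.test(x)
    c(W = unname(r$statistic), p = r$p.value)
  })
  shapiro <- data.frame(condition = colnames(mat) %||% seq_len(ncol(mat)),
                        W = vapply(sw, `[`, numeric(1), 1),
                        p = vapply(sw, `[`, numeric(1), 2))
  mau <- NULL
  if (ncol(mat) >= 3 && nrow(mat) > ncol(mat)) {
    mt <- tryCatch({
      fit <- stats::lm(mat ~ 1)
      suppressWarnings(stats::mauchly.test(fit, X = ~1))
    }, error = function(e) NULL)
    if (!is.null(mt) && is.finite(mt$p.value))
      mau <- list(statistic = unname(mt$statistic), p = mt$p.value)
  }
  list(shapiro = shapiro, mauchly = mau, gg_epsilon = gg_epsilon(mat),
       normal = all(shapiro$p > alpha, na.rm = TRUE),
       spherical = is.null(mau) || mau$p > alpha)
}

bonf <- function(p, m) pmin(1, p * m)

pairwise_labels <- function(cn) {
  cmb <- utils::combn(cn, 2)
  paste(cmb[1, ], cmb[2, ], sep = " vs ")
}

#' Friedman test with Wilcoxon signed-rank post hocs
#'
#' Omnibus Friedman chi-square over k >= 3 repeated conditions; when
#' significant, all pairwise Wilcoxon signed-rank tests with Bonferroni
#' factor k(k-1)/2. With k = 2 a single Wilcoxon signed-rank test is used
#' directly.
#'
#' @param mat numeric matrix, subjects x conditions, complete rows only.
#' @param alpha omnibus level gating the post hocs.
#' @return list: \code{test} ("friedman" or "wilcoxon"), \code{statistic},
#'   \code{df}, \code{p}, and \code{posthoc} (data.frame comparison/V/p_raw/
#'   p_bonf, NULL when not run).
#' @export
friedman_with_wilcoxon_posthoc <- function(mat, alpha = 0.05) {
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  k <- ncol(mat)
  if (k < 2) stop("friedman_with_wilcoxon_posthoc: need >= 2 conditions")
  if (k == 2) {
    w <- stats::wilcox.test(mat[, 1], mat[, 2], paired = TRUE, exact = FALSE)
    return(list(test = "wilcoxon", statistic = unname(w$statistic), df = NA,
                p = w$p.value, posthoc = NULL))
  }
  fr <- stats::friedman.test(mat)
  stat <- unname(fr$statistic)
  pval <- fr$p.value
  if (!is.finite(stat)) {  # fully tied rows (e.g. identical columns)
    stat <- 0
    pval <- 1
  }
  post <- NULL
  if (is.finite(pval) && pval < alpha) {
    cmb <- utils::combn(k, 2)
    m <- ncol(cmb)
    praw <- vstat <- numeric(m)
    for (i in seq_len(m)) {
      w <- stats::wilcox.test(mat[, cmb[1, i]], mat[, cmb[2, i]],
                              paired = TRUE, exact = FALSE)
      praw[i] <- w$p.value
      vstat[i] <- unname(w$statistic)
    }
    post <- data.frame(comparison = pairwise_labels(colnames(mat) %||% seq_len(k)),
                       V = vstat, p_raw = praw, p_bonf = bonf(praw, m))
  }
  list(test = "friedman", statistic = stat,
       df = unname(fr$parameter), p = pval, posthoc = post)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Within-subject F over k repeated conditions; when Mauchly's test rejects
#' sphericity (or \code{gg = "always"}) the Greenhouse-Geisser epsilon
#' deflates both degrees of freedom. Post hoc paired t tests with Bonferroni
#' correction are run when the omnibus is significant.
#'
#' @param mat numeric matrix, subjects x conditions.
#' @param alpha level for the sphericity gate and the post hoc gate.
#' @param gg "auto" (apply when Mauchly rejects), "always", or "never".
#' @return list: F, df (length 2, possibly epsilon-corrected), p, epsilon,
#'   gg_applied, mauchly_p, posthoc data.frame (or NULL).
#' @export
rm_anova_gg <- function(mat, alpha = 0.05, gg = c("auto", "always", "never")) {
  gg <- match.arg(gg)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  if (n < k) stop("rm_anova_gg: fewer subjects than conditions (rank deficient)")
  grand <- mean(mat)
  ss_cond <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- k * sum((rowMeans(mat) - grand)^2)
  ss_err <- sum((mat - grand)^2) - ss_cond - ss_subj
  df1 <- k - 1; df2 <- (n - 1) * (k - 1)
  Fv <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)
  mau_p <- NA_real_
  if (k >= 3 && n > k) {
    mau_p <- tryCatch(
      suppressWarnings(stats::mauchly.test(stats::lm(mat ~ 1), X = ~1)$p.value),
      error = function(e) NA_real_)
  }
  eps <- gg_epsilon(mat)
  apply_gg <- switch(gg, always = TRUE, never = FALSE,
                     auto = is.finite(mau_p) && mau_p < alpha)
  ddf1 <- if (apply_gg) eps * df1 else df1
  ddf2 <- if (apply_gg) eps * df2 else df2
  p <- stats::pf(Fv, ddf1, ddf2, lower.tail = FALSE)
  post <- NULL
  if (is.finite(p) && p < alpha && k >= 3) {
    cmb <- utils::combn(k, 2)
    m <- ncol(cmb)
    praw <- tstat <- numeric(m)
    for (i in seq_len(m)) {
      tt <- stats::t.test(mat[, cmb[1, i]], mat[, cmb[2, i]], paired = TRUE)
      praw[i] <- tt$p.value
      tstat[i] <- unname(tt$statistic)
    }
    post <- data.frame(comparison = pairwise_labels(colnames(mat) %||% seq_len(k)),
                       t = tstat, p_raw = praw, p_bonf = bonf(praw, m))
  }
  list(F = Fv, df = c(ddf1, ddf2), p = p, epsilon = eps, gg_applied = apply_gg,
       mauchly_p = mau_p, posthoc = post)
}

#' Two-way fixed-effects ANOVA on trial-level standardized RTs
#'
#' For DOUBLE-condition trials: a 2 x 2 design of the IE-transition half by
#' the EI-transition half, fitted at the trial level with interaction, plus
#' post hoc pooled-SD t tests over the four cells with Bonferroni correction.
#'
#' @param z trial-level robust-z RTs.
#' @param iet_half,eit_half factors/characters with values "1st"/"2nd".
#' @param alpha post hoc gate.
#' @return list with \code{anova} (data.frame effect/F/df1/df2/p) and
#'   \code{posthoc} (pairwise matrix of Bonferroni p-values, or NULL).
#' @export
two_way_anova_trials <- function(z, iet_half, eit_half, alpha = 0.05) {
  keep <- !is.na(z) & !is.na(iet_half) & !is.na(eit_half)
  d <- data.frame(z = z[keep], A = factor(iet_half[keep]),
                  B = factor(eit_half[keep]))
  if (nlevels(d$A) < 2 || nlevels(d$B) < 2 || any(table(d$A, d$B) == 0))
    stop("two_way_anova_trials: empty design cell")
  if (sum((d$z - mean(d$z))^2) < 1e-12) {  # degenerate all-equal response
    tab <- data.frame(effect = c("iet_half", "eit_half", "interaction"),
                      F = 0, df1 = 1, df2 = nrow(d) - 4, p = 1)
    return(list(anova = tab, posthoc = NULL))
  }
  a <- stats::anova(stats::lm(z ~ A * B, data = d))
  df2 <- a["Residuals", "Df"]
  tab <- data.frame(effect = c("iet_half", "eit_half", "interaction"),
                    F = a$`F value`[1:3], df1 = a$Df[1:3], df2 = df2,
                    p = a$`Pr(>F)`[1:3])
  post <- NULL
  if (any(tab$p[1:2] < alpha, na.rm = TRUE)) {
    cell <- interaction(d$A, d$B, sep = "/")
    pt <- stats::pairwise.t.test(d$z, cell, pool.sd = TRUE,
                                 p.adjust.method = "bonferroni")
    post <- pt$p.value
  }
  list(anova = tab, posthoc = post)
}

#' Kruskal-Wallis with exact rank-sum post hocs (first-trial analyses)
#'
#' Trial-level analysis used when each subject contributes its first test
#' trial per block: Kruskal-Wallis omnibus over the condition groups, then
#' pairwise Wilcoxon rank-sum tests (exact where ties permit) with
#' Bonferroni correction.
#'
#' @param values trial-level values (e.g. robust-z RTs).
#' @param groups condition labels, same length.
#' @param alpha post hoc gate.
#' @return list: statistic (chi-square), df, p, posthoc matrix (or NULL).
#' @export
kruskal_with_ranksum_posthoc <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  kw <- stats::kruskal.test(values, groups)
  post <- NULL
  if (is.finite(kw$p.value) && kw$p.value < alpha) {
    pt <- suppressWarnings(stats::pairwise.wilcox.test(
      values, groups, p.adjust.method = "bonferroni"))
    post <- pt$p.value
  }
  list(statistic = unname(kw$statistic), df = unname(kw$parameter),
       p = kw$p.value, posthoc = post)
}

#' Transition-by-RRI-velocity frequency analyses
#'
#' Two per-subject frequency tables mirroring the temporal-mismatch
#' analysis: (a) within each half condition (IEt-1st, IEt-2nd, EIt-1st,
#' EIt-2nd), the fraction of trials whose RRI-velocity bin is high_pos;
#' (b) within each RRI-velocity bin, the fraction of trials whose
#' EI-transition half is "2nd". Each table is analyzed by
#' \code{\link{rm_anova_gg}} over subjects with complete cells.
#'
#' @param trials trial-record data.frame (see
#'   \code{\link{build_trial_records}}).
#' @return list with \code{high_pos_by_half} and \code{eit2nd_by_bin}
#'   (long data.frames subject/condition/rate/n) and the matching
#'   \code{test_high_pos}, \code{test_eit2nd} results.
#' @export
frequency_analysis <- function(trials) {
  lab <- half_condition_label(trials)
  keep <- !is.na(lab) & !is.na(trials$delta_rri_bin)
  f_a <- stats::aggregate(
    list(rate = trials$delta_rri_bin[keep] == "high_pos"),
    by = list(subject = trials$subject[keep], condition = lab[keep]),
    FUN = mean)
  n_a <- stats::aggregate(list(n = rep(1, sum(keep))),
                          by = list(subject = trials$subject[keep],
                                    condition = lab[keep]), FUN = sum)
  f_a <- merge(f_a, n_a, by = c("subject", "condition"))

  keep_b <- !is.na(trials$delta_rri_bin)
  f_b <- stats::aggregate(
    list(rate = trials$eit_half[keep_b] == "2nd"),
    by = list(subject = trials$subject[keep_b],
              condition = as.character(trials$delta_rri_bin[keep_b])),
    FUN = mean)
  n_b <- stats::aggregate(list(n = rep(1, sum(keep_b))),
                          by = list(subject = trials$subject[keep_b],
                                    condition = as.character(trials$delta_rri_bin[keep_b])),
                          FUN = sum)
  f_b <- merge(f_b, n_b, by = c("subject", "condition"))

  mat_a <- condition_matrix(f_a, value = "rate")
  mat_b <- condition_matrix(f_b, value = "rate")
  list(high_pos_by_half = f_a, eit2nd_by_bin = f_b,
       test_high_pos = try_test(rm_anova_gg(mat_a)),
       test_eit2nd = try_test(rm_anova_gg(mat_b)))
}

#' Run the full group-level statistical battery
#'
#' Reproduces the structure of the group analyses: phase-condition accuracy
#' and RT (NOt/IEt/EIt), half-condition RT (the four transition-half
#' conditions, with a first-trial Kruskal-Wallis restriction), the 2x2
#' two-way ANOVA within DOUBLE trials, RRI-velocity-bin RT (with first-trial
#' restriction), and the two frequency analyses. For each repeated-measures
#' matrix the parametric/nonparametric branch is chosen by Shapiro-Wilk
#' screening at \code{alpha}.
#'
#' @param trials trial-record data.frame for a cohort.
#' @param alpha screening and gating level.
#' @return nested list of results (one entry per analysis), each carrying
#'   the screening outcome and the test chosen.
#' @export
run_stats_battery <- function(trials, alpha = 0.05) {
  branch <- function(mat) {
    if (nrow(mat) < 4)
      return(list(skipped = sprintf(
        "only %d complete subject(s); repeated-measures test not run", nrow(mat))))
    scr <- normality_and_sphericity(mat, alpha)
    res <- if (scr$normal) rm_anova_gg(mat, alpha) else
      friedman_with_wilcoxon_posthoc(mat, alpha)
    list(screening = scr,
         test_used = if (scr$normal) "rm_anova_gg" else "friedman",
         result = res)
  }
  out <- list()
  cm_phase <- condition_means(trials, "phase")
  out$phase_rt <- try_test(branch(condition_matrix(cm_phase)))
  out$phase_accuracy <- try_test(branch(condition_matrix(cm_phase, value = "accuracy")))
  cm_half <- condition_means(trials, "half")
  out$half_rt <- try_test(branch(condition_matrix(cm_half)))
  ft <- trials[trials$trial == 1, , drop = FALSE]
  lab_ft <- half_condition_label(ft)
  keep_ft <- !is.na(lab_ft) & ft$correct & !is.na(ft$rt_robust_z)
  out$half_rt_first_trial <- try_test(kruskal_with_ranksum_posthoc(
    ft$rt_robust_z[keep_ft], lab_ft[keep_ft], alpha))
  dd <- trials[trials$condition %in% "DOUBLE" & trials$correct &
                 !is.na(trials$rt_robust_z), , drop = FALSE]
  cells_ok <- nrow(dd) >= 8 &&
    all(c("1st", "2nd") %in% dd$iet_half) &&
    all(c("1st", "2nd") %in% dd$eit_half) &&
    all(table(dd$iet_half, dd$eit_half) > 0)
  out$double_anova <- if (cells_ok)
    two_way_anova_trials(dd$rt_robust_z, dd$iet_half, dd$eit_half, alpha)
  else list(skipped = "insufficient DOUBLE trials")
  cm_bin <- condition_means(trials, "bin")
  out$bin_rt <- try_test(branch(condition_matrix(cm_bin)))
  keep_fb <- ft$correct & !is.na(ft$rt_robust_z) & !is.na(ft$delta_rri_bin)
  out$bin_rt_first_trial <- try_test(kruskal_with_ranksum_posthoc(
    ft$rt_robust_z[keep_fb], as.character(ft$delta_rri_bin[keep_fb]), alpha))
  out$frequency <- try_test(frequency_analysis(trials))
  out
}

try_test <- function(expr) {
  tryCatch(expr, error = function(e) list(skipped = conditionMessage(e)))
}
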