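## Windowed aggregation, grand normalization / within-subject centering, and
## the random-intercept multilevel models of windowed RT on transition
## occurrence rates, RRI velocity and accuracy.

#' Aggregate trials into two-block windows
#'
#' Windows are consecutive pairs of task blocks (blocks 1-2, 3-4, ...; with
#' 30 blocks of 3 tests this gives 15 windows of 6 tests). Per subject and
#' window: mean RT over correct trials (NA when the window has none), mean
#' accuracy over all trials, the occurrence rates of EI- and IE-transitions
#' in the trial's second half over all trials, and the mean RRI velocity
#' over trials with a valid value.
#'
#' @param trials trial-record data.frame (see
#'   \code{\link{build_trial_records}}).
#' @param blocks_per_window number of blocks pooled per window.
#' @param rt_correct_only average RT over correct trials only (default), or
#'   over all trials.
#' @return data.frame: subject, window, mean_rt, accuracy, eit2nd_rate,
#'   iet2nd_rate, mean_drri, n_trials, n_correct.
#' @export
aggregate_windows <- function(trials, blocks_per_window = 2,
                              rt_correct_only = TRUE) {
  win <- (trials$block - 1) %/% blocks_per_window + 1
  key <- list(subject = trials$subject, window = win)
  agg <- stats::aggregate(
    list(accuracy = trials$correct,
         eit2nd_rate = trials$eit_half == "2nd",
         iet2nd_rate = trials$iet_half == "2nd"),
    by = key, FUN = mean)
  mrt <- stats::aggregate(
    list(mean_rt = ifelse(if (rt_correct_only) trials$correct else TRUE,
                          trials$rt_s, NA_real_)),
    by = key, FUN = function(x) if (all(is.na(x))) NA_real_ else
      mean(x, na.rm = TRUE))
  mdr <- stats::aggregate(list(mean_drri = trials$delta_rri), by = key,
                          FUN = function(x) mean(x, na.rm = TRUE))
  cnt <- stats::aggregate(list(n_trials = rep(1L, nrow(trials)),
                               n_correct = as.integer(trials$correct)),
                          by = key, FUN = sum)
  out <- Reduce(function(a, b) merge(a, b, by = c("subject", "window")),
                list(mrt, agg, mdr, cnt))
  out[order(out$subject, out$window), ]
}

#' Grand-normalize and within-subject center windowed aggregates
#'
#' Each variable is z-scored over all subject-windows (suffix \code{_n});
#' the predictors are then additionally centered on each subject's own mean
#' (suffix \code{_c}). The response keeps only the grand normalization: the
#' random intercept absorbs subject means, and subject-centering it would
#' make that intercept degenerate (available behind
#' \code{subject_center_rt} for comparison).
#'
#' @param agg result of \code{\link{aggregate_windows}}; rows with missing
#'   mean RT are dropped (with a message).
#' @param subject_center_rt also center the normalized RT within subject.
#' @return the aggregate table with added columns \code{rt_n},
#'   \code{eit2nd_n/_c}, \code{iet2nd_n/_c}, \code{acc_n/_c},
#'   \code{drri_n/_c}.
#' @export
normalize_and_center <- function(agg, subject_center_rt = FALSE) {
  drop <- is.na(agg$mean_rt)
  if (any(drop)) {
    message(sprintf("normalize_and_center: dropping %d window(s) with no correct trials",
                    sum(drop)))
    agg <- agg[!drop, , drop = FALSE]
  }
  gz <- function(x, nm) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop(sprintf("normalize_and_center: variable '%s' has zero variance", nm),
           call. = FALSE)
    (x - mean(x)) / s
  }
  ctr <- function(x) stats::ave(x, agg$subject, FUN = function(v) v - mean(v))
  agg$rt_n <- gz(agg$mean_rt, "mean_rt")
  if (subject_center_rt) agg$rt_n <- ctr(agg$rt_n)
  agg$eit2nd_n <- gz(agg$eit2nd_rate, "eit2nd_rate")
  agg$iet2nd_n <- gz(agg$iet2nd_rate, "iet2nd_rate")
  agg$acc_n <- gz(agg$accuracy, "accuracy")
  agg$drri_n <- gz(agg$mean_drri, "mean_drri")
  agg$eit2nd_c <- ctr(agg$eit2nd_n)
  agg$iet2nd_c <- ctr(agg$iet2nd_n)
  agg$acc_c <- ctr(agg$acc_n)
  agg$drri_c <- ctr(agg$drri_n)
  agg
}

#' Fit the random-intercept multilevel model of windowed RT
#'
#' Model 1 regresses the grand-normalized windowed RT on the
#' within-subject-centered EIt-2nd occurrence rate, RRI velocity, and
#' accuracy; Model 2 replaces the EIt-2nd rate with the IEt-2nd rate. Both
#' use a Gaussian random intercept per subject and fixed (population-level)
#' slopes, estimated by REML with Satterthwaite degrees of freedom for the
#' coefficient tests.
#'
#' @param data a table carrying columns \code{subject}, \code{rt_n}, and the
#'   centered predictors \code{eit2nd_c}/\code{iet2nd_c}, \code{drri_c},
#'   \code{acc_c} (see \code{\link{normalize_and_center}} or
#'   \code{\link{simulate_model_cohort}}).
#' @param model 1 or 2.
#' @return an object of class \code{cr_mlm} with methods \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{fitted},
#'   \code{residuals} and \code{ranef}.
#' @export
fit_random_intercept <- function(data, model = 1) {
  stopifnot(model %in% c(1, 2))
  pred <- if (model == 1) "eit2nd_c" else "iet2nd_c"
  need <- c("subject", "rt_n", pred, "drri_c", "acc_c")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("fit_random_intercept: missing columns: ", paste(miss, collapse = ", "))
  fml <- stats::as.formula(
    sprintf("rt_n ~ %s + drri_c + acc_c + (1 | subject)", pred))
  fit <- lmerTest::lmer(fml, data = data, REML = TRUE)
  sm <- summary(fit)
  co <- sm$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_int <- vc$vcov[vc$grp == "subject"]
  var_res <- vc$vcov[vc$grp == "Residual"]
  terms <- rownames(co)
  structure(list(
    model = model,
    formula = fml,
    coefficients = data.frame(term = terms, estimate = co[, "Estimate"],
                              se = co[, "Std. Error"], df = co[, "df"],
                              t = co[, "t value"], p = co[, "Pr(>|t|)"],
                              row.names = NULL),
    var_intercept = var_int,
    var_residual = var_res,
    n_obs = stats::nobs(fit),
    n_subjects = length(unique(data$subject)),
    singular = lme4::isSingular(fit),
    df_method = "Satterthwaite",
    fit = fit
  ), class = "cr_mlm")
}

#' @export
print.cr_mlm <- function(x, ...) {
  cat(sprintf("Random-intercept multilevel model (Model %d)\n", x$model))
  cat("  ", deparse(x$formula), "\n", sep = "")
  cat(sprintf("  %d windows, %d subjects; REML, %s df%s\n", x$n_obs,
              x$n_subjects, x$df_method,
              if (x$singular) " [singular random-effect fit]" else ""))
  co <- x$coefficients
  co$estimate <- signif(co$estimate, 3)
  co$se <- signif(co$se, 3)
  co$p <- signif(co$p, 3)
  print(co[c("term", "estimate", "se", "p")], row.names = FALSE)
  cat(sprintf("  random-intercept variance %.4f, residual variance %.4f\n",
              x$var_intercept, x$var_residual))
  invisible(x)
}

#' @export
summary.cr_mlm <- function(object, ...) {
  out <- object[c("model", "coefficients", "var_intercept", "var_residual",
                  "n_obs", "n_subjects", "singular", "df_method")]
  class(out) <- "summary.cr_mlm"
  out
}

#' @export
print.summary.cr_mlm <- function(x, ...) {
  class(x) <- NULL
  str(x, give.attr = FALSE)
  invisible(x)
}

#' @export
coef.cr_mlm <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
predict.cr_mlm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$fit, ...) else
    stats::predict(object$fit, newdata = newdata, ...)
}

#' @export
fitted.cr_mlm <- function(object, ...) stats::fitted(object$fit)

#' @export
residuals.cr_mlm <- function(object, ...) stats::residuals(object$fit)

#' Random intercepts of a fitted model
#' @param object a \code{cr_mlm} fit.
#' @return named numeric vector of subject intercept deviations.
#' @export
ranef_cr_mlm <- function(object) {
  re <- lme4::ranef(object$fit)$subject
  stats::setNames(re[, 1], rownames(re))
}

#' Simulate a cohort on the normalized aggregate scale
#'
#' Parameter-recovery generator for the multilevel models: subject-window
#' predictors are drawn standard normal and within-subject centered, the
#' normalized RT is a subject random intercept plus the linear predictor
#' plus Gaussian residual noise. Defaults give 36 subjects x 15 windows and
#' noise magnitudes that put the coefficient standard errors in the few-
#' hundredths range typical of this design.
#'
#' @param beta length-3 vector: coefficients of the transition-rate
#'   predictor, RRI velocity, and accuracy (normalized scale).
#' @param n_subjects,n_windows design size.
#' @param sigma_subject SD of the subject random intercepts.
#' @param sigma_resid residual SD.
#' @param seed integer seed.
#' @return data.frame ready for \code{\link{fit_random_intercept}} (both
#'   \code{eit2nd_c} and \code{iet2nd_c} carry the same first predictor, so
#'   either model form can be fitted).
#' @export
simulate_model_cohort <- function(beta = c(0.21, 0.145, -0.118),
                                  n_subjects = 36, n_windows = 15,
                                  sigma_subject = 0.5, sigma_resid = 0.78,
                                  seed = 1L) {
  set.seed(seed)
  n <- n_subjects * n_windows
  subject <- rep(sprintf("S%02d", seq_len(n_subjects)), each = n_windows)
  ctr <- function(x) stats::ave(x, subject, FUN = function(v) v - mean(v))
  x1 <- ctr(stats::rnorm(n))
  x2 <- ctr(stats::rnorm(n))
  x3 <- ctr(stats::rnorm(n))
  b0 <- rep(stats::rnorm(n_subjects, 0, sigma_subject), each = n_windows)
  rt <- b0 + beta[1] * x1 + beta[2] * x2 + beta[3] * x3 +
    stats::rnorm(n, 0, sigma_resid)
  data.frame(subject = subject, window = rep(seq_len(n_windows), n_subjects),
             rt_n = rt, eit2nd_c = x1, iet2nd_c = x1, drri_c = x2, acc_c = x3)
}
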