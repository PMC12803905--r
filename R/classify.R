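## Trial-level cardiorespiratory classification: respiratory-phase condition,
## half-of-trial transition labels, RRI velocity and its per-subject binning,
## robust z standardization of reaction times.

#' Classify one test trial against a respiratory phase series
#'
#' Transitions strictly inside the open interval (cue, press) determine the
#' condition: none present and the trial lies wholly within one inhalation
#' (exhalation) interval gives INH (EXH); exactly one type present gives EIt
#' or IEt; both give DOUBLE. The half label per transition type comes from
#' the first transition of that type at time tau: "1st" if
#' tau < cue + RT/2, "2nd" otherwise (a transition exactly at the midpoint is
#' assigned to the second half).
#'
#' @param cue_time,press_time trial bounds (s), \code{press_time > cue_time}.
#' @param phase a \code{\link{phase_series}} covering the trial.
#' @return list with \code{condition} ("INH", "IEt", "EXH", "EIt", "DOUBLE",
#'   or NA when the phase series does not cover the trial), \code{eit_half}
#'   and \code{iet_half} ("none", "1st", "2nd").
#' @export
classify_trial <- function(cue_time, press_time, phase) {
  stopifnot(press_time > cue_time)
  ev <- phase_events(phase)
  if (nrow(ev) == 0 || cue_time < ev$time[1] || press_time > ev$time[nrow(ev)])
    return(list(condition = NA_character_, eit_half = "none", iet_half = "none"))
  rt <- press_time - cue_time
  tau_ei <- first_transition_in(phase$ei, cue_time, press_time)
  tau_ie <- first_transition_in(phase$ie, cue_time, press_time)
  cond <- if (!is.na(tau_ei) && !is.na(tau_ie)) "DOUBLE" else
    if (!is.na(tau_ei)) "EIt" else if (!is.na(tau_ie)) "IEt" else
      if (identical(phase_at(phase, cue_time), "inhalation")) "INH" else "EXH"
  list(condition = cond,
       eit_half = half_of(tau_ei, cue_time, rt),
       iet_half = half_of(tau_ie, cue_time, rt))
}

#' RRI velocity of a trial
#'
#' delta RRI = RRI covering the button press minus RRI covering the test cue
#' (zero when both fall inside the same interval); NA when either event lies
#' outside the R-wave series.
#'
#' @param rri a \code{\link{build_rri_series}} object.
#' @param cue_time,press_time event times (s); vectorized.
#' @return numeric vector of signed RRI differences (s).
#' @export
compute_delta_rri <- function(rri, cue_time, press_time) {
  rri_at(rri, press_time) - rri_at(rri, cue_time)
}

#' Baseline-referenced RRI velocity (supplementary variant)
#'
#' delta RRI_b = RRI covering the button press minus the last RRI that ends
#' at or before the test cue; NA when no complete interval precedes the cue.
#'
#' @inheritParams compute_delta_rri
#' @return numeric vector of signed RRI differences (s).
#' @export
compute_delta_rri_b <- function(rri, cue_time, press_time) {
  n_end <- findInterval(cue_time, rri$r_times)   # count of R waves <= cue
  k <- n_end - 1L                                 # interval ending at R_{n_end}
  k[k < 1L] <- NA_integer_
  rri_at(rri, press_time) - rri$rri[k]
}

#' Bin a subject's RRI velocities by fraction of their maximum magnitude
#'
#' Per sign, let M be the maximum |delta RRI| over the subject's trials of
#' that sign; a trial with magnitude ratio r = |delta RRI|/M falls in the
#' high bin when r >= boundary_fraction and the low bin otherwise (boundary
#' value goes to the high bin). Exact zeros are assigned to low_pos. The
#' default boundary 0.5 is the log-space boundary 10^log10(0.5).
#'
#' @param delta_rri one subject's RRI velocities (s), NAs allowed.
#' @param boundary_fraction bin boundary on the magnitude ratio, in (0, 1).
#' @return factor with levels \code{high_neg, low_neg, low_pos, high_pos}.
#' @export
bin_delta_rri <- function(delta_rri, boundary_fraction = 0.5) {
  stopifnot(boundary_fraction > 0, boundary_fraction < 1)
  lv <- c("high_neg", "low_neg", "low_pos", "high_pos")
  out <- rep(NA_character_, length(delta_rri))
  ok <- !is.na(delta_rri)
  if (!any(ok)) return(factor(out, levels = lv))
  x <- delta_rri[ok]
  if (all(x == 0)) {
    warning("bin_delta_rri: all RRI velocities are zero for this subject")
    out[ok] <- "low_pos"
    return(factor(out, levels = lv))
  }
  bin1 <- function(v) {
    if (v == 0) return("low_pos")
    m <- if (v > 0) max(x[x > 0]) else max(abs(x[x < 0]))
    r <- abs(v) / m
    if (v > 0) {
      if (r >= boundary_fraction) "high_pos" else "low_pos"
    } else {
      if (r >= boundary_fraction) "high_neg" else "low_neg"
    }
  }
  out[ok] <- vapply(x, bin1, character(1))
  factor(out, levels = lv)
}

#' Robust z standardization of a subject's reaction times
#'
#' z = (RT - median) / IQR, where the median and interquartile range are
#' computed over the subject's correct trials. By construction the median of
#' z over correct trials is 0 and its IQR is 1.
#'
#' @param rt_s reaction times (s), all trials of one subject.
#' @param correct logical, correctness per trial.
#' @return list with \code{z} (per trial; NA when the scale is undefined),
#'   \code{median_s}, \code{iqr_s}, and \code{ok} (FALSE when the subject is
#'   flagged: IQR zero or fewer than 4 distinct correct RTs).
#' @export
robust_z_rt <- function(rt_s, correct) {
  stopifnot(length(rt_s) == length(correct))
  rc <- rt_s[correct & !is.na(rt_s)]
  if (length(unique(rc)) < 4) {
    warning("robust_z_rt: fewer than 4 distinct correct RTs; subject flagged")
    return(list(z = rep(NA_real_, length(rt_s)), median_s = NA_real_,
                iqr_s = NA_real_, ok = FALSE))
  }
  med <- stats::median(rc)
  iqr <- stats::IQR(rc)
  if (iqr == 0) {
    warning("robust_z_rt: zero IQR; subject flagged")
    return(list(z = rep(NA_real_, length(rt_s)), median_s = med,
                iqr_s = 0, ok = FALSE))
  }
  list(z = (rt_s - med) / iqr, median_s = med, iqr_s = iqr, ok = TRUE)
}

#' Build trial records for one subject
#'
#' Applies \code{\link{classify_trial}}, \code{\link{compute_delta_rri}},
#' \code{\link{compute_delta_rri_b}}, \code{\link{bin_delta_rri}} and
#' \code{\link{robust_z_rt}} to a subject's event table.
#'
#' @param subject subject id (character).
#' @param events data.frame with columns block, trial, cue_time_s,
#'   press_time_s, rt_s, correct (as produced by the generator or read from
#'   an events table).
#' @param phase a \code{\link{phase_series}}.
#' @param rri a \code{\link{build_rri_series}} object.
#' @param boundary_fraction bin boundary, see \code{\link{bin_delta_rri}}.
#' @return data.frame of trial records; trials the phase series does not
#'   cover carry NA condition and are counted in the \code{"qc"} attribute
#'   (fields \code{n_excluded}, \code{scale_ok}).
#' @export
build_trial_records <- function(subject, events, phase, rri,
                                boundary_fraction = 0.5) {
  cue <- events$cue_time_s
  press <- events$press_time_s
  ev <- phase_events(phase)
  # vectorized equivalent of classify_trial() over the subject's trials
  first_in <- function(times) {
    idx <- findInterval(cue, times) + 1L
    tau <- times[pmin(idx, length(times) + 1L)]
    tau[is.na(tau) | tau >= press] <- NA_real_
    tau
  }
  tau_ei <- first_in(phase$ei)
  tau_ie <- first_in(phase$ie)
  covered <- nrow(ev) > 0 & cue >= ev$time[1] & press <= ev$time[nrow(ev)]
  state_idx <- findInterval(cue, ev$time)
  inh <- state_idx >= 1 & ev$type[pmax(state_idx, 1)] == "EI"
  cond <- ifelse(!covered, NA_character_,
          ifelse(!is.na(tau_ei) & !is.na(tau_ie), "DOUBLE",
          ifelse(!is.na(tau_ei), "EIt",
          ifelse(!is.na(tau_ie), "IEt",
          ifelse(inh, "INH", "EXH")))))
  half_vec <- function(tau) ifelse(is.na(tau), "none",
                                   ifelse(tau < (cue + press) / 2, "1st", "2nd"))
  rec <- data.frame(
    subject = subject,
    block = events$block, trial = events$trial,
    cue_time_s = cue, press_time_s = press,
    rt_s = events$rt_s, correct = events$correct,
    is_match = if ("is_match" %in% names(events)) events$is_match else NA,
    condition = cond,
    not_flag = cond %in% c("INH", "EXH"),
    eit_half = half_vec(tau_ei),
    iet_half = half_vec(tau_ie),
    delta_rri = compute_delta_rri(rri, events$cue_time_s, events$press_time_s),
    delta_rri_b = compute_delta_rri_b(rri, events$cue_time_s, events$press_time_s),
    stringsAsFactors = FALSE
  )
  rec$delta_rri_bin <- bin_delta_rri(rec$delta_rri, boundary_fraction)
  z <- robust_z_rt(rec$rt_s, rec$correct)
  rec$rt_robust_z <- z$z
  attr(rec, "qc") <- list(n_excluded = sum(is.na(cond)), scale_ok = z$ok,
                          rt_median_s = z$median_s, rt_iqr_s = z$iqr_s)
  rec
}

#' Build trial records for a whole simulated cohort from ground truth
#'
#' Convenience wrapper running \code{\link{build_trial_records}} on each
#' subject of a \code{\link{simulate_cohort}} result using the generator's
#' ground-truth phase and RRI series.
#'
#' @param cohort list of subject simulations.
#' @param boundary_fraction bin boundary, see \code{\link{bin_delta_rri}}.
#' @return one data.frame of trial records with a \code{subject} column.
#' @export
cohort_trial_records <- function(cohort, boundary_fraction = 0.5) {
  recs <- lapply(names(cohort), function(id)
    build_trial_records(id, cohort[[id]]$events, cohort[[id]]$phase,
                        cohort[[id]]$rri, boundary_fraction))
  do.call(rbind, recs)
}

half_condition_label <- function(trials) {
  ifelse(trials$condition == "EIt", paste0("EIt-", trials$eit_half),
         ifelse(trials$condition == "IEt", paste0("IEt-", trials$iet_half),
                NA_character_))
}

#' Per-subject per-condition means of the robust-z RT (and accuracy)
#'
#' @param trials trial-record data.frame (multiple subjects).
#' @param grouping one of \code{"phase"} (NOt / IEt / EIt over correct
#'   trials; DOUBLE excluded, INH and EXH pooled), \code{"half"} (IEt-1st,
#'   IEt-2nd, EIt-1st, EIt-2nd over correct single-transition trials),
#'   \code{"bin"} (the four RRI-velocity bins over correct trials), or
#'   \code{"double"} (the 2x2 half-label cross within DOUBLE trials).
#' @param first_trial_only restrict to each block's first test trial.
#' @param value column averaged (default \code{"rt_robust_z"}).
#' @return long data.frame: subject, condition, mean value, n; for
#'   \code{"phase"} also per-condition accuracy over all trials.
#' @export
condition_means <- function(trials,
                            grouping = c("phase", "half", "bin", "double"),
                            first_trial_only = FALSE, value = "rt_robust_z") {
  grouping <- match.arg(grouping)
  if (first_trial_only) trials <- trials[trials$trial == 1, , drop = FALSE]
  lab <- switch(grouping,
    phase = ifelse(trials$not_flag, "NOt",
                   ifelse(trials$condition %in% c("IEt", "EIt"),
                          trials$condition, NA_character_)),
    half = half_condition_label(trials),
    bin = as.character(trials$delta_rri_bin),
    double = ifelse(trials$condition == "DOUBLE",
                    paste0("IEt-", trials$iet_half, "/EIt-", trials$eit_half),
                    NA_character_))
  acc_tab <- NULL
  if (grouping == "phase") {
    keep_a <- !is.na(lab)
    acc_tab <- stats::aggregate(list(accuracy = trials$correct[keep_a]),
                                by = list(subject = trials$subject[keep_a],
                                          condition = lab[keep_a]), FUN = mean)
  }
  keep <- !is.na(lab) & trials$correct & !is.na(trials[[value]])
  if (!any(keep)) stop("condition_means: no usable trials")
  out <- stats::aggregate(list(mean_value = trials[[value]][keep]),
                          by = list(subject = trials$subject[keep],
                                    condition = lab[keep]), FUN = mean)
  ncount <- stats::aggregate(list(n = rep(1, sum(keep))),
                             by = list(subject = trials$subject[keep],
                                       condition = lab[keep]), FUN = sum)
  out <- merge(out, ncount, by = c("subject", "condition"))
  if (!is.null(acc_tab)) out <- merge(out, acc_tab,
                                      by = c("subject", "condition"),
                                      all.x = TRUE)
  out[order(out$subject, out$condition), ]
}

#' Subjects x conditions matrix from a long condition-mean table
#'
#' @param cm result of \code{\link{condition_means}}.
#' @param value column to spread (default \code{"mean_value"}).
#' @param complete_only drop subjects missing any condition (listwise), the
#'   convention of the repeated-measures tests.
#' @return numeric matrix, rownames subjects, colnames conditions.
#' @export
condition_matrix <- function(cm, value = "mean_value", complete_only = TRUE) {
  wide <- stats::reshape(cm[c("subject", "condition", value)],
                         idvar = "subject", timevar = "condition",
                         direction = "wide")
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$subject
  colnames(m) <- sub(paste0("^", value, "\\."), "", colnames(m))
  if (complete_only) m <- m[stats::complete.cases(m), , drop = FALSE]
  m[order(rownames(m)), sort(colnames(m)), drop = FALSE]
}
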