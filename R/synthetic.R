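## Synthetic cohort generator: respiration, heartbeats (IPFM with RSA),
## DMTS task events with injectable RT effects and full ground truth.

#' Generate a ground-truth respiratory phase series (and optional flow trace)
#'
#' Cycle periods are i.i.d. gamma with mean \code{1/resp_rate_hz} and
#' coefficient of variation \code{resp_cv} (\code{resp_cv = 0} gives a
#' strictly periodic signal). Each cycle spends \code{insp_fraction} of its
#' period inhaling. The rendered flow is a half-sine per phase, positive
#' during inhalation under the default sign convention, so noise-free flow
#' crosses zero exactly at every transition.
#'
#' @param config a \code{\link{generator_config}}.
#' @param duration_s minimum time span the phase series must cover.
#' @param seed integer seed for this subject's respiration.
#' @param render if TRUE also return the 1 kHz flow \code{signal_trace}
#'   (with additive Gaussian noise of SD \code{config$noise_sd_flow}).
#' @return list with \code{phase} (a \code{\link{phase_series}}, the exact
#'   ground truth) and, when rendered, \code{trace}.
#' @export
generate_respiration <- function(config, duration_s, seed, render = FALSE) {
  if (!is.finite(duration_s) || duration_s <= 0)
    stop_config("generate_respiration: duration must be strictly positive")
  set.seed(seed)
  mean_T <- 1 / config$resp_rate_hz
  n_cycles <- ceiling(duration_s / mean_T * (1.5 + 3 * config$resp_cv)) + 5
  if (config$resp_cv == 0) {
    periods <- rep(mean_T, n_cycles)
  } else {
    shape <- 1 / config$resp_cv^2
    periods <- stats::rgamma(n_cycles, shape = shape, rate = shape / mean_T)
  }
  starts <- cumsum(c(0, periods))
  # cover the duration plus a whole-cycle buffer so every transition up to
  # duration_s (and the cycle containing it) exists
  target <- duration_s + 2 * mean_T * (1 + 3 * config$resp_cv)
  while (starts[length(starts)] < target) {  # extremely unlikely top-up
    extra <- if (config$resp_cv == 0) mean_T else
      stats::rgamma(1, shape = 1 / config$resp_cv^2,
                    rate = (1 / config$resp_cv^2) / mean_T)
    starts <- c(starts, starts[length(starts)] + extra)
    periods <- c(periods, extra)
  }
  keep <- seq_len(min(which(starts >= target)))
  starts <- starts[keep]
  n <- length(starts) - 1L
  if (config$first_transition == "EI") {
    ei <- starts[seq_len(n)]
    ie <- ei + config$insp_fraction * periods[seq_len(n)]
  } else {
    ie <- starts[seq_len(n)]
    ei <- ie + (1 - config$insp_fraction) * periods[seq_len(n)]
  }
  phase <- phase_series(ei, ie)
  out <- list(phase = phase)
  if (render)
    out$trace <- render_flow(phase, duration_s, fs_hz = config$fs_hz,
                             noise_sd = config$noise_sd_flow,
                             seed = derive_seed(seed, 11L))
  out
}

#' Render a flow trace from a phase series
#'
#' Half-sine flow per phase interval: \code{+sin} over inhalation,
#' \code{-sin} over exhalation (inhalation-positive convention), unit
#' amplitude, plus optional white Gaussian noise.
#'
#' @param phase a \code{\link{phase_series}} covering \code{[0, duration_s]}.
#' @param duration_s trace length in seconds.
#' @param fs_hz sampling rate.
#' @param noise_sd additive noise SD.
#' @param seed RNG seed for the noise.
#' @return a \code{signal_trace} (channel "flow").
#' @export
render_flow <- function(phase, duration_s, fs_hz = 1000, noise_sd = 0, seed = 1L) {
  ev <- phase_events(phase)
  n <- floor(duration_s * fs_hz)
  t <- (seq_len(n) - 1) / fs_hz
  v <- numeric(n)
  idx <- findInterval(t, ev$time)
  ok <- idx >= 1 & idx < nrow(ev)
  i <- idx[ok]
  frac <- (t[ok] - ev$time[i]) / (ev$time[i + 1] - ev$time[i])
  v[ok] <- ifelse(ev$type[i] == "EI", 1, -1) * sinpi(frac)
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(n, sd = noise_sd)
  }
  signal_trace(v, fs_hz = fs_hz, channel = "flow", noise_sd = noise_sd)
}

## Piecewise-linear knots of the instantaneous target RRI r(t):
## rri_base - rsa_amp during inhalation, + rsa_amp during exhalation, with a
## linear ramp of length <= rsa_ramp_s after each transition.
rsa_rri_knots <- function(config, phase) {
  ev <- phase_events(phase)
  lev <- ifelse(ev$type == "EI", config$rri_base_s - config$rsa_amp_s,
                config$rri_base_s + config$rsa_amp_s)
  prev <- c(if (ev$type[1] == "EI") config$rri_base_s + config$rsa_amp_s
            else config$rri_base_s - config$rsa_amp_s, lev[-length(lev)])
  gap <- c(diff(ev$time), Inf)
  ramp <- pmin(config$rsa_ramp_s, 0.9 * gap)
  kx <- as.vector(rbind(ev$time, ev$time + ramp))
  ky <- as.vector(rbind(prev, lev))
  # guard against exact ties (ramp 0)
  o <- order(kx)
  kx <- kx[o]; ky <- ky[o]
  dup <- c(FALSE, diff(kx) <= 0)
  list(x = kx[!dup], y = ky[!dup])
}

#' Generate R-wave times by integral pulse frequency modulation (IPFM)
#'
#' The instantaneous target RRI follows the respiratory phase
#' (\code{rri_base_s - rsa_amp_s} during inhalation, \code{+ rsa_amp_s}
#' during exhalation, linear ramps of \code{rsa_ramp_s} after each
#' transition). Beats are emitted whenever the integral of the instantaneous
#' rate 1/r(t) crosses an integer threshold.
#'
#' @param config a \code{\link{generator_config}}.
#' @param phase ground-truth \code{\link{phase_series}} spanning the duration.
#' @param duration_s span of the beat train (s).
#' @param seed integer seed (used only for the optional rendered ECG noise).
#' @param render if TRUE also return a synthetic ECG \code{signal_trace}
#'   built from a QRS(+P,T) template at each R time plus Gaussian noise of SD
#'   \code{config$noise_sd_ecg}.
#' @param ipfm_fs_hz internal integration grid rate (Hz).
#' @return list with \code{r_times} (strictly increasing, seconds) and,
#'   when rendered, \code{trace}.
#' @export
generate_heartbeats <- function(config, phase, duration_s, seed,
                                render = FALSE, ipfm_fs_hz = 100) {
  if (config$rsa_amp_s >= config$rri_base_s)
    stop_config("generate_heartbeats: rsa_amp_s must be < rri_base_s")
  span <- max(c(phase$ei, phase$ie, 0))
  if (span < duration_s * 0.999)
    stop_config("generate_heartbeats: phase series (%.1f s) does not span %.1f s",
                span, duration_s)
  dt <- 1 / ipfm_fs_hz
  tt <- seq(0, duration_s, by = dt)
  if (config$rsa_amp_s == 0) {
    r <- rep(config$rri_base_s, length(tt))
  } else {
    kn <- rsa_rri_knots(config, phase)
    r <- stats::approx(kn$x, kn$y, xout = tt, rule = 2)$y
  }
  m <- 1 / r
  lam <- c(0, cumsum((m[-1] + m[-length(m)]) / 2) * dt)
  n_beats <- floor(lam[length(lam)])
  if (n_beats < 2) stop_config("generate_heartbeats: duration too short")
  r_times <- stats::approx(lam, tt, xout = seq_len(n_beats), ties = "ordered")$y
  out <- list(r_times = r_times)
  if (render)
    out$trace <- render_ecg(r_times, duration_s, fs_hz = config$fs_hz,
                            noise_sd = config$noise_sd_ecg,
                            seed = derive_seed(seed, 13L))
  out
}

## Symmetric QRS (so band-pass filtering does not move the R peak) with
## small P and T waves; amplitudes in mV-like units, R peak = 1.
ecg_template <- function(fs_hz) {
  t <- seq(-0.30, 0.45, by = 1 / fs_hz)
  g <- function(mu, sd, a) a * exp(-0.5 * ((t - mu) / sd)^2)
  v <- g(-0.19, 0.028, 0.12) +    # P
    g(-0.026, 0.009, -0.14) +     # Q
    g(0, 0.009, 1.0) +            # R
    g(0.026, 0.009, -0.14) +      # S
    g(0.22, 0.05, 0.28)           # T
  list(values = v, center = which.min(abs(t)))
}

#' Render a synthetic ECG trace from R-wave times
#'
#' @param r_times R-wave times (s).
#' @param duration_s trace length (s).
#' @param fs_hz sampling rate.
#' @param noise_sd additive Gaussian noise SD.
#' @param seed RNG seed for the noise.
#' @return a \code{signal_trace} (channel "ecg").
#' @export
render_ecg <- function(r_times, duration_s, fs_hz = 1000, noise_sd = 0, seed = 1L) {
  n <- floor(duration_s * fs_hz)
  v <- numeric(n)
  tpl <- ecg_template(fs_hz)
  L <- length(tpl$values)
  for (rt in r_times) {
    c_idx <- round(rt * fs_hz) + 1L
    lo <- c_idx - tpl$center + 1L
    hi <- lo + L - 1L
    s_lo <- max(1L, lo); s_hi <- min(n, hi)
    if (s_lo > s_hi) next
    v[s_lo:s_hi] <- v[s_lo:s_hi] + tpl$values[(s_lo - lo + 1L):(s_hi - lo + 1L)]
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(n, sd = noise_sd)
  }
  signal_trace(v, fs_hz = fs_hz, channel = "ecg", noise_sd = noise_sd)
}

## First transition of a given type strictly inside (cue, press); NA if none.
first_transition_in <- function(times, cue, press) {
  inside <- times[times > cue & times < press]
  if (length(inside)) inside[1] else NA_real_
}

half_of <- function(tau, cue, rt) {
  if (is.na(tau)) return("none")
  if (tau < cue + rt / 2) "1st" else "2nd"
}

#' The DMTS stimulus space
#'
#' Full factorial of symbol, color, count and position (6 levels each),
#' 1296 distinct images.
#' @return data.frame with 1296 rows and an \code{image_id} key.
#' @export
stimulus_space <- function() {
  sp <- expand.grid(symbol = 1:6, color = 1:6, count = 1:6, position = 1:6,
                    KEEP.OUT.ATTRS = FALSE)
  sp$image_id <- seq_len(nrow(sp))
  sp
}

#' Generate the DMTS task event stream for one subject
#'
#' Schedules 30 blocks of 4 sample cues, a uniform 10-13 s delay, and 3 test
#' cues. Each test trial draws a lognormal base RT; \code{beta_eit2nd_s} is
#' added when an EI transition falls in the trial's second half (single
#' adjustment pass, final label recomputed from the final RT);
#' \code{beta_drri} times the realized RRI velocity at the final press time
#' is added; correctness is Bernoulli with an accuracy drop on EI-transition
#' trials. Match/nonmatch labels are balanced 45/45 per subject and stimulus
#' identities are drawn from the 6^4 space.
#'
#' @param config a \code{\link{generator_config}}.
#' @param phase ground-truth \code{\link{phase_series}}.
#' @param rri ground-truth \code{\link{build_rri_series}} object.
#' @param seed integer seed for this subject's events.
#' @return list with \code{events} (data.frame: block, trial, cue_time_s,
#'   press_time_s, rt_s, response, correct, is_match, image_id) and
#'   \code{truth} (data.frame of ground-truth labels per trial: condition,
#'   eit_half, iet_half, delta_rri, rt_injected_s).
#' @export
generate_task_events <- function(config, phase, rri, seed) {
  set.seed(seed)
  nb <- config$n_blocks
  ntb <- config$tests_per_block
  n_trials <- nb * ntb
  delays <- stats::runif(nb, config$delay_range_s[1], config$delay_range_s[2])
  # block-level attentional state: slow blocks are also error-prone blocks
  state <- stats::rnorm(nb)
  base_rt <- stats::rlnorm(n_trials, meanlog = log(config$rt_base_s) +
                             config$state_sd_rt * rep(state, each = ntb),
                           sdlog = config$rt_sigma_lognorm)
  acc_u <- stats::runif(n_trials)
  n_match <- floor(n_trials / 2)
  is_match <- sample(rep(c(TRUE, FALSE), c(n_match, n_trials - n_match)))
  sp_n <- 1296L
  sample_ids <- replicate(nb, sample.int(sp_n, config$samples_per_block))
  test_ids <- integer(n_trials)
  for (k in seq_len(n_trials)) {
    b <- (k - 1) %/% ntb + 1
    test_ids[k] <- if (is_match[k]) sample(sample_ids[, b], 1) else
      sample(setdiff(seq_len(sp_n), sample_ids[, b]), 1)
  }

  span <- max(c(phase$ei, phase$ie, 0))
  r_max <- rri$r_times[length(rri$r_times)]
  sample_len <- config$samples_per_block *
    (config$sample_cue_s + config$sample_gap_s)

  blk <- tri <- cue_v <- press_v <- rt_v <- dr_v <- inj_v <- numeric(n_trials)
  cond_v <- eh_v <- ih_v <- resp_v <- character(n_trials)
  corr_v <- logical(n_trials)
  t_cursor <- 0
  k <- 0L
  for (b in seq_len(nb)) {
    t_cursor <- t_cursor + sample_len + delays[b]
    for (j in seq_len(ntb)) {
      k <- k + 1L
      cue <- t_cursor
      rt0 <- base_rt[k]
      # single adjustment pass for the EIt-2nd prolongation
      tau0 <- first_transition_in(phase$ei, cue, cue + rt0)
      rt1 <- rt0 + if (half_of(tau0, cue, rt0) == "2nd") config$beta_eit2nd_s else 0
      # RRI velocity realized at the adjusted press time
      dr <- rri_at(rri, cue + rt1) - rri_at(rri, cue)
      if (is.na(dr)) dr <- 0
      rt_final <- rt1 + config$beta_drri * dr
      press <- cue + rt_final
      if (press > span || press > r_max)
        stop_config("generate_task_events: schedule (%.1f s) exceeds signal span", press)
      # ground truth recomputed from the final RT
      tau_ei <- first_transition_in(phase$ei, cue, press)
      tau_ie <- first_transition_in(phase$ie, cue, press)
      cond <- if (!is.na(tau_ei) && !is.na(tau_ie)) "DOUBLE" else
        if (!is.na(tau_ei)) "EIt" else if (!is.na(tau_ie)) "IEt" else
          if (identical(phase_at(phase, cue), "inhalation")) "INH" else "EXH"
      dr_final <- rri_at(rri, press) - rri_at(rri, cue)
      eit_trial <- cond %in% c("EIt", "DOUBLE")
      p_corr <- config$acc_base - (if (eit_trial) config$acc_eit_drop else 0) -
        config$state_acc_slope * state[b]
      p_corr <- min(max(p_corr, 0.01), 0.99)
      correct <- acc_u[k] < p_corr
      blk[k] <- b; tri[k] <- j; cue_v[k] <- cue; press_v[k] <- press
      rt_v[k] <- rt_final; dr_v[k] <- dr_final; inj_v[k] <- rt_final - rt0
      cond_v[k] <- cond
      eh_v[k] <- half_of(tau_ei, cue, rt_final)
      ih_v[k] <- half_of(tau_ie, cue, rt_final)
      corr_v[k] <- correct
      resp_v[k] <- if (correct == is_match[k]) "old" else "new"
      t_cursor <- press + config$intertrial_gap_s
    }
    t_cursor <- t_cursor + config$interblock_gap_s
  }
  list(events = data.frame(block = blk, trial = tri, cue_time_s = cue_v,
                           press_time_s = press_v, rt_s = rt_v,
                           response = resp_v, correct = corr_v,
                           is_match = is_match, image_id = test_ids,
                           stringsAsFactors = FALSE),
       truth = data.frame(block = blk, trial = tri, condition = cond_v,
                          eit_half = eh_v, iet_half = ih_v, delta_rri = dr_v,
                          rt_injected_s = inj_v, stringsAsFactors = FALSE))
}

## Conservative upper bound on the task span, for physiology generation.
schedule_duration_bound <- function(config) {
  rt_cap <- config$rt_base_s * exp(6 * config$rt_sigma_lognorm) +
    config$beta_eit2nd_s + config$beta_drri * 2 * config$rsa_amp_s
  sample_len <- config$samples_per_block *
    (config$sample_cue_s + config$sample_gap_s)
  config$n_blocks * (sample_len + config$delay_range_s[2] +
                       config$interblock_gap_s +
                       config$tests_per_block * (rt_cap + config$intertrial_gap_s)) + 30
}

#' Simulate one subject
#'
#' Generates ground-truth respiration, heartbeats and the DMTS event stream
#' for one subject. Rendering of 1 kHz traces is optional so large cohorts
#' can be simulated at the event level cheaply.
#'
#' @param config a \code{\link{generator_config}}.
#' @param subject_seed integer seed for this subject.
#' @param render render 1 kHz flow and ECG traces.
#' @return list with \code{phase}, \code{r_times}, \code{rri}, \code{events},
#'   \code{truth}, and (if rendered) \code{flow}, \code{ecg}.
#' @export
simulate_subject <- function(config, subject_seed, render = FALSE) {
  dur <- schedule_duration_bound(config)
  resp <- generate_respiration(config, dur, seed = derive_seed(subject_seed, 1L))
  heart <- generate_heartbeats(config, resp$phase, dur,
                               seed = derive_seed(subject_seed, 2L))
  rri <- build_rri_series(heart$r_times)
  task <- generate_task_events(config, resp$phase, rri,
                               seed = derive_seed(subject_seed, 3L))
  out <- list(phase = resp$phase, r_times = heart$r_times, rri = rri,
              events = task$events, truth = task$truth)
  if (render) {
    span <- ceiling(max(task$events$press_time_s) + 5)
    out$flow <- render_flow(resp$phase, span, fs_hz = config$fs_hz,
                            noise_sd = config$noise_sd_flow,
                            seed = derive_seed(subject_seed, 11L))
    out$ecg <- render_ecg(heart$r_times[heart$r_times < span - 1], span,
                          fs_hz = config$fs_hz,
                          noise_sd = config$noise_sd_ecg,
                          seed = derive_seed(subject_seed, 13L))
  }
  out
}

#' Simulate a cohort
#'
#' @param config a \code{\link{generator_config}}.
#' @param render render 1 kHz traces per subject (memory-heavy; default off).
#' @return list of per-subject simulations (see \code{\link{simulate_subject}});
#'   subject ids are \code{S01, S02, ...}.
#' @export
simulate_cohort <- function(config, render = FALSE) {
  subjects <- lapply(seq_len(config$n_subjects), function(i)
    simulate_subject(config, derive_seed(config$seed, 1000L + i), render = render))
  names(subjects) <- sprintf("S%02d", seq_len(config$n_subjects))
  subjects
}
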