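#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic delayed matching-to-sample (DMTS)
#' cohort: task structure, respiratory and cardiac physiology, reaction-time
#' (RT) model, injected effects, and rendering noise. Defaults describe a
#' 36-subject cohort performing 30 blocks of 4 sample cues, a 10-13 s delay
#' and 3 test cues (90 test trials, 45 match / 45 nonmatch), breathing at
#' 0.278 Hz with a cycle-period coefficient of variation of 26.8 %, with
#' respiratory sinus arrhythmia (RSA) shortening R-R intervals (RRIs) during
#' inhalation and lengthening them during exhalation.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_blocks task blocks per subject.
#' @param tests_per_block test cues (trials) per block.
#' @param samples_per_block sample cues per block.
#' @param delay_range_s two seconds, uniform range of the sample-test delay.
#' @param resp_rate_hz mean respiratory rate, breaths per second.
#' @param resp_cv coefficient of variation of cycle periods (unitless).
#' @param insp_fraction fraction of each cycle spent inhaling, in (0,1).
#' @param rri_base_s mean RRI in seconds.
#' @param rsa_amp_s RSA half-amplitude in seconds: instantaneous target RRI is
#'   \code{rri_base_s - rsa_amp_s} during inhalation and
#'   \code{rri_base_s + rsa_amp_s} during exhalation.
#' @param rsa_ramp_s ramp length (s) of the smooth transition between the two
#'   RRI plateaus after each phase transition.
#' @param rt_base_s median reaction time in seconds (lognormal location).
#' @param rt_sigma_lognorm lognormal shape (SD on the log scale) of base RTs.
#' @param beta_eit2nd_s injected RT prolongation (s) when an
#'   exhalation-to-inhalation (EI) transition falls in the trial's second half.
#' @param beta_drri injected linear RT dependence on RRI velocity (s per s).
#' @param acc_base correct-response probability on trials without an EI
#'   transition.
#' @param acc_eit_drop accuracy decrement on EI-transition trials.
#' @param state_sd_rt SD (log scale) of a block-level attentional state that
#'   multiplies all of a block's RTs: attention waxes and wanes slowly over
#'   the session.
#' @param state_acc_slope accuracy decrement per SD of the same block state,
#'   coupling slow blocks to error-prone blocks.
#' @param noise_sd_flow,noise_sd_ecg additive white noise SDs used when
#'   rendering the flow / ECG traces.
#' @param sample_cue_s,sample_gap_s sample-cue duration and inter-sample gap (s).
#' @param intertrial_gap_s gap between a button press and the next test cue (s).
#' @param interblock_gap_s gap between blocks (s).
#' @param first_transition type of the transition at time zero, "EI" (start
#'   inhaling) or "IE" (start exhaling).
#' @param fs_hz sampling rate of rendered traces (Hz).
#' @param seed integer RNG seed for the cohort.
#' @return an object of class \code{generator_config} (a validated list).
#' @export
generator_config <- function(n_subjects = 36L,
                             n_blocks = 30L,
                             tests_per_block = 3L,
                             samples_per_block = 4L,
                             delay_range_s = c(10, 13),
                             resp_rate_hz = 0.278,
                             resp_cv = 0.268,
                             insp_fraction = 0.4,
                             rri_base_s = 0.85,
                             rsa_amp_s = 0.05,
                             rsa_ramp_s = 0.3,
                             rt_base_s = 1.1,
                             rt_sigma_lognorm = 0.25,
                             beta_eit2nd_s = 0.35,
                             beta_drri = 1.2,
                             acc_base = 0.91,
                             acc_eit_drop = 0.05,
                             state_sd_rt = 0.08,
                             state_acc_slope = 0.07,
                             noise_sd_flow = 0,
                             noise_sd_ecg = 0,
                             sample_cue_s = 1,
                             sample_gap_s = 1,
                             intertrial_gap_s = 2,
                             interblock_gap_s = 5,
                             first_transition = c("EI", "IE"),
                             fs_hz = 1000,
                             seed = 1L) {
  first_transition <- match.arg(first_transition)
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_blocks = as.integer(n_blocks),
    tests_per_block = as.integer(tests_per_block),
    samples_per_block = as.integer(samples_per_block),
    delay_range_s = as.numeric(delay_range_s),
    resp_rate_hz = resp_rate_hz, resp_cv = resp_cv,
    insp_fraction = insp_fraction,
    rri_base_s = rri_base_s, rsa_amp_s = rsa_amp_s, rsa_ramp_s = rsa_ramp_s,
    rt_base_s = rt_base_s, rt_sigma_lognorm = rt_sigma_lognorm,
    beta_eit2nd_s = beta_eit2nd_s, beta_drri = beta_drri,
    acc_base = acc_base, acc_eit_drop = acc_eit_drop,
    state_sd_rt = state_sd_rt, state_acc_slope = state_acc_slope,
    noise_sd_flow = noise_sd_flow, noise_sd_ecg = noise_sd_ecg,
    sample_cue_s = sample_cue_s, sample_gap_s = sample_gap_s,
    intertrial_gap_s = intertrial_gap_s, interblock_gap_s = interblock_gap_s,
    first_transition = first_transition,
    fs_hz = fs_hz, seed = as.integer(seed)
  )
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  pos <- c("n_subjects", "n_blocks", "tests_per_block", "samples_per_block",
           "resp_rate_hz", "rri_base_s", "rt_base_s", "rt_sigma_lognorm",
           "fs_hz", "sample_cue_s")
  for (f in pos)
    if (!is.finite(cfg[[f]]) || cfg[[f]] <= 0)
      stop_config("generator_config: '%s' must be strictly positive", f)
  nonneg <- c("resp_cv", "rsa_amp_s", "rsa_ramp_s", "beta_eit2nd_s",
              "beta_drri", "noise_sd_flow", "noise_sd_ecg", "sample_gap_s",
              "intertrial_gap_s", "interblock_gap_s", "acc_eit_drop",
              "state_sd_rt", "state_acc_slope")
  for (f in nonneg)
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0)
      stop_config("generator_config: '%s' must be non-negative", f)
  if (cfg$insp_fraction <= 0 || cfg$insp_fraction >= 1)
    stop_config("generator_config: 'insp_fraction' must lie in (0, 1)")
  if (length(cfg$delay_range_s) != 2L || any(cfg$delay_range_s <= 0) ||
      cfg$delay_range_s[2] < cfg$delay_range_s[1])
    stop_config("generator_config: 'delay_range_s' must be a positive, ordered pair")
  p <- cfg$acc_base - cfg$acc_eit_drop
  if (cfg$acc_base <= 0 || cfg$acc_base > 1 || p <= 0 || p >= 1)
    stop_config("generator_config: accuracy probabilities must lie in (0, 1)")
  if (cfg$rsa_amp_s >= cfg$rri_base_s)
    stop_config("generator_config: 'rsa_amp_s' must be smaller than 'rri_base_s'")
  invisible(cfg)
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic DMTS cohort configuration\n")
  cat(sprintf("  %d subjects, %d blocks x (%d samples, %g-%g s delay, %d tests)\n",
              x$n_subjects, x$n_blocks, x$samples_per_block,
              x$delay_range_s[1], x$delay_range_s[2], x$tests_per_block))
  cat(sprintf("  respiration: %.3f Hz (CV %.1f%%), inspiratory fraction %.2f\n",
              x$resp_rate_hz, 100 * x$resp_cv, x$insp_fraction))
  cat(sprintf("  cardiac: RRI %.3f s, RSA half-amplitude %.3f s\n",
              x$rri_base_s, x$rsa_amp_s))
  cat(sprintf("  RT: median %.2f s (lognormal sigma %.2f); effects: EIt-2nd +%.3f s, dRRI slope %.2f s/s\n",
              x$rt_base_s, x$rt_sigma_lognorm, x$beta_eit2nd_s, x$beta_drri))
  cat(sprintf("  accuracy: %.2f base, -%.2f on EIt trials; seed %d\n",
              x$acc_base, x$acc_eit_drop, x$seed))
  invisible(x)
}
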