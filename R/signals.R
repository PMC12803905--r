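## Signal processing: flow baseline handling and phase-transition detection,
## ECG band-pass and R-wave detection.

#' Subtract a baseline level from a trace
#'
#' @param trace a \code{\link{signal_trace}}.
#' @param baseline_level level to subtract (same units as the trace); defaults
#'   to the trace's recorded baseline.
#' @return the trace shifted by \code{-baseline_level}, with its baseline
#'   metadata set to zero.
#' @export
subtract_baseline <- function(trace, baseline_level = trace$baseline_level) {
  stopifnot(is.finite(baseline_level))
  trace$values <- trace$values - baseline_level
  trace$baseline_level <- 0
  trace
}

#' Estimate the baseline noise SD from a quiet window
#'
#' The transition rule thresholds flow excursions at +/- 2 SD of the
#' baseline noise; this estimates that SD from a pre-task window of the
#' baseline-subtracted trace.
#'
#' @param trace a baseline-subtracted \code{\link{signal_trace}}.
#' @param quiet_window two times (s) bounding the window.
#' @return estimated noise SD (population SD, i.e. divisor n).
#' @export
estimate_noise_sd <- function(trace, quiet_window) {
  t <- trace_times(trace)
  sel <- t >= quiet_window[1] & t <= quiet_window[2]
  if (!any(sel)) stop("estimate_noise_sd: empty quiet window")
  if (diff(quiet_window) < 1)
    warning("estimate_noise_sd: quiet window shorter than 1 s")
  x <- trace$values[sel]
  sqrt(mean((x - mean(x))^2))
}

## Zero-phase Butterworth low-pass (order 4); returns the filtered values.
lowpass_zero_phase <- function(values, fs_hz, cutoff_hz) {
  bf <- signal::butter(4, cutoff_hz / (fs_hz / 2), type = "low")
  as.numeric(signal::filtfilt(bf, values))
}

#' Detect respiratory phase transitions from a flow trace
#'
#' Implements the +/- 2 SD flow-crossing rule: a candidate onset is a zero
#' crossing after which the flow reaches an absolute excursion above
#' \code{2 * noise_sd} before re-crossing zero; sub-threshold crossings are
#' discarded. Under the inhalation-positive convention an upward crossing is
#' an EI transition (inhalation onset) and a downward crossing an IE
#' transition. Alternation is enforced by dropping the later of two
#' consecutive same-type onsets (always, and in particular when they are
#' closer than \code{min_phase_s}).
#'
#' For noisy traces crossings are localized on a zero-phase low-passed copy
#' (\code{smooth_hz}, well above the respiratory band) so that broadband
#' noise does not scatter the crossing time; with \code{noise_sd = 0} the raw
#' trace is used and crossings are exact.
#'
#' @param trace baseline-subtracted flow \code{\link{signal_trace}}.
#' @param noise_sd baseline noise SD (see \code{\link{estimate_noise_sd}}).
#' @param min_phase_s debounce: minimum separation of same-type onsets (s).
#' @param smooth_hz low-pass cutoff used to localize crossings under noise.
#' @return a \code{\link{phase_series}}; empty (with a warning) when less
#'   than one full cycle is detected.
#' @export
detect_respiratory_transitions <- function(trace, noise_sd, min_phase_s = 0.5,
                                           smooth_hz = 5) {
  stopifnot(noise_sd >= 0, min_phase_s > 0)
  fs <- trace$fs_hz
  v <- trace$values
  w <- if (noise_sd > 0 && smooth_hz > 0) lowpass_zero_phase(v, fs, smooth_hz) else v
  pos <- w > 0
  n <- length(w)
  if (n < 2) return(empty_phase_warn())
  chg <- which(pos[-1] != pos[-n])          # crossing between chg and chg+1
  if (!length(chg)) return(empty_phase_warn())
  dt <- 1 / fs
  t0 <- trace$t0
  # linear-interpolated crossing times
  tc <- t0 + (chg - 1) * dt + dt * w[chg] / (w[chg] - w[chg + 1])
  up <- !pos[chg] & pos[chg + 1]
  # max excursion between this crossing and the next
  seg_end <- c(chg[-1], n)
  exc <- vapply(seq_along(chg), function(i)
    max(abs(w[(chg[i] + 1):seg_end[i]])), numeric(1))
  keep <- exc > 2 * noise_sd
  tc <- tc[keep]; up <- up[keep]
  if (!length(tc)) return(empty_phase_warn())
  inh_pos <- identical(trace$sign_convention %||% "inhalation_positive",
                       "inhalation_positive")
  type <- ifelse(up == inh_pos, "EI", "IE")
  # enforce strict alternation: keep the earlier of consecutive same-type onsets
  keep2 <- logical(length(tc))
  last_type <- ""
  for (i in seq_along(tc)) {
    if (type[i] != last_type) {
      keep2[i] <- TRUE
      last_type <- type[i]
    }
  }
  tc <- tc[keep2]; type <- type[keep2]
  if (length(tc) < 2) warning("detect_respiratory_transitions: less than one full cycle detected")
  phase_series(tc[type == "EI"], tc[type == "IE"])
}

empty_phase_warn <- function() {
  warning("detect_respiratory_transitions: no qualifying transitions found")
  phase_series(numeric(0), numeric(0))
}

#' Zero-phase 0.5-40 Hz ECG band-pass
#'
#' Removes baseline drift and high-frequency noise. Implemented as a cascade
#' of a zero-phase order-2 Butterworth high-pass and an order-3 low-pass
#' (numerically stabler at a 1 kHz rate than a single narrow band-pass), so
#' R-wave times are not shifted.
#'
#' @param trace an ECG \code{\link{signal_trace}}.
#' @param low_hz,high_hz band edges in Hz (must satisfy 0 < low < high < fs/2).
#' @return the filtered trace.
#' @export
bandpass_ecg <- function(trace, low_hz = 0.5, high_hz = 40) {
  fs <- trace$fs_hz
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2))
    stop("bandpass_ecg: need 0 < low_hz < high_hz < fs/2")
  hp <- signal::butter(2, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(3, high_hz / (fs / 2), type = "low")
  v <- as.numeric(signal::filtfilt(hp, trace$values))
  v <- as.numeric(signal::filtfilt(lp, v))
  trace$values <- v
  trace$baseline_level <- 0
  trace
}

#' Detect R waves from a band-passed ECG trace
#'
#' Derivative-energy detection in the Pan-Tompkins style: differentiate,
#' square, moving-window integrate (150 ms), then pick peaks of the
#' integrated energy with an adaptive signal/noise threshold and a
#' refractory period, refining each beat to the local maximum of the
#' band-passed ECG.
#'
#' @param trace band-passed ECG \code{\link{signal_trace}}.
#' @param refractory_s minimum separation of beats (s).
#' @param integration_s moving-window integration length (s).
#' @return strictly increasing R-wave times (s); empty for a flat trace.
#' @export
detect_r_waves <- function(trace, refractory_s = 0.2, integration_s = 0.15) {
  fs <- trace$fs_hz
  v <- trace$values
  n <- length(v)
  if (n < fs || max(abs(v)) == 0) return(numeric(0))
  d <- c(0, diff(v)) * fs
  sq <- d^2
  w <- max(1L, round(integration_s * fs))
  cs <- cumsum(sq)
  integ <- (cs - c(rep(0, w), cs[seq_len(n - w)])) / w
  # local maxima of the integrated energy
  pk <- which(diff(sign(diff(integ))) < 0) + 1L
  if (!length(pk)) return(numeric(0))
  # adaptive two-level threshold (signal peak / noise peak running estimates)
  init <- integ[seq_len(min(n, 2 * fs))]
  spk <- max(init)
  npk <- mean(init)
  thr <- npk + 0.25 * (spk - npk)
  beats <- numeric(0)
  last <- -Inf
  refr <- refractory_s * fs
  for (i in pk) {
    p <- integ[i]
    if (p > thr && (i - last) > refr) {
      beats <- c(beats, i)
      last <- i
      spk <- 0.875 * spk + 0.125 * p
    } else {
      npk <- 0.875 * npk + 0.125 * p
    }
    thr <- npk + 0.25 * (spk - npk)
  }
  if (!length(beats)) return(numeric(0))
  # refine: local maximum of the band-passed ECG near each energy peak
  # (the integration window delays the energy peak by roughly w/2)
  half <- round(0.15 * fs)
  r_idx <- vapply(beats, function(i) {
    lo <- max(1L, as.integer(i - half)); hi <- min(n, as.integer(i + round(0.05 * fs)))
    lo + which.max(v[lo:hi]) - 1L
  }, numeric(1))
  r_idx <- sort(unique(r_idx))
  if (length(r_idx) > 1) r_idx <- r_idx[c(TRUE, diff(r_idx) > refr)]
  trace$t0 + (r_idx - 1) / fs
}

#' Flag RRI outliers for quality control
#'
#' Replaces manual beat verification: flags intervals further than
#' \code{z_max} subject-SDs from the subject mean RRI.
#'
#' @param rri a \code{\link{build_rri_series}} object.
#' @param z_max flag threshold in SD units.
#' @return logical vector, one flag per RRI.
#' @export
qc_rri_outliers <- function(rri, z_max = 3) {
  s <- stats::sd(rri$rri)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(rri$rri)))
  abs(rri$rri - mean(rri$rri)) / s > z_max
}
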