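#' Uniformly sampled signal trace
#'
#' Container for one channel (respiratory flow or ECG) sampled at a fixed
#' rate. Sample times are implicit: \code{t0 + (0:(n-1))/fs_hz}.
#'
#' @param values numeric vector of samples.
#' @param fs_hz sampling rate in Hz.
#' @param channel label, e.g. "flow" or "ecg".
#' @param t0 time (s) of the first sample.
#' @param baseline_level baseline in signal units (0 after subtraction).
#' @param noise_sd known or estimated noise SD in signal units (NA if unknown).
#' @param sign_convention for flow: "inhalation_positive" (default) or
#'   "inhalation_negative".
#' @return object of class \code{signal_trace}.
#' @export
signal_trace <- function(values, fs_hz, channel = "flow", t0 = 0,
                         baseline_level = 0, noise_sd = NA_real_,
                         sign_convention = "inhalation_positive") {
  stopifnot(is.numeric(values), all(is.finite(values)), fs_hz > 0)
  structure(list(values = values, fs_hz = fs_hz, channel = channel, t0 = t0,
                 baseline_level = baseline_level, noise_sd = noise_sd,
                 sign_convention = sign_convention),
            class = "signal_trace")
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace: %s, %d samples @ %g Hz (%.1f s), baseline %g>\n",
              x$channel, length(x$values), x$fs_hz,
              length(x$values) / x$fs_hz, x$baseline_level))
  invisible(x)
}

#' Sample times of a trace
#' @param trace a \code{signal_trace}.
#' @return numeric vector of times in seconds.
#' @export
trace_times <- function(trace) {
  trace$t0 + (seq_along(trace$values) - 1) / trace$fs_hz
}

#' Respiratory phase transition series
#'
#' Ordered exhalation-to-inhalation (EI, inhalation onset) and
#' inhalation-to-exhalation (IE, exhalation onset) transition times. The
#' merged sequence must strictly alternate, so the series partitions time
#' into inhalation intervals [EI_k, IE_k) and exhalation intervals
#' [IE_k, EI_{k+1}).
#'
#' @param ei numeric vector of EI transition times (s), strictly increasing.
#' @param ie numeric vector of IE transition times (s), strictly increasing.
#' @return object of class \code{phase_series}.
#' @export
phase_series <- function(ei, ie) {
  ei <- as.numeric(ei); ie <- as.numeric(ie)
  if (length(ei) && any(diff(ei) <= 0)) stop("EI times must be strictly increasing")
  if (length(ie) && any(diff(ie) <= 0)) stop("IE times must be strictly increasing")
  tt <- c(ei, ie)
  ty <- rep(c("EI", "IE"), c(length(ei), length(ie)))
  o <- order(tt)
  if (length(tt) > 1 && any(ty[o][-1] == ty[o][-length(o)]))
    stop("phase_series: merged EI/IE sequence must strictly alternate")
  structure(list(ei = ei, ie = ie), class = "phase_series")
}

#' @export
print.phase_series <- function(x, ...) {
  cat(sprintf("<phase_series: %d EI, %d IE transitions", length(x$ei), length(x$ie)))
  if (length(x$ei) || length(x$ie))
    cat(sprintf(", span %.1f-%.1f s", min(x$ei, x$ie), max(x$ei, x$ie)))
  cat(">\n")
  invisible(x)
}

## Merged transitions as a data.frame(time, type) sorted by time.
phase_events <- function(phase) {
  tt <- c(phase$ei, phase$ie)
  ty <- rep(c("EI", "IE"), c(length(phase$ei), length(phase$ie)))
  o <- order(tt)
  data.frame(time = tt[o], type = ty[o], stringsAsFactors = FALSE)
}

#' Respiratory phase at given times
#'
#' @param phase a \code{phase_series}.
#' @param t numeric vector of times (s).
#' @return character vector: "inhalation", "exhalation", or NA outside the
#'   series' span. A time exactly at a transition belongs to the phase it
#'   starts (half-open intervals).
#' @export
phase_at <- function(phase, t) {
  ev <- phase_events(phase)
  if (nrow(ev) == 0) return(rep(NA_character_, length(t)))
  idx <- findInterval(t, ev$time)  # 0 before first transition
  out <- rep(NA_character_, length(t))
  ok <- idx >= 1
  out[ok] <- ifelse(ev$type[idx[ok]] == "EI", "inhalation", "exhalation")
  out
}

#' R-wave time and R-R interval series
#'
#' RRI_n = R_n - R_{n-1}; interval n owns the half-open time range
#' (R_{n-1}, R_n], so an event coincident with an R wave belongs to the
#' interval that R wave terminates.
#'
#' @param r_times strictly increasing R-wave times (s), length >= 2.
#' @return object of class \code{rri_series} with fields \code{r_times} and
#'   \code{rri} (successive differences, seconds).
#' @export
build_rri_series <- function(r_times) {
  r_times <- as.numeric(r_times)
  if (length(r_times) < 2) stop("build_rri_series: need at least two R-wave times")
  d <- diff(r_times)
  if (any(d <= 0)) stop("build_rri_series: R-wave times must be strictly increasing")
  structure(list(r_times = r_times, rri = d), class = "rri_series")
}

#' @export
print.rri_series <- function(x, ...) {
  cat(sprintf("<rri_series: %d R waves, mean RRI %.3f s, span %.1f-%.1f s>\n",
              length(x$r_times), mean(x$rri), x$r_times[1],
              x$r_times[length(x$r_times)]))
  invisible(x)
}

#' Index of the RRI covering a time point
#'
#' @param rri a \code{rri_series}.
#' @param t numeric vector of times (s).
#' @return integer vector: n such that R_{n-1} < t <= R_n, or NA when t is at
#'   or before the first R wave or after the last.
#' @export
rri_index_at <- function(rri, t) {
  idx <- findInterval(t, rri$r_times, left.open = TRUE)
  idx[idx < 1L | idx > length(rri$rri)] <- NA_integer_
  as.integer(idx)
}

#' RRI value (s) covering a time point
#' @inheritParams rri_index_at
#' @return numeric vector of RRI values, NA where uncovered.
#' @export
rri_at <- function(rri, t) {
  rri$rri[rri_index_at(rri, t)]
}
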