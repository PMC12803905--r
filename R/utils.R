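#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

rms <- function(x) sqrt(mean(x^2))

#' Noise standard deviation for a target signal-to-noise ratio
#'
#' Converts a desired SNR in decibels, defined on signal power
#' (SNR = 10 log10(P_signal / P_noise)), into the standard deviation of
#' additive white Gaussian noise.
#'
#' @param signal numeric vector, the clean signal.
#' @param snr_db target signal-to-noise ratio in dB.
#' @return noise standard deviation in signal units.
#' @export
noise_sd_for_snr <- function(signal, snr_db) {
  rms(signal) / 10^(snr_db / 20)
}

## Deterministic sub-seed derivation: keeps every derived seed a valid
## 32-bit integer and independent of R's global RNG state.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647) + 1L
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)
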