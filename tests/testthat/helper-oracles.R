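## Independent brute-force oracles used to cross-check the package's
## classification, RRI, binning and aggregation code. Deliberately written
## with explicit loops / scans, sharing no code with the implementation.

# scan-based trial classification: membership of every transition is tested
# individually, and the phase of transition-free trials is found by scanning
# the merged event list
oracle_classify <- function(cue, press, ei, ie) {
  in_ei <- c(); in_ie <- c()
  for (tau in ei) if (tau > cue && tau < press) in_ei <- c(in_ei, tau)
  for (tau in ie) if (tau > cue && tau < press) in_ie <- c(in_ie, tau)
  ev_t <- c(ei, ie)
  ev_y <- c(rep("EI", length(ei)), rep("IE", length(ie)))
  o <- order(ev_t); ev_t <- ev_t[o]; ev_y <- ev_y[o]
  if (length(ev_t) == 0 || cue < ev_t[1] || press > ev_t[length(ev_t)])
    return(list(condition = NA_character_, eit_half = "none", iet_half = "none"))
  cond <- if (length(in_ei) > 0 && length(in_ie) > 0) "DOUBLE"
  else if (length(in_ei) > 0) "EIt"
  else if (length(in_ie) > 0) "IEt"
  else {
    j <- 0
    for (i in seq_along(ev_t)) if (ev_t[i] <= cue) j <- i
    if (ev_y[j] == "EI") "INH" else "EXH"
  }
  half <- function(taus) {
    if (length(taus) == 0) return("none")
    if (min(taus) < cue + (press - cue) / 2) "1st" else "2nd"
  }
  list(condition = cond, eit_half = half(in_ei), iet_half = half(in_ie))
}

# linear-scan RRI lookup: interval (R_{n-1}, R_n]
oracle_rri_at <- function(r_times, t) {
  for (n in 2:length(r_times))
    if (t > r_times[n - 1] && t <= r_times[n])
      return(r_times[n] - r_times[n - 1])
  NA_real_
}

oracle_delta_rri <- function(r_times, cue, press) {
  oracle_rri_at(r_times, press) - oracle_rri_at(r_times, cue)
}

oracle_delta_rri_b <- function(r_times, cue, press) {
  prior <- NA_real_
  for (n in 2:length(r_times))
    if (r_times[n] <= cue) prior <- r_times[n] - r_times[n - 1]
  oracle_rri_at(r_times, press) - prior
}

# per-value binning by scan over the subject's values
oracle_bin <- function(values, boundary = 0.5) {
  out <- character(length(values))
  for (i in seq_along(values)) {
    v <- values[i]
    if (is.na(v)) { out[i] <- NA_character_; next }
    if (v == 0) { out[i] <- "low_pos"; next }
    m <- 0
    for (u in values)
      if (!is.na(u) && sign(u) == sign(v) && abs(u) > m) m <- abs(u)
    r <- abs(v) / m
    out[i] <- if (v > 0) {
      if (r >= boundary) "high_pos" else "low_pos"
    } else {
      if (r >= boundary) "high_neg" else "low_neg"
    }
  }
  out
}

# loop-based two-block window aggregation
oracle_aggregate <- function(trials, blocks_per_window = 2) {
  out <- NULL
  for (s in sort(unique(trials$subject))) {
    ts <- trials[trials$subject == s, ]
    for (w in sort(unique((ts$block - 1) %/% blocks_per_window + 1))) {
      tw <- ts[(ts$block - 1) %/% blocks_per_window + 1 == w, ]
      rc <- tw$rt_s[tw$correct]
      out <- rbind(out, data.frame(
        subject = s, window = w,
        mean_rt = if (length(rc)) mean(rc) else NA_real_,
        accuracy = mean(tw$correct),
        eit2nd_rate = mean(tw$eit_half == "2nd"),
        iet2nd_rate = mean(tw$iet_half == "2nd"),
        mean_drri = mean(tw$delta_rri[!is.na(tw$delta_rri)])))
    }
  }
  out
}

# rank-based Friedman statistic from the textbook formula
oracle_friedman <- function(mat) {
  n <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  12 / (n * k * (k + 1)) * sum(colSums(R)^2) - 3 * n * (k + 1)
}

# random strictly-alternating phase series starting with an EI transition
random_phase_series <- function(n_cycles, t0 = 0) {
  gaps <- stats::runif(2 * n_cycles, 0.4, 3)
  tt <- t0 + cumsum(gaps)
  phase_series(tt[seq(1, length(tt), by = 2)], tt[seq(2, length(tt), by = 2)])
}

# RMS over the middle 80 % of a vector (ignores filter edge transients)
rms_mid <- function(x) {
  n <- length(x)
  i <- seq(max(1, floor(n * 0.1)), ceiling(n * 0.9))
  sqrt(mean(x[i]^2))
}

# small event-level cohort config used across tests (kept at study-default
# physiology and effects, fewer subjects only where a test's property does
# not depend on cohort size)
test_config <- function(...) generator_config(...)
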