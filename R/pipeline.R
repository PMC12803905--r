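## End-to-end orchestration: simulate -> detect -> classify -> stats -> mlm,
## plus on-disk TSV/JSON interchange and input validation.

#' Write / read a signal trace as TSV
#'
#' Two tab-separated columns \code{time_s}, \code{value}, with a header.
#' @param trace a \code{\link{signal_trace}}.
#' @param path output file.
#' @export
write_signal_tsv <- function(trace, path) {
  utils::write.table(
    data.frame(time_s = trace_times(trace), value = trace$values),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_signal_tsv
#' @param channel channel label for the trace read back.
#' @return \code{read_signal_tsv}: a \code{signal_trace} (the sampling rate
#'   is inferred from the time column and checked for uniformity).
#' @export
read_signal_tsv <- function(path, channel = "flow") {
  d <- utils::read.delim(path)
  stopifnot(all(c("time_s", "value") %in% names(d)))
  dt <- diff(d$time_s)
  if (length(dt) && (max(dt) - min(dt)) > 1e-9 * max(dt))
    stop("read_signal_tsv: non-uniform sampling in ", path)
  signal_trace(d$value, fs_hz = 1 / stats::median(dt), channel = channel,
               t0 = d$time_s[1])
}

#' Write / read a task event table as TSV
#' @param events events data.frame (see \code{\link{generate_task_events}}).
#' @param path file path.
#' @export
write_events_tsv <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @export
read_events_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write one simulated subject to a directory
#'
#' Emits \code{flow.tsv}, \code{ecg.tsv} (when rendered), \code{events.tsv},
#' \code{truth.json} and a \code{config.yaml} echo.
#'
#' @param sim result of \code{\link{simulate_subject}}.
#' @param dir output directory (created).
#' @param config the \code{\link{generator_config}} used.
#' @export
write_subject_data <- function(sim, dir, config) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$flow)) write_signal_tsv(sim$flow, file.path(dir, "flow.tsv"))
  if (!is.null(sim$ecg)) write_signal_tsv(sim$ecg, file.path(dir, "ecg.tsv"))
  write_events_tsv(sim$events, file.path(dir, "events.tsv"))
  jsonlite::write_json(
    list(ei = sim$phase$ei, ie = sim$phase$ie, r_times = sim$r_times,
         trials = sim$truth),
    file.path(dir, "truth.json"), digits = NA)
  yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Validate an on-disk subject directory
#'
#' Checks sampling uniformity, monotone times, event times within the signal
#' span, non-positive RTs, and block/trial count consistency against a
#' configuration.
#'
#' @param dir subject directory containing at least \code{events.tsv}.
#' @param config optional \code{\link{generator_config}} for count checks.
#' @return character vector of violations (empty when well-formed).
#' @export
validate_inputs <- function(dir, config = NULL) {
  v <- character(0)
  ef <- file.path(dir, "events.tsv")
  if (!file.exists(ef)) return("missing events.tsv")
  ev <- read_events_tsv(ef)
  need <- c("block", "trial", "cue_time_s", "press_time_s", "correct")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    return(sprintf("events.tsv: missing column(s) %s", paste(miss, collapse = ", ")))
  if (any(ev$press_time_s <= ev$cue_time_s))
    v <- c(v, sprintf("events.tsv: non-positive RT in %d trial(s)",
                      sum(ev$press_time_s <= ev$cue_time_s)))
  if (is.unsorted(ev$cue_time_s))
    v <- c(v, "events.tsv: cue times not monotone increasing")
  if (!is.null(config)) {
    if (length(unique(ev$block)) != config$n_blocks)
      v <- c(v, sprintf("events.tsv: %d blocks, expected %d",
                        length(unique(ev$block)), config$n_blocks))
    bad <- names(which(table(ev$block) != config$tests_per_block))
    if (length(bad))
      v <- c(v, sprintf("events.tsv: block(s) %s lack %d tests",
                        paste(bad, collapse = ","), config$tests_per_block))
  }
  for (ch in c("flow", "ecg")) {
    f <- file.path(dir, paste0(ch, ".tsv"))
    if (!file.exists(f)) next
    tr <- tryCatch(read_signal_tsv(f, channel = ch), error = function(e) e)
    if (inherits(tr, "error")) {
      v <- c(v, sprintf("%s.tsv: %s", ch, conditionMessage(tr)))
      next
    }
    span <- trace_times(tr)[length(tr$values)]
    if (max(ev$press_time_s) > span)
      v <- c(v, sprintf("%s.tsv: events outside signal span (%.1f > %.1f s)",
                        ch, max(ev$press_time_s), span))
  }
  v
}

#' Run the full analysis pipeline on a simulated cohort
#'
#' Simulates a cohort, recovers phase and RRI series (either directly from
#' the generator's ground truth, or by rendering 1 kHz traces and running
#' the detectors), classifies trials, runs the statistical battery, fits
#' both multilevel models, and writes \code{trials.tsv}, \code{qc.json},
#' \code{stats_report.json}, \code{model1.json}, \code{model2.json},
#' \code{tables.md} and \code{provenance.json} to \code{out_dir}.
#'
#' @param config a \code{\link{generator_config}}.
#' @param out_dir output directory (created); NULL to skip writing.
#' @param detect "ground_truth" (use the generator's series) or "signals"
#'   (render traces, detect transitions and R waves).
#' @param boundary_fraction RRI-velocity bin boundary.
#' @return invisible list: trials, qc, stats, model1, model2, aggregates.
#' @export
run_pipeline <- function(config = generator_config(), out_dir = NULL,
                         detect = c("ground_truth", "signals"),
                         boundary_fraction = 0.5) {
  detect <- match.arg(detect)
  cohort <- simulate_cohort(config, render = detect == "signals")
  qc <- list(detect = detect, subjects = list())
  if (detect == "signals") {
    for (id in names(cohort)) {
      s <- cohort[[id]]
      flow <- subtract_baseline(s$flow)
      nsd <- if (config$noise_sd_flow > 0) config$noise_sd_flow else 0
      s$phase <- detect_respiratory_transitions(flow, noise_sd = nsd)
      r <- detect_r_waves(bandpass_ecg(s$ecg))
      s$rri <- build_rri_series(r)
      qc$subjects[[id]] <- list(n_ei = length(s$phase$ei),
                                n_ie = length(s$phase$ie),
                                n_r = length(r),
                                n_rri_outliers = sum(qc_rri_outliers(s$rri)))
      s$flow <- s$ecg <- NULL
      cohort[[id]] <- s
    }
  }
  trials <- cohort_trial_records(cohort, boundary_fraction)
  qc$n_excluded_trials <- sum(is.na(trials$condition))
  stats_out <- run_stats_battery(trials)
  agg <- tryCatch(normalize_and_center(aggregate_windows(trials)),
                  error = function(e) {
                    warning("aggregation not normalized: ", conditionMessage(e))
                    NULL
                  })
  fit_or_null <- function(model) tryCatch(
    if (is.null(agg)) stop("no normalized aggregate table") else
      fit_random_intercept(agg, model = model),
    error = function(e) {
      warning(sprintf("model %d not fitted: %s", model, conditionMessage(e)))
      NULL
    })
  m1 <- fit_or_null(1)
  m2 <- fit_or_null(2)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_events_tsv(trials, file.path(out_dir, "trials.tsv"))
    jsonlite::write_json(qc, file.path(out_dir, "qc.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(strip_tests(stats_out),
                         file.path(out_dir, "stats_report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    for (m in Filter(Negate(is.null), list(m1, m2)))
      jsonlite::write_json(
        summary(m)[c("model", "coefficients", "var_intercept",
                     "var_residual", "n_obs", "n_subjects")],
        file.path(out_dir, sprintf("model%d.json", m$model)),
        auto_unbox = TRUE, digits = NA, dataframe = "rows", force = TRUE)
    writeLines(unlist(lapply(Filter(Negate(is.null), list(m1, m2)),
                             function(m) c(model_table_md(m), ""))),
               file.path(out_dir, "tables.md"))
    jsonlite::write_json(
      list(config = unclass(config), seed = config$seed,
           n_trials = nrow(trials),
           n_windows = if (is.null(agg)) 0L else nrow(agg),
           package_version = as.character(utils::packageVersion("cardioresp"))),
      file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(trials = trials, qc = qc, stats = stats_out,
                 model1 = m1, model2 = m2, aggregates = agg))
}

## drop non-serializable members (lm/lmer fits) before JSON export
strip_tests <- function(x) {
  if (inherits(x, c("lm", "merMod", "cr_mlm"))) return(NULL)
  if (is.list(x)) return(lapply(x, strip_tests))
  x
}

model_table_md <- function(m) {
  co <- m$coefficients[m$coefficients$term != "(Intercept)", ]
  c(sprintf("### Model %d: random-intercept regression of windowed RT", m$model),
    "", "| term | coefficient (SE) | p-value |", "|---|---|---|",
    sprintf("| %s | %.3f (%.4f) | %.3g |", co$term, co$estimate, co$se, co$p),
    "",
    sprintf("Random-intercept variance %.4f; residual variance %.4f; %d windows, %d subjects.",
            m$var_intercept, m$var_residual, m$n_obs, m$n_subjects))
}
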