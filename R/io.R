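#' Write a trial log to CSV
#'
#' Column order is fixed: \code{session_id, trial_index, itd_us, response,
#' correct, is_correction, seed}; booleans are written as 0/1, responses as
#' "L"/"R".  Comma-separated, UTF-8, mandatory header, no index column.
#'
#' @param records Trial log data.frame (see [simulate_session()]).
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_trial_csv <- function(records, path) {
  cols <- c("session_id", "trial_index", "itd_us", "response", "correct",
            "is_correction", "seed")
  missing <- setdiff(cols, names(records))
  if (length(missing))
    stop("trial log lacks column(s): ", paste(missing, collapse = ", "))
  out <- records[cols]
  out$correct <- as.integer(as.logical(out$correct))
  out$is_correction <- as.integer(as.logical(out$is_correction))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial log from CSV
#'
#' Validates the schema written by [write_trial_csv()]: all columns present
#' (an error names any missing one), boolean flags coded 0/1, responses
#' "L"/"R", and \code{trial_index} non-decreasing within each session.
#'
#' @param path CSV file path.
#' @return A \code{trial_log} data.frame with logical \code{correct} and
#'   \code{is_correction}.
#' @export
read_trial_csv <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  cols <- c("session_id", "trial_index", "itd_us", "response", "correct",
            "is_correction", "seed")
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop("trial CSV lacks column(s): ", paste(missing, collapse = ", "))
  if (nrow(df)) {
    if (!all(df$response %in% c("L", "R")))
      stop("response column must be 'L' or 'R' (first bad line: ",
           which(!df$response %in% c("L", "R"))[1] + 1L, ")")
    for (col in c("correct", "is_correction")) {
      if (!all(df[[col]] %in% c(0L, 1L)))
        stop(col, " column must be 0/1 (first bad line: ",
             which(!df[[col]] %in% c(0L, 1L))[1] + 1L, ")")
    }
    unsorted <- tapply(df$trial_index, df$session_id,
                       function(x) is.unsorted(x))
    if (any(unsorted))
      stop("trial_index not sorted within session(s): ",
           paste(names(unsorted)[unsorted], collapse = ", "))
  }
  df$correct <- as.logical(df$correct)
  df$is_correction <- as.logical(df$is_correction)
  class(df) <- c("trial_log", "data.frame")
  df
}

# Full-precision numeric formatting so text round-trips are lossless.
fmt_full <- function(x) sprintf("%.17g", x)

#' Write a recording block to a plain-text bundle
#'
#' The package's native recording container is a directory holding
#' \code{meta.json} (sample rate, dimensions, optional ground-truth tuning
#' parameters), \code{events.csv} (\code{time_s,itd_us} per stimulus) and
#' \code{trace.csv} (one column per channel, full \code{%.17g} precision so
#' the round-trip is lossless).
#'
#' @param block A \code{recording_block}.
#' @param path Directory to create/overwrite.
#' @return \code{path}, invisibly.
#' @export
write_recording <- function(block, path) {
  stopifnot(inherits(block, "recording_block"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(sample_rate_hz = block$sample_rate_hz,
               n_channels = nrow(block$trace),
               n_samples = ncol(block$trace))
  gt <- block$ground_truth$tuning
  if (!is.null(gt)) meta$ground_truth_tuning <- unclass(gt)
  if (!is.null(block$ground_truth$spike_times_s))
    meta$ground_truth_spike_times_s <-
      as.numeric(block$ground_truth$spike_times_s)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  ev <- data.frame(time_s = fmt_full(block$event_time_s),
                   itd_us = fmt_full(block$event_itd_us))
  utils::write.csv(ev, file.path(path, "events.csv"), row.names = FALSE,
                   quote = FALSE)
  tr <- apply(block$trace, 1, fmt_full)
  if (is.null(dim(tr))) tr <- matrix(tr, ncol = nrow(block$trace))
  utils::write.table(tr, file.path(path, "trace.csv"), sep = ",",
                     row.names = FALSE,
                     col.names = paste0("ch", seq_len(nrow(block$trace))),
                     quote = FALSE)
  invisible(path)
}

#' Read a recording block from a plain-text bundle
#'
#' Inverse of [write_recording()]; validates that the sample rate is
#' present and that event times and ITD labels have equal length.
#'
#' @param path Bundle directory.
#' @return A \code{recording_block}.
#' @export
read_recording <- function(path) {
  stopifnot(dir.exists(path))
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$sample_rate_hz))
    stop("recording bundle lacks sample_rate_hz")
  ev <- utils::read.csv(file.path(path, "events.csv"))
  if (!all(c("time_s", "itd_us") %in% names(ev)))
    stop("events.csv must have columns time_s,itd_us")
  tr <- as.matrix(utils::read.csv(file.path(path, "trace.csv")))
  trace <- t(tr)
  dimnames(trace) <- NULL
  if (nrow(trace) != meta$n_channels || ncol(trace) != meta$n_samples)
    stop("trace dimensions disagree with meta.json")
  gt <- NULL
  if (!is.null(meta$ground_truth_tuning)) {
    tg <- meta$ground_truth_tuning
    gt <- list(tuning = tuning_function(tg$shape, tg$depth, tg$best_itd_us,
                                        tg$width_us, tg$base_rate_hz,
                                        tg$evoked_rate_hz,
                                        tg$response_type),
               spike_times_s = as.numeric(meta$ground_truth_spike_times_s))
  }
  structure(list(trace = trace,
                 sample_rate_hz = meta$sample_rate_hz,
                 event_time_s = as.numeric(ev$time_s),
                 event_itd_us = as.numeric(ev$itd_us),
                 ground_truth = gt),
            class = "recording_block")
}

#' Run a simulate-and-analyze pipeline
#'
#' Executes one of two chains end-to-end and writes machine-readable
#' artifacts:
#' \describe{
#'   \item{behavior}{[simulate_session()] -> trial CSV ->
#'     [fit_psychometric()] -> JSON fit report (+ per-ITD proportions
#'     CSV).}
#'   \item{neuro}{[make_trial_schedule()] -> [simulate_recording()] ->
#'     [build_response_matrix()] -> [compute_stvr()] and [tuning_curve()]
#'     -> JSON site report + tuning-curve CSV.}
#' }
#' All randomness flows from \code{config$seed}; re-running with the same
#' config reproduces the outputs byte-identically on the same platform.
#' Every JSON report embeds a provenance block (config echo, seed, package
#' version).
#'
#' @param config Named list.  Common: \code{chain} ("behavior"/"neuro"),
#'   \code{seed}, \code{out_dir}.  Behavior chain: \code{model} (a
#'   [psych_model()] or list of its parameters), \code{n_trials},
#'   \code{itd_set}.  Neuro chain: \code{tuning} (a [tuning_function()] or
#'   parameter list), \code{schedule} (parameter list for
#'   [make_trial_schedule()]), \code{snr}, \code{noise_sd},
#'   \code{measure}, \code{windows} (parameter list for
#'   [analysis_windows()]).
#' @return Invisibly, a list of the objects produced (and file paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config), !is.null(config$chain),
            !is.null(config$out_dir))
  chain <- match.arg(config$chain, c("behavior", "neuro"))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  prov <- list(package = "itdsense",
               version = as.character(utils::packageVersion("itdsense")),
               seed = seed,
               config = config[setdiff(names(config),
                                       c("model", "tuning", "out_dir"))])
  if (chain == "behavior") {
    model <- config$model
    if (!inherits(model, "psych_model")) model <- do.call(psych_model, model)
    n_trials <- if (is.null(config$n_trials)) 3000L else config$n_trials
    itd_set <- if (is.null(config$itd_set)) default_behavior_itd_set()
               else config$itd_set
    log <- simulate_session(model, itd_set, n_trials, seed)
    trials_path <- file.path(config$out_dir, "trials.csv")
    write_trial_csv(log, trials_path)
    fit <- fit_psychometric(log)
    report <- list(provenance = prov,
                   ground_truth = unclass(model),
                   fit = as.list(coef(fit)),
                   neg_log_likelihood = fit$neg_log_likelihood,
                   converged = fit$converged,
                   boundary = fit$boundary,
                   n_trials_used = fit$n_trials_used,
                   slope_pct_per_us = fit$slope_pct_per_us,
                   threshold75_us = fit$threshold75_us,
                   threshold_defined = fit$threshold_defined)
    report_path <- file.path(config$out_dir, "fit_report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, na = "null")
    utils::write.csv(fit$proportions,
                     file.path(config$out_dir, "proportions.csv"),
                     row.names = FALSE)
    invisible(list(log = log, fit = fit, report = report,
                   paths = c(trials_path, report_path)))
  } else {
    tuning <- config$tuning
    if (!inherits(tuning, "tuning_function"))
      tuning <- do.call(tuning_function, tuning)
    sched_args <- if (is.null(config$schedule)) list() else config$schedule
    sched_args$seed <- seed
    schedule <- do.call(make_trial_schedule, sched_args)
    rec <- simulate_recording(tuning, schedule,
                              noise_sd = config$noise_sd %||% 1,
                              snr = config$snr %||% 10,
                              seed = seed + 1L)
    win_args <- if (is.null(config$windows)) list() else config$windows
    windows <- do.call(analysis_windows, win_args)
    measure <- config$measure %||% "amua_mean"
    rm_ <- build_response_matrix(rec, windows, measure)
    stvr <- compute_stvr(rm_)
    curve <- tuning_curve(rm_)
    report <- list(provenance = prov,
                   ground_truth = unclass(tuning),
                   stvr = stvr$stvr, f_stat = stvr$f_stat,
                   p_value = stvr$p_value,
                   df_between = stvr$df_between,
                   df_within = stvr$df_within,
                   significant = stvr$significant,
                   measure = measure)
    site_path <- file.path(config$out_dir, "site.json")
    jsonlite::write_json(report, site_path, auto_unbox = TRUE, digits = NA,
                         na = "null")
    curve_path <- file.path(config$out_dir, "tuning_curve.csv")
    utils::write.csv(curve, curve_path, row.names = FALSE)
    invisible(list(recording = rec, matrix = rm_, stvr = stvr,
                   curve = curve, report = report,
                   paths = c(site_path, curve_path)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
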