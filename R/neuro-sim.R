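#' Parametric ITD tuning function for simulated multi-units
#'
#' Defines how the firing rate of a simulated multi-unit depends on stimulus
#' ITD.  The driven rate in the response window is
#' \code{base_rate_hz + evoked_rate_hz * ((1 - depth) + depth * g(itd))}
#' where \code{g} is a shape in \[0, 1\]:
#' \describe{
#'   \item{peak}{Gaussian bump centered on \code{best_itd_us} with SD
#'     \code{width_us}.}
#'   \item{sigmoid}{monotonic logistic transition at \code{best_itd_us}
#'     with scale \code{width_us}.}
#'   \item{trough}{inverted Gaussian (suppression at \code{best_itd_us}).}
#'   \item{multipeak}{raised cosine with period \code{2 * width_us}.}
#' }
#' \code{depth = 0} makes the rate independent of ITD (null tuning);
#' \code{depth = 1} modulates the evoked rate fully.  Rates are never
#' negative by construction.
#'
#' @param shape One of "peak", "sigmoid", "trough", "multipeak".
#' @param depth Modulation depth in \[0, 1\].
#' @param best_itd_us Center/transition ITD in microseconds.
#' @param width_us Tuning width (SD / logistic scale / half-period) in
#'   microseconds.
#' @param base_rate_hz Baseline multi-unit firing rate (Hz) outside the
#'   response window.
#' @param evoked_rate_hz Stimulus-evoked rate increase (Hz) at full drive.
#' @param response_type "sustained" (response window 3-80 ms post onset) or
#'   "onset" (3-15 ms); response latency is 3 ms either way.
#' @return Object of class \code{tuning_function}; call it via
#'   [tuning_rate()].
#' @export
#' @examples
#' tf <- tuning_function("sigmoid", depth = 0.8, best_itd_us = 0,
#'                       width_us = 40)
#' tuning_rate(tf, c(-160, 0, 160))
tuning_function <- function(shape = c("peak", "sigmoid", "trough",
                                      "multipeak"),
                            depth = 1,
                            best_itd_us = 0,
                            width_us = 50,
                            base_rate_hz = 20,
                            evoked_rate_hz = 200,
                            response_type = c("sustained", "onset")) {
  shape <- match.arg(shape)
  response_type <- match.arg(response_type)
  stopifnot(depth >= 0, depth <= 1, width_us > 0,
            base_rate_hz >= 0, evoked_rate_hz >= 0)
  structure(list(shape = shape, depth = depth, best_itd_us = best_itd_us,
                 width_us = width_us, base_rate_hz = base_rate_hz,
                 evoked_rate_hz = evoked_rate_hz,
                 response_type = response_type,
                 response_window_ms = if (response_type == "sustained")
                   c(3, 80) else c(3, 15)),
            class = "tuning_function")
}

#' Evaluate a tuning function: driven firing rate vs ITD
#'
#' @param tuning A [tuning_function()].
#' @param itd_us ITD(s) in microseconds.
#' @return Firing rate (Hz) in the response window for each ITD.
#' @export
tuning_rate <- function(tuning, itd_us) {
  stopifnot(inherits(tuning, "tuning_function"))
  x <- (itd_us - tuning$best_itd_us) / tuning$width_us
  g <- switch(tuning$shape,
              peak = exp(-0.5 * x^2),
              sigmoid = stats::plogis(x),
              trough = 1 - exp(-0.5 * x^2),
              multipeak = 0.5 + 0.5 * cospi(x))
  tuning$base_rate_hz +
    tuning$evoked_rate_hz * ((1 - tuning$depth) + tuning$depth * g)
}

#' Build a pseudo-random ITD trial schedule
#'
#' The recording protocol presents every ITD level the same number of times
#' in shuffled order at a fixed inter-stimulus interval.  The default
#' arguments reproduce the standard design: 17 levels from -163.84 to
#' +163.84 us in 20.48 us steps, 30 repeats each (510 events), 500 ms
#' apart.
#'
#' @param itd_min_us,itd_max_us,step_us ITD range and step; the step must
#'   divide the range exactly.
#' @param n_repeats Presentations per level.
#' @param isi_ms Inter-stimulus (onset-to-onset) interval in ms.
#' @param seed Integer seed for the shuffle.
#' @param order "shuffle" (full random permutation of the trial list) or
#'   "blocked" (one shuffled pass through all levels per repeat block).
#' @param lead_in_s Silence before the first onset (s).
#' @return List of class \code{trial_schedule} with \code{event_time_s},
#'   \code{itd_us} (per-event labels), \code{levels_us} and \code{isi_ms}.
#' @export
#' @examples
#' sched <- make_trial_schedule(seed = 1)
#' length(sched$event_time_s)  # 510
make_trial_schedule <- function(itd_min_us = -163.84,
                                itd_max_us = 163.84,
                                step_us = 20.48,
                                n_repeats = 30,
                                isi_ms = 500,
                                seed = 1,
                                order = c("shuffle", "blocked"),
                                lead_in_s = 0.1) {
  order <- match.arg(order)
  stopifnot(itd_max_us > itd_min_us, step_us > 0, n_repeats >= 1,
            isi_ms > 0)
  n_steps <- (itd_max_us - itd_min_us) / step_us
  if (abs(n_steps - round(n_steps)) > 1e-9)
    stop("step_us must divide the ITD range exactly")
  levels <- itd_min_us + step_us * 0:round(n_steps)
  set.seed(as.integer(seed))
  labels <- if (order == "shuffle") {
    sample(rep(levels, n_repeats))
  } else {
    unlist(lapply(seq_len(n_repeats), function(i) sample(levels)))
  }
  times <- lead_in_s + (seq_along(labels) - 1L) * isi_ms / 1000
  structure(list(event_time_s = times, itd_us = labels,
                 levels_us = levels, isi_ms = isi_ms),
            class = "trial_schedule")
}

# Canonical biphasic extracellular spike template: 1.2 ms, sharp negative
# deflection followed by a slower positive rebound, unit peak magnitude.
spike_template <- function(fs, dur_ms = 1.2) {
  n <- max(3L, round(dur_ms / 1000 * fs))
  t <- seq(0, 1, length.out = n)
  w <- -sin(2 * pi * t) * exp(-3 * t)       # biphasic, decaying
  w / max(abs(w))
}

#' Simulate an extracellular IC recording with known ITD tuning
#'
#' Generates a raw voltage trace emulating a multi-unit recording during an
#' ITD tuning-curve protocol.  Spikes are drawn from an inhomogeneous
#' Poisson process: within each stimulus' response window the rate is
#' \code{tuning_rate(tuning, itd)}; elsewhere it is the baseline rate.  Each
#' spike adds a biphasic 1.2 ms template (amplitude jittered +/-20%) to
#' white Gaussian noise.  The first 2.5 ms after every stimulus onset carry
#' a large decaying artifact-like transient so that downstream artifact
#' blanking is exercised.  The ground truth (tuning function, schedule and
#' spike times) is retained in the returned block.
#'
#' @param tuning A [tuning_function()].
#' @param schedule A [make_trial_schedule()] result.
#' @param sample_rate_hz Recording sample rate (Hz); default 24414.0625
#'   (24.414 kHz).
#' @param noise_sd Standard deviation of the white background noise.
#' @param snr Spike template peak amplitude in units of \code{noise_sd}.
#' @param artifact_amp Peak amplitude of the onset artifact transient, in
#'   units of \code{noise_sd}.
#' @param seed Integer seed; identical seeds give bit-identical traces.
#' @return Object of class \code{recording_block}: \code{trace} (numeric
#'   matrix, channels x samples), \code{sample_rate_hz},
#'   \code{event_time_s}, \code{event_itd_us} and a \code{ground_truth}
#'   list (\code{tuning}, \code{spike_times_s}, \code{schedule}).
#' @export
#' @examples
#' sched <- make_trial_schedule(n_repeats = 2, seed = 1)
#' rec <- simulate_recording(tuning_function("peak"), sched, seed = 1)
simulate_recording <- function(tuning, schedule,
                               sample_rate_hz = 24414.0625,
                               noise_sd = 1,
                               snr = 10,
                               artifact_amp = 30,
                               seed = 1) {
  stopifnot(inherits(tuning, "tuning_function"),
            inherits(schedule, "trial_schedule"),
            noise_sd > 0, snr >= 0)
  fs <- sample_rate_hz
  set.seed(as.integer(seed))
  dur_s <- max(schedule$event_time_s) + schedule$isi_ms / 1000
  n <- ceiling(dur_s * fs)
  trace <- stats::rnorm(n, sd = noise_sd)

  tmpl <- spike_template(fs) * snr * noise_sd
  win <- tuning$response_window_ms / 1000      # s post onset
  rates <- tuning_rate(tuning, schedule$itd_us)
  isi_s <- schedule$isi_ms / 1000

  spike_times <- vector("list", length(schedule$event_time_s) + 1L)
  # per event: driven spikes in the response window, baseline elsewhere in
  # the inter-stimulus interval
  for (i in seq_along(schedule$event_time_s)) {
    t0 <- schedule$event_time_s[i]
    n_drv <- stats::rpois(1, rates[i] * (win[2] - win[1]))
    drv <- t0 + win[1] + stats::runif(n_drv) * (win[2] - win[1])
    n_bas <- stats::rpois(1, tuning$base_rate_hz * isi_s)
    bas <- t0 + stats::runif(n_bas) * isi_s
    bas <- bas[bas < t0 + win[1] | bas > t0 + win[2]]  # thin response span
    spike_times[[i]] <- c(drv, bas)
  }
  # baseline spikes in the lead-in
  lead <- schedule$event_time_s[1]
  n_lead <- stats::rpois(1, tuning$base_rate_hz * lead)
  spike_times[[length(spike_times)]] <- stats::runif(n_lead) * lead
  spike_times <- sort(unlist(spike_times))

  for (st in spike_times) {
    i0 <- floor(st * fs) + 1L
    idx <- seq.int(i0, length.out = length(tmpl))
    keep <- idx <= n
    amp <- stats::runif(1, 0.8, 1.2)          # +/-20% amplitude jitter
    trace[idx[keep]] <- trace[idx[keep]] + amp * tmpl[keep]
  }

  # artifact-like transient: damped alternating spike in the first 2.5 ms
  art_n <- round(0.0025 * fs)
  art <- artifact_amp * noise_sd *
    cos(2 * pi * 2000 * seq_len(art_n) / fs) *
    exp(-seq_len(art_n) / (0.0005 * fs))
  for (t0 in schedule$event_time_s) {
    i0 <- floor(t0 * fs) + 1L
    idx <- seq.int(i0, length.out = art_n)
    keep <- idx <= n
    trace[idx[keep]] <- trace[idx[keep]] + art[keep]
  }

  structure(list(trace = matrix(trace, nrow = 1),
                 sample_rate_hz = fs,
                 event_time_s = schedule$event_time_s,
                 event_itd_us = schedule$itd_us,
                 ground_truth = list(tuning = tuning,
                                     spike_times_s = spike_times,
                                     schedule = schedule)),
            class = "recording_block")
}

#' @export
print.recording_block <- function(x, ...) {
  cat(sprintf(
    "Recording block: %d channel(s), %d samples at %.6g Hz (%.3g s)\n",
    nrow(x$trace), ncol(x$trace), x$sample_rate_hz,
    ncol(x$trace) / x$sample_rate_hz))
  cat(sprintf("  %d events, %d ITD levels\n", length(x$event_time_s),
              length(unique(x$event_itd_us))))
  if (!is.null(x$ground_truth$tuning))
    cat("  ground truth:", x$ground_truth$tuning$shape, "tuning, depth",
        x$ground_truth$tuning$depth, "\n")
  invisible(x)
}
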