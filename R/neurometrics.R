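#' AMUA filter configuration
#'
#' Parameters of the analog multi-unit activity chain: band-pass the raw
#' trace into the spike band (300 Hz - 6 kHz), full-wave rectify, then
#' low-pass (6 kHz) to smooth the rectified signal.  Filters are Butterworth
#' of the given order, applied forward-backward (zero phase) by default so
#' analysis windows stay aligned with stimulus onsets.
#'
#' @param bp_low_hz,bp_high_hz Band-pass corner frequencies (Hz).
#' @param lp_hz Post-rectification low-pass corner (Hz).
#' @param filter_order Butterworth order (default 4).
#' @param zero_phase Apply filters forward-backward (default TRUE).
#' @return Object of class \code{amua_config}.
#' @export
amua_config <- function(bp_low_hz = 300, bp_high_hz = 6000, lp_hz = 6000,
                        filter_order = 4, zero_phase = TRUE) {
  stopifnot(bp_low_hz > 0, bp_high_hz > bp_low_hz, lp_hz > 0,
            filter_order >= 1)
  structure(list(bp_low_hz = bp_low_hz, bp_high_hz = bp_high_hz,
                 lp_hz = lp_hz, filter_order = as.integer(filter_order),
                 zero_phase = zero_phase),
            class = "amua_config")
}

apply_filt <- function(filt, x, zero_phase) {
  if (zero_phase) signal::filtfilt(filt, x)
  else as.numeric(signal::filter(filt, x))
}

bandpass_trace <- function(trace, fs, config) {
  nyq <- fs / 2
  hi <- config$bp_high_hz
  if (hi >= nyq) {
    hi <- 0.99 * nyq
    warning("bp_high_hz at or above Nyquist; clipped to ",
            format(hi), " Hz")
  }
  bp <- signal::butter(config$filter_order,
                       c(config$bp_low_hz, hi) / nyq, type = "pass")
  apply_filt(bp, trace, config$zero_phase)
}

#' Analog multi-unit activity (AMUA) of a voltage trace
#'
#' Computes the AMUA signal at the native sample rate: band-pass into the
#' spike band, take the absolute value, low-pass.  The AMUA amplitude is a
#' spike-density proxy that is robust to spike collisions and
#' sometimes-subthreshold spikes, and it scales linearly with the input
#' (homogeneity of linear filters and rectification).
#'
#' @param trace Numeric vector (one channel).
#' @param fs Sample rate in Hz.
#' @param config An [amua_config()].
#' @return Numeric AMUA vector, same length as the input; non-negative up
#'   to filter ringing (the minimum is reported in attribute
#'   \code{min_value}).
#' @export
compute_amua <- function(trace, fs, config = amua_config()) {
  stopifnot(is.numeric(trace), fs > 0, inherits(config, "amua_config"))
  warmup <- 3 * (2 * config$filter_order + 1)
  if (length(trace) <= warmup)
    stop("trace shorter than filter warm-up (", warmup, " samples)")
  rect <- abs(bandpass_trace(trace, fs, config))
  nyq <- fs / 2
  lp_hz <- min(config$lp_hz, 0.99 * nyq)
  lp <- signal::butter(config$filter_order, lp_hz / nyq, type = "low")
  out <- apply_filt(lp, rect, config$zero_phase)
  attr(out, "min_value") <- min(out)
  out
}

#' Detect multi-unit spikes by threshold crossing
#'
#' Band-passes the trace into the spike band and marks times where the
#' signal magnitude first exceeds \code{k_sd} standard deviations of the
#' band-passed signal (crossings of either polarity).  Crossings closer
#' together than the refractory span are merged into the first one.  The SD
#' is estimated on the whole band-passed trace, optionally excluding
#' blanked artifact spans.
#'
#' @param trace Numeric vector (one channel), at least 100 ms long.
#' @param fs Sample rate (Hz).
#' @param config An [amua_config()] (its band-pass settings are used).
#' @param k_sd Threshold in SD units (default 4).
#' @param refractory_ms Merge window in ms (default 1).
#' @param exclude_spans_s Optional two-column matrix of (start, end) times
#'   in seconds excluded from the SD estimate (e.g. stimulus artifacts).
#' @return Numeric vector of spike times in seconds.
#' @export
detect_spikes <- function(trace, fs, config = amua_config(), k_sd = 4,
                          refractory_ms = 1, exclude_spans_s = NULL) {
  stopifnot(is.numeric(trace), fs > 0)
  if (length(trace) < 0.1 * fs)
    stop("trace shorter than 100 ms; SD estimate unreliable")
  if (stats::sd(trace) == 0)
    stop("zero-variance trace: cannot set spike threshold")
  bp <- bandpass_trace(trace, fs, config)
  keep <- rep(TRUE, length(bp))
  if (!is.null(exclude_spans_s)) {
    spans <- matrix(exclude_spans_s, ncol = 2)
    for (i in seq_len(nrow(spans))) {
      i0 <- max(1L, floor(spans[i, 1] * fs) + 1L)
      i1 <- min(length(bp), ceiling(spans[i, 2] * fs))
      if (i1 >= i0) keep[i0:i1] <- FALSE
    }
  }
  sd_bp <- stats::sd(bp[keep])
  if (!is.finite(sd_bp) || sd_bp == 0)
    stop("zero-variance trace: cannot set spike threshold")
  above <- abs(bp) >= k_sd * sd_bp
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  if (length(onsets) == 0L) return(numeric(0))
  # refractory merge: drop crossings within refractory_ms of the kept one
  ref_n <- refractory_ms / 1000 * fs
  kept <- onsets[1]
  last <- onsets[1]
  for (o in onsets[-1]) {
    if (o - last > ref_n) {
      kept <- c(kept, o)
      last <- o
    }
  }
  (kept - 1) / fs
}

#' Analysis windows for event-locked responses
#'
#' Default windows of the tuning-curve analysis: response 3-80 ms after
#' stimulus onset, baseline 300-500 ms after onset, with the first 2.5 ms
#' (dominated by electrical stimulus artifacts) blanked.
#'
#' @param response_ms Two-element (start, end) response window, ms post
#'   onset.
#' @param baseline_ms Two-element baseline window, ms post onset.
#' @param artifact_blank_ms Span blanked at onset (ms); must not extend past
#'   the response start into the analyzed span (the effective response
#'   start is \code{max(response_ms[1], artifact_blank_ms)}).
#' @return Object of class \code{analysis_windows}.
#' @export
analysis_windows <- function(response_ms = c(3, 80),
                             baseline_ms = c(300, 500),
                             artifact_blank_ms = 2.5) {
  stopifnot(length(response_ms) == 2, length(baseline_ms) == 2,
            response_ms[1] < response_ms[2],
            baseline_ms[1] < baseline_ms[2],
            response_ms[2] <= baseline_ms[1],
            artifact_blank_ms >= 0)
  structure(list(response_ms = as.numeric(response_ms),
                 baseline_ms = as.numeric(baseline_ms),
                 artifact_blank_ms = artifact_blank_ms),
            class = "analysis_windows")
}

#' Event-locked response matrix of a recording
#'
#' For every stimulus event, measures the response amplitude in the response
#' window (mean AMUA amplitude, or spike count from threshold crossings) and
#' the baseline amplitude in the baseline window, then groups responses by
#' ITD level.  The artifact blank is excluded from the response window.
#'
#' @param rec A \code{recording_block} (see [simulate_recording()] /
#'   [read_recording()]).
#' @param windows An [analysis_windows()].
#' @param measure "amua_mean" (default) or "spike_count".
#' @param config [amua_config()] used for filtering / spike detection.
#' @param channel Channel index (default 1).
#' @param k_sd Spike threshold for \code{measure = "spike_count"}.
#' @return Object of class \code{response_matrix}: \code{values} (levels x
#'   repeats matrix), \code{baselines} (same shape), \code{itd_levels_us},
#'   \code{measure}, \code{n_dropped} (events too close to the trace end,
#'   dropped with a warning).  Ragged designs (unequal repeats after drops)
#'   are balanced by truncating every level to the smallest repeat count,
#'   with a warning.
#' @export
build_response_matrix <- function(rec, windows = analysis_windows(),
                                  measure = c("amua_mean", "spike_count"),
                                  config = amua_config(), channel = 1L,
                                  k_sd = 4) {
  measure <- match.arg(measure)
  stopifnot(inherits(rec, "recording_block"),
            inherits(windows, "analysis_windows"))
  fs <- rec$sample_rate_hz
  trace <- rec$trace[channel, ]
  resp0 <- max(windows$response_ms[1], windows$artifact_blank_ms) / 1000
  resp1 <- windows$response_ms[2] / 1000
  bas0 <- windows$baseline_ms[1] / 1000
  bas1 <- windows$baseline_ms[2] / 1000
  n <- length(trace)

  end_needed <- pmax(resp1, bas1)
  ok <- (rec$event_time_s + end_needed) * fs <= n
  n_dropped <- sum(!ok)
  if (n_dropped > 0)
    warning(n_dropped, " event(s) too close to the trace end; dropped")
  times <- rec$event_time_s[ok]
  labels <- rec$event_itd_us[ok]

  win_mean <- function(x, t0, a, b) {
    i0 <- floor((t0 + a) * fs) + 1L
    i1 <- floor((t0 + b) * fs)
    mean(x[i0:i1])
  }
  if (measure == "amua_mean") {
    amua <- compute_amua(trace, fs, config)
    resp <- vapply(times, function(t0) win_mean(amua, t0, resp0, resp1),
                   0.0)
    base <- vapply(times, function(t0) win_mean(amua, t0, bas0, bas1), 0.0)
  } else {
    blank_spans <- cbind(times, times + windows$artifact_blank_ms / 1000)
    st <- detect_spikes(trace, fs, config, k_sd = k_sd,
                        exclude_spans_s = blank_spans)
    count_in <- function(t0, a, b) sum(st >= t0 + a & st < t0 + b)
    resp <- vapply(times, function(t0) count_in(t0, resp0, resp1), 0L)
    base <- vapply(times, function(t0) count_in(t0, bas0, bas1), 0L)
  }

  levels <- sort(unique(labels))
  counts <- table(factor(labels, levels = levels))
  n_rep <- min(counts)
  if (length(unique(as.integer(counts))) > 1L)
    warning("unequal repeats across ITD levels; truncating to ", n_rep,
            " per level")
  values <- matrix(NA_real_, length(levels), n_rep)
  baselines <- matrix(NA_real_, length(levels), n_rep)
  for (j in seq_along(levels)) {
    idx <- which(labels == levels[j])[seq_len(n_rep)]
    values[j, ] <- resp[idx]
    baselines[j, ] <- base[idx]
  }
  structure(list(values = values, baselines = baselines,
                 itd_levels_us = levels, measure = measure,
                 n_dropped = n_dropped),
            class = "response_matrix")
}

#' Baseline-corrected, normalized ITD tuning curve
#'
#' Per-level mean response minus the mean baseline, normalized by the
#' maximum baseline-corrected mean across levels (so the curve peaks at 1
#' whenever any level exceeds baseline).  SEM per level is reported on the
#' same scales.
#'
#' @param matrix A \code{response_matrix} (see [build_response_matrix()]).
#' @return data.frame with columns \code{itd_us, mean, sem, norm_mean,
#'   norm_sem}; \code{mean} is the baseline-corrected per-level mean.  When
#'   no level exceeds baseline, normalization divides by the absolute
#'   maximum and attribute \code{all_below_baseline} is set.
#' @export
tuning_curve <- function(matrix) {
  stopifnot(inherits(matrix, "response_matrix"))
  base_mean <- mean(matrix$baselines)
  corrected <- matrix$values - base_mean
  m <- rowMeans(corrected)
  sem <- apply(corrected, 1, stats::sd) / sqrt(ncol(corrected))
  norm <- max(m)
  flag <- FALSE
  if (norm <= 0) {
    norm <- max(abs(m))
    flag <- TRUE
    if (norm == 0) stop("flat curve at baseline: cannot normalize")
  }
  out <- data.frame(itd_us = matrix$itd_levels_us, mean = m, sem = sem,
                    norm_mean = m / norm, norm_sem = sem / norm)
  attr(out, "all_below_baseline") <- flag
  out
}

stvr_from_groups <- function(values, groups) {
  grand <- mean(values)
  mg <- tapply(values, groups, mean)
  ng <- tapply(values, groups, length)
  k <- length(mg)
  ss_group <- sum(ng * (mg - grand)^2)
  ss_total <- sum((values - grand)^2)
  if (ss_total == 0) stop("zero total variance: STVR undefined")
  ss_within <- ss_total - ss_group
  df_b <- k - 1L
  df_w <- length(values) - k
  f <- (ss_group / df_b) / (ss_within / df_w)
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  structure(list(stvr = ss_group / ss_total,
                 ss_group = ss_group, ss_total = ss_total,
                 f_stat = f, p_value = p,
                 df_between = as.integer(df_b), df_within = as.integer(df_w),
                 significant = p <= 0.01),
            class = "stvr_result")
}

#' Signal-to-total variance ratio (STVR) of an ITD response matrix
#'
#' The STVR quantifies the strength of ITD tuning as the proportion of
#' trial-to-trial variance in response amplitude explained by stimulus ITD:
#' the between-level (group) sum of squares of a one-way ANOVA divided by
#' the total sum of squares.  It ranges from 0 (no effect of ITD) to 1
#' (responses completely determined by ITD); values above 0.5 are
#' conventionally read as good ITD sensitivity.  Significance is the
#' one-way ANOVA F test at \code{p <= 0.01}.  STVR is invariant under
#' affine rescaling of the responses, so window means and window sums give
#' identical values.
#'
#' @param matrix A \code{response_matrix}, a plain numeric matrix (rows =
#'   ITD levels, columns = repeats), or a numeric vector accompanied by
#'   \code{groups}.
#' @param groups Grouping vector (required when \code{matrix} is a vector).
#' @return Object of class \code{stvr_result}: \code{stvr},
#'   \code{ss_group}, \code{ss_total}, \code{f_stat}, \code{p_value},
#'   \code{df_between}, \code{df_within}, \code{significant}.
#' @export
#' @examples
#' compute_stvr(rbind(c(0, 2), c(4, 6)))  # stvr = 0.8
compute_stvr <- function(matrix, groups = NULL) {
  if (inherits(matrix, "response_matrix")) {
    values <- as.numeric(matrix$values)
    groups <- rep(seq_along(matrix$itd_levels_us), ncol(matrix$values))
  } else if (is.matrix(matrix)) {
    values <- as.numeric(matrix)
    groups <- rep(seq_len(nrow(matrix)), ncol(matrix))
  } else {
    stopifnot(!is.null(groups), length(groups) == length(matrix))
    values <- as.numeric(matrix)
  }
  groups <- as.integer(factor(groups))
  k <- length(unique(groups))
  if (k < 2) stop("need at least 2 ITD levels")
  if (any(tabulate(groups) < 2)) stop("need at least 2 repeats per level")
  stvr_from_groups(values, groups)
}

#' @export
print.stvr_result <- function(x, digits = 4, ...) {
  cat(sprintf("STVR = %.*g (F(%d, %d) = %.*g, p = %.3g)%s\n",
              digits, x$stvr, x$df_between, x$df_within, digits, x$f_stat,
              x$p_value,
              if (x$significant) "  [significant at p <= 0.01]" else ""))
  invisible(x)
}

#' @export
summary.stvr_result <- function(object, ...) {
  cat("One-way ANOVA of responses grouped by ITD\n")
  cat(sprintf("  SS(group) = %.6g, SS(total) = %.6g, SS(within) = %.6g\n",
              object$ss_group, object$ss_total,
              object$ss_total - object$ss_group))
  print(object, ...)
  invisible(object)
}

#' Permutation null distribution of the STVR
#'
#' Re-computes the STVR under random shuffles of the ITD labels, giving a
#' distribution-free companion to the parametric ANOVA p-value.  Under the
#' null the expected STVR is \code{(k - 1) / (N - 1)} (the expectation of
#' R-squared under exchangeability), about 0.031 for the 17-level x
#' 30-repeat design.
#'
#' @param matrix As in [compute_stvr()].
#' @param n_perm Number of permutations (a warning is raised below 100).
#' @param seed Integer seed.
#' @param groups Optional grouping vector for vector input.
#' @return List with \code{p_perm} (permutation p-value, add-one
#'   estimator), \code{observed} (the [compute_stvr()] result),
#'   \code{null_stvr} (the permuted values) and \code{null_quantiles}
#'   (5/50/95/99%).
#' @export
stvr_null_distribution <- function(matrix, n_perm = 1000, seed = 1,
                                   groups = NULL) {
  if (n_perm < 100) warning("n_perm < 100: permutation p is coarse")
  if (inherits(matrix, "response_matrix")) {
    values <- as.numeric(matrix$values)
    groups <- rep(seq_along(matrix$itd_levels_us), ncol(matrix$values))
  } else if (is.matrix(matrix)) {
    values <- as.numeric(matrix)
    groups <- rep(seq_len(nrow(matrix)), ncol(matrix))
  } else {
    stopifnot(!is.null(groups))
    values <- as.numeric(matrix)
  }
  obs <- compute_stvr(values, groups)
  set.seed(as.integer(seed))
  null_stvr <- vapply(seq_len(n_perm), function(i)
    stvr_from_groups(sample(values), groups)$stvr, 0.0)
  list(p_perm = (1 + sum(null_stvr >= obs$stvr)) / (n_perm + 1),
       observed = obs,
       null_stvr = null_stvr,
       null_quantiles = stats::quantile(null_stvr,
                                        c(0.05, 0.5, 0.95, 0.99)))
}
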