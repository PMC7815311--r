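#' Stimulus specification for binaural pulse-train stimuli
#'
#' Bundles the timing parameters of a sample-quantized binaural stimulus:
#' either a biphasic electric pulse train (clinical-style duty cycle) or an
#' acoustic click train (one-sample delta impulses).  ITDs are realized as
#' integer-sample delays of the lagging channel, so the achievable ITD grid is
#' set by the sample rate: one sample is 20.48 us at 48,828.125 Hz (electric)
#' and 20.83 us at 48,000 Hz (acoustic).
#'
#' The sign convention throughout the package is
#' \code{ITD = arrival time at left ear - arrival time at right ear}:
#' a positive ITD means the left arrival is later, i.e. the right ear leads,
#' so the generator delays the \emph{left} channel by
#' \code{round(itd_us * sample_rate_hz / 1e6)} samples; a negative ITD means
#' the left ear leads and the right channel is delayed.
#'
#' @param sample_rate_hz Sample rate in Hz (48828.125 for the electric
#'   stimulator, 48000 for the acoustic rig).
#' @param pulse_rate_hz Pulse repetition rate in Hz (50 Hz in the
#'   lateralization task).
#' @param duration_ms Train duration in ms (200 ms in the task).  The pulse
#'   count is \code{floor(pulse_rate_hz * duration_ms / 1000)}.
#' @param amplitude Peak amplitude (unitless; current or DAC units).
#' @param phase_samples_pos,phase_samples_gap,phase_samples_neg Integer sample
#'   counts of the positive phase, inter-phase zero gap and negative phase of
#'   each biphasic pulse.  The defaults 3/2/3 at 48,828.125 Hz give the
#'   clinical duty cycle of 61.44 us positive, 40.96 us zero, 61.44 us
#'   negative.  Ignored by the click generator.
#' @param itd_us Requested interaural time difference in microseconds
#'   (signed; see sign convention above).
#'
#' @return An object of class \code{stimulus_spec} (a list with the fields
#'   above).
#' @seealso [make_biphasic_pulse_train()], [make_acoustic_click_train()],
#'   [quantize_itd()]
#' @export
#' @examples
#' spec <- stimulus_spec(itd_us = 20.48)
#' wave <- make_biphasic_pulse_train(spec)
stimulus_spec <- function(sample_rate_hz = 48828.125,
                          pulse_rate_hz = 50,
                          duration_ms = 200,
                          amplitude = 1,
                          phase_samples_pos = 3L,
                          phase_samples_gap = 2L,
                          phase_samples_neg = 3L,
                          itd_us = 0) {
  stopifnot(is.numeric(sample_rate_hz), length(sample_rate_hz) == 1L,
            sample_rate_hz > 0,
            is.numeric(pulse_rate_hz), pulse_rate_hz > 0,
            is.numeric(duration_ms), duration_ms > 0,
            is.numeric(itd_us), length(itd_us) == 1L)
  phases <- c(phase_samples_pos, phase_samples_gap, phase_samples_neg)
  if (any(phases < 0) || any(phases != round(phases)))
    stop("phase sample counts must be non-negative integers")
  structure(list(sample_rate_hz = sample_rate_hz,
                 pulse_rate_hz = pulse_rate_hz,
                 duration_ms = duration_ms,
                 amplitude = amplitude,
                 phase_samples_pos = as.integer(phase_samples_pos),
                 phase_samples_gap = as.integer(phase_samples_gap),
                 phase_samples_neg = as.integer(phase_samples_neg),
                 itd_us = itd_us),
            class = "stimulus_spec")
}

#' Quantize an ITD to the integer-sample grid of a device
#'
#' ITDs are delivered by delaying one channel by a whole number of samples, so
#' a requested ITD is rounded to the nearest achievable value.
#'
#' @param itd_us Requested ITD in microseconds (signed).
#' @param sample_rate_hz Device sample rate in Hz.
#' @return A list with \code{shift_samples} (signed integer,
#'   \code{round(itd_us * fs / 1e6)}) and \code{realized_itd_us}
#'   (\code{shift_samples * 1e6 / fs}).  The realized ITD is always within
#'   half a sample period of the request.
#' @export
#' @examples
#' quantize_itd(25, 48828.125)  # snaps to one sample = 20.48 us
quantize_itd <- function(itd_us, sample_rate_hz) {
  stopifnot(sample_rate_hz > 0)
  shift <- as.integer(round(itd_us * sample_rate_hz / 1e6))
  list(shift_samples = shift,
       realized_itd_us = shift * 1e6 / sample_rate_hz)
}

# Place one pulse shape at each epoch start of one channel, with an integer
# sample offset.  Offset samples that fall past the end are truncated.
place_pulses <- function(n_samples, epoch_starts, pulse, offset) {
  x <- numeric(n_samples)
  for (s in epoch_starts) {
    i0 <- s + offset
    idx <- seq.int(i0, length.out = length(pulse))
    keep <- idx >= 1L & idx <= n_samples
    x[idx[keep]] <- x[idx[keep]] + pulse[keep]
  }
  x
}

# Shared frame for both generators: epoch starts, channel offsets, checks.
binaural_frame <- function(spec, pulse_len_samples) {
  fs <- spec$sample_rate_hz
  n_samples <- floor(spec$duration_ms / 1000 * fs)
  n_pulses <- floor(spec$pulse_rate_hz * spec$duration_ms / 1000)
  if (n_samples < 1L || n_pulses < 1L)
    stop("zero-length stimulus: increase duration or pulse rate")
  q <- quantize_itd(spec$itd_us, fs)
  ipi_samples <- fs / spec$pulse_rate_hz
  if (abs(q$shift_samples) >= ipi_samples)
    stop("|ITD| exceeds one inter-pulse interval (",
         format(ipi_samples * 1e6 / fs), " us)")
  # positive ITD (left arrival minus right arrival > 0) = right ear leading,
  # so the left channel lags; epochs start at t = 0, 1/rate, 2/rate, ...
  starts <- 1L + as.integer(round((seq_len(n_pulses) - 1L) * ipi_samples))
  off_left <- max(q$shift_samples, 0L)
  off_right <- max(-q$shift_samples, 0L)
  list(n_samples = n_samples, starts = starts,
       off_left = off_left, off_right = off_right, quant = q)
}

new_binaural_waveform <- function(left, right, fs, spec, quant) {
  structure(list(left = left, right = right,
                 sample_rate_hz = fs,
                 itd_us_requested = spec$itd_us,
                 itd_us_realized = quant$realized_itd_us,
                 shift_samples = quant$shift_samples),
            class = "binaural_waveform")
}

#' Generate a binaural biphasic electric pulse train
#'
#' Builds the two-channel sample sequence of a charge-balanced biphasic pulse
#' train (positive phase, zero gap, negative phase per pulse) carrying the
#' requested ITD as an integer-sample delay of the lagging channel.  Both
#' channels contain pulses of identical shape and amplitude, so the stimulus
#' carries no interaural level cue (see [compute_rms_ild()]).
#'
#' @param spec A [stimulus_spec()].
#' @return A \code{binaural_waveform}: list with \code{left}, \code{right}
#'   (equal-length numeric vectors), \code{sample_rate_hz},
#'   \code{itd_us_requested}, \code{itd_us_realized} and
#'   \code{shift_samples}.
#' @export
#' @examples
#' w <- make_biphasic_pulse_train(stimulus_spec(itd_us = 0))
#' identical(w$left, w$right)  # TRUE: zero ITD is bit-identical
make_biphasic_pulse_train <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  pulse <- spec$amplitude * c(rep(1, spec$phase_samples_pos),
                              rep(0, spec$phase_samples_gap),
                              rep(-1, spec$phase_samples_neg))
  if (length(pulse) == 0L) stop("pulse shape has zero samples")
  fr <- binaural_frame(spec, length(pulse))
  left <- place_pulses(fr$n_samples, fr$starts, pulse, fr$off_left)
  right <- place_pulses(fr$n_samples, fr$starts, pulse, fr$off_right)
  new_binaural_waveform(left, right, spec$sample_rate_hz, spec, fr$quant)
}

#' Generate a binaural acoustic click train
#'
#' Each pulse epoch carries a single-sample unit impulse (a digital delta
#' "click"); the ITD is applied as an integer-sample delay of the lagging
#' channel.  Tube or transducer coloration is not modeled: clicks are ideal
#' impulses.
#'
#' @inheritParams make_biphasic_pulse_train
#' @return A \code{binaural_waveform}; see [make_biphasic_pulse_train()].
#' @export
#' @examples
#' w <- make_acoustic_click_train(stimulus_spec(sample_rate_hz = 48000,
#'                                              itd_us = 20.83))
#' w$shift_samples       # 1
make_acoustic_click_train <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  pulse <- spec$amplitude
  fr <- binaural_frame(spec, 1L)
  left <- place_pulses(fr$n_samples, fr$starts, pulse, fr$off_left)
  right <- place_pulses(fr$n_samples, fr$starts, pulse, fr$off_right)
  new_binaural_waveform(left, right, spec$sample_rate_hz, spec, fr$quant)
}

#' @export
print.binaural_waveform <- function(x, ...) {
  cat("Binaural waveform:", length(x$left), "samples/channel at",
      x$sample_rate_hz, "Hz\n")
  cat(sprintf("  ITD requested %.4g us, realized %.4g us (%d-sample shift)\n",
              x$itd_us_requested, x$itd_us_realized, x$shift_samples))
  invisible(x)
}

#' Residual interaural level difference of a binaural waveform
#'
#' Computes the level difference between the two channels as the difference in
#' root-mean-square power, \code{20 * log10(rms(left) / rms(right))} dB.
#' Positive values mean the left channel is louder.  For equal-amplitude
#' pulse trains at any ITD this is exactly 0 dB, which is the point: ITD
#' stimuli built by sample delays carry no level cue.
#'
#' @param wave A \code{binaural_waveform}.
#' @return Level difference in dB (scalar).
#' @export
compute_rms_ild <- function(wave) {
  stopifnot(inherits(wave, "binaural_waveform"))
  rms <- function(x) sqrt(mean(x^2))
  rl <- rms(wave$left); rr <- rms(wave$right)
  if (rl == 0 || rr == 0)
    stop("RMS ILD undefined: a channel is all-zero")
  20 * log10(rl / rr)
}
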