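#' Ground-truth psychometric model parameters
#'
#' The four-parameter cumulative-Gaussian model of the probability of a
#' "right" response in a 2AFC lateralization trial:
#' \deqn{p_R = \Phi(ITD \cdot \alpha + \beta)(1 - \gamma) + \gamma/2 + \delta}
#' with ITD in ms, \eqn{\Phi} the standard normal CDF, \eqn{\alpha} the
#' sensitivity (1/ms), \eqn{\beta} an ear bias (argument offset: the subject
#' hears the midline at a non-zero ITD), \eqn{\gamma \in [0,1]} the lapse
#' rate (fraction of trials answered by guessing) and \eqn{\delta} a spout
#' bias (additive preference for the right response spout).
#'
#' @param alpha_per_ms Sensitivity \eqn{\alpha} in 1/ms.
#' @param beta Ear bias \eqn{\beta} (unitless argument offset).
#' @param gamma Lapse rate \eqn{\gamma} in \[0, 1\].
#' @param delta Spout bias \eqn{\delta} (probability offset).
#' @return An object of class \code{psych_model}.
#' @export
#' @examples
#' m <- psych_model(alpha_per_ms = 12.53)
#' response_probability(m, itd_us = c(-150, 0, 150))
psych_model <- function(alpha_per_ms, beta = 0, gamma = 0, delta = 0) {
  stopifnot(is.numeric(alpha_per_ms), is.numeric(beta),
            is.numeric(gamma), gamma >= 0, gamma <= 1,
            is.numeric(delta))
  structure(list(alpha_per_ms = alpha_per_ms, beta = beta,
                 gamma = gamma, delta = delta),
            class = "psych_model")
}

#' @export
print.psych_model <- function(x, ...) {
  cat(sprintf(
    "Psychometric model: alpha = %.4g /ms, beta = %.4g, gamma = %.4g, delta = %.4g\n",
    x$alpha_per_ms, x$beta, x$gamma, x$delta))
  invisible(x)
}

# Core of Eq-style model; itd in ms.  Returns probabilities clamped to [0,1]
# with attribute "clamped" when the raw value left the unit interval (only
# possible through delta).
psych_prob_ms <- function(itd_ms, alpha, beta, gamma, delta) {
  p <- stats::pnorm(itd_ms * alpha + beta) * (1 - gamma) + gamma / 2 + delta
  clamped <- any(p < 0 | p > 1)
  p <- pmin(pmax(p, 0), 1)
  attr(p, "clamped") <- clamped
  p
}

#' Probability of a "right" response at a given ITD
#'
#' Evaluates the four-parameter psychometric model (see [psych_model()]) at
#' the given ITDs.  ITD is taken in microseconds (the unit of trial logs) and
#' converted to ms internally, matching the 1/ms unit of \eqn{\alpha}.
#'
#' @param model A [psych_model()].
#' @param itd_us ITD(s) in microseconds; positive = right ear leading.
#' @return Vector of probabilities in \[0, 1\].  If the spout bias pushed the
#'   raw value outside the unit interval the result carries attribute
#'   \code{clamped = TRUE}.
#' @export
response_probability <- function(model, itd_us) {
  stopifnot(inherits(model, "psych_model"))
  psych_prob_ms(itd_us / 1000, model$alpha_per_ms, model$beta,
                model$gamma, model$delta)
}

#' Default behavioral ITD set
#'
#' The lateralization task draws each fresh stimulus uniformly from a fixed
#' set of ITDs spanning +/-160 us in 25 us steps.  Because 160 is not a
#' multiple of 25, the set honors both the step and the endpoints:
#' 0, +/-25, ..., +/-150, +/-160 us (15 levels).  Fully configurable
#' wherever it is consumed.
#'
#' @return Sorted numeric vector of ITDs in microseconds.
#' @export
default_behavior_itd_set <- function() {
  sort(c(0, c(-1, 1) %o% c(seq(25, 150, by = 25), 160)))
}

#' Simulate a 2AFC lateralization session with correction trials
#'
#' Generates a trial log from a known ground-truth model.  After each correct
#' trial a new ITD is drawn uniformly at random from \code{itd_set}; after an
#' incorrect trial the same ITD is repeated as a correction trial
#' (\code{is_correction = TRUE}) until answered correctly (optionally capped).
#' Responses are Bernoulli draws with p from [response_probability()].
#'
#' Side mapping: positive ITD (right ear leading) is reinforced at the right
#' spout; at ITD = 0 the rewarded side is drawn uniformly per trial, so the
#' zero point is uninformative about bias in expectation.  Correction trials
#' are part of the log but must be excluded from psychometric analysis
#' ([filter_analysis_trials()]): they are predictable from the previous
#' outcome and would bias the fit.
#'
#' @param model A [psych_model()] (the ground truth).
#' @param itd_set ITD levels in microseconds to sample from.
#' @param n_trials Total number of trials to generate (corrections included).
#' @param seed Integer seed; identical inputs reproduce identical logs.
#' @param session_id Identifier stored with every trial.
#' @param max_corrections Cap on consecutive correction trials at one ITD;
#'   \code{Inf} (default) repeats until correct.
#' @return A data.frame of class \code{trial_log} with columns
#'   \code{session_id}, \code{trial_index} (0-based), \code{itd_us},
#'   \code{response} ("L"/"R"), \code{correct}, \code{is_correction},
#'   \code{seed}.
#' @export
#' @examples
#' log <- simulate_session(psych_model(12.53), n_trials = 200, seed = 1)
#' head(log)
simulate_session <- function(model,
                             itd_set = default_behavior_itd_set(),
                             n_trials,
                             seed,
                             session_id = "sim",
                             max_corrections = Inf) {
  stopifnot(inherits(model, "psych_model"),
            length(itd_set) >= 1L, n_trials >= 1L)
  set.seed(as.integer(seed))
  itd <- numeric(n_trials)
  response <- character(n_trials)
  correct <- logical(n_trials)
  is_corr <- logical(n_trials)
  cur_itd <- sample(itd_set, 1L)
  pending_correction <- FALSE
  n_consec <- 0L
  for (i in seq_len(n_trials)) {
    itd[i] <- cur_itd
    is_corr[i] <- pending_correction
    p_right <- response_probability(model, cur_itd)
    resp_right <- stats::runif(1) < p_right
    response[i] <- if (resp_right) "R" else "L"
    # rewarded side: sign of ITD; coin flip at exactly zero
    rewarded_right <- if (cur_itd > 0) TRUE
                      else if (cur_itd < 0) FALSE
                      else stats::runif(1) < 0.5
    correct[i] <- resp_right == rewarded_right
    if (correct[i] || n_consec >= max_corrections) {
      # next trial is a fresh draw (also when the correction cap is hit)
      cur_itd <- sample(itd_set, 1L)
      pending_correction <- FALSE
      n_consec <- 0L
    } else {
      pending_correction <- TRUE
      n_consec <- n_consec + 1L
    }
  }
  out <- data.frame(session_id = session_id,
                    trial_index = seq_len(n_trials) - 1L,
                    itd_us = itd,
                    response = response,
                    correct = correct,
                    is_correction = is_corr,
                    seed = seed,
                    stringsAsFactors = FALSE)
  class(out) <- c("trial_log", "data.frame")
  out
}

#' Drop correction trials from a trial log
#'
#' Correction trials repeat the previous (incorrectly answered) stimulus and
#' can be answered by a "change side after a mistake" strategy, so the
#' psychometric analysis uses only non-correction trials.  Order is
#' preserved.
#'
#' @param log A trial log (data.frame with an \code{is_correction} column).
#' @return The subset with \code{is_correction == FALSE}.
#' @export
filter_analysis_trials <- function(log) {
  stopifnot(is.data.frame(log), "is_correction" %in% names(log))
  out <- log[!as.logical(log$is_correction), , drop = FALSE]
  rownames(out) <- NULL
  out
}
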