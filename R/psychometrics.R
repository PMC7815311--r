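#' Wilson score confidence interval for a binomial proportion
#'
#' @param k Number of successes (vectorized).
#' @param n Number of trials (> 0).
#' @param conf Confidence level in (0, 1); default 0.95.
#' @return A data.frame with columns \code{lower} and \code{upper};
#'   \code{0 <= lower <= k/n <= upper <= 1}.
#' @export
#' @examples
#' wilson_interval(15, 20)
wilson_interval <- function(k, n, conf = 0.95) {
  stopifnot(all(n >= 1), all(k >= 0), all(k <= n),
            conf > 0, conf < 1)
  z <- stats::qnorm((1 + conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- (z / denom) * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  data.frame(lower = pmax(0, center - half), upper = pmin(1, center + half))
}

#' Per-ITD response proportions with Wilson intervals
#'
#' Aggregates a trial log (corrections excluded) into one row per distinct
#' ITD: trial count, "right"-response count, proportion and its Wilson score
#' interval.
#'
#' @param trials Trial log data.frame with columns \code{itd_us} and
#'   \code{response} ("L"/"R"); correction trials should be removed first
#'   (see [filter_analysis_trials()]).
#' @param conf Confidence level for the Wilson intervals.
#' @return data.frame with columns \code{itd_us, n, k, p_hat, lower, upper},
#'   sorted by ITD.
#' @export
proportions_by_itd <- function(trials, conf = 0.95) {
  stopifnot(is.data.frame(trials))
  if (nrow(trials) == 0L)
    return(data.frame(itd_us = numeric(0), n = integer(0), k = integer(0),
                      p_hat = numeric(0), lower = numeric(0),
                      upper = numeric(0)))
  if ("is_correction" %in% names(trials) && any(as.logical(trials$is_correction)))
    warning("trial log contains correction trials; ",
            "filter_analysis_trials() before aggregating")
  r <- trials$response == "R"
  n <- tapply(r, trials$itd_us, length)
  k <- tapply(r, trials$itd_us, sum)
  itd <- as.numeric(names(n))
  o <- order(itd)
  ci <- wilson_interval(as.integer(k[o]), as.integer(n[o]), conf)
  data.frame(itd_us = itd[o], n = as.integer(n[o]), k = as.integer(k[o]),
             p_hat = as.numeric(k[o] / n[o]),
             lower = ci$lower, upper = ci$upper, row.names = NULL)
}

# Bernoulli negative log-likelihood of the 4-parameter model on a trial log.
# theta = c(alpha_per_ms, beta, gamma, delta); itd in ms, r logical "right".
# Probabilities are clamped to [eps, 1 - eps] so separable data stay finite.
nll_theta <- function(theta, itd_ms, r, eps = 1e-9) {
  p <- psych_prob_ms(itd_ms, theta[1], theta[2], theta[3], theta[4])
  p <- pmin(pmax(as.numeric(p), eps), 1 - eps)
  -sum(r * log(p) + (1 - r) * log1p(-p))
}

#' Negative log-likelihood of a psychometric model on a trial log
#'
#' Bernoulli likelihood, one term per trial:
#' \eqn{-\sum_i [r_i \log p_R + (1 - r_i)\log(1 - p_R)]} with \eqn{r_i = 1}
#' for a "right" response.  Probabilities are clamped to
#' \code{[1e-9, 1 - 1e-9]}; if clamping occurred the result carries
#' attribute \code{clamped = TRUE}.  Correction trials must be excluded
#' beforehand (a warning is raised otherwise).
#'
#' @param model A [psych_model()] (or a \code{psychfit}).
#' @param trials Trial log with \code{itd_us} and \code{response}.
#' @return Scalar negative log-likelihood.
#' @export
neg_log_likelihood <- function(model, trials) {
  if (inherits(model, "psychfit")) model <- model$model
  stopifnot(inherits(model, "psych_model"), is.data.frame(trials),
            nrow(trials) > 0L)
  if ("is_correction" %in% names(trials) && any(as.logical(trials$is_correction)))
    warning("trial log contains correction trials")
  theta <- c(model$alpha_per_ms, model$beta, model$gamma, model$delta)
  itd_ms <- trials$itd_us / 1000
  r <- as.numeric(trials$response == "R")
  p_raw <- psych_prob_ms(itd_ms, theta[1], theta[2], theta[3], theta[4])
  val <- nll_theta(theta, itd_ms, r)
  if (!is.finite(val)) stop("non-finite negative log-likelihood")
  attr(val, "clamped") <- any(p_raw < 1e-9 | p_raw > 1 - 1e-9)
  val
}

# Deterministic multi-start set on the standardized ITD axis (itd_z =
# itd_ms / scale, so a "typical" sensitivity is order 1): heuristic
# probit-regression start plus fixed alternates spanning low/high
# sensitivity and lapse regimes.
fit_starts <- function(props, itd_z_levels, alpha_z_max) {
  alpha0 <- 2; beta0 <- 0
  fit <- tryCatch(
    suppressWarnings(
      stats::glm(cbind(k, n - k) ~ z,
                 family = stats::binomial(link = "probit"),
                 data = data.frame(k = props$k, n = props$n,
                                   z = itd_z_levels))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    if (all(is.finite(cf))) {
      alpha0 <- min(max(cf[["z"]], 0), alpha_z_max)
      beta0 <- min(max(cf[["(Intercept)"]], -5), 5)
    }
  }
  rbind(c(alpha0, beta0, 0.02, 0),
        c(alpha0 * 0.5, beta0, 0.1, 0),
        c(min(alpha0 * 2, alpha_z_max), beta0, 0.02, 0),
        c(0.5, 0, 0.05, 0),
        c(4, 0, 0.2, 0.05),
        c(0.1, 0, 0.3, -0.05))
}

#' Fit the four-parameter psychometric model by maximum likelihood
#'
#' Fits \eqn{p_R = \Phi(ITD \cdot \alpha + \beta)(1-\gamma) + \gamma/2 +
#' \delta} to a 2AFC trial log by minimizing the Bernoulli negative
#' log-likelihood with multi-start box-constrained quasi-Newton optimization
#' (L-BFGS-B; one start from a heuristic probit regression on per-level
#' proportions, the rest from a fixed grid of alternates).  Box constraints
#' keep the model valid: \eqn{\gamma \in [0, 0.5]},
#' \eqn{\delta \in [-0.3, 0.3]}, \eqn{\alpha \in [0, \alpha_{max}]} with the
#' default \eqn{\alpha_{max}} chosen so a single hardware ITD step
#' (20.48 us) can span the whole curve.  The fit is invariant to trial order
#' and deterministic for a given log.
#'
#' @param trials Trial log data.frame (columns \code{itd_us},
#'   \code{response}; optionally \code{is_correction}).
#' @param exclude_corrections Drop correction trials before fitting
#'   (default TRUE; they are predictable from the previous outcome).
#' @param alpha_max Upper box constraint on \eqn{\alpha} (1/ms).
#' @param conf Confidence level for the per-ITD Wilson intervals in the
#'   report.
#' @return An object of class \code{psychfit}: the fitted [psych_model()],
#'   \code{neg_log_likelihood}, \code{converged}, \code{boundary} (TRUE when
#'   a parameter sits on its box constraint, e.g. separable data pushing
#'   \eqn{\alpha} to \eqn{\alpha_{max}}), \code{n_trials_used}, the per-ITD
#'   proportion table, and derived \code{slope_pct_per_us},
#'   \code{threshold75_us} with crossing points (see [slope_at_zero()],
#'   [threshold75()]).
#' @seealso [slope_at_zero()], [threshold75()], [proportions_by_itd()]
#' @export
#' @examples
#' log <- simulate_session(psych_model(12.53), n_trials = 1500, seed = 7)
#' fit <- fit_psychometric(log)
#' coef(fit)
#' summary(fit)
fit_psychometric <- function(trials, exclude_corrections = TRUE,
                             alpha_max = 300, conf = 0.95) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0L)
  if (exclude_corrections && "is_correction" %in% names(trials))
    trials <- filter_analysis_trials(trials)
  if (length(unique(trials$itd_us)) < 2L)
    stop("need at least 2 distinct ITD levels to fit")
  props <- proportions_by_itd(trials, conf)
  itd_ms <- trials$itd_us / 1000
  r <- as.numeric(trials$response == "R")
  degenerate <- all(r == 1) || all(r == 0)
  nz <- itd_ms != 0
  separable <- any(nz) && all(r[nz] == (itd_ms[nz] > 0))

  # standardize the ITD axis so the optimizer sees an O(1) problem and the
  # result is exactly invariant to the unit the log was expressed in
  scale <- max(abs(itd_ms))
  if (scale == 0) stop("all trials at zero ITD")
  itd_z <- itd_ms / scale
  lower <- c(0, -5, 0, -0.3)
  upper <- c(alpha_max * scale, 5, 0.5, 0.3)
  starts <- fit_starts(props, props$itd_us / 1000 / scale, upper[1])
  best <- NULL
  any_conv <- FALSE
  for (s in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(starts[s, ], nll_theta, itd_ms = itd_z, r = r,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  theta <- best$par
  on_boundary <- any(abs(theta - lower) < 1e-8 & lower != 0 |
                     abs(theta - upper) < 1e-8) ||
                 theta[1] >= upper[1] - 1e-6
  model <- psych_model(theta[1] / scale, theta[2], theta[3], theta[4])
  fit <- structure(list(model = model,
                        neg_log_likelihood = best$value,
                        converged = any_conv,
                        boundary = on_boundary || degenerate || separable,
                        n_trials_used = nrow(trials),
                        proportions = props,
                        conf = conf,
                        trials = trials),
                   class = "psychfit")
  fit$slope_pct_per_us <- slope_at_zero(fit)
  thr <- threshold75(fit)
  fit$threshold75_us <- thr$threshold75_us
  fit$itd25_us <- thr$itd25_us
  fit$itd75_us <- thr$itd75_us
  fit$threshold_defined <- thr$defined
  fit
}

#' Psychometric slope at zero ITD
#'
#' The sensitivity summary of a fitted curve: the derivative of the
#' cumulative-Gaussian component at ITD = 0,
#' \eqn{slope = \varphi(0)\,\alpha\,(1-\gamma)} in 1/ms, reported in percent
#' "right" per microsecond (divide by 10).  Following the published
#' convention the density is evaluated at 0, not at the ear bias \eqn{\beta};
#' \code{exact = TRUE} instead evaluates \eqn{\varphi(\beta)\,\alpha\,
#' (1-\gamma)}, the true derivative of the fitted curve at ITD = 0.
#'
#' @param fit A \code{psychfit} or [psych_model()].
#' @param exact Use \eqn{\varphi(\beta)} instead of \eqn{\varphi(0)}.
#' @return Slope in % "right" per microsecond.
#' @export
slope_at_zero <- function(fit, exact = FALSE) {
  model <- if (inherits(fit, "psychfit")) fit$model else fit
  stopifnot(inherits(model, "psych_model"))
  at <- if (exact) model$beta else 0
  stats::dnorm(at) * model$alpha_per_ms * (1 - model$gamma) / 10
}

#' 75%-correct lateralization threshold
#'
#' Finds the ITDs at which the fitted curve crosses 25% and 75% "right"
#' responses (bisection-based root finding on +/-10 ms, tolerance 1e-4 ms)
#' and returns the mean of their absolute values.  If the lapse rate or
#' spout bias make either level unreachable (e.g. \eqn{\gamma = 0.6} caps
#' \eqn{p_R} at 0.7) the threshold is flagged undefined rather than raising
#' an error.
#'
#' @param fit A \code{psychfit} or [psych_model()].
#' @return List with \code{threshold75_us}, \code{itd25_us},
#'   \code{itd75_us} and logical \code{defined}; the numeric fields are
#'   \code{NA} when undefined.
#' @export
threshold75 <- function(fit) {
  model <- if (inherits(fit, "psychfit")) fit$model else fit
  stopifnot(inherits(model, "psych_model"))
  undefined <- list(threshold75_us = NA_real_, itd25_us = NA_real_,
                    itd75_us = NA_real_, defined = FALSE)
  p_at <- function(itd_ms)
    as.numeric(psych_prob_ms(itd_ms, model$alpha_per_ms, model$beta,
                             model$gamma, model$delta))
  lim <- c(p_at(-10), p_at(10))
  cross <- function(level) {
    f <- function(x) p_at(x) - level
    if (f(-10) * f(10) > 0) return(NA_real_)
    stats::uniroot(f, c(-10, 10), tol = 1e-4)$root * 1000  # -> us
  }
  i25 <- cross(0.25)
  i75 <- cross(0.75)
  if (is.na(i25) || is.na(i75)) return(undefined)
  list(threshold75_us = (abs(i25) + abs(i75)) / 2,
       itd25_us = i25, itd75_us = i75, defined = TRUE)
}

#' Compare psychometric slopes between two groups (Wilcoxon)
#'
#' Nonparametric comparison of two sets of slopes (or thresholds): by
#' default the paired signed-rank test, with the unpaired rank-sum test via
#' \code{paired = FALSE}.  Exact p-values are used whenever the sample size
#' permits and there are no ties; zero differences are dropped (Wilcoxon's
#' original convention), ties are mid-ranked with the normal approximation.
#' Two identical paired lists therefore give p = 1 by convention.
#'
#' @param slopes_a,slopes_b Numeric vectors (equal length when paired).
#' @param paired Paired signed-rank (default) or unpaired rank-sum.
#' @return List with \code{statistic}, \code{p_value}, \code{method},
#'   \code{n_used} (pairs after zero-dropping, or group sizes), and group
#'   medians and means.
#' @export
#' @examples
#' compare_groups(c(.66, .37, .36, 1.37, .52), c(.49, .46, .35, 1.5, .44))
compare_groups <- function(slopes_a, slopes_b, paired = TRUE) {
  stopifnot(length(slopes_a) >= 2, length(slopes_b) >= 2)
  summ <- list(median_a = stats::median(slopes_a),
               median_b = stats::median(slopes_b),
               mean_a = mean(slopes_a), mean_b = mean(slopes_b))
  if (paired) {
    stopifnot(length(slopes_a) == length(slopes_b))
    d <- slopes_a - slopes_b
    d <- d[d != 0]
    if (length(d) == 0L)
      return(c(list(statistic = 0, p_value = 1,
                    method = "Wilcoxon signed rank (all differences zero)",
                    n_used = 0L), summ))
    ht <- stats::wilcox.test(d)
    c(list(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = ht$method, n_used = length(d)), summ)
  } else {
    ht <- stats::wilcox.test(slopes_a, slopes_b)
    c(list(statistic = unname(ht$statistic), p_value = ht$p.value,
           method = ht$method,
           n_used = c(length(slopes_a), length(slopes_b))), summ)
  }
}

# ---- psychfit methods -----------------------------------------------------

#' @export
coef.psychfit <- function(object, ...) {
  m <- object$model
  c(alpha_per_ms = m$alpha_per_ms, beta = m$beta,
    gamma = m$gamma, delta = m$delta)
}

#' @export
logLik.psychfit <- function(object, ...) {
  val <- -object$neg_log_likelihood
  attr(val, "df") <- 4L
  attr(val, "nobs") <- object$n_trials_used
  class(val) <- "logLik"
  val
}

#' @export
print.psychfit <- function(x, digits = 4, ...) {
  cat("Psychometric fit (cumulative Gaussian with lapse and biases)\n")
  print(coef(x), digits = digits)
  cat(sprintf("slope at 0 ITD: %.*g %%/us; 75%% threshold: %s us\n",
              digits, x$slope_pct_per_us,
              if (isTRUE(x$threshold_defined))
                format(x$threshold75_us, digits = digits) else "undefined"))
  cat(sprintf("n = %d non-correction trials; -logLik = %.*g%s\n",
              x$n_trials_used, digits, x$neg_log_likelihood,
              if (isTRUE(x$boundary)) " [boundary fit]" else ""))
  invisible(x)
}

#' @export
summary.psychfit <- function(object, ...) {
  structure(list(fit = object), class = "summary.psychfit")
}

#' @export
print.summary.psychfit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\nPer-ITD proportions (Wilson", format(100 * x$fit$conf),
      "% CI):\n")
  print(x$fit$proportions, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Predicted probability of a "right" response
#'
#' @param object A \code{psychfit}.
#' @param newdata Optional data.frame with an \code{itd_us} column, or a
#'   numeric vector of ITDs in microseconds; defaults to the fitted trials.
#' @param ... Unused.
#' @return Vector of predicted probabilities.
#' @export
predict.psychfit <- function(object, newdata = NULL, ...) {
  itd_us <- if (is.null(newdata)) object$trials$itd_us
            else if (is.data.frame(newdata)) newdata$itd_us
            else as.numeric(newdata)
  as.numeric(response_probability(object$model, itd_us))
}

#' @export
residuals.psychfit <- function(object, type = c("deviance", "response"),
                               ...) {
  type <- match.arg(type)
  r <- as.numeric(object$trials$response == "R")
  p <- predict(object)
  if (type == "response") return(r - p)
  eps <- 1e-12
  d2 <- -2 * (r * log(pmax(p, eps)) + (1 - r) * log(pmax(1 - p, eps)))
  sign(r - p) * sqrt(pmax(d2, 0))
}

#' Simulate responses from a fitted psychometric model
#'
#' Draws Bernoulli "right"/"left" responses at the fitted trials' ITDs
#' (parametric bootstrap draws from the fitted curve).
#'
#' @param object A \code{psychfit}.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return data.frame with one column per simulation of "L"/"R" characters.
#' @export
simulate.psychfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- predict(object)
  out <- as.data.frame(replicate(nsim,
           ifelse(stats::runif(length(p)) < p, "R", "L"),
           simplify = FALSE),
         col.names = paste0("sim_", seq_len(nsim)))
  out
}

#' Plot a fitted psychometric curve
#'
#' Observed per-ITD proportions with Wilson intervals, the fitted curve, and
#' the tangent at zero ITD (the reported slope).
#'
#' @param x A \code{psychfit}.
#' @param ... Passed to \code{plot.default}.
#' @export
plot.psychfit <- function(x, ...) {
  pr <- x$proportions
  grid_us <- seq(min(pr$itd_us), max(pr$itd_us), length.out = 200)
  p_fit <- predict(x, grid_us)
  graphics::plot(pr$itd_us, pr$p_hat, ylim = c(0, 1), pch = 16,
                 col = "blue",
                 xlab = "ITD (us), positive = right ear leading",
                 ylab = "proportion 'right' responses", ...)
  graphics::arrows(pr$itd_us, pr$lower, pr$itd_us, pr$upper, angle = 90,
                   code = 3, length = 0.03, col = "blue")
  graphics::lines(grid_us, p_fit, col = "red", lwd = 2)
  p0 <- predict(x, 0)
  graphics::abline(a = p0, b = x$slope_pct_per_us / 100,
                   col = "darkgreen", lty = 2)
  invisible(x)
}
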