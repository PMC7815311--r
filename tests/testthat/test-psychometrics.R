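test_that("Wilson intervals match a score-equation root-finder", {
  expect_equal(wilson_interval(0, 10)$lower, 0)
  # p-hat = 0.5 gives an interval symmetric about 0.5
  ci <- wilson_interval(5, 10)
  expect_equal(ci$lower + ci$upper, 1, tolerance = 1e-12)
  # frozen from the root-finding oracle (and checked live below)
  ci <- wilson_interval(15, 20)
  expect_equal(c(ci$lower, ci$upper), c(0.5312990, 0.8881385),
               tolerance = 1e-6)
  for (case in list(c(15, 20), c(1, 7), c(49, 50), c(0, 4), c(30, 60))) {
    got <- wilson_interval(case[1], case[2])
    want <- wilson_oracle(case[1], case[2])
    expect_equal(c(got$lower, got$upper), want, tolerance = 1e-9)
  }
  expect_error(wilson_interval(3, 0))
})

test_that("Wilson interval coverage is near nominal", {
  set.seed(2024)
  for (p in c(0.1, 0.5, 0.9)) {
    # exact coverage: binomial sum over all attainable intervals
    kk <- 0:50
    ci_all <- wilson_interval(kk, 50)
    exact <- sum(dbinom(kk, 50, p) *
                   (ci_all$lower <= p & p <= ci_all$upper))
    k <- rbinom(1e4, 50, p)
    ci <- wilson_interval(k, 50)
    coverage <- mean(ci$lower <= p & p <= ci$upper)
    expect_lt(abs(coverage - exact), 0.01)
    expect_gte(coverage, 0.93)
    expect_lte(coverage, 0.975)
  }
})

test_that("the Bernoulli negative log-likelihood has its closed-form values", {
  log <- simulate_session(psych_model(10), n_trials = 500, seed = 5)
  kept <- filter_analysis_trials(log)
  # chance model: n log 2
  expect_equal(as.numeric(neg_log_likelihood(psych_model(0), kept)),
               nrow(kept) * log(2), tolerance = 1e-12)
  # additivity: duplicated log doubles the value
  v1 <- as.numeric(neg_log_likelihood(psych_model(9, 0.1, 0.05, 0.02), kept))
  v2 <- as.numeric(neg_log_likelihood(psych_model(9, 0.1, 0.05, 0.02),
                                      rbind(kept, kept)))
  expect_equal(v2, 2 * v1, tolerance = 1e-12)
  # a model that predicts every observed response approaches 0
  sep <- kept[kept$itd_us != 0, ]
  sep$response <- ifelse(sep$itd_us > 0, "R", "L")
  v <- as.numeric(neg_log_likelihood(psych_model(1e6), sep))
  expect_lt(v, 1e-6)
  expect_warning(neg_log_likelihood(psych_model(0), log), "correction")
})

test_that("maximum-likelihood fitting recovers generating parameters", {
  truth <- psych_model(12.53)
  log <- simulate_session(truth, n_trials = 4000, seed = 17)
  fit <- fit_psychometric(log)
  expect_true(fit$converged)
  expect_false(fit$boundary)
  expect_equal(fit$n_trials_used, sum(!log$is_correction))
  cf <- coef(fit)
  expect_lt(abs(cf[["alpha_per_ms"]] - 12.53) / 12.53, 0.15)
  # slope near 0.50 %/us (phi(0) * 12.53 / 10)
  expect_equal(fit$slope_pct_per_us, dnorm(0) * 12.53 / 10,
               tolerance = 0.15)
  # fit is invariant to trial order
  set.seed(1)
  fit2 <- fit_psychometric(log[sample(nrow(log)), ])
  expect_equal(coef(fit2), cf, tolerance = 1e-6)
})

test_that("fitting flags degenerate and null data", {
  # coin-flip data: slope indistinguishable from zero
  null_log <- simulate_session(psych_model(0), n_trials = 5000, seed = 23)
  fit0 <- fit_psychometric(null_log)
  expect_lt(abs(fit0$slope_pct_per_us), 0.02)
  # perfectly separable data: sensitivity runs to its box constraint
  log <- simulate_session(psych_model(5), n_trials = 400, seed = 3)
  log <- log[log$itd_us != 0, ]
  log$response <- ifelse(log$itd_us > 0, "R", "L")
  log$is_correction <- FALSE
  fit_sep <- fit_psychometric(log)
  expect_true(fit_sep$boundary)
  # sensitivity runs into the flat, near-perfect-likelihood regime
  expect_gt(coef(fit_sep)[["alpha_per_ms"]], 100)
  expect_lt(coef(fit_sep)[["gamma"]], 0.01)
  expect_error(fit_psychometric(log[log$itd_us == 25, ]), "distinct ITD")
})

test_that("alpha rescales exactly with the ITD unit", {
  log <- simulate_session(psych_model(10), n_trials = 2000, seed = 77)
  fit_us <- fit_psychometric(log)
  log_scaled <- log
  log_scaled$itd_us <- log_scaled$itd_us * 1000  # now really in ns slots
  fit_ns <- fit_psychometric(log_scaled)
  expect_equal(coef(fit_ns)[["alpha_per_ms"]] * 1000,
               coef(fit_us)[["alpha_per_ms"]], tolerance = 1e-5)
})

test_that("the slope statistic follows the lapse-corrected density formula", {
  expect_equal(slope_at_zero(psych_model(10)), dnorm(0) * 10 / 10,
               tolerance = 1e-12)
  expect_equal(slope_at_zero(psych_model(10, gamma = 1)), 0)
  expect_equal(slope_at_zero(psych_model(12.53, gamma = 0.2)),
               dnorm(0) * 12.53 * 0.8 / 10, tolerance = 1e-12)
  # published convention evaluates the density at 0, not at beta ...
  m <- psych_model(10, beta = 0.5)
  expect_equal(slope_at_zero(m), dnorm(0) * 10 / 10, tolerance = 1e-12)
  # ... while the exact derivative uses phi(beta); check numerically
  h <- 1e-4  # us
  num <- (as.numeric(response_probability(m, h)) -
          as.numeric(response_probability(m, -h))) / (2 * h) * 100
  expect_equal(slope_at_zero(m, exact = TRUE), num, tolerance = 1e-6)
  # for beta = 0 the reported slope equals the numerical derivative
  m0 <- psych_model(10)
  num0 <- (as.numeric(response_probability(m0, h)) -
           as.numeric(response_probability(m0, -h))) / (2 * h) * 100
  expect_equal(slope_at_zero(m0), num0, tolerance = 1e-6)
})

test_that("75% thresholds match the probit closed form and flag unreachable levels", {
  thr <- threshold75(psych_model(12.53))
  expect_true(thr$defined)
  expect_equal(thr$threshold75_us, qnorm(0.75) / 12.53 * 1000,
               tolerance = 1e-3)
  expect_equal(abs(thr$itd25_us), abs(thr$itd75_us), tolerance = 1e-3)
  # heavy lapse caps p at 0.7: threshold undefined, not an error
  thr2 <- threshold75(psych_model(12.53, gamma = 0.6))
  expect_false(thr2$defined)
  expect_true(is.na(thr2$threshold75_us))
})

test_that("per-ITD proportion tables conserve trials", {
  expect_equal(nrow(proportions_by_itd(
    data.frame(itd_us = numeric(0), response = character(0)))), 0)
  one <- data.frame(itd_us = rep(100, 10),
                    response = rep(c("R", "L"), c(7, 3)))
  tab <- proportions_by_itd(one)
  expect_equal(tab$n, 10)
  expect_equal(tab$k, 7)
  expect_equal(tab$p_hat, 0.7)
  log <- filter_analysis_trials(
    simulate_session(psych_model(8), n_trials = 1000, seed = 13))
  tab <- proportions_by_itd(log)
  expect_equal(sum(tab$n), nrow(log))
  expect_equal(tab$itd_us, sort(unique(log$itd_us)))
})

test_that("group comparisons use the exact Wilcoxon lattice", {
  a <- c(0.66, 0.37, 0.36, 1.37, 0.52)
  # identical paired lists: all differences zero, p = 1 by convention
  same <- compare_groups(a, a, paired = TRUE)
  expect_equal(same$p_value, 1)
  expect_equal(same$n_used, 0L)
  # paired n = 5: attainable exact p-values are multiples of 1/32
  b <- a + c(0.1, -0.2, 0.15, -0.05, 0.3)
  res <- compare_groups(a, b, paired = TRUE)
  expect_equal(res$p_value * 32, round(res$p_value * 32), tolerance = 1e-9)
  # brute-force enumeration over the 2^5 sign patterns
  d <- a - b
  v_obs <- sum(rank(abs(d))[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 5))
  v_all <- as.matrix(signs) %*% rank(abs(d))
  p_exact <- min(1, 2 * min(mean(v_all >= v_obs), mean(v_all <= v_obs)))
  expect_equal(res$p_value, p_exact, tolerance = 1e-9)
  # unpaired separation: minimal attainable rank-sum p at n = m = 5
  shifted <- a + 100
  res_u <- compare_groups(shifted, a, paired = FALSE)
  expect_equal(res_u$p_value, 2 / choose(10, 5), tolerance = 1e-9)
  expect_equal(res_u$median_a - res_u$median_b, 100)
})

test_that("psychfit methods are coherent", {
  log <- simulate_session(psych_model(12), n_trials = 1500, seed = 55)
  fit <- fit_psychometric(log)
  expect_s3_class(fit, "psychfit")
  expect_named(coef(fit), c("alpha_per_ms", "beta", "gamma", "delta"))
  expect_equal(as.numeric(logLik(fit)), -fit$neg_log_likelihood)
  p <- predict(fit, c(-160, 0, 160))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(all(diff(p) > 0))
  r <- residuals(fit, type = "response")
  expect_equal(length(r), fit$n_trials_used)
  expect_lt(abs(mean(r)), 0.05)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sim), c(fit$n_trials_used, 2L))
  expect_true(all(unlist(sim) %in% c("L", "R")))
  expect_output(print(fit), "slope at 0 ITD")
  expect_output(print(summary(fit)), "Per-ITD proportions")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
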