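test_that("AMUA extraction is linear-homogeneous and zero-preserving", {
  expect_equal(max(abs(compute_amua(rep(0, 5000), 24414.0625))), 0)
  set.seed(40)
  x <- rnorm(20000)
  a1 <- compute_amua(x, 24414.0625)
  a3 <- compute_amua(3 * x, 24414.0625)
  expect_equal(as.numeric(a3), 3 * as.numeric(a1), tolerance = 1e-10)
  expect_error(compute_amua(rnorm(10), 24414.0625), "warm-up")
  # band edge above Nyquist is clipped with a warning
  expect_warning(compute_amua(x, 10000), "Nyquist")
})

test_that("mean AMUA amplitude tracks spike density", {
  fs <- 24414.0625
  tmpl_hits <- function(rate_hz, seed) {
    set.seed(seed)
    n <- round(fs)                       # 1 s
    x <- rnorm(n, sd = 1)
    k <- rpois(1, rate_hz)
    at <- sort(sample.int(n - 100, k))
    tmpl <- 8 * itdsense:::spike_template(fs)
    for (i in at) x[i:(i + length(tmpl) - 1)] <-
      x[i:(i + length(tmpl) - 1)] + tmpl
    mean(compute_amua(x, fs))
  }
  wins <- vapply(1:100, function(s)
    tmpl_hits(100, 2 * s) > tmpl_hits(10, 2 * s + 1), TRUE)
  expect_gte(mean(wins), 0.95)
})

test_that("spike detection finds implanted spikes and respects thresholds", {
  fs <- 24414.0625
  set.seed(60)
  x <- rnorm(round(fs), sd = 1)
  sd0 <- sd(x)
  # implant one large spike at 0.5 s
  i0 <- round(0.5 * fs)
  tmpl <- itdsense:::spike_template(fs) * 10 * sd0
  x2 <- x
  x2[i0:(i0 + length(tmpl) - 1)] <- x2[i0:(i0 + length(tmpl) - 1)] + tmpl
  st <- detect_spikes(x2, fs, k_sd = 6)
  expect_equal(length(st), 1)
  expect_lt(abs(st - 0.5), 5e-4)
  # pure Gaussian noise at 4 SD: false positives on the order of the
  # Gaussian tail, 2 * (1 - pnorm(4)) per sample before refractory merging
  st_noise <- detect_spikes(x, fs, k_sd = 4)
  rate <- length(st_noise) / length(x)
  expect_lt(rate, 5 * 2 * (1 - pnorm(4)))
  # absurd threshold: nothing detected
  expect_equal(length(detect_spikes(x, fs, k_sd = 50)), 0)
  expect_error(detect_spikes(rep(1, round(fs)), fs), "zero-variance")
  expect_error(detect_spikes(rnorm(100), fs), "100 ms")
})

test_that("response matrices reproduce the schedule design", {
  rec <- tiny_recording(seed = 71)
  m <- build_response_matrix(rec, tiny_windows())
  expect_equal(dim(m$values), c(5L, 4L))
  expect_equal(m$itd_levels_us, seq(-80, 80, by = 40))
  expect_equal(dim(m$baselines), dim(m$values))
  expect_equal(m$n_dropped, 0)
  # spike-count measure equals a direct window count on detected spikes
  m_sc <- build_response_matrix(rec, tiny_windows(),
                                measure = "spike_count")
  w <- tiny_windows()
  st <- detect_spikes(rec$trace[1, ], rec$sample_rate_hz,
                      exclude_spans_s = cbind(rec$event_time_s,
                                              rec$event_time_s + 0.0025))
  t0 <- rec$event_time_s[1]
  oracle <- sum(st >= t0 + 0.003 & st < t0 + 0.020)
  lvl <- match(rec$event_itd_us[1], m_sc$itd_levels_us)
  expect_equal(m_sc$values[lvl, 1], oracle)
  # events whose windows overrun the trace are dropped with a warning
  short <- rec
  short$trace <- rec$trace[, 1:(ncol(rec$trace) - 2000), drop = FALSE]
  expect_warning(
    expect_warning(m2 <- build_response_matrix(short, tiny_windows()),
                   "dropped"),
    "truncating")
  expect_equal(m2$n_dropped, 1)
})

test_that("tuning curves are baseline-corrected and peak-normalized", {
  fake_matrix <- function(values, baselines) {
    structure(list(values = values, baselines = baselines,
                   itd_levels_us = seq_len(nrow(values)) * 10,
                   measure = "amua_mean", n_dropped = 0L),
              class = "response_matrix")
  }
  # identical responses above baseline: flat curve at 1
  m <- fake_matrix(matrix(5, 4, 6), matrix(1, 4, 6))
  tc <- tuning_curve(m)
  expect_equal(tc$norm_mean, rep(1, 4))
  # one responsive level: 1 there, ~0 elsewhere
  v <- matrix(1, 4, 6); v[3, ] <- 9
  tc2 <- tuning_curve(fake_matrix(v, matrix(1, 4, 6)))
  expect_equal(tc2$norm_mean, c(0, 0, 1, 0))
  # suppression-only responses fall back to |max| normalization w/ flag
  v3 <- matrix(c(0.2, 0.1, 0.05, 0.15), 4, 6)
  tc3 <- tuning_curve(fake_matrix(v3, matrix(1, 4, 6)))
  expect_true(attr(tc3, "all_below_baseline"))
  expect_equal(max(abs(tc3$norm_mean)), 1)
  # simulated sigmoid at high SNR peaks on the saturating side
  tf <- tuning_function("sigmoid", depth = 1, best_itd_us = 0,
                        width_us = 30, evoked_rate_hz = 400,
                        response_type = "onset")
  rec <- simulate_recording(tf, tiny_schedule(n_repeats = 6, seed = 81),
                            seed = 81)
  tc4 <- tuning_curve(build_response_matrix(rec, tiny_windows()))
  expect_gt(tc4$norm_mean[5], tc4$norm_mean[1])
  expect_equal(which.max(tc4$norm_mean) %in% 4:5, TRUE)
})

test_that("STVR matches hand-computed ANOVA and the brute-force oracle", {
  # hand ANOVA: groups {0,2} and {4,6} -> ss_group 16, ss_total 20
  r <- compute_stvr(rbind(c(0, 2), c(4, 6)))
  expect_equal(r$stvr, 0.8)
  expect_equal(r$ss_group, 16)
  expect_equal(r$ss_total, 20)
  # zero within-group variance: stvr exactly 1
  r1 <- compute_stvr(rbind(c(1, 1), c(3, 3)))
  expect_equal(r1$stvr, 1)
  # the standard design's degrees of freedom
  m <- matrix(rnorm(17 * 30), 17, 30)
  r2 <- compute_stvr(m)
  expect_equal(r2$df_between, 16L)
  expect_equal(r2$df_within, 17L * 29L)
  # oracle equivalence on random small matrices, including ragged designs
  set.seed(90)
  for (i in 1:100) {
    k <- sample(2:6, 1)
    n <- sample(2:8, 1)
    vals <- rnorm(k * n, sd = runif(1, 0.5, 3))
    groups <- rep(seq_len(k), n)
    got <- compute_stvr(vals, groups)
    want <- stvr_oracle(vals, groups)
    expect_equal(got$stvr, want$stvr, tolerance = 1e-12)
    expect_equal(got$f_stat, want$f, tolerance = 1e-12)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  # cross-check against stats::aov on one draw
  df <- data.frame(y = as.numeric(m), g = factor(rep(1:17, 30)))
  tab <- summary(stats::aov(y ~ g, df))[[1]]
  expect_equal(r2$stvr,
               tab["g", "Sum Sq"] / sum(tab[, "Sum Sq"]),
               tolerance = 1e-10)
  expect_equal(r2$p_value, tab["g", "Pr(>F)"], tolerance = 1e-10)
  expect_error(compute_stvr(matrix(1, 2, 3)), "zero total variance")
  expect_error(compute_stvr(matrix(rnorm(4), 1, 4)), "2 ITD levels")
})

test_that("STVR is invariant under affine transforms of the responses", {
  set.seed(91)
  m <- matrix(rnorm(8 * 5, mean = rep(1:8, 5)), 8, 5)
  base <- compute_stvr(m)
  for (ab in list(c(2, 0), c(-3, 10), c(0.01, -5))) {
    tr <- compute_stvr(ab[1] * m + ab[2])
    expect_equal(tr$stvr, base$stvr, tolerance = 1e-12)
    expect_equal(tr$f_stat, base$f_stat, tolerance = 1e-10)
  }
})

test_that("permutation null agrees with the parametric ANOVA", {
  set.seed(92)
  m <- matrix(rnorm(17 * 30), 17, 30)
  nd <- stvr_null_distribution(m, n_perm = 2000, seed = 12)
  expect_lt(abs(nd$p_perm - nd$observed$p_value), 0.02)
  # null mean STVR ~ (k-1)/(N-1)
  expect_equal(mean(nd$null_stvr), 16 / 509, tolerance = 0.1)
  # determinism and extreme statistics
  nd2 <- stvr_null_distribution(m, n_perm = 200, seed = 12)
  nd3 <- stvr_null_distribution(m, n_perm = 200, seed = 12)
  expect_identical(nd2$null_stvr, nd3$null_stvr)
  sep <- rbind(matrix(0, 2, 5), matrix(10, 2, 5)) +
    matrix(rnorm(20, sd = 0.01), 4, 5)
  nds <- stvr_null_distribution(sep, n_perm = 400, seed = 3)
  expect_lte(nds$p_perm, 1 / 400)
  expect_warning(stvr_null_distribution(m, n_perm = 50, seed = 1),
                 "coarse")
})
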