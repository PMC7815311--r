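# Shared fixtures: small, fast synthetic inputs built in code.

# Compact recording protocol: 5 ITD levels x 4 repeats with shortened
# analysis windows so unit tests stay fast; the full 17 x 30 design is
# exercised where the design itself is under test.
tiny_schedule <- function(n_repeats = 4, seed = 11, isi_ms = 100)
  make_trial_schedule(itd_min_us = -80, itd_max_us = 80, step_us = 40,
                      n_repeats = n_repeats, isi_ms = isi_ms, seed = seed)

tiny_windows <- function()
  analysis_windows(response_ms = c(3, 20), baseline_ms = c(50, 90),
                   artifact_blank_ms = 2.5)

tiny_recording <- function(depth = 1, shape = "peak", seed = 11,
                           snr = 10, n_repeats = 4) {
  tf <- tuning_function(shape, depth = depth, best_itd_us = 0,
                        width_us = 40, base_rate_hz = 20,
                        evoked_rate_hz = 400, response_type = "onset")
  simulate_recording(tf, tiny_schedule(n_repeats = n_repeats), seed = seed,
                     snr = snr)
}

# Brute-force one-way ANOVA / STVR oracle: explicit double loop.
stvr_oracle <- function(values, groups) {
  grand <- mean(values)
  ss_total <- 0
  for (x in values) ss_total <- ss_total + (x - grand)^2
  ss_group <- 0
  for (g in unique(groups)) {
    xs <- values[groups == g]
    ss_group <- ss_group + length(xs) * (mean(xs) - grand)^2
  }
  k <- length(unique(groups))
  df_b <- k - 1
  df_w <- length(values) - k
  ss_within <- ss_total - ss_group
  f <- (ss_group / df_b) / (ss_within / df_w)
  list(stvr = ss_group / ss_total, f = f,
       p = pf(f, df_b, df_w, lower.tail = FALSE))
}

# Wilson interval oracle: direct root-finding on the score equation
# (p-hat - p) / sqrt(p (1 - p) / n) = -+ z.
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm((1 + conf) / 2)
  phat <- k / n
  g <- function(p) (phat - p) / sqrt(p * (1 - p) / n)
  lo <- if (k == 0) 0 else
    uniroot(function(p) g(p) - z, c(1e-12, min(phat, 1 - 1e-12)),
            tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(function(p) g(p) + z, c(max(phat, 1e-12), 1 - 1e-12),
            tol = 1e-12)$root
  c(lo, hi)
}
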