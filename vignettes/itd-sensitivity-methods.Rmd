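---
title: "Quantifying behavioral and neural ITD sensitivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying behavioral and neural ITD sensitivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itdsense)
```

This vignette is the package's own account of the science it implements:
the stimulus construction, the behavioral model and its estimators, the
neural tuning statistic, what the synthetic-data generators do and do not
emulate, and the numerical choices that were genuinely open.

## Stimuli and the ITD sign convention

Binaural ITD stimuli are built as two identical channels with one channel
delayed by an integer number of samples.  The package's single signed axis
is **ITD = arrival time at the left ear − arrival time at the right ear**:
positive ITD means the right ear leads, so the generator delays the *left*
channel; negative ITD means the left ear leads.  Electrophysiology datasets
that prefer an ipsi/contra-leading convention should record that mapping as
per-dataset metadata rather than flipping the core axis.

Two device profiles matter in practice:

* **Electric** (CI stimulator): 48,828.125 Hz sample rate, so one sample is
  20.48 µs.  Biphasic pulses use 3 samples positive, 2 zero, 3 negative —
  61.44 / 40.96 / 61.44 µs, the clinical-style charge-balanced duty cycle.
* **Acoustic** (click rig): 48,000 Hz, one sample = 20.83 µs; each pulse
  epoch is a single-sample delta "click".

Requested ITDs are rounded to the nearest sample (`quantize_itd()`) and the
realized value is reported; no fractional-delay filtering is attempted,
because the experimental hardware itself only delays whole samples.  Since
both channels contain pulses of identical shape and amplitude, the RMS
interaural level difference is exactly 0 dB at any ITD — `compute_rms_ild()`
exists to audit this, because a residual level cue would confound ITD
sensitivity.  Physical-rig coloration (tube resonances that turn delta
clicks into decaying ring pulses) is deliberately not modeled: it is a
property of the transducer chain, and it leaves the interaural timing
relation untouched.

## The behavioral model

Each 2AFC trial yields a left/right choice.  The probability of "right" is

$$p_R = \Phi(\mathrm{ITD}\cdot\alpha + \beta)\,(1-\gamma) + \tfrac{\gamma}{2} + \delta$$

* $\alpha$ — sensitivity, 1/ms.  The steepness of the cumulative Gaussian;
  a value near 12.5/ms corresponds to a slope of 0.5 %/µs.
* $\beta$ — ear bias (unitless argument offset): the subject's perceptual
  midline sits at $-\beta/\alpha$ ms rather than zero.
* $\gamma \in [0, 0.5]$ — lapse rate: the fraction of trials answered by a
  stimulus-independent coin flip.  Animals trained by trial and error lapse
  at non-negligible rates, which flattens the asymptotes; ignoring
  $\gamma$ biases $\alpha$ downward.
* $\delta \in [-0.3, 0.3]$ — spout bias: an additive preference for one
  response spout.  Unlike $\beta$ it shifts both asymptotes.

ITDs live in µs in trial logs and are converted to ms inside the model.
Probabilities can leave $[0,1]$ only through $\delta$; they are clamped and
the clamping flagged.

### Fitting

`fit_psychometric()` minimizes the per-trial Bernoulli negative
log-likelihood with L-BFGS-B under the box constraints above, plus
$\alpha \in [0, 300]$ /ms — the upper limit chosen so that a single
hardware step of 20.48 µs can traverse essentially the whole curve, which
is as steep as the stimulus grid can resolve.  Six deterministic starts are
used: one from a probit regression on the per-level proportions (the
standard fast heuristic), the rest a fixed grid over low/high sensitivity
and lapse regimes.  Internally the ITD axis is standardized by its maximum
absolute value, which makes the optimization identical whatever unit the
log used — refitting the same data expressed in different units rescales
$\hat\alpha$ exactly.  Likelihood probabilities are clamped to
$[10^{-9}, 1-10^{-9}]$ so perfectly separable data remain finite; such fits
are flagged `boundary` (detected directly from the response pattern, since
a plateaued likelihood may stop the optimizer anywhere in the
near-perfect regime).

### Derived statistics

* **Slope at zero ITD**, reported in % "right" per µs:
  $\varphi(0)\,\alpha\,(1-\gamma)/10$.  The density is evaluated at 0, not
  at $\beta$ — the published convention obtained by differentiating the
  bias-free model.  For biased fits the exact derivative is
  $\varphi(\beta)\,\alpha\,(1-\gamma)$; `slope_at_zero(fit, exact = TRUE)`
  reports it, and for typical $|\beta| < 0.2$ the two differ by under 2%.
* **75% threshold**: the curve is solved for $p_R = 0.25$ and $0.75$ by
  root finding (bisection on ±10 ms, tolerance $10^{-4}$ ms ≡ 0.1 µs) and
  the mean absolute crossing is returned.  Large $\gamma$ or $\delta$ can
  make a level unreachable; that is a legitimate outcome, flagged
  `defined = FALSE` rather than thrown as an error.
* **Wilson score intervals** for per-ITD proportions.  Note the exact
  coverage of the 95% Wilson interval oscillates with $n$ and $p$ (it is
  0.9703 at $n = 50$, $p = 0.1$), so tests compare empirical coverage to
  the exact binomial sum, not to 0.95.
* **Group comparisons**: Wilcoxon tests on slopes or thresholds.  The
  default is the paired signed-rank test — with five subjects per group its
  exact two-sided p-values lie on the lattice of multiples of 1/32 — with
  the unpaired rank-sum variant by flag, since published wording rarely
  says which was used.  Zero differences are dropped (Wilcoxon's original
  convention; two identical lists give p = 1), ties are mid-ranked.

## The behavioral session generator

`simulate_session()` draws Bernoulli choices from a ground-truth model
under the training regime used with animals: after a correct trial a fresh
ITD is drawn uniformly from the stimulus set; after an error the same
stimulus repeats as a **correction trial** until answered correctly
(optionally capped).  Correction trials guard against one-sided response
strategies during training but are trivially predictable ("change side
after a mistake"), so they carry an `is_correction` flag and
`filter_analysis_trials()` removes them before fitting.

Two conventions the task description leaves open are fixed and documented:
positive ITD (right ear leading) is reinforced at the right spout, and
zero-ITD trials are rewarded on a random side so they stay uninformative
about bias.  The default stimulus set spans ±160 µs "in 25 µs steps";
since 160 is not a multiple of 25, the set honors both the step and the
endpoints — {0, ±25, …, ±150, ±160} µs — and is configurable everywhere.
Session-level bookkeeping that does not reach the analysis (timeouts,
water rewards, session scheduling, training dynamics) is not simulated.

## The neural recording generator

`simulate_recording()` emulates a multi-unit extracellular recording during
an ITD tuning protocol: 17 ITDs from −163.84 to +163.84 µs in 20.48 µs
steps, 30 repeats each in shuffled order, 500 ms inter-stimulus interval,
sampled at 24.414 kHz (all defaults, all configurable).  Spikes are an
inhomogeneous Poisson process whose rate in the response window follows a
parametric tuning shape — Gaussian peak, monotonic sigmoid, trough, or
multi-peak (raised cosine) — scaled by a modulation depth in $[0,1]$;
elsewhere the baseline rate applies.  Each spike adds a biphasic 1.2 ms
template (±20% amplitude jitter) to white Gaussian noise, and every onset
carries a large 2.5 ms damped transient so that downstream artifact
blanking is genuinely exercised.  Sustained (3–80 ms) and onset-only
(3–15 ms) response types cover the observed range of latencies.

What this generator does **not** emulate: biophysical spike shapes and
refractoriness, electrode drift, correlated (1/f or line) noise, true
electrical artifact physics, and multi-channel geometry (extra channels are
independent).  Passing tests therefore demonstrate that the analysis chain
recovers known rate structure through realistic filtering and noise — not
that it is robust to every pathology of in vivo data.

## The neural analysis chain

1. **AMUA**: band-pass 300 Hz–6 kHz → absolute value → low-pass 6 kHz, at
   the native rate.  Filters are 4th-order Butterworth applied
   forward-backward: the zero-phase choice keeps response windows aligned
   with stimulus onsets, and the order is conventional for this measure
   (the field's descriptions rarely state either).  The mean AMUA amplitude
   in the 3–80 ms response window is the per-trial response; 300–500 ms
   serves as baseline; the first 2.5 ms are blanked for the stimulus
   artifact (the effective response start is max(3, 2.5) = 3 ms).
2. **Spike detection** (for rasters and the spike-count measure): magnitude
   crossings of the band-passed trace at 4 SD, either polarity, merged
   within 1 ms.  Plain SD is used as printed descriptions specify — not the
   robust MAD estimate — computed on the whole band-passed trace with
   artifact spans excludable.
3. **Tuning curves**: per-level mean minus the mean baseline, normalized by
   the maximum baseline-corrected level mean; SEM per level.  Purely
   suppressive sites are normalized by the absolute maximum and flagged.
4. **STVR**: from the one-way ANOVA of responses grouped by ITD,
   $\mathrm{STVR} = SS_{group}/SS_{total} \in [0, 1]$ — the proportion of
   trial-to-trial variance explained by ITD.  (Some textual descriptions
   invert the ratio; the stated definition and 0–1 range force this
   orientation.)  Significance is the ANOVA F test at $p \le 0.01$; for the
   full design the degrees of freedom are 16 and 493 (29 per level).  The
   statistic is affine-invariant, so window means and window sums agree.
   `stvr_null_distribution()` provides a permutation companion whose null
   mean is $(k-1)/(N-1) \approx 0.031$ for the full design.

## Problem sizes used by the test and acceptance runs

Chosen as a deliberate balance between statistical resolution and a test
suite that runs in minutes on one core; stated here so they are not
mistaken for study parameters:

* psychometric recovery: 50 sessions of 3000 non-correction trials across
  $\alpha \in \{5, 12.5, 25\}$/ms and $\gamma \in \{0, 0.1\}$;
* STVR null calibration: 5000 Gaussian simulations of the full 17 × 30
  design;
* end-to-end neural recovery: 100 paired runs (depth 0 vs 0.8) of the
  17-level schedule at 8 repeats, native sample rate and 500 ms interval —
  at the generator's signal-to-noise defaults, 8 repeats already give the
  F test overwhelming power, while the depth-0 control calibrates the 1%
  false-positive rate;
* unit tests use a compact 5-level protocol with shortened windows where
  only mechanics, not the design, are under test.

## Known limitations

* The psychometric fit is a point estimate; no bootstrap or Bayesian
  uncertainty on parameters (Wilson intervals quantify only per-level
  binomial uncertainty).
* `simulate_session()` models a constant lapse rate; attention and
  motivation dynamics are out of scope.
* The recording container is a plain-text bundle; traces longer than a few
  minutes are better regenerated from seed than stored.
* Tuning-shape classification (peak vs multi-peak, etc.) is not automated;
  the shapes exist as generator options, not as a fitted taxonomy.
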