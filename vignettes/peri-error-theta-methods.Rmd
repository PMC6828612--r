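---
title: "Methods: peri-error reaction-time dynamics and frontal midline theta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-error reaction-time dynamics and frontal midline theta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(peritheta)
```

## The scientific problem

After committing an error in a speeded forced-choice task, people typically
slow down (post-error slowing, PES), and errors are typically preceded by a
run of progressively faster responses (pre-error speeding). In clinical
groups such as ADHD, the post-error readjustment can be delayed or reduced.
On the neural side, error commission is accompanied by a transient burst of
frontal midline theta (FMΘ, 4–8 Hz power at Fz/Cz), a standard EEG marker
of performance monitoring, and this burst can be attenuated in ADHD.

`peritheta` implements the full analysis chain for this kind of two-group
peri-error study — trial classification, reaction-time standardization,
mixed-model inference, EEG preprocessing, time-frequency analysis, and
power analysis — together with a synthetic cohort generator that injects
every effect as an explicit parameter, so the entire pipeline can be
validated by parameter recovery without any real recordings.

## Trial classification

The unit of analysis is the *isolated* commission error: an error preceded
and followed by at least three correct trials within the same block. Its
six correct neighbours are labelled ER−3…ER−1 and ER+1…ER+3. A correct
trial at distance greater than three from every non-correct trial is
*error-free*; everything else is excluded. Two decisions the definition
leaves open are resolved as follows and tested against a brute-force
oracle:

* **Block boundaries.** Classification windows never cross blocks. An
  error too close to a block edge cannot be isolated (its required
  neighbours do not exist), whereas a correct trial near an edge can still
  be error-free — the unobserved context outside the block is treated as
  error-free.
* **Overlapping neighbourhoods.** With exactly three correct trials
  between two isolated errors, a correct trial would be an ER±k neighbour
  of both. Such trials are excluded rather than double-labelled, so the
  labels always partition the trials.
* **Misses** count as non-correct (they break correct runs and disqualify
  neighbouring errors from isolation) but are never themselves isolated
  errors, which are commission errors by definition.

Reaction times are standardized per subject against the error-free trials
only: `z = (rt − mean_EF) / sd_EF`, applied to every trial including
errors. Subjects with fewer than five isolated errors are excluded before
any model fitting.

## Mixed-effects inference

All inference uses maximum-likelihood (never REML) random-intercept models
so that likelihood-ratio tests between nested fixed-effect structures are
valid. The linear mixed model is fitted by profiling: for a given variance
ratio ψ = σ²_subject/σ²_residual, the GLS fixed effects and the residual
variance have closed forms (the per-subject covariance `I + ψJ` inverts
analytically), leaving a one-dimensional optimization over log ψ with the
boundary ψ = 0 (ordinary regression) checked explicitly. The logistic
mixed model for trial-wise accuracy integrates its scalar random intercept
by adaptive Gauss–Hermite quadrature with 21 nodes (21 vs 41 nodes changes
the log-likelihood by less than 1e-4 on the test fixtures). Both
implementations are cross-checked against `lme4` in the test suite, and
the LMM optimizer against a dense two-dimensional grid search over
(ψ, σ²).

Model coding choices that fix the sign and meaning of the reported
estimates:

* the pre-error window (ER−3…ER−1) and post-error window (ER+1…ER+3) are
  fitted separately, with the trial-position covariate centred within each
  window, so the intercept is the mean standardized RT of that window and
  the slope is the per-trial change;
* treatment coding with TD and ER+1 (or ER−1) as reference levels
  elsewhere; group effects are reported as the ADHD coefficient;
* no multiple-testing correction is applied, matching common practice for
  this design; every p-value is reported raw.

The split-plot group × position ANOVA on subject means is retained as a
cross-check of the mixed-model route (its interaction F equals the squared
two-sample t on difference scores, which the tests verify), and the
two-sample comparisons use pooled-variance Student t-tests, giving the
classical `n1 + n2 − 2` degrees of freedom.

Power for the group comparison uses the noncentral t distribution with
noncentrality `d·sqrt(n1·n2/(n1+n2))`; the minimum detectable effect size
solves the monotone power curve by bisection to 1e-4 and is conventionally
reported to two decimals.

## EEG pipeline

The preprocessing order is fixed and mirrors standard practice: 50 Hz
notch (48.5–51.5 Hz band-stop Butterworth, order 4 per pass), 0.3–40 Hz
band-pass (fourth-order Butterworth high- and low-pass in cascade), blink
detection on VEOG (|deviation| > 5 MAD with a 300 ms refractory period),
joint-decorrelation removal of the blink component, response-locked
epoching (−2…+2 s), and ±80 µV amplitude rejection on the scalp channels
(EOG exempt, and applied after cleaning so blinks do not inflate the
rejection count).

Numerical notes:

* All filters are zero-phase (forward–backward), so the effective order
  doubles and no group delay is introduced; a cross-correlation test
  verifies the zero-lag property.
* The 0.3 Hz high-pass edge is 0.0012 of the Nyquist frequency; in
  expanded transfer-function form such a filter is numerically fragile, so
  the high/low-pass are implemented as cascades of analytically designed
  biquad sections (bilinear transform with prewarping, Butterworth pole
  Q factors) and the notch is factored into second-order sections via
  `polyroot`. This keeps filtering linear to ~1e-12 and lets the magnitude
  responses match their analytic forms.
* Joint decorrelation solves the generalized eigenproblem of the
  blink-window covariance (±300 ms around detected blinks) against the
  whole-recording covariance after a ridge regularization of 1e-9 × trace;
  by default the single strongest component is projected out. The blink
  window length and component count are free parameters of the method —
  the original description of this procedure leaves them open — and both
  are exposed as arguments.

Time-frequency analysis uses a moving 0.5 s Hann window (250 samples at
500 Hz, hence exact 2 Hz bin spacing without zero padding) stepped by
50 ms from −1.5 to +1.5 s, at 2–36 Hz. Power is scaled so a sinusoid of
amplitude A at a bin frequency yields A²/2 µV², log-transformed as
10·log10 with a −300 dB floor, and baseline-corrected per trial by
subtracting the mean log power of the windows whose centres fall 0.75 to
0.25 s before that trial's prime onset (located inside the response-locked
epoch through the stored prime-onset offset; re-epoching prime-locked data
would give the identical windows, so the offset route is used). FMΘ is the
dB average over the 4, 6 and 8 Hz bins and electrodes Fz and Cz, and the
per-trial summary averages ±0.4 s around the response (17 grid points).
Summaries come in two references: `vs_baseline` (dB against the pre-prime
baseline) and `vs_errorfree` (additionally centred on the subject's mean
error-free summary, which is then exactly zero per subject).

## The synthetic cohort

The generator's defaults are the study conditions the pipeline targets:

| parameter | TD | ADHD |
|---|---|---|
| subjects | 14 | 26 |
| trials | 3 × 96 | 3 × 96 |
| mean error-free RT (ms) | 427 | 459 |
| SD error-free RT (ms) | 31 | 41 |
| error rate | 0.068 | 0.097 |
| error z offset (SD) | −1.39 | −1.39 |
| pre-error z, ER−3…−1 | −0.16, −0.26, −0.36 | same |
| post-error z, ER+1…+3 | 0, 0, 0 | −0.44, −0.02, 0 |
| compatibility effect (ms) | 20 (+27 at ER+1) | same |
| error / correct theta burst (dB) | 3.0 / 0.8 | 1.5 / 0.8 |

Standardized RT is built as subject intercept (variance 0.05, kept small
so fixed effects dominate) + label offset + compatibility effect +
Gaussian residual, with the compatibility and residual variances summing
to one so that error-free trials have unit within-subject variance — the
scale on which the pipeline's own standardization then recovers the
injected offsets without shrinkage. Correctness layouts are resampled
(bounded retries) until each subject has at least five isolated errors, so
the inclusion filter never empties a default cohort; with a zero error
rate the requirement is waived and an all-correct cohort is returned. The
published point estimates this profile reproduces are internally tense in
one place (the group-level ER−1 value and the TD ER−1→ER+1 step cannot
both hold exactly); the generator uses the per-cell point values and
leaves the tension to the data rather than reconciling it.

Timing uses a 150 ms prime–target asynchrony (a standard masked-priming
value; the source design figure gives no number) and an inter-trial
interval jittered uniformly on 1.5–2.0 s, which guarantees that a trial's
pre-prime baseline window can never overlap the previous response's
±0.4 s theta window. Trial repetition at block ends is not modelled: it
changes trial counts, not the peri-error logic under test.

The EEG renderer composes, per channel, 1/f background noise (amplitude
spectrum ∝ 1/(f+1)^(α/2), RMS 10 µV), a 50 Hz line component, biphasic
frontal-weighted eyeblinks mirrored into VEOG, response-locked 6 Hz theta
bursts (Hann envelope spanning ±0.4 s; 6 Hz is the centre of the 4–8 Hz
band), and occasional >80 µV artifact segments that exercise the rejection
stage.

**Burst calibration.** The one non-obvious step is choosing the burst
amplitude so that the *pipeline's* dB measure recovers `theta_burst_db`.
The measure averages log power over windows, bins and channels, and log of
signal-plus-noise power is biased relative to log of mean power, so the
mapping from amplitude to measured dB is computed numerically: the
windowed-FFT noise-bin variance is estimated from a long realization of
the generator's own noise model, the expected log power of burst-plus-
noise is evaluated with fixed common-random-number draws over carrier
phase and complex Gaussian noise, and the amplitude solves a 1-D
root-finding problem. The calibration also models the only preprocessing
effect that matters at theta frequencies: removing the blink component
attenuates any source whose topography overlaps the blink topography, by
the closed-form factor `t_ch − b_ch (b'C₀⁻¹t)/(b'C₀⁻¹b)` under the model
covariance `C₀ = σ²I + σ²_b bb' + σ²_t tt'`. Because the burst variance
term depends on the amplitudes being solved for, the calibration iterates
this fixed point three times. The procedure is deterministic (private,
fixed RNG substream; caller's RNG state restored) and validated end to
end: a 40-subject cohort recovers the injected 3.0/1.5 dB within ±0.3 dB.

**What the generator does not emulate.** Channel noise is independent
across electrodes (no spatially correlated background), there is no
saccade model beyond noise on HEOG, burst amplitude does not vary across
subjects or trials, and topographies are fixed vectors rather than a head
model. Passing recovery tests therefore demonstrates that the pipeline
measures what it claims on data satisfying its own assumptions — not that
those assumptions hold for any particular real recording.

## Problem sizes used in the tests

The test suite validates behavioral recovery on a 200-subjects-per-group
cohort (a scale at which estimator noise is ~0.01–0.02 SD units, an order
of magnitude under the ±0.05 acceptance bands) and EEG recovery on twenty
40-subject cohorts at 72 trials per subject, aggregating subject-level
means across seeds for the ±0.3 dB check and using the per-seed t-tests
for the group-separation check. The property battery runs the
classification oracle on 1000 random sequences, a 1000-replicate null
simulation for the likelihood-ratio test's type-I error, and closed-form
oracles for the short-time FFT and the filter responses.

## Known limitations

* Random intercepts only — no random slopes, crossed effects, or
  Satterthwaite degrees of freedom; LRT p-values rely on standard χ²
  asymptotics (the χ² df is the fixed-effect count difference).
* The logistic model reports conditional (subject-specific) log-odds;
  with a nonzero random-intercept variance these are slightly larger in
  magnitude than marginal logit differences.
* The EDF writer/reader supports the subset this package produces
  (uniform sampling rate, one-second records, 16-bit).
* Welch-pooled alternatives to the t-tests and cluster-based permutation
  statistics for the time-frequency maps are out of scope.
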