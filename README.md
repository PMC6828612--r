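# peritheta

Peri-error reaction-time dynamics and frontal midline theta (FMΘ) analysis
for two-group forced-choice EEG experiments, with a fully parameterized
synthetic-cohort generator for validation by parameter recovery.

## What it does

Around an *isolated* error — a commission error flanked by at least three
correct trials — reaction times follow a characteristic trajectory:
progressive pre-error speeding, a fast error, and post-error slowing whose
time course can differ between groups (e.g., delayed recovery in ADHD).
`peritheta` implements the complete analysis chain for such studies:

* **Behavior** — peri-error classification (`ER−3…ER+3`, error-free,
  excluded), per-subject RT standardization against error-free trials
  (`z = (rt − mean_EF)/sd_EF`), the ≥5-isolated-errors inclusion rule, and
  compatibility-effect contrasts.
* **Inference** — maximum-likelihood random-intercept linear mixed models
  (profiled GLS over the variance ratio), a 21-node adaptive Gauss–Hermite
  logistic mixed model for trial-wise accuracy, likelihood-ratio tests
  (`χ² = 2·Δℓ`), a split-plot group × position ANOVA cross-check, pooled
  t-tests, and two-sample power via the noncentral t distribution with
  `ncp = d·sqrt(n1·n2/(n1+n2))`.
* **EEG** — zero-phase Butterworth notch (48.5–51.5 Hz) and band-pass
  (0.3–40 Hz) filters, MAD-threshold blink detection, joint-decorrelation
  (generalized-eigendecomposition) blink removal, response-locked epochs
  (−2…+2 s), ±80 µV rejection, Hann-tapered moving-window FFT
  (0.5 s windows, −1.5…+1.5 s × 2–36 Hz grid), 10·log10 power with a
  trial-wise pre-prime (−0.75…−0.25 s) dB baseline, and FMΘ summaries
  (4–8 Hz × {Fz, Cz} × ±0.4 s).
* **Synthesis** — `sample_behavior()` and `render_eeg()` generate trial
  tables and continuous 10-channel, 500 Hz recordings (1/f noise, line
  noise, eyeblinks, calibrated response-locked theta bursts, artifact
  segments), written to EDF + events TSV by `write_dataset()`.

## A worked example

```r
library(peritheta)

# a small synthetic cohort: 6 TD + 8 ADHD subjects, 288 trials each
params <- cohort_params(n_td = 6, n_adhd = 8, seed = 42)
behavior <- sample_behavior(params)
res <- analyze_behavior(behavior)

res$inclusion$summary$mean
#> [1] 13.64286          # isolated errors per retained subject

subset(res$results, term %in% c("error_intercept", "erp1_intercept_ADHD",
                                "erp1_to_erp2_ADHD"))
#> # A tibble: 3 × 5
#>   term                estimate chisq    df  p_value
#>   <chr>                  <dbl> <dbl> <int>    <dbl>
#> 1 error_intercept       -1.29  49.7      1 1.79e-12
#> 2 erp1_intercept_ADHD   -0.398  8.83     1 2.96e- 3
#> 3 erp1_to_erp2_ADHD      0.270  3.09     1 7.87e- 2
```

Errors are ~1.3 SD faster than each subject's error-free mean, the ADHD
group is still speeded on the first post-error trial (z ≈ −0.4), and slows
from ER+1 to ER+2 — the delayed-recovery signature, already visible at
this small cohort size (the generator injects −1.39, −0.44 and +0.42; a
200-subject cohort recovers them to ±0.05).

The power analysis for the classic 26 + 14 design:

```r
ttest_power(d = 0.42, n1 = 26, n2 = 14)
#> two-sample t power: d = 0.420, n = 26/14, alpha = 0.050 -> 0.235
round(min_detectable_d(0.8, 26, 14), 2)
#> [1] 0.95
```

With EEG (slower), `run_pipeline(params)` renders and preprocesses each
subject's recording, computes FMΘ summaries, and adds the group-level
theta battery; `plot_peri_error_profile()` and `plot_theta_timecourse()`
draw the standard figures.

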