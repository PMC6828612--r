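# Small cohorts reused across test files, built once per session.
.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache)) {
    assign(key, force(expr), envir = .cohort_cache)
  }
  get(key, envir = .cohort_cache)
}

small_behavior <- function() {
  cached("small_behavior", sample_behavior(
    cohort_params(n_td = 6, n_adhd = 8, seed = 42)))
}

small_recording <- function() {
  cached("small_recording", {
    gp <- group_params()
    cal <- calibrate_theta_amplitude(gp)
    beh <- sample_behavior(cohort_params(n_td = 2, n_adhd = 1,
                                         trials_per_block = 24, seed = 5))
    sub <- beh[beh$subject == "sub-001", ]
    list(bundle = render_eeg(sub, gp, seed = 7, calibration = cal),
         behavior = sub, params = gp, calibration = cal)
  })
}
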