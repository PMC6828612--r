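# Build a minimal epoch set directly (bypassing the preprocessing chain) so
# the time-frequency stage can be tested against closed forms.
mk_epochs <- function(signal_fun, n_trials = 3, fs = 500,
                      prime_offset = -0.6, channels = c("Fz", "Cz")) {
  times <- seq(-2, 2, by = 1 / fs)
  dat <- array(0, c(n_trials, length(channels), length(times)))
  for (i in seq_len(n_trials)) {
    for (ci in seq_along(channels)) {
      dat[i, ci, ] <- signal_fun(times, i, ci)
    }
  }
  structure(list(
    data = dat, times = times, channels = channels,
    meta = tibble::tibble(
      subject = "s1", group = "TD", subtype = NA_character_,
      block = 1L, trial = seq_len(n_trials),
      compatibility = "compatible", correct = 1L, rt_ms = 450,
      prime_offset_s = rep(prime_offset, n_trials),
      peri_label = rep("ERROR_FREE", n_trials)),
    mask = rep(TRUE, n_trials)),
    class = "epoch_set")
}

test_that("the grid is exactly as documented", {
  ep <- mk_epochs(function(t, i, c) rnorm(length(t)))
  tfr <- stft_power(ep)
  expect_equal(tfr$freqs, seq(2, 36, by = 2))
  expect_equal(tfr$times, seq(-1.5, 1.5, by = 0.05))
  expect_equal(dim(tfr$power), c(3, 2, 18, 61))
})

test_that("a bin-frequency sinusoid matches the Hann closed form at every grid time", {
  A <- 10; phi <- 0.7
  ep <- mk_epochs(function(t, i, c) A * cos(2 * pi * 6 * t + phi),
                  n_trials = 1)
  tfr <- stft_power(ep)
  p6 <- tfr$power[1, 1, tfr$freqs == 6, ]
  # oracle: closed-form Hann-windowed DFT power of the same segment; the
  # window centred at grid time tc starts 125 samples earlier
  for (ti in c(1, 17, 31, 45, 61)) {
    tc <- tfr$times[ti]
    t0 <- tc - 125 / 500
    p_or <- oracle_hann_sin_power(A, 6, phi + 2 * pi * 6 * t0, 500, 250, 3)
    expect_equal(10^(p6[ti] / 10), p_or, tolerance = 1e-9)
  }
  # amplitude calibration: power approximates A^2/2 (small leakage term)
  expect_equal(10^(p6[31] / 10), A^2 / 2, tolerance = 1e-3)
  # constant across grid times
  expect_lt(diff(range(p6)), 1e-6)
})

test_that("white-noise spectra are flat and total power tracks the variance", {
  set.seed(25)
  ep <- mk_epochs(function(t, i, c) rnorm(length(t), 0, 5), n_trials = 60)
  tfr <- stft_power(ep)
  by_freq <- apply(10^(tfr$power / 10), 3, mean)
  expect_lt(diff(range(by_freq)) / mean(by_freq), 0.25)

  # Parseval on one tapered segment: summed bin power = windowed variance
  x <- ep$data[1, 1, 1:250]
  w <- 0.5 - 0.5 * cos(2 * pi * (0:249) / 250)
  lhs <- sum(Mod(fft(w * x))^2) / 250
  expect_equal(lhs, sum((w * x)^2), tolerance = 1e-10)
})

test_that("a silent epoch hits the documented dB floor", {
  ep <- mk_epochs(function(t, i, c) rep(0, length(t)), n_trials = 1)
  tfr <- stft_power(ep)
  expect_true(all(tfr$power == -300))
})

test_that("scaling amplifies pre-baseline log power and cancels after baseline", {
  set.seed(26)
  sig <- function(t, i, c) rnorm(length(t), 0, 8)
  ep1 <- mk_epochs(sig, n_trials = 10)
  ep2 <- ep1
  ep2$data <- ep1$data * 3
  t1 <- stft_power(ep1); t2 <- stft_power(ep2)
  expect_equal(t2$power, t1$power + 20 * log10(3), tolerance = 1e-9)
  b1 <- baseline_correct(t1); b2 <- baseline_correct(t2)
  expect_equal(b2$power, b1$power, tolerance = 1e-9)
})

test_that("statistically identical baseline and activation give ~0 dB", {
  set.seed(27)
  ep <- mk_epochs(function(t, i, c) rnorm(length(t), 0, 10), n_trials = 400)
  tfr <- baseline_correct(stft_power(ep))
  m <- mean(tfr$power[, , tfr$freqs %in% c(4, 6, 8), ])
  expect_lt(abs(m), 0.2)
})

test_that("a four-fold power step in the activation window reads +6.02 dB", {
  # 6 Hz tone, amplitude doubled (power x 4) from t = -0.8; with a -0.9 s
  # prime offset the baseline windows (data down to -0.9 s relative to the
  # response) see only the unit amplitude, the ±0.4 s summary windows
  # (data from -0.65 s) only the doubled one
  ep <- mk_epochs(function(t, i, c) {
    A <- ifelse(t >= -0.8, 20, 10)
    A * cos(2 * pi * 6 * t + i)
  }, n_trials = 3, prime_offset = -0.9)
  tfr <- baseline_correct(stft_power(ep))
  sel <- abs(tfr$times) <= 0.4 + 1e-9
  act <- tfr$power[, , tfr$freqs == 6, sel]
  expect_equal(mean(act), 10 * log10(4), tolerance = 1e-3)
})

test_that("trials without a reachable baseline are flagged and excluded", {
  ep <- mk_epochs(function(t, i, c) rnorm(length(t)), n_trials = 2,
                  prime_offset = -2.5)   # baseline centres outside the grid
  expect_message(tfr <- baseline_correct(stft_power(ep)), "flagged")
  expect_true(all(!tfr$meta$baseline_ok))
  tc <- fmtheta_timecourse(tfr)
  expect_equal(nrow(theta_summaries(tc, "vs_baseline")), 0)
})

test_that("theta averaging uses bins 4/6/8, Fz and Cz, and 17 time points", {
  ep <- mk_epochs(function(t, i, c) rnorm(length(t)))
  tfr <- baseline_correct(stft_power(ep))
  # constant field: averaging returns the constant
  tfr$power[] <- 2.5
  tc <- fmtheta_timecourse(tfr)
  expect_equal(dim(tc$values), c(3, 61))
  expect_true(all(abs(tc$values - 2.5) < 1e-12))
  # burst confined to the 6 Hz bin contributes a third of its dB
  tfr$power[] <- 0
  tfr$power[, , tfr$freqs == 6, ] <- 3
  tc2 <- fmtheta_timecourse(tfr)
  expect_true(all(abs(tc2$values - 1) < 1e-12))
  # summary window has 17 grid points
  expect_equal(sum(abs(tc2$times) <= 0.4 + 1e-9), 17)
  expect_error(fmtheta_timecourse(tfr, channels = c("Fz", "Pz")),
               "not present")
})

test_that("error-free-referenced summaries centre each subject at zero", {
  set.seed(28)
  ep <- mk_epochs(function(t, i, c) rnorm(length(t), 0, 10), n_trials = 30)
  ep$meta$peri_label <- rep(c("ERROR_FREE", "ERROR_ISOLATED"), 15)
  tfr <- baseline_correct(stft_power(ep))
  tc <- fmtheta_timecourse(tfr)
  s <- theta_summaries(tc, "vs_errorfree")
  ef <- s$theta_db[s$peri_label == "ERROR_FREE"]
  expect_equal(mean(ef), 0, tolerance = 1e-12)
})

test_that("epochs shorter than the grid demands are rejected", {
  ep <- mk_epochs(function(t, i, c) rnorm(length(t)))
  ep$data <- ep$data[, , 201:1801, drop = FALSE]
  ep$times <- ep$times[201:1801]
  expect_error(stft_power(ep), "too short")
})
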