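tone_eeg <- function(freqs_amps, n = 20000, fs = 500, nch = 2) {
  t <- seq_len(n) / fs
  x <- rowSums(sapply(freqs_amps, function(fa) fa[2] * sin(2 * pi * fa[1] * t)))
  continuous_eeg(matrix(rep(x, each = nch), nch), paste0("ch", seq_len(nch)),
                 srate = fs)
}

interior <- function(n, drop = 2500) (drop + 1):(n - drop)

test_that("the notch removes 50 Hz and spares 10 Hz", {
  e50 <- notch_filter(tone_eeg(list(c(50, 10))))
  i <- interior(20000)
  expect_lt(max(abs(e50$data[1, i])), 0.1)
  e10 <- notch_filter(tone_eeg(list(c(10, 10))))
  expect_equal(max(abs(e10$data[1, i])), 10, tolerance = 0.01)
  ez <- notch_filter(continuous_eeg(matrix(0, 2, 5000), c("a", "b")))
  expect_true(all(ez$data == 0))
})

test_that("the band-pass removes DC, keeps 6 Hz, attenuates 45 Hz analytically", {
  edc <- tone_eeg(list(c(3, 0)))
  edc$data <- edc$data + 100
  out <- bandpass_filter(edc)
  i <- interior(20000)
  expect_lt(mean(abs(out$data[1, i])), 1)

  e6 <- bandpass_filter(tone_eeg(list(c(6, 10))))
  expect_equal(max(abs(e6$data[1, i])), 10, tolerance = 0.02)

  e45 <- bandpass_filter(tone_eeg(list(c(45, 10))))
  lp <- signal::butter(4, 40 / 250, type = "low")
  hp <- signal::butter(4, 0.3 / 250, type = "high")
  gain <- oracle_filter_gain(lp, 45, 500) * oracle_filter_gain(hp, 45, 500)
  expect_equal(max(abs(e45$data[1, i])) / 10, gain, tolerance = 0.02)
})

test_that("filtering is linear and zero-phase", {
  set.seed(22)
  x <- rnorm(8000); y <- rnorm(8000)
  mk <- function(v) continuous_eeg(matrix(v, 1), "a", 500)
  fx <- bandpass_filter(mk(x))$data
  fy <- bandpass_filter(mk(y))$data
  fxy <- bandpass_filter(mk(2 * x + 3 * y))$data
  expect_equal(fxy, 2 * fx + 3 * fy, tolerance = 1e-9)

  tone <- sin(2 * pi * 6 * seq_len(8000) / 500)
  ft <- bandpass_filter(mk(tone))$data[1, ]
  i <- interior(8000, 1000)
  lags <- -5:5
  cc <- vapply(lags, function(L) {
    stats::cor(tone[i], ft[i + L])
  }, numeric(1))
  expect_equal(lags[which.max(cc)], 0)
})

test_that("blink detection finds injected blinks and respects the refractory period", {
  set.seed(23)
  fs <- 500; n <- 120000
  veog <- rnorm(n, 0, 10)
  tpl <- peritheta:::blink_template(fs) * 300
  times <- seq(5, 230, by = 5) + runif(46, 0, 1)
  for (t0 in times) veog <- peritheta:::add_at(veog, tpl, round(t0 * fs) + 1)
  bl <- detect_blinks(veog, fs)
  # template peak sits 0.15 s after onset
  expected <- round((times + 0.15) * fs)
  hits <- vapply(expected, function(e) any(abs(bl$peaks - e) <= 20),
                 logical(1))
  expect_gte(mean(hits), 0.95)
  expect_lte(length(bl$peaks), length(times) + 2)   # ~no false alarms
  expect_true(all(diff(bl$peaks) >= 150))

  # pure-noise false alarms below 1 per minute
  bl0 <- detect_blinks(rnorm(n, 0, 10), fs)
  expect_lt(length(bl0$peaks) / (n / fs / 60), 1)

  # two close deflections merge into one detection
  v2 <- rnorm(5000, 0, 5)
  v2 <- peritheta:::add_at(v2, tpl, 2000)
  v2 <- peritheta:::add_at(v2, tpl, 2050)
  expect_equal(length(detect_blinks(v2, fs)$peaks), 1)

  expect_warning(detect_blinks(rep(0, 1000), fs), "flat")
})

test_that("joint decorrelation removes a rank-1 blink and spares the rest", {
  set.seed(24)
  fs <- 500; n <- 100000
  topo <- c(0.3, 0.25, 0.1, 1)        # blink pattern, EOG-dominated
  tpl <- peritheta:::blink_template(fs) * 300
  blink <- numeric(n)
  for (t0 in seq(3, 195, by = 4)) {
    blink <- peritheta:::add_at(blink, tpl, round(t0 * fs) + 1)
  }
  noise <- matrix(rnorm(4 * n, 0, 10), 4)
  X <- noise + outer(topo, blink)
  eeg <- continuous_eeg(X, c("Fz", "Cz", "Pz", "VEOG"), fs)
  bl <- detect_blinks(X[4, ], fs)
  pre_cor <- cor(X[1, ], blink)
  expect_gt(pre_cor, 0.6)
  cleaned <- joint_decorrelation_clean(eeg, bl)
  expect_lt(abs(cor(cleaned$data[1, ], blink)), 0.1)
  expect_equal(dim(cleaned$data), dim(X))
  # channels orthogonal to the blink topography barely change
  expect_gt(cor(cleaned$data[3, ], noise[3, ]), 0.99)

  # zero components removed: identity
  same <- joint_decorrelation_clean(eeg, bl, n_remove = 0)
  expect_identical(same$data, eeg$data)
  # removing every component annihilates the data
  expect_warning(gone <- joint_decorrelation_clean(eeg, bl, n_remove = 4),
                 "all-zero")
  expect_lt(max(abs(gone$data)), 1e-6)
})

test_that("epoching is sample-exact and drops edge responses", {
  rec <- small_recording()
  eeg <- rec$bundle$eeg
  ev <- rec$bundle$events
  expect_message(ep <- epoch_responses(eeg, ev), regexp = NA)
  fs <- eeg$srate
  expect_equal(dim(ep$data)[3], 4 * fs + 1)
  expect_equal(ep$times[1001], 0)
  # time-0 sample equals the continuous sample at the response index
  resp <- ev[ev$event_type == "response", ]
  i <- 5
  c0 <- round(resp$onset_s[i] * fs) + 1
  expect_equal(unname(ep$data[i, , 1001]), unname(eeg$data[, c0]))
  expect_lte(dim(ep$data)[1], nrow(resp))

  # a response too close to the recording start is dropped and logged
  ev2 <- ev
  ev2$onset_s[ev2$event_type == "response"][1] <- 0.5
  expect_message(ep2 <- epoch_responses(eeg, ev2), "dropped")
  expect_equal(dim(ep2$data)[1], dim(ep$data)[1] - 1)
  expect_equal(nrow(ep2$dropped), 1)
})

test_that("artifact rejection applies the ±80 µV boundary to scalp channels only", {
  dat <- array(0, c(3, 10, 2001))
  dat[1, 3, 900] <- 81          # just over, scalp
  dat[2, 3, 900] <- 79          # just under
  dat[3, 9, 900] <- 500         # VEOG is exempt
  ep <- structure(list(data = dat, times = seq(-2, 2, by = 1 / 500),
                       channels = c("F3", "Fz", "F4", "C3", "Cz", "C4",
                                    "O1", "O2", "VEOG", "HEOG"),
                       meta = tibble::tibble(id = 1:3),
                       mask = rep(TRUE, 3)),
                  class = "epoch_set")
  out <- reject_artifacts(ep)
  expect_equal(out$mask, c(FALSE, TRUE, TRUE))
})

test_that("the generator's injected high-amplitude epochs are all rejected", {
  gp <- group_params(artifact_rate = 0.15)
  cal <- small_recording()$calibration
  beh <- sample_behavior(cohort_params(n_td = 2, n_adhd = 1,
                                       trials_per_block = 24, seed = 31))
  sub <- beh[beh$subject == "sub-001", ]
  b <- render_eeg(sub, gp, seed = 8, calibration = cal)
  truth <- attr(b, "truth")
  expect_gt(nrow(truth$artifact_trials), 0)
  ep <- preprocess_eeg(b$eeg, b$events)
  bad_key <- interaction(truth$artifact_trials$block,
                         truth$artifact_trials$trial)
  flagged <- interaction(ep$meta$block, ep$meta$trial) %in% bad_key
  expect_true(all(!ep$mask[flagged]))
})
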