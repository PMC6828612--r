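# Spatial weights of the two injected sources. The blink source is
# EOG-dominated with a frontal gradient; the theta source is fronto-central
# (Fz/Cz) and absent from the EOG channels, so targeted decorrelation of
# blinks leaves it essentially untouched.
BLINK_TOPO <- c(F3 = 0.25, Fz = 0.30, F4 = 0.25, C3 = 0.08, Cz = 0.10,
                C4 = 0.08, O1 = 0.02, O2 = 0.02, VEOG = 1, HEOG = 0.05)
BURST_TOPO <- c(F3 = 0.4, Fz = 0.8, F4 = 0.4, C3 = 0.6, Cz = 1,
                C4 = 0.6, O1 = 0.1, O2 = 0.1, VEOG = 0, HEOG = 0)
BLINK_AMP_UV <- 300          # VEOG peak amplitude of a blink
THETA_HZ <- 6                # burst carrier: centre of the 4-8 Hz band

# 1/f-type background noise via frequency-domain shaping: amplitude
# spectrum 1/(f + 1)^(exponent/2), scaled to the requested RMS.
# Generates `nch` independent channels in one batched inverse FFT.
pink_noise <- function(n, fs, exponent = 1, rms = 10, nch = 1L) {
  # even, 2-3-5-smooth synthesis length keeps the FFT O(n log n)
  n2 <- stats::nextn(n, c(2, 3, 5))
  if (n2 %% 2L) n2 <- stats::nextn(n2 + 1L, c(2, 3, 5))
  nh <- n2 %/% 2L
  f <- (1:(nh - 1L)) * fs / n2
  amp <- 1 / (f + 1)^(exponent / 2)
  full <- matrix(complex(real = 0), n2, nch)
  spec <- matrix(complex(modulus = amp,
                         argument = runif((nh - 1L) * nch, 0, 2 * pi)),
                 nh - 1L, nch)
  full[2:nh, ] <- spec
  full[n2:(nh + 2L), ] <- Conj(spec)
  full[nh + 1L, ] <- (1 / (nh * fs / n2 + 1)^(exponent / 2)) *
    sample(c(-1, 1), nch, replace = TRUE)
  x <- Re(stats::mvfft(full, inverse = TRUE))[seq_len(n), , drop = FALSE]
  x <- sweep(x, 2L, sqrt(colMeans(x^2)) / rms, "/")
  if (nch == 1L) drop(x) else t(x)     # nch x n
}

# Hann envelope spanning +/- half_s around its centre, sampled at fs.
burst_envelope <- function(fs, half_s = 0.4) {
  n <- 2L * round(half_s * fs) + 1L
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

# Biphasic eyeblink template (~400 ms): 300 ms positive Hann lobe followed
# by a 100 ms negative rebound, unit peak.
blink_template <- function(fs) {
  n1 <- round(0.3 * fs); n2 <- round(0.1 * fs)
  lobe1 <- 0.5 - 0.5 * cos(2 * pi * (seq_len(n1) - 1) / (n1 - 1))
  lobe2 <- -0.25 * (0.5 - 0.5 * cos(2 * pi * (seq_len(n2) - 1) / (n2 - 1)))
  c(lobe1, lobe2)
}

# Add `template * gain` into `x` centred/started at sample `at` (clipped at
# the edges).
add_at <- function(x, template, at) {
  i0 <- max(1L, at); i1 <- min(length(x), at + length(template) - 1L)
  if (i0 > i1) return(x)
  x[i0:i1] <- x[i0:i1] + template[(i0 - at + 1L):(i1 - at + 1L)]
  x
}

#' Calibrate theta-burst amplitudes against the dB measure
#'
#' Computes the burst amplitudes (µV at the Cz reference gain) that make
#' the pipeline's frontal-midline theta measure - Hann-window FFT power at
#' 4/6/8 Hz averaged over Fz and Cz and ±0.4 s, baseline-corrected in dB -
#' recover `theta_burst_db` (error responses) and `theta_correct_db`
#' (correct responses) in expectation.
#'
#' The expectation is evaluated under the generator's own noise model: the
#' windowed-FFT noise-bin variance is estimated from a long realization of
#' the 1/f background, the expected log power of burst-plus-noise is
#' computed with fixed common-random-number draws (random carrier phase,
#' complex Gaussian noise), and the amplitude solves a one-dimensional
#' root-finding problem. The procedure is deterministic: it uses a private,
#' fixed RNG substream and restores the caller's RNG state.
#'
#' The calibration also models the one effect of preprocessing that is not
#' negligible at theta frequencies: the joint-decorrelation blink cleaning
#' attenuates any source whose topography overlaps the blink topography.
#' With model covariances `C0 = sigma_n^2 I + sigma_b^2 bb' + sigma_t^2 tt'`
#' the cleaned burst gain at channel ch is
#' `t_ch - b_ch (b' C0^-1 t) / (b' C0^-1 b)`, and the cleaned noise
#' variance scales accordingly; both enter the expectation. The burst
#' variance term depends on the amplitudes being solved for, so the
#' calibration iterates the fixed point a few times.
#'
#' @param params `"group_params"`.
#' @param fs sampling rate (Hz).
#' @param n_draws Monte-Carlo draws for the expectation (default 6000).
#' @param soa_s,iti_mean_s trial-timing constants used to approximate the
#'   response rate (burst density) of the recording.
#' @param jd_removed will the pipeline remove a blink component (default 1,
#'   the preprocessing default)? Set 0 when cleaning is disabled.
#' @return list: `amp_error`, `amp_correct` (µV), `v_f` (noise-bin power at
#'   4/6/8 Hz in the pipeline's scaled units), `burst_gain` (effective
#'   Fz/Cz burst gains after cleaning).
#' @export
calibrate_theta_amplitude <- function(params, fs = 500, n_draws = 6000,
                                      soa_s = 0.15, iti_mean_s = 1.75,
                                      jd_removed = 1L) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(723901)

  nwin <- round(0.5 * fs)
  taper <- hann_taper(nwin)
  scale <- 2 / sum(taper)^2
  freqs <- c(4, 6, 8)
  bins <- freqs * 0.5 + 1L                 # FFT rows on the 2 Hz grid

  # noise-bin variance from a long background realization
  L <- 2^20
  noise <- pink_noise(L, fs, params$noise_exponent, params$noise_rms_uv)
  nseg <- L %/% nwin
  segs <- matrix(noise[seq_len(nseg * nwin)], nrow = nwin)
  co <- stats::mvfft(segs * taper)[bins, , drop = FALSE]
  v_f <- rowMeans(Mod(co)^2) * scale

  # quadrature burst spectra per summary-grid time (unit amplitude at Cz)
  env <- burst_envelope(fs)
  half <- (length(env) - 1L) %/% 2L
  tt <- ((-half):half) / fs
  cos_t <- env * cos(2 * pi * THETA_HZ * tt)
  sin_t <- env * sin(2 * pi * THETA_HZ * tt)
  grid_t <- seq(-0.4, 0.4, by = 0.05)
  seg_of <- function(w, tc) {
    idx <- round(tc * fs) + (-(nwin %/% 2L)):(nwin %/% 2L - 1L)
    out <- numeric(nwin)
    ok <- idx >= -half & idx <= half
    out[ok] <- w[idx[ok] + half + 1L]
    out
  }
  Fc <- sapply(grid_t, function(tc) fft(seg_of(cos_t, tc) * taper)[bins])
  Fs <- sapply(grid_t, function(tc) fft(seg_of(sin_t, tc) * taper)[bins])
  # Fc, Fs: 3 freqs x 17 times, complex, unscaled FFT units

  phi <- runif(n_draws, 0, 2 * pi)
  Z <- complex(real = rnorm(n_draws, 0, sqrt(0.5)),
               imaginary = rnorm(n_draws, 0, sqrt(0.5)))
  elog <- mean(10 * log10(Mod(Z)^2))   # log-of-chi-squared bias term

  # post-cleaning burst gains and noise-variance scaling at Fz/Cz
  bvec <- BLINK_TOPO[PERITHETA_CHANNELS]
  tvec <- BURST_TOPO[PERITHETA_CHANNELS]
  chs <- match(c("Fz", "Cz"), PERITHETA_CHANNELS)
  tpl <- blink_template(fs) * BLINK_AMP_UV
  s2b <- params$blink_rate_hz * sum(tpl^2) / fs
  resp_rate <- 1 / (iti_mean_s + soa_s + params$mean_rt_ms / 1000)
  e_burst <- sum(burst_envelope(fs)^2) / 2 / fs  # per response, unit amp
  s2n <- params$noise_rms_uv^2
  cleaning <- jd_removed >= 1L && params$blink_rate_hz > 0
  jd_model <- function(s2t) {
    if (!cleaning) {
      return(list(g = tvec[chs], ng = c(1, 1)))
    }
    C0 <- s2n * diag(length(bvec)) + s2b * outer(bvec, bvec) +
      s2t * outer(tvec, tvec)
    ci_b <- solve(C0, bvec)
    beta <- bvec * as.numeric(crossprod(ci_b, tvec) / crossprod(ci_b, bvec))
    g <- (tvec - beta)[chs]
    # noise variance after removing the estimated blink component
    G <- diag(length(bvec)) - outer(bvec, ci_b) / sum(ci_b * bvec)
    ng <- rowSums(G[chs, , drop = FALSE]^2)
    list(g = g, ng = ng)
  }

  measure <- function(amp, jd) {
    tot <- 0
    for (ch in 1:2) {
      vch <- v_f * jd$ng[ch]
      mu_base <- 10 * log10(vch) + elog
      for (fi in 1:3) {
        nf <- sqrt(vch[fi])
        for (ti in seq_along(grid_t)) {
          S0 <- (cos(phi) * Fc[fi, ti] - sin(phi) * Fs[fi, ti]) * sqrt(scale)
          mu_act <- mean(10 * log10(Mod(amp * jd$g[ch] * S0 + nf * Z)^2))
          tot <- tot + (mu_act - mu_base[fi])
        }
      }
    }
    tot / (3 * length(grid_t) * 2)
  }
  solve_amp <- function(target_db, jd) {
    if (target_db <= 0) return(0)
    exp(uniroot(function(la) measure(exp(la), jd) - target_db,
                interval = log(c(1e-3, 1e3)), tol = 1e-4)$root)
  }

  amp_e <- 0; amp_c <- 0; jd <- jd_model(0)
  for (it in 1:3) {                     # fixed point over the burst variance
    s2t <- resp_rate * e_burst *
      ((1 - params$error_rate) * amp_c^2 + params$error_rate * amp_e^2)
    jd <- jd_model(s2t)
    amp_e <- solve_amp(params$theta_burst_db, jd)
    amp_c <- solve_amp(params$theta_correct_db, jd)
  }
  list(amp_error = amp_e, amp_correct = amp_c, v_f = v_f,
       burst_gain = jd$g)
}

#' Render a continuous EEG recording for one subject
#'
#' Synthesizes a 10-channel, 500 Hz recording from a subject's behavioral
#' trial table: 1/f background noise per channel, a 50 Hz line component,
#' biphasic eyeblinks (frontal-weighted, mirrored into VEOG) at random
#' times, response-locked 6 Hz theta bursts (Hann envelope spanning ±0.4 s,
#' amplitudes calibrated so the analysis pipeline recovers the group's
#' `theta_burst_db` / `theta_correct_db`), and occasional high-amplitude
#' artifact segments exceeding the ±80 µV rejection threshold.
#'
#' @param behavior one subject's rows from [sample_behavior()].
#' @param params the subject's `"group_params"`.
#' @param seed integer seed for this recording.
#' @param calibration optional result of [calibrate_theta_amplitude()]
#'   (computed on the fly when missing; pass it when rendering a cohort to
#'   avoid recomputation).
#' @param fs sampling rate (Hz, default 500).
#' @return object of class `"recording_bundle"`: list with `eeg`
#'   (`"continuous_eeg"`), `events` (long-format events tibble), `subject`,
#'   `group`, `subtype`.
#' @export
render_eeg <- function(behavior, params, seed,
                       calibration = NULL, fs = 500) {
  stopifnot(inherits(params, "group_params"),
            length(unique(behavior$subject)) == 1L)
  if (is.null(calibration)) calibration <- calibrate_theta_amplitude(params, fs)
  set.seed(seed)
  dur <- max(behavior$response_onset_s) + 2.5
  n <- ceiling(dur * fs)
  nch <- length(PERITHETA_CHANNELS)

  X <- pink_noise(n, fs, params$noise_exponent, params$noise_rms_uv,
                  nch = nch)
  if (params$line_amp_uv > 0) {
    line_t <- 2 * pi * 50 * seq_len(n) / fs
    for (ci in seq_len(nch)) {
      X[ci, ] <- X[ci, ] +
        params$line_amp_uv * sin(line_t + runif(1, 0, 2 * pi))
    }
  }

  # eyeblinks: Poisson times with a 1 s refractory period
  tpl <- blink_template(fs) * BLINK_AMP_UV
  n_blinks <- rpois(1, params$blink_rate_hz * dur)
  bt <- sort(runif(n_blinks, 0.5, dur - 1))
  if (length(bt) > 1L) bt <- bt[c(TRUE, diff(bt) > 1)]
  blink_src <- numeric(n)
  for (t0 in bt) blink_src <- add_at(blink_src, tpl, round(t0 * fs) + 1L)
  X <- X + outer(BLINK_TOPO[PERITHETA_CHANNELS], blink_src)

  # response-locked theta bursts
  env <- burst_envelope(fs)
  half <- (length(env) - 1L) %/% 2L
  tt <- ((-half):half) / fs
  resp <- behavior[!behavior$miss, ]
  amps <- ifelse(resp$correct == 1L, calibration$amp_correct,
                 calibration$amp_error)
  burst_src <- numeric(n)
  for (i in seq_len(nrow(resp))) {
    if (amps[i] <= 0) next
    w <- amps[i] * env * cos(2 * pi * THETA_HZ * tt + runif(1, 0, 2 * pi))
    c0 <- round(resp$response_onset_s[i] * fs) + 1L
    burst_src <- add_at(burst_src, w, c0 - half)
  }
  X <- X + outer(BURST_TOPO[PERITHETA_CHANNELS], burst_src)

  # occasional high-amplitude artifact segments (exercise the rejection)
  art <- which(runif(nrow(resp)) < params$artifact_rate)
  if (length(art)) {
    na <- round(0.3 * fs)
    lump <- 150 * sin(pi * (seq_len(na) - 1) / (na - 1))
    for (i in art) {
      ch <- sample(seq_along(PERITHETA_SCALP), 1L)
      c0 <- round((resp$response_onset_s[i] + 0.1) * fs) + 1L
      X[ch, ] <- add_at(X[ch, ], lump, c0)
    }
  }

  eeg <- continuous_eeg(X, PERITHETA_CHANNELS, srate = fs,
                        meta = list(subject = behavior$subject[1],
                                    group = behavior$group[1],
                                    subtype = behavior$subtype[1]))
  out <- structure(list(eeg = eeg, events = behavior_to_events(behavior),
                        subject = behavior$subject[1],
                        group = behavior$group[1],
                        subtype = behavior$subtype[1]),
                   class = "recording_bundle")
  # generator ground truth, for parameter-recovery tests
  attr(out, "truth") <- list(
    blink_times_s = bt,
    artifact_trials = resp[art, c("block", "trial")],
    amp_error = calibration$amp_error,
    amp_correct = calibration$amp_correct)
  out
}

#' Generate a full synthetic cohort
#'
#' Samples the behavioral tables and (optionally) renders one EEG recording
#' per subject, reusing a single theta-amplitude calibration per group.
#'
#' @param params `"cohort_params"`.
#' @param eeg render EEG recordings too? (default TRUE; FALSE gives the
#'   much faster behavior-only cohort).
#' @return list: `behavior` (cohort tibble), `bundles` (named list of
#'   `"recording_bundle"`, NULL when `eeg = FALSE`), `params`.
#' @export
generate_cohort <- function(params, eeg = TRUE) {
  behavior <- sample_behavior(params)
  bundles <- NULL
  if (eeg) {
    calib <- list(TD = calibrate_theta_amplitude(params$td),
                  ADHD = calibrate_theta_amplitude(params$adhd))
    subjects <- unique(behavior$subject)
    bundles <- vector("list", length(subjects))
    names(bundles) <- subjects
    for (i in seq_along(subjects)) {
      sub <- behavior[behavior$subject == subjects[i], ]
      gp <- if (sub$group[1] == "TD") params$td else params$adhd
      bundles[[i]] <- render_eeg(sub, gp,
                                 seed = (params$seed + 7919L * i) %% .Machine$integer.max,
                                 calibration = calib[[sub$group[1]]])
    }
  }
  list(behavior = behavior, bundles = bundles, params = params)
}
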