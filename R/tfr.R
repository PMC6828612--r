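# Hann taper of length n (periodic-symmetric variant used throughout).
hann_taper <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

# dB floor guarding log(0) for silent segments.
DB_FLOOR <- -300

#' Moving-window FFT power of response-locked epochs
#'
#' Computes log spectral power on the canonical time-frequency grid: 0.5 s
#' Hann-tapered windows (250 samples at 500 Hz, no zero padding, hence an
#' exact 2 Hz bin spacing) whose centres move from -1.5 to +1.5 s relative
#' to the response in steps of 50 ms (61 grid times), evaluated at
#' 2, 4, ..., 36 Hz (18 bins). Power is scaled so that a sinusoid of
#' amplitude A at a bin frequency yields `A^2 / 2` (µV² units) and then
#' log-transformed as `10 * log10(power)`, floored at -300 dB, so that
#' later differences are in dB.
#'
#' A window centred at grid time t covers samples `t*fs - 125 .. t*fs + 124`
#' relative to the response sample; epochs must span at least ±1.75 s so
#' every window fits.
#'
#' @param epochs `"epoch_set"` (typically from [preprocess_eeg()]); only
#'   unrejected epochs are transformed.
#' @param channels channels to transform (default: all in the epoch set).
#' @param tmin,tmax,tstep grid-time parameters in seconds.
#' @param fmin,fmax,fstep frequency-grid parameters in Hz.
#' @param window_s window length in seconds (default 0.5).
#' @return object of class `"tfr"`: list with `power` (array trials x
#'   channels x frequencies x times, 10*log10 µV²), `freqs`, `times`,
#'   `channels`, `meta`, `baseline_corrected = FALSE`.
#' @export
stft_power <- function(epochs, channels = NULL,
                       tmin = -1.5, tmax = 1.5, tstep = 0.05,
                       fmin = 2, fmax = 36, fstep = 2, window_s = 0.5) {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- round(1 / diff(epochs$times[1:2]))
  if (is.null(channels)) channels <- epochs$channels
  ch_idx <- match(channels, epochs$channels)
  if (anyNA(ch_idx)) stop("channel(s) not present: ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))
  nwin <- round(window_s * fs)
  grid_t <- seq(tmin, tmax, by = tstep)
  freqs <- seq(fmin, fmax, by = fstep)
  bins <- freqs * window_s           # cycles per window
  if (any(abs(bins - round(bins)) > 1e-9)) {
    stop("frequency grid must align with the 1/window_s bin spacing")
  }
  bins <- round(bins)
  if (min(epochs$times) > tmin - window_s / 2 + 1e-9 ||
      max(epochs$times) < tmax + window_s / 2 - 1e-9) {
    stop("epochs too short: need data spanning the full window at every grid time")
  }
  keep <- which(epochs$mask)
  nt <- length(keep)
  taper <- hann_taper(nwin)
  scale <- 2 / sum(taper)^2          # sinusoid amplitude A -> power A^2/2
  # window start sample (in the epoch time axis) per grid time
  t0_idx <- vapply(grid_t, function(t) {
    which.min(abs(epochs$times - t))
  }, integer(1)) - (nwin %/% 2)
  seg_idx <- outer(seq_len(nwin) - 1L, t0_idx, `+`)   # nwin x ntimes
  # tapered DFT basis restricted to the requested bins (nwin x nfreq);
  # power via one complex matrix product per channel
  basis <- exp(-2i * pi * outer(seq_len(nwin) - 1L, bins) / nwin) * taper
  pow <- array(NA_real_, c(nt, length(ch_idx), length(freqs), length(grid_t)))
  ntt <- length(grid_t)
  for (ci in seq_along(ch_idx)) {
    segs <- matrix(0, nwin, ntt * nt)
    for (i in seq_len(nt)) {
      x <- epochs$data[keep[i], ch_idx[ci], ]
      segs[, ((i - 1L) * ntt + 1L):(i * ntt)] <- matrix(x[seg_idx], nrow = nwin)
    }
    co <- crossprod(segs, basis)            # (ntt*nt) x nfreq, complex
    p <- (Mod(co)^2) * scale
    pow[, ci, , ] <- aperm(array(p, c(ntt, nt, length(freqs))), c(2, 3, 1))
  }
  pow <- 10 * log10(pmax(pow, 10^(DB_FLOOR / 10)))
  structure(list(power = pow, freqs = freqs, times = grid_t,
                 channels = channels, meta = epochs$meta[keep, ],
                 baseline_corrected = FALSE),
            class = "tfr")
}

#' @export
print.tfr <- function(x, ...) {
  cat(sprintf("TFR: %d trials x %d channels x %d freqs x %d times (%s)\n",
              dim(x$power)[1], dim(x$power)[2], dim(x$power)[3],
              dim(x$power)[4],
              if (x$baseline_corrected) "dB vs baseline" else "10*log10 uV^2"))
  invisible(x)
}

#' Trial-wise pre-prime dB baseline correction
#'
#' For each trial and frequency, subtracts the mean log power of the grid
#' windows whose centres fall between -0.75 and -0.25 s relative to that
#' trial's prime onset (located inside the response-locked epoch via the
#' stored prime-onset offset). Because windows are 0.5 s long, the baseline
#' draws on data from -1 to 0 s relative to the prime. After correction
#' values are dB differences from baseline. Trials whose baseline window
#' falls entirely outside the grid are flagged and excluded
#' (`baseline_ok = FALSE` in `meta`).
#'
#' @param tfr `"tfr"` from [stft_power()] (not yet baseline-corrected).
#' @param baseline_window baseline limits in seconds relative to the prime
#'   (default `c(-0.75, -0.25)`).
#' @return baseline-corrected `"tfr"` (`baseline_corrected = TRUE`); `meta`
#'   gains a `baseline_ok` column.
#' @export
baseline_correct <- function(tfr, baseline_window = c(-0.75, -0.25)) {
  stopifnot(inherits(tfr, "tfr"), !tfr$baseline_corrected)
  if (is.null(tfr$meta$prime_offset_s)) {
    stop("per-trial prime offsets missing from `meta`")
  }
  nt <- dim(tfr$power)[1]
  ok <- logical(nt)
  for (i in seq_len(nt)) {
    t_rel_prime <- tfr$times - tfr$meta$prime_offset_s[i]
    sel <- which(t_rel_prime >= baseline_window[1] - 1e-9 &
                   t_rel_prime <= baseline_window[2] + 1e-9)
    if (length(sel) == 0L) next
    ok[i] <- TRUE
    base <- apply(tfr$power[i, , , sel, drop = FALSE], c(2, 3), mean)
    tfr$power[i, , , ] <- tfr$power[i, , , ] - as.vector(base)
  }
  if (any(!ok)) {
    message(sum(!ok), " trial(s) without a valid pre-prime baseline; flagged")
  }
  tfr$meta$baseline_ok <- ok
  tfr$baseline_corrected <- TRUE
  tfr
}

#' Frontal-midline theta timecourse
#'
#' Averages baseline-corrected time-frequency power over the theta band
#' (bins 4, 6 and 8 Hz on the 2 Hz grid) and the fronto-central electrodes
#' Fz and Cz, in the dB domain, yielding one timecourse per trial.
#'
#' @param tfr `"tfr"` (baseline-corrected).
#' @param channels electrodes to average (default `c("Fz", "Cz")`).
#' @param band theta band limits in Hz (default `c(4, 8)`, inclusive).
#' @return object of class `"theta_timecourse"`: list with `values`
#'   (matrix trials x times, dB), `times`, `meta`.
#' @export
fmtheta_timecourse <- function(tfr, channels = c("Fz", "Cz"),
                               band = c(4, 8)) {
  stopifnot(inherits(tfr, "tfr"))
  ch_idx <- match(channels, tfr$channels)
  if (anyNA(ch_idx)) stop("channel(s) not present: ",
                          paste(channels[is.na(ch_idx)], collapse = ", "))
  f_idx <- which(tfr$freqs >= band[1] - 1e-9 & tfr$freqs <= band[2] + 1e-9)
  vals <- apply(tfr$power[, ch_idx, f_idx, , drop = FALSE], c(1, 4), mean)
  structure(list(values = vals, times = tfr$times, meta = tfr$meta),
            class = "theta_timecourse")
}

#' Per-trial time-averaged theta summaries
#'
#' Averages each trial's theta timecourse over -0.4 to +0.4 s relative to
#' the response (17 grid points). In mode `"vs_baseline"` the dB values are
#' kept as they are (power relative to the pre-prime baseline); in mode
#' `"vs_errorfree"` the subject's mean error-free summary is subtracted, so
#' error-free trials average to zero per subject by construction. Subjects
#' without error-free trials are excluded from `"vs_errorfree"` with a
#' message.
#'
#' @param timecourse `"theta_timecourse"` whose `meta` carries `peri_label`
#'   (attach labels before calling, e.g. via [run_pipeline()]).
#' @param mode `"vs_baseline"` or `"vs_errorfree"`.
#' @param window summary window in seconds (default `c(-0.4, 0.4)`).
#' @return tibble: one row per trial with `subject`, `group`, `subtype`,
#'   `peri_label`, `theta_db`, `mode`.
#' @export
theta_summaries <- function(timecourse, mode = c("vs_baseline", "vs_errorfree"),
                            window = c(-0.4, 0.4)) {
  mode <- match.arg(mode)
  stopifnot(inherits(timecourse, "theta_timecourse"))
  meta <- timecourse$meta
  if (is.null(meta$peri_label)) stop("`meta` lacks a `peri_label` column")
  sel <- which(timecourse$times >= window[1] - 1e-9 &
                 timecourse$times <= window[2] + 1e-9)
  val <- rowMeans(timecourse$values[, sel, drop = FALSE])
  if (!is.null(meta$baseline_ok)) {
    val[!meta$baseline_ok] <- NA_real_
  }
  out <- tibble::tibble(
    subject = meta$subject, group = meta$group,
    subtype = if (!is.null(meta$subtype)) meta$subtype else NA_character_,
    peri_label = meta$peri_label, theta_db = val, mode = mode)
  out <- out[!is.na(out$theta_db), ]
  if (mode == "vs_errorfree") {
    ef <- dplyr::summarise(
      dplyr::group_by(out[out$peri_label == "ERROR_FREE", ], .data$subject),
      ef_mean = mean(.data$theta_db), .groups = "drop")
    no_ef <- setdiff(unique(out$subject), ef$subject)
    if (length(no_ef)) {
      message(length(no_ef),
              " subject(s) without error-free trials excluded from vs_errorfree")
      out <- out[!(out$subject %in% no_ef), ]
    }
    out$theta_db <- out$theta_db - ef$ef_mean[match(out$subject, ef$subject)]
  }
  out
}

#' Subject-level theta means per peri-error condition
#'
#' Collapses per-trial theta summaries to one mean per subject and
#' condition label - the unit on which the group-level mixed models and
#' t-tests operate.
#'
#' @param summaries tibble from [theta_summaries()].
#' @return tibble: `subject`, `group`, `subtype`, `peri_label`, `mode`,
#'   `theta_db` (mean), `n_trials`.
#' @export
theta_subject_means <- function(summaries) {
  dplyr::summarise(
    dplyr::group_by(summaries, .data$subject, .data$group, .data$subtype,
                    .data$peri_label, .data$mode),
    n_trials = dplyr::n(), theta_db = mean(.data$theta_db),
    .groups = "drop")
}
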