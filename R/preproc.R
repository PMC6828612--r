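#' Construct a continuous EEG object
#'
#' @param data numeric matrix, channels x samples, microvolts.
#' @param channels character vector of channel labels (unique).
#' @param srate sampling rate in Hz (the pipeline requires 500).
#' @param meta optional named list of subject metadata.
#' @return object of class `"continuous_eeg"`.
#' @export
continuous_eeg <- function(data, channels, srate = 500, meta = list()) {
  data <- as.matrix(data)
  stopifnot(nrow(data) == length(channels), !anyDuplicated(channels),
            all(is.finite(data)))
  structure(list(data = data, channels = channels, srate = srate,
                 meta = meta), class = "continuous_eeg")
}

#' @export
print.continuous_eeg <- function(x, ...) {
  cat(sprintf("continuous EEG: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$srate, ncol(x$data) / x$srate))
  invisible(x)
}

# Zero-phase application of a cascade of second-order sections.
filtfilt_sections <- function(x, sections) {
  for (s in sections) x <- .filtfilt_channels_cpp(s$b, s$a, x)
  x
}

# Analytic biquad sections of an even-order digital Butterworth high/low
# pass (bilinear transform with prewarping, section Q factors from the
# Butterworth pole angles). Numerically far better conditioned than the
# expanded transfer function when the band edge is a tiny fraction of the
# sampling rate.
butter_sections <- function(order, f, fs, type = c("low", "high")) {
  type <- match.arg(type)
  stopifnot(order %% 2 == 0)
  wc <- tan(pi * f / fs)
  lapply(seq_len(order / 2), function(k) {
    Q <- 1 / (2 * cos((2 * k - 1) * pi / (2 * order)))
    c0 <- 1 + wc / Q + wc^2
    b <- if (type == "low") c(wc^2, 2 * wc^2, wc^2) / c0 else
      c(1, -2, 1) / c0
    list(b = b, a = c(1, 2 * (wc^2 - 1) / c0, (1 - wc / Q + wc^2) / c0))
  })
}

# Factor a real transfer function into biquad sections (conjugate pole and
# zero pairs via polyroot), used for the band-stop notch.
tf2sections <- function(b, a) {
  pair_quads <- function(coefs) {
    r <- polyroot(rev(coefs / coefs[1]))
    r <- r[order(Arg(r))]
    up <- r[Im(r) > 1e-9]
    quads <- lapply(up, function(p) c(1, -2 * Re(p), Mod(p)^2))
    real_r <- Re(r[abs(Im(r)) <= 1e-9])
    if (length(real_r) %% 2) stop("odd number of real roots")
    if (length(real_r)) {
      real_r <- sort(real_r)
      for (i in seq(1, length(real_r), by = 2)) {
        quads <- c(quads, list(c(1, -(real_r[i] + real_r[i + 1]),
                                 real_r[i] * real_r[i + 1])))
      }
    }
    quads
  }
  qb <- pair_quads(b); qa <- pair_quads(a)
  if (length(qb) != length(qa)) stop("cannot pair sections")
  gain <- (b[1] / a[1])^(1 / length(qb))
  mapply(function(bq, aq) list(b = gain * bq, a = aq),
         qb, qa, SIMPLIFY = FALSE)
}

#' Zero-phase 50 Hz notch filter
#'
#' Band-stop Butterworth filter (order 4 per pass, stopband 48.5-51.5 Hz)
#' applied forward and backward (zero phase, squared magnitude response).
#'
#' @param eeg `"continuous_eeg"` object sampled at 500 Hz.
#' @return filtered `"continuous_eeg"`.
#' @export
notch_filter <- function(eeg) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (eeg$srate != 500) stop("notch filter is specified for 500 Hz data")
  bf <- signal::butter(4, c(48.5, 51.5) / (eeg$srate / 2), type = "stop")
  eeg$data <- filtfilt_sections(eeg$data, tf2sections(bf$b, bf$a))
  eeg
}

#' Zero-phase 0.3-40 Hz band-pass filter
#'
#' Fourth-order Butterworth high-pass at 0.3 Hz cascaded with a
#' fourth-order low-pass at 40 Hz, each applied forward and backward
#' (zero phase). The cascade is used instead of a single band-pass
#' transfer function because an 0.3 Hz band edge at 500 Hz makes the
#' direct-form band-pass numerically unstable; the cascade has the same
#' nominal edges and doubled effective order from the two passes.
#'
#' @param eeg `"continuous_eeg"` object sampled at 500 Hz.
#' @return filtered `"continuous_eeg"`.
#' @export
bandpass_filter <- function(eeg) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  if (eeg$srate != 500) stop("band-pass filter is specified for 500 Hz data")
  sections <- c(butter_sections(4, 0.3, eeg$srate, "high"),
                butter_sections(4, 40, eeg$srate, "low"))
  eeg$data <- filtfilt_sections(eeg$data, sections)
  eeg
}

#' Detect eyeblinks in the vertical EOG channel
#'
#' Threshold peak detection: samples where `|VEOG - median|` exceeds
#' `k * MAD` are candidate blink samples; local maxima of the rectified
#' signal are kept with a minimum separation (refractory period), stronger
#' peaks winning ties.
#'
#' @param veog numeric vector, the vertical EOG channel (µV).
#' @param srate sampling rate (Hz).
#' @param k MAD multiplier for the detection threshold (default 5).
#' @param min_sep_s minimum separation between blink peaks in seconds
#'   (default 0.3).
#' @return list of class `"blink_events"`: `peaks` (strictly increasing
#'   sample indices), `threshold` (µV deviation from median), `k`.
#' @export
detect_blinks <- function(veog, srate = 500, k = 5, min_sep_s = 0.3) {
  med <- median(veog)
  dev <- abs(veog - med)
  scale <- mad(veog)
  if (scale == 0) {
    warning("flat VEOG channel; no blinks detected")
    return(structure(list(peaks = integer(0), threshold = Inf, k = k),
                     class = "blink_events"))
  }
  thr <- k * scale
  above <- dev > thr
  if (!any(above)) {
    return(structure(list(peaks = integer(0), threshold = thr, k = k),
                     class = "blink_events"))
  }
  # contiguous supra-threshold runs -> peak sample of each run
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  cand <- vapply(runs, function(i) {
    seg <- starts[i]:ends[i]
    seg[which.max(dev[seg])]
  }, integer(1))
  # enforce refractory period, strongest peaks first
  min_sep <- round(min_sep_s * srate)
  keep <- logical(length(cand))
  for (i in order(dev[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_sep)) keep[i] <- TRUE
  }
  structure(list(peaks = sort(cand[keep]), threshold = thr, k = k),
            class = "blink_events")
}

#' Remove ocular artifacts by joint decorrelation
#'
#' Targeted spatial filtering: a bias covariance is estimated from
#' blink-centred windows (default ±300 ms) and a reference covariance from
#' the whole recording; the generalized eigendecomposition of the pair
#' yields components ordered by blink-to-total power ratio. The leading
#' components (default: the single strongest, or all with eigenvalue ratio
#' above `ratio_threshold` if that is given) are projected out and the data
#' reconstructed in sensor space. With a rank-1 blink source and enough
#' data this removes the blink contribution while leaving uncorrelated
#' brain sources untouched.
#'
#' @param eeg `"continuous_eeg"` (all channels, including EOG).
#' @param blinks `"blink_events"` from [detect_blinks()].
#' @param window_s half-width of the blink window in seconds (default 0.3).
#' @param n_remove number of components to remove (default 1). Ignored when
#'   `ratio_threshold` is given.
#' @param ratio_threshold optional eigenvalue-ratio threshold (e.g. 3):
#'   remove every component whose blink-to-total power ratio, normalized by
#'   the median ratio, exceeds it.
#' @return cleaned `"continuous_eeg"`; attributes `removed` (component
#'   count) and `eigenratios` record what was projected out.
#' @export
joint_decorrelation_clean <- function(eeg, blinks, window_s = 0.3,
                                      n_remove = 1L, ratio_threshold = NULL) {
  stopifnot(inherits(eeg, "continuous_eeg"), inherits(blinks, "blink_events"))
  if (nrow(eeg$data) < 2L) stop("joint decorrelation needs at least 2 channels")
  if (length(blinks$peaks) < 1L) stop("no blink events supplied")
  X <- eeg$data
  nsmp <- ncol(X)
  hw <- round(window_s * eeg$srate)
  sel <- unlist(lapply(blinks$peaks, function(p) {
    max(1L, p - hw):min(nsmp, p + hw)
  }))
  sel <- unique(sel)
  Xc <- X - rowMeans(X)
  C0 <- tcrossprod(Xc) / nsmp
  Cb <- tcrossprod(Xc[, sel, drop = FALSE]) / length(sel)
  # ridge-regularize against rank deficiency
  ridge <- 1e-9 * sum(diag(C0))
  C0 <- C0 + ridge * diag(nrow(C0))
  # generalized eigendecomposition of (Cb, C0) via whitening
  e0 <- eigen(C0, symmetric = TRUE)
  W0 <- e0$vectors %*% diag(1 / sqrt(e0$values)) %*% t(e0$vectors)
  eb <- eigen(W0 %*% Cb %*% W0, symmetric = TRUE)
  W <- W0 %*% eb$vectors              # unmixing: columns sorted by ratio
  ratios <- eb$values
  if (!is.null(ratio_threshold)) {
    n_remove <- sum(ratios / median(ratios) > ratio_threshold)
  }
  if (n_remove == 0L) {
    out <- eeg
    attr(out, "removed") <- 0L
    attr(out, "eigenratios") <- ratios
    return(out)
  }
  if (n_remove >= nrow(X)) {
    warning("removing all components yields an all-zero recording")
  }
  M <- solve(t(W))                    # mixing: X = M %*% (t(W) %*% X)
  rm_idx <- seq_len(min(n_remove, nrow(X)))
  Y <- t(W[, rm_idx, drop = FALSE]) %*% X
  eeg$data <- X - M[, rm_idx, drop = FALSE] %*% Y
  attr(eeg, "removed") <- length(rm_idx)
  attr(eeg, "eigenratios") <- ratios
  eeg
}

#' Cut response-locked epochs
#'
#' Segments the continuous recording into epochs from -2 to +2 s around
#' every response event (2001 samples at 500 Hz; sample 1001 is the
#' response sample). Responses without 2 s of data on both sides are
#' dropped and logged. The prime-onset offset (prime minus response, in
#' seconds, negative) is stored per trial for the pre-prime baseline of the
#' time-frequency stage.
#'
#' @param eeg `"continuous_eeg"`.
#' @param events events tibble (the [behavior_to_events()] schema) for one
#'   subject; only `response` rows are used, and matching `prime` rows
#'   supply the baseline offsets.
#' @param tmin,tmax epoch limits in seconds (defaults -2, +2).
#' @return object of class `"epoch_set"`: list with `data` (array trials x
#'   channels x samples), `times` (seconds, 0 = response), `channels`,
#'   `meta` (per-trial tibble incl. `prime_offset_s`), `mask` (logical,
#'   TRUE = retained), `dropped` (log tibble of skipped responses).
#' @export
epoch_responses <- function(eeg, events, tmin = -2, tmax = 2) {
  stopifnot(inherits(eeg, "continuous_eeg"))
  fs <- eeg$srate
  resp <- events[events$event_type == "response", ]
  prim <- events[events$event_type == "prime", ]
  key <- interaction(resp$block, resp$trial)
  prime_onset <- prim$onset_s[match(key, interaction(prim$block, prim$trial))]
  n0 <- round(tmin * fs); n1 <- round(tmax * fs)
  times <- seq(n0, n1) / fs
  centers <- round(resp$onset_s * fs) + 1L
  ok <- centers + n0 >= 1L & centers + n1 <= ncol(eeg$data)
  dropped <- resp[!ok, c("block", "trial", "onset_s")]
  if (nrow(dropped)) {
    message(nrow(dropped), " response(s) too close to the recording edge; dropped")
  }
  resp <- resp[ok, ]; centers <- centers[ok]; prime_onset <- prime_onset[ok]
  nt <- length(centers)
  dat <- array(NA_real_, c(nt, nrow(eeg$data), length(times)))
  for (i in seq_len(nt)) {
    dat[i, , ] <- eeg$data[, (centers[i] + n0):(centers[i] + n1)]
  }
  meta <- tibble::as_tibble(resp[c("subject", "group", "subtype", "block",
                                   "trial", "compatibility", "correct",
                                   "rt_ms")])
  meta$prime_offset_s <- prime_onset - resp$onset_s
  structure(list(data = dat, times = times, channels = eeg$channels,
                 meta = meta, mask = rep(TRUE, nt), dropped = dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch set: %d trials x %d channels x %d samples (%g..%g s); %d rejected\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times), max(x$times), sum(!x$mask)))
  invisible(x)
}

#' Amplitude-threshold artifact rejection
#'
#' Marks an epoch as rejected when any sample of any scalp channel exceeds
#' the threshold in absolute value (default ±80 µV). EOG channels are
#' exempt (ocular activity is handled by joint decorrelation).
#'
#' @param epochs `"epoch_set"`.
#' @param threshold_uv rejection threshold in µV (default 80).
#' @param exclude_channels channels exempt from the criterion
#'   (default VEOG, HEOG).
#' @return the epoch set with its `mask` updated (`FALSE` = rejected).
#' @export
reject_artifacts <- function(epochs, threshold_uv = 80,
                             exclude_channels = c("VEOG", "HEOG")) {
  stopifnot(inherits(epochs, "epoch_set"))
  chans <- which(!(epochs$channels %in% exclude_channels))
  bad <- apply(epochs$data[, chans, , drop = FALSE], 1L,
               function(m) any(abs(m) > threshold_uv))
  epochs$mask <- epochs$mask & !bad
  epochs
}

#' Run the fixed preprocessing chain
#'
#' Applies, in the documented fixed order: notch filter, band-pass filter,
#' blink detection (VEOG), joint decorrelation cleaning, response-locked
#' epoching, and ±80 µV artifact rejection.
#'
#' @param eeg `"continuous_eeg"` with a `VEOG` channel.
#' @param events events tibble for the same subject.
#' @param blink_k MAD multiplier for blink detection.
#' @param n_remove joint-decorrelation components to remove (default 1).
#' @param threshold_uv rejection threshold (µV).
#' @return `"epoch_set"` after rejection; attribute `"blinks"` carries the
#'   detected blink events.
#' @export
preprocess_eeg <- function(eeg, events, blink_k = 5, n_remove = 1L,
                           threshold_uv = 80) {
  eeg <- notch_filter(eeg)
  eeg <- bandpass_filter(eeg)
  blinks <- detect_blinks(eeg$data[match("VEOG", eeg$channels), ], eeg$srate,
                          k = blink_k)
  if (length(blinks$peaks) > 0L) {
    eeg <- joint_decorrelation_clean(eeg, blinks, n_remove = n_remove)
  }
  epochs <- epoch_responses(eeg, events)
  epochs <- reject_artifacts(epochs, threshold_uv = threshold_uv)
  attr(epochs, "blinks") <- blinks
  epochs
}
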