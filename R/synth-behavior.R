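#' Group-level generator parameters
#'
#' Bundles every behavioral and EEG effect injected for one group of a
#' synthetic cohort. Defaults reproduce the study conditions the pipeline is
#' designed for: a typically-developing (TD) group with mean error-free RT
#' 427 ms (SD 31 ms) and error rate 0.068, and an ADHD group with 459 ms
#' (SD 41 ms) and error rate 0.097. Peri-error offsets are expressed in
#' within-subject SD units of error-free RT: errors at -1.39, pre-error
#' speeding (-0.16, -0.26, -0.36) over ER-3..ER-1 (a -0.1 SD/trial ramp),
#' and group-specific post-error recovery - immediate in TD (0, 0, 0),
#' delayed in ADHD (-0.44, -0.02, 0), i.e. a 0.42 SD ER+1 to ER+2 slowing.
#'
#' @param group group label, e.g. `"TD"` or `"ADHD"`.
#' @param mean_rt_ms mean error-free RT (ms).
#' @param sd_rt_ms within-subject SD of error-free RT (ms).
#' @param error_rate commission-error probability per trial (0, 0.5).
#' @param miss_rate missed-response probability per trial (default 0).
#' @param z_error error-trial RT offset, SD units.
#' @param z_pre offsets for ER-3, ER-2, ER-1 (SD units).
#' @param z_post offsets for ER+1, ER+2, ER+3 (SD units).
#' @param compat_effect_ms compatibility effect (compatible minus
#'   incompatible RT, ms) on error-free and pre-error trials.
#' @param compat_post_increment_ms additional compatibility effect on ER+1
#'   trials relative to ER-1 (ms).
#' @param theta_burst_db error-locked frontal-midline theta power above the
#'   pre-prime baseline, in dB, as recovered by the time-frequency pipeline.
#' @param theta_correct_db same for correct responses.
#' @param subject_sd between-subject SD of the RT intercept (SD units).
#' @param blink_rate_hz eyeblink rate (events/s) in the EEG renderer.
#' @param noise_exponent spectral exponent of the 1/f EEG background.
#' @param noise_rms_uv RMS amplitude of the EEG background per channel (µV).
#' @param line_amp_uv 50 Hz line-noise amplitude (µV).
#' @param artifact_rate fraction of trials receiving an injected
#'   high-amplitude (>80 µV) artifact segment, to exercise rejection.
#' @return object of class `"group_params"` (a named list).
#' @export
group_params <- function(group = "TD",
                         mean_rt_ms = 427, sd_rt_ms = 31,
                         error_rate = 0.068, miss_rate = 0,
                         z_error = -1.39,
                         z_pre = c(-0.16, -0.26, -0.36),
                         z_post = c(0, 0, 0),
                         compat_effect_ms = 20,
                         compat_post_increment_ms = 27,
                         theta_burst_db = 3.0,
                         theta_correct_db = 0.8,
                         subject_sd = sqrt(0.05),
                         blink_rate_hz = 0.25,
                         noise_exponent = 1,
                         noise_rms_uv = 10,
                         line_amp_uv = 2,
                         artifact_rate = 0.02) {
  stopifnot(error_rate > 0 || error_rate == 0, error_rate < 0.5,
            sd_rt_ms > 0, length(z_pre) == 3L, length(z_post) == 3L,
            theta_burst_db >= 0, theta_correct_db >= 0,
            miss_rate >= 0, miss_rate < 0.5)
  structure(list(
    group = group, mean_rt_ms = mean_rt_ms, sd_rt_ms = sd_rt_ms,
    error_rate = error_rate, miss_rate = miss_rate, z_error = z_error,
    z_pre = z_pre, z_post = z_post, compat_effect_ms = compat_effect_ms,
    compat_post_increment_ms = compat_post_increment_ms,
    theta_burst_db = theta_burst_db, theta_correct_db = theta_correct_db,
    subject_sd = subject_sd, blink_rate_hz = blink_rate_hz,
    noise_exponent = noise_exponent, noise_rms_uv = noise_rms_uv,
    line_amp_uv = line_amp_uv, artifact_rate = artifact_rate),
    class = "group_params")
}

#' Default ADHD-group parameters
#'
#' [group_params()] preset for the synthetic ADHD group: slower and more
#' variable error-free RT (459 ms, SD 41 ms), higher error rate (0.097),
#' delayed post-error recovery (ER+1 at -0.44 SD, recovery only at ER+2)
#' and an attenuated error-locked theta burst (1.5 dB vs 3.0 dB).
#'
#' @param ... overrides passed on to [group_params()].
#' @return object of class `"group_params"`.
#' @export
adhd_group_params <- function(...) {
  defaults <- list(group = "ADHD", mean_rt_ms = 459, sd_rt_ms = 41,
                   error_rate = 0.097, z_post = c(-0.44, -0.02, 0),
                   theta_burst_db = 1.5)
  do.call(group_params, modifyList(defaults, list(...)))
}

#' Cohort-level generator parameters
#'
#' @param n_td,n_adhd subjects per group (defaults 14 and 26, the group
#'   sizes entering the peri-error analyses).
#' @param trials_per_block trials per block (default 96).
#' @param n_blocks number of blocks (default 3; 288 trials total).
#' @param seed integer RNG seed; a fixed seed makes the cohort fully
#'   reproducible.
#' @param td,adhd [group_params()] objects for the two groups.
#' @param soa_s prime-to-target stimulus-onset asynchrony, seconds
#'   (default 0.15).
#' @param iti_range_s inter-trial interval (response to next prime) range,
#'   seconds; jittered uniformly (default 1.5-2.0 s, which guarantees the
#'   pre-prime baseline window never overlaps the previous response's
#'   ±0.4 s theta window).
#' @param max_retries bound on correctness-layout resampling when enforcing
#'   at least five isolated errors per subject.
#' @return object of class `"cohort_params"`.
#' @export
cohort_params <- function(n_td = 14, n_adhd = 26,
                          trials_per_block = 96, n_blocks = 3,
                          seed = 1,
                          td = group_params(),
                          adhd = adhd_group_params(),
                          soa_s = 0.15,
                          iti_range_s = c(1.5, 2.0),
                          max_retries = 500L) {
  stopifnot(n_td >= 1, n_adhd >= 1, trials_per_block >= 1, n_blocks >= 1,
            inherits(td, "group_params"), inherits(adhd, "group_params"),
            length(iti_range_s) == 2L, iti_range_s[1] >= 1.2)
  structure(list(n_td = n_td, n_adhd = n_adhd,
                 trials_per_block = trials_per_block, n_blocks = n_blocks,
                 seed = seed, td = td, adhd = adhd, soa_s = soa_s,
                 iti_range_s = iti_range_s, max_retries = max_retries),
            class = "cohort_params")
}

# Correctness layout with >= min_iso isolated errors, resampled up to
# max_retries times. Errors out for pathological rates.
sample_correctness <- function(n_trials, n_blocks, error_rate, miss_rate,
                               min_iso = 5L, max_retries = 500L) {
  block <- rep(seq_len(n_blocks), each = n_trials)
  if (error_rate == 0) min_iso <- 0L   # no-error cohort: nothing to isolate
  for (i in seq_len(max_retries)) {
    u <- runif(n_blocks * n_trials)
    err <- u < error_rate
    mis <- u >= error_rate & u < error_rate + miss_rate
    correct <- !(err | mis)
    lab <- classify_trials(correct, block, miss = mis)
    if (sum(lab == "ERROR_ISOLATED") >= min_iso) {
      return(list(correct = correct, miss = mis, block = block, label = lab))
    }
  }
  stop("could not obtain ", min_iso, " isolated errors in ", max_retries,
       " layouts; error_rate/miss_rate are pathological for this trial count")
}

# Stimulus/response timeline for one subject. Blocks are separated by a 5 s
# pause; a 2 s lead-in and 2.5 s tail give epoching room at the edges.
build_timeline <- function(block, rt_s, soa_s, iti_range_s) {
  n <- length(block)
  iti <- runif(n, iti_range_s[1], iti_range_s[2])
  prime <- numeric(n); target <- numeric(n); resp <- numeric(n)
  t_cur <- 2.0
  for (i in seq_len(n)) {
    if (i > 1L && block[i] != block[i - 1L]) t_cur <- t_cur + 5.0
    prime[i] <- t_cur
    target[i] <- prime[i] + soa_s
    resp[i] <- target[i] + rt_s[i]
    t_cur <- resp[i] + iti[i]
  }
  tibble::tibble(prime_onset_s = prime, target_onset_s = target,
                 response_onset_s = resp)
}

#' Sample behavioral trial tables for a synthetic cohort
#'
#' Draws, for every subject, a correctness layout (resampled until at least
#' five isolated errors exist), a stimulus/response timeline, and
#' standardized-RT values built as subject intercept + peri-error offset +
#' compatibility effect + Gaussian residual, where the compatibility and
#' residual components are scaled so error-free trials have unit
#' within-subject variance. RTs are `mean_rt_ms + z * sd_rt_ms`. Peri-error
#' offsets are applied only around isolated errors; all commission errors
#' receive the error offset.
#'
#' @param params a [cohort_params()] object.
#' @return tibble with one row per trial and columns `subject`, `group`,
#'   `subtype`, `block`, `trial`, `compatibility`, `correct`, `miss`,
#'   `rt_ms`, `prime_onset_s`, `target_onset_s`, `response_onset_s`, and the
#'   generator ground truth `z_true` and `label_true`.
#' @export
sample_behavior <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n_trials <- params$trials_per_block * params$n_blocks
  groups <- c(rep("TD", params$n_td), rep("ADHD", params$n_adhd))
  out <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    gp <- if (groups[s] == "TD") params$td else params$adhd
    subtype <- if (groups[s] == "ADHD") {
      sample(c("I", "H/C"), 1L, prob = c(13, 19))
    } else NA_character_
    lay <- sample_correctness(params$trials_per_block, params$n_blocks,
                              gp$error_rate, gp$miss_rate,
                              max_retries = params$max_retries)
    compat <- sample(c("compatible", "incompatible"),
                     n_trials, replace = TRUE)
    z <- synth_z(lay, compat, gp)
    rt_ms <- gp$mean_rt_ms + z * gp$sd_rt_ms
    rt_ms <- pmax(rt_ms, 50)          # physical floor; essentially never hit
    rt_ms[lay$miss] <- NA_real_
    rt_fill <- ifelse(is.na(rt_ms), gp$mean_rt_ms, rt_ms)
    tl <- build_timeline(lay$block, rt_fill / 1000,
                         params$soa_s, params$iti_range_s)
    out[[s]] <- tibble::tibble(
      subject = sprintf("sub-%03d", s), group = groups[s], subtype = subtype,
      block = lay$block,
      trial = rep(seq_len(params$trials_per_block), params$n_blocks),
      compatibility = compat, correct = as.integer(lay$correct),
      miss = lay$miss, rt_ms = rt_ms,
      prime_onset_s = tl$prime_onset_s, target_onset_s = tl$target_onset_s,
      response_onset_s = tl$response_onset_s,
      z_true = z, label_true = as.character(lay$label))
  }
  dplyr::bind_rows(out)
}

# Standardized-RT process for one subject given a classified layout.
synth_z <- function(lay, compat, gp) {
  n <- length(lay$correct)
  offset <- numeric(n)
  lab <- as.character(lay$label)
  offset[!lay$correct & !lay$miss] <- gp$z_error   # all commission errors
  for (k in 1:3) {
    offset[lab == paste0("ER_M", 4 - k)] <- gp$z_pre[k]   # ER_M3..ER_M1
    offset[lab == paste0("ER_P", k)] <- gp$z_post[k]
  }
  half_base <- (gp$compat_effect_ms / 2) / gp$sd_rt_ms
  half <- rep(half_base, n)
  half[lab == "ER_P1"] <-
    (gp$compat_effect_ms + gp$compat_post_increment_ms) / 2 / gp$sd_rt_ms
  sgn <- ifelse(compat == "compatible", 1, -1)
  resid_sd <- sqrt(1 - half_base^2)   # error-free within-subject variance = 1
  b <- rnorm(1, 0, gp$subject_sd)
  b + offset + sgn * half + rnorm(n, 0, resid_sd)
}

#' Convert a cohort trial table to long-format events
#'
#' Expands each trial into `prime`, `target` and `response` events with
#' onsets in seconds, matching the events-TSV schema written by
#' [write_dataset()].
#'
#' @param behavior tibble from [sample_behavior()] (one or more subjects).
#' @return events tibble with columns `onset_s`, `duration_s`, `event_type`,
#'   `block`, `trial`, `compatibility`, `correct`, `rt_ms`, `subject`,
#'   `group`, `subtype`.
#' @export
behavior_to_events <- function(behavior) {
  cols <- c("block", "trial", "compatibility", "correct", "rt_ms",
            "subject", "group", "subtype")
  mk <- function(df, onset, type) {
    tibble::tibble(onset_s = onset, duration_s = 0, event_type = type,
                   df[cols])
  }
  resp <- behavior[!behavior$miss, ]   # responses exist for non-misses only
  out <- dplyr::bind_rows(
    mk(behavior, behavior$prime_onset_s, "prime"),
    mk(behavior, behavior$target_onset_s, "target"),
    mk(resp, resp$response_onset_s, "response"))
  tibble::as_tibble(out[order(out$subject, out$onset_s), ])
}

#' Rebuild a trial table from long-format events
#'
#' Inverse of [behavior_to_events()]: collapses prime/target/response events
#' back to one row per trial (the input schema of [peri_error_table()]).
#'
#' @param events events tibble (the [write_dataset()] TSV schema).
#' @return trial-level tibble with onset columns restored.
#' @export
events_to_behavior <- function(events) {
  key <- c("subject", "group", "subtype", "block", "trial")
  primes <- events[events$event_type == "prime", ]
  targets <- events[events$event_type == "target", ]
  resps <- events[events$event_type == "response", ]
  tab <- primes[c(key, "compatibility", "correct", "rt_ms")]
  tab$prime_onset_s <- primes$onset_s
  tab$target_onset_s <- targets$onset_s[match(
    interaction(tab$subject, tab$block, tab$trial),
    interaction(targets$subject, targets$block, targets$trial))]
  tab$response_onset_s <- resps$onset_s[match(
    interaction(tab$subject, tab$block, tab$trial),
    interaction(resps$subject, resps$block, resps$trial))]
  tab$miss <- is.na(tab$response_onset_s)
  dplyr::arrange(tibble::as_tibble(tab), .data$subject, .data$block,
                 .data$trial)
}
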