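#' Standardize reaction times against error-free trials
#'
#' Computes per-subject standardized reaction times: the subject's mean RT
#' over error-free trials is subtracted and the result divided by the
#' standard deviation of the same error-free trials (the z-score analogue).
#' The transform is applied to *every* trial with an RT, including errors,
#' so error and peri-error RTs are expressed in units of the subject's own
#' error-free variability.
#'
#' @param trials tibble with at least columns `subject`, `rt_ms` and
#'   `peri_label` (as produced by [classify_trials()]).
#' @return the input tibble with a `z_rt` column added.
#' @export
standardize_rt <- function(trials) {
  stopifnot(all(c("subject", "rt_ms", "peri_label") %in% names(trials)))
  out <- dplyr::group_by(trials, .data$subject)
  out <- dplyr::mutate(out, z_rt = {
    ef <- .data$peri_label == "ERROR_FREE" & !is.na(.data$rt_ms)
    if (sum(ef) < 2L) {
      stop("subject ", .data$subject[1L],
           ": fewer than 2 error-free trials with RT; cannot standardize")
    }
    m <- mean(.data$rt_ms[ef])
    s <- sd(.data$rt_ms[ef])
    if (s == 0) stop("subject ", .data$subject[1L],
                     ": zero error-free RT variance (degenerate)")
    (.data$rt_ms - m) / s
  })
  dplyr::ungroup(out)
}

#' Filter subjects by isolated-error count
#'
#' Retains only subjects with at least `min_isolated` isolated errors
#' (default 5), the inclusion rule for all peri-error analyses. Returns the
#' filtered table together with a per-subject report and summary statistics
#' of the isolated-error counts among retained subjects (mean, SD, range).
#'
#' @param trials classified trial tibble (columns `subject`, `peri_label`,
#'   and optionally `group`).
#' @param min_isolated minimum number of isolated errors (default 5).
#' @return list with elements `trials` (retained rows), `report` (tibble:
#'   subject, group, n_isolated, retained) and `summary` (list: n_retained,
#'   n_dropped, mean, sd, min, max of isolated-error counts among retained).
#' @export
subject_inclusion_filter <- function(trials, min_isolated = 5L) {
  stopifnot(all(c("subject", "peri_label") %in% names(trials)))
  grp_cols <- intersect(c("subject", "group"), names(trials))
  report <- dplyr::summarise(
    dplyr::group_by(trials, dplyr::across(dplyr::all_of(grp_cols))),
    n_isolated = sum(.data$peri_label == "ERROR_ISOLATED"),
    .groups = "drop")
  report$retained <- report$n_isolated >= min_isolated
  keep <- report$subject[report$retained]
  kept_counts <- report$n_isolated[report$retained]
  summary <- list(
    n_retained = length(keep),
    n_dropped  = sum(!report$retained),
    mean = if (length(kept_counts)) mean(kept_counts) else NA_real_,
    sd   = if (length(kept_counts) > 1) sd(kept_counts) else NA_real_,
    min  = if (length(kept_counts)) min(kept_counts) else NA_integer_,
    max  = if (length(kept_counts)) max(kept_counts) else NA_integer_)
  list(trials = dplyr::filter(trials, .data$subject %in% keep),
       report = report, summary = summary)
}

#' Compatibility effect in a peri-error stratum
#'
#' Mean RT difference between compatibly and incompatibly primed correct
#' trials of one stratum (`ER_M1`, `ER_P1` or `ERROR_FREE`):
#' `mean(RT | compatible) - mean(RT | incompatible)`. Positive values mean
#' slower responses after compatible primes (the negative compatibility
#' effect direction).
#'
#' @param trials classified trial tibble with `peri_label`, `compatibility`
#'   (`"compatible"` / `"incompatible"`), `correct`, `rt_ms`.
#' @param stratum one of `"ER_M1"`, `"ER_P1"`, `"ERROR_FREE"`.
#' @return list with `effect_ms` (NA if undefined), `n_compatible`,
#'   `n_incompatible`, `defined` flag.
#' @export
compatibility_effect <- function(trials, stratum) {
  stratum <- match.arg(stratum, c("ER_M1", "ER_P1", "ERROR_FREE"))
  sub <- trials[trials$peri_label == stratum &
                  as.logical(trials$correct) & !is.na(trials$rt_ms), ]
  nc <- sum(sub$compatibility == "compatible")
  ni <- sum(sub$compatibility == "incompatible")
  if (nc == 0L || ni == 0L) {
    return(list(effect_ms = NA_real_, n_compatible = nc,
                n_incompatible = ni, defined = FALSE))
  }
  eff <- mean(sub$rt_ms[sub$compatibility == "compatible"]) -
    mean(sub$rt_ms[sub$compatibility == "incompatible"])
  list(effect_ms = eff, n_compatible = nc, n_incompatible = ni,
       defined = TRUE)
}

#' Build the long-format peri-error analysis table
#'
#' Runs classification, standardization and subject inclusion on a cohort
#' trial table and returns one row per retained trial (isolated errors,
#' ER±1-3 neighbours, error-free trials), with the signed trial-position
#' covariate attached. Excluded trials never reach the statistics.
#'
#' @param behavior cohort tibble with columns `subject`, `group`, `subtype`,
#'   `block`, `trial`, `compatibility`, `correct`, `rt_ms` (NA for misses).
#' @param min_isolated subject-inclusion threshold (default 5).
#' @return list: `table` (analysis tibble), `inclusion` (report + summary
#'   from [subject_inclusion_filter()]), and `all_trials` (every trial of
#'   every retained subject with `peri_label` and `z_rt` attached, including
#'   excluded trials - used e.g. to label EEG epochs).
#' @export
peri_error_table <- function(behavior, min_isolated = 5L) {
  stopifnot(all(c("subject", "block", "correct", "rt_ms") %in% names(behavior)))
  behavior <- dplyr::arrange(behavior, .data$subject, .data$block, .data$trial)
  behavior <- dplyr::mutate(
    dplyr::group_by(behavior, .data$subject),
    peri_label = classify_trials(.data$correct, .data$block,
                                 miss = is.na(.data$rt_ms) & !.data$correct))
  behavior <- dplyr::ungroup(behavior)
  behavior <- standardize_rt(behavior)
  incl <- subject_inclusion_filter(behavior, min_isolated = min_isolated)
  if (nrow(incl$trials) == 0L) {
    stop("no subjects remain after the isolated-error inclusion filter")
  }
  tab <- dplyr::filter(incl$trials, .data$peri_label != "EXCLUDED")
  tab$position <- peri_position(tab$peri_label)
  keep <- intersect(c("subject", "group", "subtype", "block", "trial",
                      "peri_label", "position", "z_rt", "rt_ms",
                      "compatibility", "correct"), names(tab))
  list(table = tab[keep], inclusion = incl[c("report", "summary")],
       all_trials = incl$trials)
}
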