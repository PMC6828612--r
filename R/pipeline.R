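#' Full behavioral analysis of a cohort trial table
#'
#' Runs classification, standardization and inclusion, then fits the
#' peri-error mixed-model battery with likelihood-ratio tests:
#'
#' * error trials: standardized-RT intercept (vs 0) and group difference;
#' * pre-error trials (ER-3..ER-1): intercept at the centred position,
#'   per-trial position slope, group main effect and group x position
#'   interaction;
#' * post-error trials (ER+1..ER+3): the same four effects;
#' * post hoc within-group fits: ER+1 intercept per group, ER+2 vs ER+1
#'   contrast within ADHD, ER+1 vs ER-1 contrast per group;
#' * a random-intercept logistic model of trial-wise correctness with a
#'   group effect;
#' * the group (2) x position (ER-1, ER+1) mixed ANOVA cross-check on
#'   subject means;
#' * compatibility effects per stratum and the error-free RT group
#'   comparison (pooled-variance t-test on subject means).
#'
#' Position covariates are centred within the pre- (at ER-2) and post-error
#' (at ER+2) windows, so intercepts are the across-window mean standardized
#' RT; treatment coding elsewhere uses TD and ER+1 as reference levels.
#'
#' @param behavior cohort tibble (the [sample_behavior()] schema).
#' @param min_isolated subject-inclusion threshold (default 5).
#' @return list of class `"behavior_results"`: `results` (tidy tibble:
#'   term, estimate, chisq, df, p_value), `fits` (named list), `anova`,
#'   `compat`, `rt_summary`, `inclusion`, `table` (analysis table),
#'   `all_trials`.
#' @export
analyze_behavior <- function(behavior, min_isolated = 5L) {
  pt <- peri_error_table(behavior, min_isolated = min_isolated)
  tab <- pt$table
  tab$group <- factor(tab$group, levels = intersect(c("TD", "ADHD"),
                                                    unique(tab$group)))
  fits <- list()
  rows <- list()
  add <- function(term, est, test = NULL) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      term = term, estimate = est,
      chisq = if (is.null(test)) NA_real_ else test$chisq,
      df = if (is.null(test)) NA_integer_ else test$df,
      p_value = if (is.null(test)) NA_real_ else test$p_value)
  }

  err <- tab[tab$peri_label == "ERROR_ISOLATED", ]
  fits$error <- fit_lmm_ml(z_rt ~ 1, err)
  add("error_intercept", unname(coef(fits$error)[1]),
      lrt(fits$error, fit_lmm_ml(z_rt ~ 0, err)))
  if (nlevels(tab$group) == 2L) {
    fits$error_group <- fit_lmm_ml(z_rt ~ group, err)
    add("error_group", unname(coef(fits$error_group)["groupADHD"]),
        lrt(fits$error_group, fits$error))
  }

  fit_window <- function(sub, prefix) {
    full0 <- fit_lmm_ml(z_rt ~ pos_c, sub)
    add(paste0(prefix, "_intercept"), unname(coef(full0)["(Intercept)"]),
        lrt(full0, fit_lmm_ml(z_rt ~ 0 + pos_c, sub)))
    add(paste0(prefix, "_slope"), unname(coef(full0)["pos_c"]),
        lrt(full0, fit_lmm_ml(z_rt ~ 1, sub)))
    if (nlevels(tab$group) == 2L) {
      fg <- fit_lmm_ml(z_rt ~ pos_c + group, sub)
      add(paste0(prefix, "_group"), unname(coef(fg)["groupADHD"]),
          lrt(fg, full0))
      fi <- fit_lmm_ml(z_rt ~ pos_c * group, sub)
      add(paste0(prefix, "_interaction"), unname(coef(fi)["pos_c:groupADHD"]),
          lrt(fi, fg))
    }
    full0
  }
  pre <- tab[tab$peri_label %in% c("ER_M3", "ER_M2", "ER_M1"), ]
  pre$pos_c <- pre$position + 2L
  fits$pre <- fit_window(pre, "pre")
  post <- tab[tab$peri_label %in% c("ER_P1", "ER_P2", "ER_P3"), ]
  post$pos_c <- post$position - 2L
  fits$post <- fit_window(post, "post")

  for (g in levels(tab$group)) {
    p1 <- tab[tab$peri_label == "ER_P1" & tab$group == g, ]
    f <- fit_lmm_ml(z_rt ~ 1, p1)
    fits[[paste0("erp1_", g)]] <- f
    add(paste0("erp1_intercept_", g), unname(coef(f)[1]),
        lrt(f, fit_lmm_ml(z_rt ~ 0, p1)))

    m1p1 <- tab[tab$peri_label %in% c("ER_M1", "ER_P1") & tab$group == g, ]
    m1p1$lab <- factor(m1p1$peri_label, levels = c("ER_M1", "ER_P1"))
    f2 <- fit_lmm_ml(z_rt ~ lab, m1p1)
    add(paste0("erm1_to_erp1_", g), unname(coef(f2)["labER_P1"]),
        lrt(f2, fit_lmm_ml(z_rt ~ 1, m1p1)))
  }
  if ("ADHD" %in% levels(tab$group)) {
    p12 <- tab[tab$peri_label %in% c("ER_P1", "ER_P2") &
                 tab$group == "ADHD", ]
    p12$lab <- factor(p12$peri_label, levels = c("ER_P1", "ER_P2"))
    fits$adhd_p1_p2 <- fit_lmm_ml(z_rt ~ lab, p12)
    add("erp1_to_erp2_ADHD", unname(coef(fits$adhd_p1_p2)["labER_P2"]),
        lrt(fits$adhd_p1_p2, fit_lmm_ml(z_rt ~ 1, p12)))
  }

  # trial-wise accuracy (all trials of retained subjects)
  acc <- pt$all_trials
  acc$err <- 1L - as.integer(acc$correct)
  if (length(unique(acc$group)) == 2L) {
    acc$group <- factor(acc$group, levels = levels(tab$group))
    fits$accuracy <- fit_logistic_mixed(err ~ group, acc)
    add("accuracy_group_logodds",
        unname(coef(fits$accuracy)["groupADHD"]),
        lrt(fits$accuracy, fit_logistic_mixed(err ~ 1, acc)))
  }

  # mixed ANOVA cross-check on ER-1 / ER+1 subject means
  anova_tab <- NULL
  sm <- dplyr::summarise(
    dplyr::group_by(tab[tab$peri_label %in% c("ER_M1", "ER_P1"), ],
                    .data$subject, .data$group, .data$peri_label),
    value = mean(.data$z_rt), .groups = "drop")
  sm$position <- sm$peri_label
  if (length(unique(sm$group)) == 2L &&
      all(table(sm$subject) == 2L)) {
    anova_tab <- mixed_anova_2x2(sm)
  }

  compat <- lapply(setNames(nm = c("ER_M1", "ER_P1", "ERROR_FREE")),
                   function(s) compatibility_effect(tab, s))

  ef <- tab[tab$peri_label == "ERROR_FREE", ]
  rt_subj <- dplyr::summarise(dplyr::group_by(ef, .data$subject, .data$group),
                              mean_rt = mean(.data$rt_ms), .groups = "drop")
  rt_summary <- dplyr::summarise(dplyr::group_by(rt_subj, .data$group),
                                 mean_rt_ms = mean(.data$mean_rt),
                                 sd_rt_ms = sd(.data$mean_rt),
                                 n = dplyr::n(), .groups = "drop")
  rt_test <- if (length(unique(rt_subj$group)) == 2L) {
    two_sample_t(rt_subj$mean_rt[rt_subj$group == "TD"],
                 rt_subj$mean_rt[rt_subj$group == "ADHD"])
  } else NULL

  structure(list(results = dplyr::bind_rows(rows), fits = fits,
                 anova = anova_tab, compat = compat,
                 rt_summary = rt_summary, rt_test = rt_test,
                 inclusion = pt$inclusion, table = tab,
                 all_trials = pt$all_trials),
            class = "behavior_results")
}

#' Group-level statistics on theta summaries
#'
#' Reproduces the frontal-midline-theta inference battery on subject-level
#' means: one-sample t-tests of error and error-free theta against zero
#' across groups, the TD vs ADHD two-sample contrasts for error trials
#' (both baseline modes), and random-intercept mixed models over the
#' pre-error and post-error ER±1-3 windows (intercept, group, position,
#' interaction) on the error-free-referenced summaries.
#'
#' @param subject_means tibble from [theta_subject_means()] containing both
#'   modes (`vs_baseline`, `vs_errorfree`).
#' @return list of class `"theta_results"`: `results` tibble (term,
#'   estimate, statistic, df, p_value), `subject_means`.
#' @export
analyze_theta <- function(subject_means) {
  sm <- subject_means
  rows <- list()
  add <- function(term, est, stat = NA_real_, df = NA_real_, p = NA_real_) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      term = term, estimate = est, statistic = stat, df = df, p_value = p)
  }
  pick <- function(label, mode) {
    sm[sm$peri_label == label & sm$mode == mode, ]
  }
  for (lab in c("ERROR_ISOLATED", "ERROR_FREE")) {
    x <- pick(lab, "vs_baseline")
    if (nrow(x) >= 2L) {
      ht <- stats::t.test(x$theta_db)
      add(paste0("theta_", tolower(lab), "_vs0"), mean(x$theta_db),
          unname(ht$statistic), unname(ht$parameter), ht$p.value)
    }
    if (length(unique(x$group)) == 2L) {
      tt <- two_sample_t(x$theta_db[x$group == "TD"],
                         x$theta_db[x$group == "ADHD"])
      add(paste0("theta_", tolower(lab), "_group"), tt$mean_diff,
          tt$t, tt$df, tt$p_value)
    }
  }
  xe <- pick("ERROR_ISOLATED", "vs_errorfree")
  if (length(unique(xe$group)) == 2L) {
    tt <- two_sample_t(xe$theta_db[xe$group == "TD"],
                       xe$theta_db[xe$group == "ADHD"])
    add("theta_error_vs_errorfree_group", tt$mean_diff, tt$t, tt$df,
        tt$p_value)
  }

  for (win in c("pre", "post")) {
    labs <- if (win == "pre") c("ER_M3", "ER_M2", "ER_M1") else
      c("ER_P1", "ER_P2", "ER_P3")
    w <- sm[sm$peri_label %in% labs & sm$mode == "vs_errorfree", ]
    if (nrow(w) < 4L) next
    w$pos_c <- peri_position(w$peri_label) -
      mean(range(peri_position(w$peri_label)))
    f0 <- fit_lmm_ml(theta_db ~ pos_c, w)
    t_int <- lrt(f0, fit_lmm_ml(theta_db ~ 0 + pos_c, w))
    add(paste0("theta_", win, "_intercept"),
        unname(coef(f0)["(Intercept)"]), t_int$chisq, t_int$df,
        t_int$p_value)
    t_slope <- lrt(f0, fit_lmm_ml(theta_db ~ 1, w))
    add(paste0("theta_", win, "_slope"), unname(coef(f0)["pos_c"]),
        t_slope$chisq, t_slope$df, t_slope$p_value)
    if (length(unique(w$group)) == 2L) {
      w$group <- factor(w$group, levels = c("TD", "ADHD"))
      fg <- fit_lmm_ml(theta_db ~ pos_c + group, w)
      tg <- lrt(fg, f0)
      add(paste0("theta_", win, "_group"),
          unname(coef(fg)["groupADHD"]), tg$chisq, tg$df, tg$p_value)
      fi <- fit_lmm_ml(theta_db ~ pos_c * group, w)
      ti <- lrt(fi, fg)
      add(paste0("theta_", win, "_interaction"),
          unname(coef(fi)["pos_c:groupADHD"]), ti$chisq, ti$df, ti$p_value)
    }
  }
  structure(list(results = dplyr::bind_rows(rows), subject_means = sm),
            class = "theta_results")
}

#' Process one recording bundle through the EEG pipeline
#'
#' Preprocess (filters, blink removal, epoching, rejection), transform
#' (moving-window FFT, pre-prime dB baseline), and summarize (FMtheta
#' per-trial summaries in both baseline modes), attaching peri-error labels
#' from the classified behavior table.
#'
#' @param bundle `"recording_bundle"`.
#' @param labels classified trials of this subject (columns `block`,
#'   `trial`, `peri_label`), e.g. from [analyze_behavior()]'s `all_trials`.
#' @param channels channels entering the time-frequency stage (default
#'   Fz and Cz, the FMtheta electrodes).
#' @return tibble of per-trial theta summaries (both modes bound together).
#' @export
process_recording <- function(bundle, labels,
                              channels = c("Fz", "Cz")) {
  epochs <- preprocess_eeg(bundle$eeg, bundle$events)
  key <- interaction(epochs$meta$block, epochs$meta$trial)
  epochs$meta$peri_label <-
    as.character(labels$peri_label)[match(key, interaction(labels$block,
                                                           labels$trial))]
  tfr <- stft_power(epochs, channels = channels)
  tfr <- baseline_correct(tfr)
  tc <- fmtheta_timecourse(tfr)
  dplyr::bind_rows(theta_summaries(tc, "vs_baseline"),
                   theta_summaries(tc, "vs_errorfree"))
}

#' Run the end-to-end pipeline on a synthetic cohort
#'
#' Simulate, preprocess, analyze, report: generates a cohort from the given
#' parameters, runs the behavioral mixed-model battery, optionally renders
#' and processes the EEG of every subject and runs the theta battery, and
#' returns all result tables together with the power analysis and the
#' provenance needed to regenerate the run (parameters + seed).
#'
#' @param params `"cohort_params"`.
#' @param eeg process EEG too? (`FALSE` = behavior-only mode, much faster).
#' @param outdir optional directory: result tables are written as TSV and
#'   the configuration as JSON.
#' @param power_n1,power_n2 group sizes for the power-analysis block
#'   (default: the cohort's group sizes).
#' @return list of class `"report_bundle"`: `behavior`
#'   (`"behavior_results"`), `theta` (`"theta_results"` or NULL),
#'   `theta_trials` (per-trial summaries or NULL), `power`
#'   (from [power_report()]), `params`.
#' @export
run_pipeline <- function(params, eeg = TRUE, outdir = NULL,
                         power_n1 = NULL, power_n2 = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  cohort <- generate_cohort(params, eeg = eeg)
  behav <- analyze_behavior(cohort$behavior)
  theta <- NULL; theta_trials <- NULL
  if (eeg) {
    per_sub <- lapply(cohort$bundles, function(b) {
      lab <- behav$all_trials[behav$all_trials$subject == b$subject, ]
      if (nrow(lab) == 0L) return(NULL)   # subject dropped by inclusion
      process_recording(b, lab)
    })
    theta_trials <- dplyr::bind_rows(per_sub)
    theta <- analyze_theta(theta_subject_means(theta_trials))
  }
  pw <- power_report(n1 = if (is.null(power_n1)) params$n_adhd else power_n1,
                     n2 = if (is.null(power_n2)) params$n_td else power_n2)
  out <- structure(list(behavior = behav, theta = theta,
                        theta_trials = theta_trials, power = pw,
                        params = params),
                   class = "report_bundle")
  if (!is.null(outdir)) write_report(out, outdir)
  out
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  wt(report$behavior$results, "behavior_results.tsv")
  wt(report$behavior$table, "analysis_table.tsv")
  wt(report$behavior$inclusion$report, "inclusion_report.tsv")
  if (!is.null(report$theta)) {
    wt(report$theta$results, "theta_results.tsv")
    wt(report$theta$subject_means, "theta_subject_means.tsv")
  }
  wt(report$power$table, "power_table.tsv")
  jsonlite::write_json(unclass_params(report$params),
                       file.path(outdir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("peritheta report bundle\n")
  cat(sprintf("  cohort: %d TD + %d ADHD subjects, seed %d\n",
              x$params$n_td, x$params$n_adhd, x$params$seed))
  cat(sprintf("  behavioral terms: %d; theta terms: %s\n",
              nrow(x$behavior$results),
              if (is.null(x$theta)) "none (behavior-only run)" else
                nrow(x$theta$results)))
  cat(sprintf("  power at d = 0.42: %.3f; min d for %d%% power: %.2f\n",
              ttest_power(0.42, x$power$n1, x$power$n2)$power,
              round(100 * x$power$power_target), x$power$min_d))
  invisible(x)
}
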