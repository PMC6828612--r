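mk_trials <- function(rt, correct, compat = NULL, subject = "s1") {
  n <- length(rt)
  tibble::tibble(
    subject = subject, block = 1L, trial = seq_len(n),
    compatibility = if (is.null(compat)) rep("compatible", n) else compat,
    correct = as.integer(correct), rt_ms = rt)
}

test_that("standardization uses error-free mean and SD only", {
  # error-free trials engineered to mean 459, SD 41 exactly
  ef <- 459 + 41 * scale(rnorm(50))[, 1]
  rt <- c(ef, 418, 459, 459 - 1.39 * 41)
  correct <- c(rep(1, 50), 0, 1, 0)
  tr <- mk_trials(rt, correct)
  tr$peri_label <- factor(c(rep("ERROR_FREE", 50), "ERROR_ISOLATED",
                            "EXCLUDED", "ERROR_ISOLATED"))
  z <- standardize_rt(tr)$z_rt
  expect_equal(z[51], -1, tolerance = 1e-12)
  expect_equal(z[52], 0, tolerance = 1e-12)
  expect_equal(z[53], -1.39, tolerance = 1e-12)
})

test_that("standardization is idempotent on error-free values", {
  set.seed(7)
  tr <- mk_trials(rnorm(40, 450, 30), rep(1, 40))
  tr$peri_label <- factor(rep("ERROR_FREE", 40))
  z1 <- standardize_rt(tr)
  tr2 <- z1
  tr2$rt_ms <- tr2$z_rt
  z2 <- standardize_rt(tr2)
  expect_equal(z2$z_rt, z1$z_rt, tolerance = 1e-12)
})

test_that("degenerate subjects are rejected", {
  tr <- mk_trials(rep(450, 10), rep(1, 10))
  tr$peri_label <- factor(rep("ERROR_FREE", 10))
  expect_error(standardize_rt(tr), "variance")
  tr2 <- mk_trials(c(450, 451), c(1, 1))
  tr2$peri_label <- factor(c("ERROR_FREE", "EXCLUDED"))
  expect_error(standardize_rt(tr2), "fewer than 2")
})

test_that("inclusion filter applies the five-isolated-error boundary", {
  tr <- dplyr::bind_rows(
    mk_trials(rnorm(20, 450, 30), rep(1, 20), subject = "s1"),
    mk_trials(rnorm(20, 450, 30), rep(1, 20), subject = "s2"))
  tr$peri_label <- factor(c(rep("ERROR_ISOLATED", 4), rep("ERROR_FREE", 16),
                            rep("ERROR_ISOLATED", 5), rep("ERROR_FREE", 15)),
                          levels = levels(classify_trials(1, 1)))
  out <- subject_inclusion_filter(tr)
  expect_equal(sort(unique(out$trials$subject)), "s2")
  expect_equal(out$summary$n_retained, 1)
  expect_equal(out$summary$n_dropped, 1)
  expect_equal(out$summary$mean, 5)
})

test_that("inclusion report carries the isolated-error count summaries", {
  beh <- small_behavior()
  res <- peri_error_table(beh)
  s <- res$inclusion$summary
  expect_true(s$min >= 5)
  expect_true(s$mean > 5 && s$mean < 30)
  expect_equal(nrow(res$inclusion$report), 14)
})

test_that("compatibility effect recovers a constructed difference", {
  set.seed(11)
  n <- 4000
  compat <- rep(c("compatible", "incompatible"), n / 2)
  rt <- 450 + ifelse(compat == "compatible", 10, -10) + rnorm(n, 0, 5)
  tr <- mk_trials(rt, rep(1, n), compat)
  tr$peri_label <- factor(rep("ERROR_FREE", n))
  eff <- compatibility_effect(tr, "ERROR_FREE")
  expect_true(eff$defined)
  expect_equal(eff$effect_ms, 20, tolerance = 0.5)
})

test_that("compatibility effect is zero for identical distributions and flagged when undefined", {
  tr <- mk_trials(rep(c(440, 460), 10), rep(1, 20),
                  rep(c("compatible", "incompatible"), each = 10))
  tr$rt_ms <- rep(450, 20)
  tr$peri_label <- factor(rep("ER_M1", 20))
  expect_equal(compatibility_effect(tr, "ER_M1")$effect_ms, 0)
  tr$compatibility <- "compatible"
  eff <- compatibility_effect(tr, "ER_M1")
  expect_false(eff$defined)
  expect_true(is.na(eff$effect_ms))
})

test_that("the analysis table keeps exactly the retained, non-excluded trials", {
  beh <- small_behavior()
  res <- peri_error_table(beh)
  expect_false(any(res$table$peri_label == "EXCLUDED"))
  labs <- table(res$all_trials$peri_label)
  expect_equal(nrow(res$table), sum(labs) - labs[["EXCLUDED"]])
  expect_equal(nrow(res$all_trials), nrow(beh))  # nobody dropped here
  # generator truth and pipeline classification agree
  expect_equal(as.character(res$all_trials$peri_label),
               res$all_trials$label_true)
})

test_that("ER labels appear once per non-overlapping isolated error", {
  correct <- c(1, 1, 1, 0, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1)
  lab <- classify_trials(correct, rep(1, 14))
  counts <- table(lab)
  expect_equal(unname(counts["ERROR_ISOLATED"]),
               unname(counts["ER_P1"]))
  expect_equal(unname(counts["ER_M3"]), 2)
})

test_that("an empty cohort after filtering is a clear error", {
  beh <- small_behavior()
  expect_error(peri_error_table(beh, min_isolated = 10000L),
               "no subjects remain")
})
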