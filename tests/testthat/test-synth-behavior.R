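test_that("a zero-error-rate cohort is all-correct and offset-free", {
  p <- cohort_params(n_td = 2, n_adhd = 1, seed = 3,
                     td = group_params(error_rate = 0),
                     adhd = adhd_group_params(error_rate = 0))
  beh <- sample_behavior(p)
  expect_true(all(beh$correct == 1L))
  expect_true(all(beh$label_true == "ERROR_FREE"))
})

test_that("identical seeds give identical cohorts, different seeds differ", {
  p <- cohort_params(n_td = 2, n_adhd = 2, seed = 9)
  b1 <- sample_behavior(p)
  b2 <- sample_behavior(p)
  expect_identical(b1, b2)
  p2 <- cohort_params(n_td = 2, n_adhd = 2, seed = 10)
  expect_false(identical(sample_behavior(p2), b1))
})

test_that("every subject has at least five isolated errors", {
  beh <- small_behavior()
  counts <- tapply(beh$label_true == "ERROR_ISOLATED", beh$subject, sum)
  expect_true(all(counts >= 5))
})

test_that("pathological error rates exhaust the retry bound", {
  expect_error(
    sample_behavior(cohort_params(n_td = 1, n_adhd = 1, seed = 1,
                                  trials_per_block = 4, n_blocks = 1,
                                  max_retries = 10L)),
    "retries|pathological|layouts")
})

test_that("error-free residuals approach mean 0 and SD 1 at large n", {
  p <- cohort_params(n_td = 1, n_adhd = 1, trials_per_block = 3400,
                     seed = 21)
  beh <- sample_behavior(p)
  for (s in unique(beh$subject)) {
    z <- beh$z_true[beh$subject == s & beh$label_true == "ERROR_FREE"]
    expect_gt(length(z), 3000)
    expect_equal(sd(z), 1, tolerance = 0.05)
    expect_equal(mean(z - mean(z)), 0)          # residuals centre exactly
    expect_lt(abs(mean(z)), 0.05 + 3 * sqrt(0.05))  # intercept-dominated
  }
})

test_that("injected peri-error offsets sit where the labels are", {
  beh <- small_behavior()
  adhd <- beh[beh$group == "ADHD", ]
  # subject-centred means by label recover the injected profile direction
  adhd <- dplyr::mutate(dplyr::group_by(adhd, subject),
                        zc = z_true - mean(z_true[label_true == "ERROR_FREE"]))
  adhd <- dplyr::ungroup(adhd)
  m <- tapply(adhd$zc, adhd$label_true, mean)
  expect_lt(m[["ERROR_ISOLATED"]], -1)
  expect_lt(m[["ER_M1"]], m[["ER_M3"]])
  expect_lt(m[["ER_P1"]], -0.2)
  expect_lt(abs(m[["ERROR_FREE"]]), 0.05)
})

test_that("timelines are strictly increasing with the documented gaps", {
  beh <- small_behavior()
  one <- beh[beh$subject == beh$subject[1], ]
  expect_true(all(diff(one$prime_onset_s) > 0))
  expect_equal(one$target_onset_s - one$prime_onset_s,
               rep(0.15, nrow(one)), tolerance = 1e-12)
  expect_true(all(one$response_onset_s > one$target_onset_s))
  # response-to-next-prime gap at least the ITI floor within blocks
  gap <- one$prime_onset_s[-1] - one$response_onset_s[-nrow(one)]
  same_block <- diff(one$block) == 0
  expect_true(all(gap[same_block] >= 1.5 - 1e-9))
  expect_true(all(gap[same_block] <= 2.0 + 1e-9))
})

test_that("misses carry no RT and break correct runs", {
  p <- cohort_params(n_td = 2, n_adhd = 1, seed = 13,
                     td = group_params(miss_rate = 0.05),
                     adhd = adhd_group_params(miss_rate = 0.05))
  beh <- sample_behavior(p)
  expect_true(any(beh$miss))
  expect_true(all(is.na(beh$rt_ms[beh$miss])))
  expect_true(all(beh$correct[beh$miss] == 0L))
  expect_true(all(beh$label_true[beh$miss] == "EXCLUDED"))
})

test_that("events round-trip back to the trial table", {
  beh <- small_behavior()
  ev <- behavior_to_events(beh)
  expect_setequal(unique(ev$event_type), c("prime", "target", "response"))
  back <- events_to_behavior(ev)
  ord <- order(beh$subject, beh$block, beh$trial)
  expect_equal(back$rt_ms, beh$rt_ms[ord])
  expect_equal(back$correct, beh$correct[ord])
  expect_equal(back$prime_onset_s, beh$prime_onset_s[ord])
})
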