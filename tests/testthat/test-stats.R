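mk_anova_data <- function(td, adhd) {
  n1 <- nrow(td); n2 <- nrow(adhd)
  tibble::tibble(
    subject = rep(c(sprintf("t%02d", seq_len(n1)),
                    sprintf("a%02d", seq_len(n2))), each = 2),
    group = rep(c(rep("TD", n1), rep("ADHD", n2)), each = 2),
    position = rep(c("ER_M1", "ER_P1"), n1 + n2),
    value = c(t(cbind(rbind(td, adhd)))))
}

test_that("mixed ANOVA has the split-plot degrees of freedom", {
  set.seed(15)
  td <- matrix(rnorm(28), 14, 2); adhd <- matrix(rnorm(52), 26, 2)
  res <- mixed_anova_2x2(mk_anova_data(as.data.frame(td),
                                       as.data.frame(adhd)))
  expect_equal(res$df1, rep(1L, 3))
  expect_equal(res$df2, rep(38L, 3))   # 26 + 14 subjects -> n - 2
})

test_that("null group/position structure is not declared significant", {
  set.seed(14)
  # subject effects only: no group, position or interaction structure
  base <- rnorm(20)
  vals <- cbind(base, base) + matrix(rnorm(40, 0, 0.5), 20)
  res <- mixed_anova_2x2(mk_anova_data(as.data.frame(vals[1:10, ]),
                                       as.data.frame(vals[11:20, ])))
  expect_true(all(res$p_value > 0.05))
  expect_true(all(res$F < 4))
})

test_that("group F equals the squared two-sample t on subject means", {
  set.seed(19)
  td <- matrix(rnorm(28, 0.5), 14, 2); adhd <- matrix(rnorm(52), 26, 2)
  res <- mixed_anova_2x2(mk_anova_data(as.data.frame(td),
                                       as.data.frame(adhd)))
  tt <- two_sample_t(rowMeans(td), rowMeans(adhd))
  expect_equal(unname(res$F[res$effect == "group"]), tt$t^2,
               tolerance = 1e-8)
})

test_that("interaction F equals the squared two-sample t on difference scores", {
  set.seed(16)
  td <- matrix(rnorm(40, c(0, 0.3)), 20, 2, byrow = TRUE)
  adhd <- matrix(rnorm(40, c(-0.4, -0.1)), 20, 2, byrow = TRUE)
  res <- mixed_anova_2x2(mk_anova_data(as.data.frame(td),
                                       as.data.frame(adhd)))
  dt <- td[, 2] - td[, 1]; da <- adhd[, 2] - adhd[, 1]
  tt <- two_sample_t(dt, da)
  expect_equal(unname(res$F[res$effect == "group:position"]), tt$t^2,
               tolerance = 1e-8)
})

test_that("missing cells are rejected", {
  d <- mk_anova_data(as.data.frame(matrix(rnorm(8), 4, 2)),
                     as.data.frame(matrix(rnorm(8), 4, 2)))
  expect_error(mixed_anova_2x2(d[-1, ]), "one value per subject")
})

test_that("two-sample t matches a hand-computed textbook fixture", {
  x <- c(12, 14, 15, 13, 16)
  y <- c(10, 11, 12, 14)
  # pooled-variance Student t computed by hand
  sp2 <- (4 * var(x) + 3 * var(y)) / 7
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 5 + 1 / 4))
  res <- two_sample_t(x, y)
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$df, 7)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), 7), tolerance = 1e-12)
})

test_that("paired t has n - 1 degrees of freedom", {
  set.seed(17)
  x <- rnorm(26); y <- x + rnorm(26, 0.3)
  res <- two_sample_t(x, y, paired = TRUE)
  expect_equal(res$df, 25)
  expect_error(two_sample_t(1, 2), "at least 2")
})

test_that("equal samples give t = 0, p = 1", {
  x <- c(1, 2, 3, 4)
  res <- two_sample_t(x, x)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
})

test_that("noncentral-t power behaves as a power function must", {
  expect_equal(ttest_power(0, 26, 14)$power, 0.05, tolerance = 1e-10)
  expect_equal(ttest_power(0.42, 26, 14)$power,
               ttest_power(-0.42, 26, 14)$power)
  d_grid <- seq(0.1, 2, by = 0.1)
  pw <- vapply(d_grid, function(d) ttest_power(d, 26, 14)$power, numeric(1))
  expect_true(all(diff(pw) > 0))
  expect_gt(ttest_power(6, 26, 14)$power, 0.999999)
  expect_gt(ttest_power(0.5, 60, 60)$power, ttest_power(0.5, 26, 14)$power)
})

test_that("analytic power agrees with a Monte-Carlo rejection rate", {
  set.seed(18)
  nsim <- 40000
  d <- 0.42; n1 <- 26; n2 <- 14
  x <- matrix(rnorm(n1 * nsim, d), n1)
  y <- matrix(rnorm(n2 * nsim), n2)
  sp2 <- ((n1 - 1) * matrixStats_colVars(x) +
            (n2 - 1) * matrixStats_colVars(y)) / (n1 + n2 - 2)
  tv <- (colMeans(x) - colMeans(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  rej <- mean(abs(tv) > qt(0.975, n1 + n2 - 2))
  expect_equal(rej, ttest_power(d, n1, n2)$power, tolerance = 0.01)
})

test_that("minimum detectable d round-trips through the power function", {
  d80 <- min_detectable_d(0.8, 26, 14)
  expect_gte(ttest_power(d80, 26, 14)$power, 0.8 - 1e-6)
  expect_lt(ttest_power(d80 - 0.01, 26, 14)$power, 0.8)
  expect_lt(min_detectable_d(0.8, 100, 100), d80)   # larger n, smaller d
})

test_that("the power report tabulates the grid and the 80% threshold", {
  rep <- power_report(26, 14, d_grid = c(0.2, 0.42, 0.95))
  expect_equal(nrow(rep$table), 3)
  expect_true(all(diff(rep$table$power) > 0))
  expect_equal(rep$min_d, min_detectable_d(0.8, 26, 14), tolerance = 1e-6)
})
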