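#' Two-by-two mixed (split-plot) ANOVA
#'
#' Cross-check for the mixed-model route: a group (between-subject, 2
#' levels) by trial-position (within-subject, 2 levels) ANOVA on one mean
#' per subject and cell, using the standard split-plot decomposition
#' (between-subject stratum for the group effect, within-subject stratum for
#' position and the interaction). With `n` subjects each effect has
#' `(1, n - 2)` degrees of freedom.
#'
#' @param subject_means tibble with columns `subject`, `group`, `position`
#'   (2 levels each for group/position) and `value`, one row per subject ×
#'   position cell.
#' @return tibble with one row per effect (`group`, `position`,
#'   `group:position`): `F`, `df1`, `df2`, `p_value`.
#' @export
mixed_anova_2x2 <- function(subject_means) {
  d <- subject_means
  stopifnot(all(c("subject", "group", "position", "value") %in% names(d)))
  d$subject <- factor(d$subject); d$group <- factor(d$group)
  d$position <- factor(d$position)
  if (nlevels(d$group) != 2L || nlevels(d$position) != 2L) {
    stop("`group` and `position` must each have exactly 2 levels")
  }
  counts <- table(d$subject, d$position)
  if (any(counts != 1L)) stop("need exactly one value per subject x position cell")
  fit <- aov(value ~ group * position + Error(subject), data = d)
  sm <- summary(fit)
  betw <- sm[["Error: subject"]][[1]]
  with <- sm[["Error: Within"]][[1]]
  get_row <- function(tab, nm) {
    i <- trimws(rownames(tab)) == nm
    c(F = tab[i, "F value"], df1 = tab[i, "Df"],
      df2 = tab[trimws(rownames(tab)) == "Residuals", "Df"],
      p = tab[i, "Pr(>F)"])
  }
  res <- rbind(group = get_row(betw, "group"),
               position = get_row(with, "position"),
               `group:position` = get_row(with, "group:position"))
  tibble::tibble(effect = rownames(res), F = res[, "F"],
                 df1 = as.integer(res[, "df1"]),
                 df2 = as.integer(res[, "df2"]), p_value = res[, "p"])
}

#' Two-sample or paired Student t-test
#'
#' Thin wrapper around [stats::t.test()] with pooled variance (classical
#' Student test) for the unpaired case, matching reported degrees of freedom
#' `n1 + n2 - 2` (unpaired) and `n - 1` (paired). Two-sided.
#'
#' @param x,y numeric vectors (equal length when `paired = TRUE`).
#' @param paired logical.
#' @return list with `t`, `df`, `p_value`, `mean_diff`.
#' @export
two_sample_t <- function(x, y, paired = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("need at least 2 observations per sample")
  ht <- stats::t.test(x, y, paired = paired, var.equal = !paired)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value,
       mean_diff = if (paired) mean(x - y) else mean(x) - mean(y))
}

#' Power of a two-sided two-sample t-test
#'
#' Analytic power via the noncentral t distribution: with effect size `d`
#' (Cohen's d) and group sizes `n1`, `n2`, the noncentrality parameter is
#' `d * sqrt(n1 * n2 / (n1 + n2))` on `n1 + n2 - 2` degrees of freedom, and
#' power is the probability mass of the noncentral t beyond the two-sided
#' critical values. `power(0) = alpha`, and power is symmetric in the sign
#' of `d`.
#'
#' @param d Cohen's d effect size (sign is irrelevant).
#' @param n1,n2 group sizes (>= 2).
#' @param alpha two-sided significance level (default 0.05).
#' @return list of class `"power_result"`: `power`, `d`, `n1`, `n2`,
#'   `alpha`, `ncp`, `df`.
#' @export
ttest_power <- function(d, n1, n2, alpha = 0.05) {
  stopifnot(n1 >= 2, n2 >= 2, alpha > 0, alpha < 1)
  d <- abs(d)
  df <- n1 + n2 - 2
  ncp <- d * sqrt(n1 * n2 / (n1 + n2))
  tcrit <- qt(1 - alpha / 2, df)
  pw <- pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    pt(-tcrit, df, ncp = ncp)
  structure(list(power = pw, d = d, n1 = n1, n2 = n2, alpha = alpha,
                 ncp = ncp, df = df), class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("two-sample t power: d = %.3f, n = %d/%d, alpha = %.3f -> %.3f\n",
              x$d, x$n1, x$n2, x$alpha, x$power))
  invisible(x)
}

#' Minimum detectable effect size
#'
#' Smallest Cohen's d reaching the target power for a two-sided two-sample
#' t-test at the given group sizes, found by root bisection on the analytic
#' power curve (which is strictly increasing in d) to tolerance 1e-4.
#' Conventionally reported to two decimals.
#'
#' @param power_target target power in (0, 1).
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level.
#' @return numeric minimum d (full precision; round to 2 decimals for
#'   reporting).
#' @export
min_detectable_d <- function(power_target, n1, n2, alpha = 0.05) {
  stopifnot(power_target > 0, power_target < 1)
  f <- function(d) ttest_power(d, n1, n2, alpha)$power - power_target
  d <- uniroot(f, interval = c(1e-8, 50), tol = 1e-5)$root
  while (ttest_power(d, n1, n2, alpha)$power < power_target) {
    d <- d + 1e-5   # land on the attaining side of the root
  }
  d
}

#' Power-analysis table over a grid of effect sizes
#'
#' @param n1,n2 group sizes.
#' @param alpha two-sided significance level.
#' @param d_grid effect sizes to tabulate (default `seq(0.1, 1.5, 0.01)`).
#' @param power_target target used for the minimum-detectable-d line
#'   (default 0.8).
#' @return list: `table` (tibble d, power), `min_d` (for `power_target`),
#'   `n1`, `n2`, `alpha`.
#' @export
power_report <- function(n1, n2, alpha = 0.05,
                         d_grid = seq(0.1, 1.5, by = 0.01),
                         power_target = 0.8) {
  stopifnot(length(d_grid) >= 1, all(d_grid >= 0))
  pw <- vapply(d_grid, function(d) ttest_power(d, n1, n2, alpha)$power,
               numeric(1))
  list(table = tibble::tibble(d = d_grid, power = pw),
       min_d = min_detectable_d(power_target, n1, n2, alpha),
       power_target = power_target, n1 = n1, n2 = n2, alpha = alpha)
}
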