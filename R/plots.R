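#' Plot the peri-error standardized-RT profile
#'
#' Group means ± standard errors of standardized RT over ER-3..ER+3
#' (position 0 = the isolated error), with the error-free reference at
#' zero.
#'
#' @param table analysis table from [peri_error_table()] /
#'   [analyze_behavior()].
#' @return a ggplot object.
#' @export
plot_peri_error_profile <- function(table) {
  d <- table[!is.na(table$position), ]
  d <- dplyr::summarise(
    dplyr::group_by(d, .data$group, .data$position),
    mean_z = mean(.data$z_rt), se = sd(.data$z_rt) / sqrt(dplyr::n()),
    .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$position, y = .data$mean_z,
                                  colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean_z - .data$se,
                                          ymax = .data$mean_z + .data$se),
                             position = ggplot2::position_dodge(0.2)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(0.2)) +
    ggplot2::scale_x_continuous(breaks = -3:3) +
    ggplot2::labs(x = "trial position relative to isolated error",
                  y = "standardized RT (SD units)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot group-average frontal-midline theta timecourses
#'
#' Mean ± SEM (over trials) of the baseline-corrected theta timecourse per
#' group, for one condition label.
#'
#' @param timecourse `"theta_timecourse"` whose `meta` carries `peri_label`
#'   and `group`.
#' @param label condition to plot (default `"ERROR_ISOLATED"`).
#' @return a ggplot object.
#' @export
plot_theta_timecourse <- function(timecourse, label = "ERROR_ISOLATED") {
  keep <- timecourse$meta$peri_label == label
  if (!any(keep, na.rm = TRUE)) stop("no trials with label ", label)
  v <- timecourse$values[which(keep), , drop = FALSE]
  g <- timecourse$meta$group[which(keep)]
  d <- do.call(rbind, lapply(unique(g), function(gg) {
    vv <- v[g == gg, , drop = FALSE]
    data.frame(group = gg, time = timecourse$times,
               mean_db = colMeans(vv),
               se = apply(vv, 2, sd) / sqrt(nrow(vv)))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$mean_db,
                                  colour = .data$group,
                                  fill = .data$group)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_db - .data$se,
                                      ymax = .data$mean_db + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time relative to response (s)",
                  y = "FM-theta power (dB vs pre-prime baseline)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
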