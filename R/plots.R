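#' Plot a density time series
#'
#' Density (fish/ha) over time by stratum with approximate 95% intervals.
#'
#' @param densities Output of [density_table()].
#' @return A ggplot object.
#' @export
plot_density <- function(densities) {
  densities |>
    ggplot2::ggplot(ggplot2::aes(x = .data$date, y = .data$density_ha,
                                 colour = .data$stratum)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = pmax(.data$density_ha - 1.96 * .data$se_density_ha, 0),
                   ymax = .data$density_ha + 1.96 * .data$se_density_ha,
                   fill = .data$stratum),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = NULL, y = "density (fish/ha)", colour = "stratum",
                  fill = "stratum") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.growth_fit <- function(object, ages = seq(0.25, 7, by = 0.25),
                                ...) {
  cohorts <- fit_cohorts(object)
  if (length(cohorts) == 0) {
    df <- predict_mean_trajectory(object, ages = ages) |>
      dplyr::mutate(group = "all")
  } else {
    df <- purrr::map_dfr(cohorts, function(ch) {
      predict_mean_trajectory(object, ages = ages, cohort = ch) |>
        dplyr::mutate(group = ch)
    })
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$age_years, y = .data$length_mm,
                                   colour = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper,
                                      fill = .data$group),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "age (years)", y = "length (mm)",
                  colour = "cohort", fill = "cohort",
                  subtitle = "mode trajectories (random effects at 0)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cjs_fit <- function(object, ...) {
  df <- object$phi_table |>
    dplyr::filter(.data$identifiable)
  grp <- if ("cohort" %in% names(df)) "cohort" else NULL
  aes <- if (!is.null(grp)) {
    ggplot2::aes(x = .data$interval, y = .data$phi_annual,
                 colour = .data$cohort, group = .data$cohort)
  } else {
    ggplot2::aes(x = .data$interval, y = .data$phi_annual, group = 1)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lcl,
                                          ymax = .data$ucl),
                             position = ggplot2::position_dodge(0.4),
                             size = 0.2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "interval", y = "annual apparent survival") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.early_survival_fit <- function(object, ...) {
  df <- object$per_year |>
    dplyr::filter(.data$sigma_annual > 0, !is.na(.data$d_mean))
  co <- object$coefficients$estimate
  ggplot2::ggplot(df, ggplot2::aes(x = log(.data$d_mean),
                                   y = log(.data$sigma_annual))) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = co[1], slope = co[2],
                         linetype = "dashed") +
    ggplot2::labs(x = "log mean density (fish/ha)",
                  y = "log annual first-overwinter survival") +
    ggplot2::theme_minimal()
}
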