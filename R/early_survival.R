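#' Build per-year overwinter records from an encounter table
#'
#' For each year `t`: `n0` = distinct fish sampled at age 0+ in September of
#' `t` (all of which are fin-clipped on first capture), and `s1` = distinct
#' fin-clipped fish of cohort `t` sampled in June of `t + 1`. Because only
#' fish clipped at 0+ can appear clipped at 1+ in June, immigrants that were
#' never sampled at 0+ cannot leak into `s1` — the identification that makes
#' the estimator robust to immigration from the unsampled source reach.
#'
#' @param encounters Encounter table.
#' @param densities Optional age-class density table ([density_table()]);
#'   attaches `d_mean`, the mean of the older-than-0+ density at September
#'   of `t` and June of `t + 1`.
#' @return Tibble: `year`, `n0`, `s1`, `interval_days`, and `d_mean` when
#'   densities are supplied.
#' @export
overwinter_records <- function(encounters, densities = NULL) {
  id_col <- if ("fish_id" %in% names(encounters)) "fish_id" else "tag_id"
  assert_columns(encounters, c(id_col, "date", "age_years", "fin_clipped"),
                 "`encounters`")
  enc <- encounters |>
    dplyr::mutate(season = season_of(.data$date),
                  year = year_of(.data$date),
                  age_class = age_class_of(.data$age_years))
  n0_tbl <- enc |>
    dplyr::filter(.data$season == "September", .data$age_class == 0) |>
    dplyr::distinct(.data$year, .data[[id_col]]) |>
    dplyr::count(.data$year, name = "n0")
  s1_tbl <- enc |>
    dplyr::filter(.data$season == "June", .data$age_class == 1,
                  .data$fin_clipped == 1) |>
    dplyr::distinct(.data$year, .data[[id_col]]) |>
    dplyr::count(.data$year, name = "s1") |>
    dplyr::mutate(year = .data$year - 1L)

  sep_dates <- enc |>
    dplyr::filter(.data$season == "September") |>
    dplyr::distinct(.data$year, .data$date) |>
    dplyr::summarise(date = min(.data$date), .by = "year")
  jun_dates <- enc |>
    dplyr::filter(.data$season == "June") |>
    dplyr::distinct(.data$year, .data$date) |>
    dplyr::summarise(date = min(.data$date), .by = "year")

  out <- n0_tbl |>
    dplyr::left_join(s1_tbl, by = "year") |>
    dplyr::mutate(s1 = tidyr::replace_na(.data$s1, 0L)) |>
    dplyr::left_join(sep_dates |> dplyr::rename(sep_date = "date"),
                     by = "year") |>
    dplyr::left_join(jun_dates |> dplyr::mutate(year = .data$year - 1L) |>
                       dplyr::rename(jun_date = "date"),
                     by = "year") |>
    dplyr::mutate(interval_days =
                    as.numeric(.data$jun_date - .data$sep_date)) |>
    dplyr::filter(!is.na(.data$interval_days)) |>
    dplyr::select("year", "n0", "s1", "interval_days")

  if (!is.null(densities)) {
    d <- densities |>
      dplyr::filter(.data$stratum == ">0+") |>
      dplyr::mutate(year = year_of(.data$date),
                    season = season_of(.data$date))
    d_sep <- d |> dplyr::filter(.data$season == "September") |>
      dplyr::select("year", d_sep = "density_ha")
    d_jun <- d |> dplyr::filter(.data$season == "June") |>
      dplyr::mutate(year = .data$year - 1L) |>
      dplyr::select("year", d_jun = "density_ha")
    out <- out |>
      dplyr::left_join(d_sep, by = "year") |>
      dplyr::left_join(d_jun, by = "year") |>
      dplyr::mutate(d_mean = (.data$d_sep + .data$d_jun) / 2) |>
      dplyr::select(-"d_sep", -"d_jun")
  }
  out
}

#' First-overwinter apparent survival from fin-clipped fish
#'
#' Binomial estimator of the probability that a fish sampled (and clipped)
#' at age 0+ in September is sampled again at 1+ the following June:
#' `sigma = s1 / n0`, `SE = sqrt(sigma * (1 - sigma) / n0)`. Annualised as
#' `sigma_annual = sigma^(365.25 / interval_days)` with a delta-method SE.
#' Because `s1` counts only clipped fish, immigration of unsampled
#' individuals does not inflate the estimate.
#'
#' An optional detection correction divides the raw ratio by the
#' probability of being sampled in June when alive (e.g. `1 - (1 - q)^2`
#' for two passes at per-pass probability `q`); with per-pass capture
#' probabilities around 0.9 the correction is ~1%.
#'
#' @param records Tibble from [overwinter_records()] (columns `year`, `n0`,
#'   `s1`, `interval_days`, optionally `d_mean`).
#' @param capture_prob Optional per-occasion detection probability for the
#'   June sampling used to correct the ratio (default `NULL`, raw ratio).
#' @param fixed_exponent If `TRUE`, annualise with the fixed 12/9 exponent
#'   (a nine-month overwinter interval) instead of the actual interval
#'   length.
#' @return Tibble with `sigma_interval`, `se_interval`, `sigma_annual`,
#'   `se_annual`, `boundary` flag appended to `records`. Years with
#'   `n0 = 0` are dropped with a warning; `s1 > n0` (after correction)
#'   is an error, since the fin-clip rule makes it impossible without
#'   immigrant leakage.
#' @export
estimate_sigma0 <- function(records, capture_prob = NULL,
                            fixed_exponent = FALSE) {
  assert_columns(records, c("year", "n0", "s1", "interval_days"),
                 "`records`")
  drop <- records$n0 == 0
  if (any(drop)) {
    warn(sprintf("year(s) %s skipped: no 0+ fish sampled in September.",
                 paste(records$year[drop], collapse = ", ")))
    records <- records[!drop, , drop = FALSE]
  }
  sigma <- records$s1 / records$n0
  if (!is.null(capture_prob)) sigma <- sigma / capture_prob
  if (any(sigma > 1)) {
    abort("s1 exceeds n0 (after detection correction): the fin-clip rule was violated (immigrant leakage?).")
  }
  expo <- if (fixed_exponent) 12 / 9 else 365.25 / records$interval_days
  se_int <- sqrt(sigma * (1 - sigma) / records$n0)
  sigma_a <- sigma^expo
  se_a <- ifelse(sigma %in% c(0, 1), 0,
                 expo * sigma^(expo - 1) * se_int)
  records |>
    dplyr::mutate(sigma_interval = sigma, se_interval = se_int,
                  sigma_annual = sigma_a, se_annual = se_a,
                  boundary = sigma %in% c(0, 1))
}

#' Density dependence of first-overwinter survival (log-log regression)
#'
#' Ordinary least squares of `log(sigma_annual)` on `log(d_mean)`, the mean
#' older-fish density over the overwinter interval. Returns the intercept
#' and slope with standard errors, adjusted R-squared and the two-sided
#' p-value of the slope. Years with a zero survival estimate are excluded
#' (log undefined) with a warning.
#'
#' @param sigma_table Output of [estimate_sigma0()] including a `d_mean`
#'   column.
#' @return Object of class `"early_survival_fit"`: list with `per_year`
#'   (the input), `coefficients` tibble (`alpha`, `beta`), `adj_r_squared`,
#'   `p_value`, `n_years`, and the underlying `lm` fit.
#' @export
density_dependence_regression <- function(sigma_table) {
  assert_columns(sigma_table, c("sigma_annual", "d_mean"), "`sigma_table`")
  zero <- sigma_table$sigma_annual <= 0
  if (any(zero)) {
    warn(sprintf("%d year(s) with zero survival excluded from the log-log regression.",
                 sum(zero)))
  }
  use <- sigma_table[!zero & !is.na(sigma_table$d_mean), , drop = FALSE]
  if (nrow(use) < 3) {
    abort("need >= 3 years with positive survival and density for the regression.")
  }
  fit <- lm(log(sigma_annual) ~ log(d_mean), data = use)
  sm <- summary(fit)
  co <- sm$coefficients
  structure(
    list(per_year = sigma_table,
         coefficients = tibble::tibble(
           term = c("alpha", "beta"),
           estimate = unname(co[, 1]), std.error = unname(co[, 2]),
           statistic = unname(co[, 3]), p.value = unname(co[, 4])),
         adj_r_squared = sm$adj.r.squared,
         p_value = co[2, 4], n_years = nrow(use), lm_fit = fit),
    class = "early_survival_fit"
  )
}

#' @export
print.early_survival_fit <- function(x, ...) {
  co <- x$coefficients
  cat("First-overwinter survival, log-log density dependence\n")
  cat(sprintf("  alpha = %.2f +/- %.2f, beta = %.2f +/- %.2f (adj R2 = %.2f, p = %.3f, %d years)\n",
              co$estimate[1], co$std.error[1], co$estimate[2],
              co$std.error[2], x$adj_r_squared, x$p_value, x$n_years))
  invisible(x)
}

#' @export
tidy.early_survival_fit <- function(x, ...) x$coefficients

#' @export
glance.early_survival_fit <- function(x, ...) {
  tibble::tibble(adj.r.squared = x$adj_r_squared, p.value = x$p_value,
                 n_years = x$n_years)
}
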