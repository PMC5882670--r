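#' Proportion of late incomers among sampled fish
#'
#' For each September occasion, the fraction of sampled fish aged 1+ or
#' older whose first-ever capture happened with an intact adipose fin at
#' 1+ in September or older — fish that were never sampled locally at 0+
#' (September) or 1+ (June) and therefore entered from the unsampled source
#' reach. Fish of cohorts born before the monitoring started cannot be
#' classified (they were never catchable at 0+) and are excluded via
#' `min_cohort`.
#'
#' The classification uses fin-clip status only, so it covers untagged fish
#' too and is invariant to the tagging threshold.
#'
#' @param encounters Encounter table.
#' @param min_cohort Earliest cohort (birth year) that can be classified;
#'   defaults to the first sampling year in the data. Occasions whose
#'   sampled fish are predominantly unclassifiable are still reported, on
#'   the classifiable subset.
#' @return Tibble per September occasion: `year`, `n_fish` (classifiable,
#'   age >= 1+), `n_late`, `prop_late`, binomial `se`.
#' @export
incomer_proportion <- function(encounters, min_cohort = NULL) {
  id_col <- if ("fish_id" %in% names(encounters)) "fish_id" else "tag_id"
  assert_columns(encounters, c(id_col, "date", "age_years", "fin_clipped"),
                 "`encounters`")
  enc <- encounters |>
    dplyr::mutate(season = season_of(.data$date),
                  year = year_of(.data$date),
                  age_class = age_class_of(.data$age_years),
                  cohort = .data$year - .data$age_class)
  min_cohort <- min_cohort %||% min(enc$year)

  first_cap <- enc |>
    dplyr::arrange(.data$date, .data$pass) |>
    dplyr::distinct(.data[[id_col]], .keep_all = TRUE) |>
    dplyr::mutate(late = .data$fin_clipped == 0 &
                    ((.data$season == "September" & .data$age_class >= 1) |
                       (.data$season == "June" & .data$age_class >= 2))) |>
    dplyr::select(dplyr::all_of(id_col), "late")

  enc |>
    dplyr::filter(.data$season == "September", .data$age_class >= 1,
                  .data$cohort >= min_cohort) |>
    dplyr::distinct(.data$year, .data[[id_col]]) |>
    dplyr::left_join(first_cap, by = id_col) |>
    dplyr::summarise(
      n_fish = dplyr::n(),
      n_late = sum(.data$late),
      prop_late = mean(.data$late),
      se = sqrt(.data$prop_late * (1 - .data$prop_late) / .data$n_fish),
      .by = "year"
    ) |>
    dplyr::arrange(.data$year)
}

#' Lagged correlation between recruitment and older-fish density
#'
#' Pearson correlation between the density of 0+ fish in September of year
#' `t` and the density of older-than-0+ fish `lag` years later — the test
#' of whether variation in recruitment drives later variation in the
#' standing stock.
#'
#' @param series Annual series with columns `year`, `d0` (0+ density) and
#'   `d_gt0` (older-than-0+ density).
#' @param lags Integer lags to test (default `c(1, 2)`).
#' @return Tibble per lag: `lag`, `r`, `p_value`, `n_pairs`.
#' @export
lagged_density_correlation <- function(series, lags = c(1, 2)) {
  assert_columns(series, c("year", "d0", "d_gt0"), "`series`")
  purrr::map_dfr(lags, function(lag) {
    paired <- dplyr::inner_join(
      series |> dplyr::select("year", "d0"),
      series |> dplyr::mutate(year = .data$year - lag) |>
        dplyr::select("year", "d_gt0"),
      by = "year"
    ) |> dplyr::filter(complete.cases(.data$d0, .data$d_gt0))
    if (nrow(paired) < 4) {
      abort(sprintf("fewer than 4 overlapping year pairs at lag %d.", lag))
    }
    ct <- cor.test(paired$d0, paired$d_gt0)
    tibble::tibble(lag = lag, r = unname(ct$estimate),
                   p_value = ct$p.value, n_pairs = nrow(paired))
  })
}

# fit a list of lm candidates and rank by AIC; shared by the recruitment
# and size-at-age-0 selections
rank_lm_candidates <- function(data, formulas) {
  rows <- purrr::imap(formulas, function(f, label) {
    fit <- tryCatch(lm(f, data = data), error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(model = label, npar = NA_integer_, loglik = NA_real_,
                     aic = NA_real_, r_squared = NA_real_,
                     status = conditionMessage(fit), fit = list(NULL))
    } else {
      ll <- logLik(fit)
      tibble::tibble(model = label,
                     npar = attr(ll, "df"),
                     loglik = as.numeric(ll),
                     aic = aic(as.numeric(ll), attr(ll, "df")),
                     r_squared = summary(fit)$r.squared,
                     status = "ok", fit = list(fit))
    }
  })
  aic_rank(dplyr::bind_rows(rows))
}

#' Candidate models of annual recruitment
#'
#' Ranks by AIC a small candidate set for September 0+ density `R_t` as a
#' function of the previous year's spawner density and spring degree-days:
#' the null (constant) model, linear terms, and modest-df regression
#' splines in place of penalised smoothers — with ~10 years of data,
#' fixed-df splines inside ordinary least squares keep every candidate
#' likelihood exact and comparable. "No predictor wins" is a perfectly
#' representable outcome.
#'
#' @param series Annual tibble with columns `year`, `r_t` (0+ September
#'   density), `d_spawners_prev` (spawner density in September of
#'   `year - 1`), `gdd_spring` (degree-days 1 January to 31 May).
#' @param spline_df Degrees of freedom for the spline candidates (default
#'   3); spline candidates whose df exceed `n - 2` are skipped with a
#'   warning.
#' @return Ranked candidate tibble as from [aic_rank()], with `r_squared`.
#' @export
fit_recruitment <- function(series, spline_df = 3) {
  assert_columns(series, c("year", "r_t", "d_spawners_prev", "gdd_spring"),
                 "`series`")
  series <- series |> dplyr::filter(complete.cases(
    .data$r_t, .data$d_spawners_prev, .data$gdd_spring))
  n <- nrow(series)
  forms <- list(
    "null" = r_t ~ 1,
    "spawners" = r_t ~ d_spawners_prev,
    "gdd" = r_t ~ gdd_spring,
    "spawners+gdd" = r_t ~ d_spawners_prev + gdd_spring
  )
  if (spline_df <= n - 2) {
    forms[["s(spawners)"]] <-
      stats::as.formula(sprintf("r_t ~ splines::bs(d_spawners_prev, df = %d)",
                                spline_df))
    forms[["s(gdd)"]] <-
      stats::as.formula(sprintf("r_t ~ splines::bs(gdd_spring, df = %d)",
                                spline_df))
  } else {
    warn(sprintf("spline candidates skipped: df = %d exceeds n - 2 = %d.",
                 spline_df, n - 2))
  }
  rank_lm_candidates(series, forms)
}

#' Candidate models of mean length at age 0+
#'
#' AIC ranking for cohort mean September length of 0+ fish on the log
#' scale, with candidate predictors log older-fish density, degree-days to
#' 31 August, and their interaction.
#'
#' @param series Annual tibble with columns `year`, `l0_mean` (mm, > 0),
#'   `d_gt0` (> 0) and `gdd_aug`.
#' @return Ranked candidate tibble with `r_squared` and slope signs
#'   recoverable from the `fit` list-column.
#' @export
fit_size_at_age0 <- function(series) {
  assert_columns(series, c("year", "l0_mean", "d_gt0", "gdd_aug"),
                 "`series`")
  series <- series |> dplyr::filter(complete.cases(
    .data$l0_mean, .data$d_gt0, .data$gdd_aug))
  if (nrow(series) < 5) abort("need >= 5 years for size-at-age-0 models.")
  if (any(series$l0_mean <= 0) || any(series$d_gt0 <= 0)) {
    abort("`l0_mean` and `d_gt0` must be positive for the log transform.")
  }
  series <- series |>
    dplyr::mutate(log_l0 = log(.data$l0_mean),
                  log_d = log(.data$d_gt0))
  forms <- list(
    "null" = log_l0 ~ 1,
    "density" = log_l0 ~ log_d,
    "gdd" = log_l0 ~ gdd_aug,
    "density+gdd" = log_l0 ~ log_d + gdd_aug,
    "density*gdd" = log_l0 ~ log_d * gdd_aug
  )
  rank_lm_candidates(series, forms)
}

#' Movement summaries and the multi-sector GLM
#'
#' Per-fish summaries of where tagged fish were sampled over their
#' lifetimes: number of distinct sectors, whether any pair of sampled
#' sectors is non-adjacent, and the number of distinct years sampled. The
#' population summary reports the proportion of tagged fish ever sampled in
#' more than one sector (with binomial SE) and a logistic GLM of that
#' indicator on the number of years sampled.
#'
#' @param encounters Encounter table (tagged fish only are used).
#' @return Object of class `"movement_summary"`: `per_fish` tibble,
#'   `prop_multi`, `se_prop`, `prop_nonadjacent_given_multi`, `glm`
#'   coefficient tibble (`NULL` and flagged when degenerate, e.g. no
#'   movement at all).
#' @export
movement_analysis <- function(encounters) {
  assert_columns(encounters, c("tag_id", "date", "sector"), "`encounters`")
  per_fish <- encounters |>
    dplyr::filter(!is.na(.data$tag_id)) |>
    dplyr::summarise(
      n_sectors = dplyr::n_distinct(.data$sector),
      n_years = dplyr::n_distinct(year_of(.data$date)),
      nonadjacent = max(.data$sector) - min(.data$sector) >= 2,
      .by = "tag_id"
    ) |>
    dplyr::mutate(multi = .data$n_sectors >= 2)
  n <- nrow(per_fish)
  prop <- mean(per_fish$multi)
  glm_tbl <- NULL
  degenerate <- prop %in% c(0, 1)
  if (!degenerate) {
    g <- glm(multi ~ n_years, family = binomial(), data = per_fish)
    co <- summary(g)$coefficients
    glm_tbl <- tibble::tibble(term = rownames(co),
                              estimate = unname(co[, 1]),
                              std.error = unname(co[, 2]),
                              p.value = unname(co[, 4]))
  } else {
    warn("all fish in a single sector class; movement GLM skipped.")
  }
  structure(
    list(per_fish = per_fish,
         prop_multi = prop,
         se_prop = sqrt(prop * (1 - prop) / n),
         prop_nonadjacent_given_multi =
           if (any(per_fish$multi)) mean(per_fish$nonadjacent[per_fish$multi])
           else NA_real_,
         glm = glm_tbl, degenerate = degenerate, n_fish = n),
    class = "movement_summary"
  )
}

#' @export
print.movement_summary <- function(x, ...) {
  cat(sprintf("Movement: %.0f%% +/- %.0f%% of %d tagged fish sampled in > 1 sector\n",
              100 * x$prop_multi, 100 * x$se_prop, x$n_fish))
  if (!is.null(x$glm)) {
    cat(sprintf("  GLM(multi ~ years sampled): alpha = %.2f +/- %.2f, beta = %.2f +/- %.2f\n",
                x$glm$estimate[1], x$glm$std.error[1],
                x$glm$estimate[2], x$glm$std.error[2]))
  }
  invisible(x)
}

#' Flag cohorts with anomalous average growth
#'
#' Hypothesis-generating screen for unobserved extreme events: a cohort is
#' flagged when its predicted average (mode) length at a reference age
#' deviates from the cross-cohort median both (i) beyond its own
#' confidence interval and (ii) by more than 3 robust standard deviations
#' (median absolute deviation scale) of the cross-cohort spread. The
#' second condition guards against the order-statistic bias of the median
#' when a sizeable fraction of cohorts is genuinely shifted: without it,
#' ordinary cohorts on the far side of the shifted median are flagged
#' spuriously. Persistently fast-growing early cohorts, for instance, are
#' the signature of a density release after a mass-mortality event before
#' monitoring began. Optionally attaches z-scores of a density series for
#' the same years to aid interpretation. The output is a screen, not a
#' test: flagged cohorts warrant investigation, nothing more.
#'
#' @param fit A [fit_growth()] object with `cohort` on at least one growth
#'   parameter.
#' @param reference_age Age (years) at which cohorts are compared; must
#'   exceed the fitted `t0`.
#' @param densities Optional tibble `year`, `density` for z-score context.
#' @param level Confidence level for the per-cohort intervals. The default
#'   (`NULL`) Bonferroni-adjusts a 5% family-wise rate across the cohorts
#'   screened (`1 - 0.05 / n_cohorts`), keeping the expected number of
#'   spurious flags per screen low — a screen should favour specificity.
#' @return Tibble per cohort: predicted `length_mm` with `lower`/`upper`,
#'   `median_length` across cohorts, `flagged`, and `density_z` when
#'   supplied. Attribute `"note"` marks the output as hypothesis-generating.
#' @export
flag_anomalous_cohorts <- function(fit, reference_age = 3,
                                   densities = NULL, level = NULL) {
  cohorts <- fit$design_k$levels %||% fit$design_l$levels
  if (is.null(cohorts) || length(cohorts) < 3) {
    abort("need a growth fit with >= 3 cohort levels to screen for anomalies.")
  }
  level <- level %||% (1 - 0.05 / length(cohorts))
  if (reference_age <= fit$gamma0) {
    abort("`reference_age` must exceed the fitted t0.")
  }
  preds <- purrr::map_dfr(cohorts, function(ch) {
    predict_mean_trajectory(fit, ages = reference_age, cohort = ch,
                            level = level) |>
      dplyr::mutate(cohort = ch)
  })
  med <- median(preds$length_mm)
  mad_scale <- 1.4826 * median(abs(preds$length_mm - med))
  out <- preds |>
    dplyr::transmute(
      cohort = .data$cohort,
      length_mm = .data$length_mm,
      lower = .data$lower, upper = .data$upper,
      median_length = med,
      robust_z = (.data$length_mm - med) / mad_scale,
      flagged = (.data$lower > med | .data$upper < med) &
        abs(.data$robust_z) > 3
    )
  if (!is.null(densities)) {
    assert_columns(densities, c("year", "density"), "`densities`")
    dz <- densities |>
      dplyr::mutate(density_z = (.data$density - mean(.data$density)) /
                      sd(.data$density)) |>
      dplyr::mutate(cohort = as.character(.data$year))
    out <- out |> dplyr::left_join(dz |> dplyr::select("cohort", "density_z"),
                                   by = "cohort")
  }
  attr(out, "note") <-
    "hypothesis-generating screen; flags are not significance tests"
  out
}
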