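#' Two-pass removal abundance estimate
#'
#' Closed-form depletion estimator for two electrofishing passes with equal
#' per-pass capture probability: with first- and second-pass catches `c1` and
#' `c2`, the abundance estimate is `N = c1^2 / (c1 - c2)`, the per-pass
#' capture probability `p = 1 - c2 / c1`, and
#' `Var(N) = c1^2 c2^2 (c1 + c2) / (c1 - c2)^4`. Densities are scaled to fish
#' per hectare over the sampled surface.
#'
#' When the catches do not deplete (`c2 >= c1 > 0`) the closed form is
#' undefined; the minimum possible abundance `c1 + c2` is returned with
#' `method = "fallback"`, an `NA` standard error and a warning. `c1 = 0`
#' yields a zero estimate with zero SE.
#'
#' @param counts Data frame with integer columns `c1` and `c2`; any other
#'   columns (occasion, stratum) are carried through.
#' @param area_m2 Sampled stream surface in square metres.
#' @return `counts` with columns `n_hat`, `se_n`, `p_hat`, `density_ha`,
#'   `se_density_ha`, `method` (`"closed_form"` or `"fallback"`) appended.
#' @examples
#' two_pass_estimate(tibble::tibble(c1 = 100, c2 = 10))
#' @export
two_pass_estimate <- function(counts, area_m2 = 746.27) {
  assert_columns(counts, c("c1", "c2"), "`counts`")
  if (any(area_m2 <= 0)) abort("`area_m2` must be positive.")
  c1 <- counts$c1
  c2 <- counts$c2
  if (any(c1 < 0 | c2 < 0) || any(c1 != round(c1) | c2 != round(c2))) {
    abort("`c1` and `c2` must be non-negative integers.")
  }
  closed <- c1 > c2
  zero <- c1 == 0 & c2 == 0
  fallback <- !closed & !zero

  n_hat <- ifelse(closed, c1^2 / (c1 - c2), c1 + c2)
  var_n <- ifelse(closed, c1^2 * c2^2 * (c1 + c2) / (c1 - c2)^4, NA_real_)
  var_n[zero] <- 0
  p_hat <- ifelse(closed, 1 - c2 / c1, NA_real_)
  n_hat[zero] <- 0

  if (any(fallback)) {
    warn(sprintf(
      "%d stratum/strata did not deplete (c2 >= c1); reporting minimum abundance c1 + c2 with no SE.",
      sum(fallback)))
  }
  counts |>
    dplyr::mutate(
      n_hat = n_hat,
      se_n = sqrt(var_n),
      p_hat = p_hat,
      density_ha = fish_per_ha(n_hat, area_m2),
      se_density_ha = fish_per_ha(sqrt(var_n), area_m2),
      method = ifelse(fallback, "fallback", "closed_form")
    )
}

removal_strata_rules <- c("age_class", "cohort", "length_threshold", "total")

#' Density table by occasion and stratum from an encounter table
#'
#' Tallies distinct fish caught in the first and second electrofishing pass
#' per occasion and stratum, then applies [two_pass_estimate()]. Young of the
#' year (age class `0+`) are only reported for September occasions: they
#' emerge days before the June sampling and are not yet catchable then.
#'
#' Supported stratification rules:
#' * `"age_class"` — `0+` versus `>0+` (from `age_years`).
#' * `"cohort"` — year-of-birth cohort (`year - floor(age_years)`).
#' * `"length_threshold"` — above/below `length_threshold` mm; with the
#'   default 150 mm the `>150mm` stratum is the density of potential spawners.
#' * `"total"` — all fish pooled.
#'
#' @param encounters Encounter table with columns `fish_id` (or `tag_id`),
#'   `occasion_index`, `date`, `pass`, `length_mm`, `age_years`.
#' @param strata Stratification rule, one of
#'   `"age_class"`, `"cohort"`, `"length_threshold"`, `"total"`.
#' @param area_m2 Sampled stream surface in square metres.
#' @param length_threshold Threshold in mm for the `"length_threshold"` rule.
#' @return Tibble with one row per occasion and stratum: catch counts and the
#'   columns added by [two_pass_estimate()]. Strata with zero catch at an
#'   occasion where they are defined are reported with `n_hat = 0`.
#' @export
density_table <- function(encounters, strata = "age_class",
                          area_m2 = 746.27, length_threshold = 150) {
  assert_columns(encounters,
                 c("occasion_index", "date", "pass", "length_mm", "age_years"),
                 "`encounters`")
  if (!strata %in% removal_strata_rules) {
    abort(sprintf("unknown stratum rule '%s'; supported rules: %s",
                  strata, paste(removal_strata_rules, collapse = ", ")))
  }
  id_col <- if ("fish_id" %in% names(encounters)) "fish_id" else "tag_id"
  enc <- encounters |>
    dplyr::mutate(
      season = season_of(.data$date),
      year = year_of(.data$date),
      stratum = switch(
        strata,
        age_class = ifelse(age_class_of(.data$age_years) == 0, "0+", ">0+"),
        cohort = as.character(.data$year - age_class_of(.data$age_years)),
        length_threshold = ifelse(.data$length_mm > length_threshold,
                                  paste0(">", length_threshold, "mm"),
                                  paste0("<=", length_threshold, "mm")),
        total = "all"
      )
    )
  occ <- enc |>
    dplyr::distinct(.data$occasion_index, .data$date, .data$season, .data$year)

  counts <- enc |>
    dplyr::distinct(.data$occasion_index, .data$pass, .data$stratum,
                    .data[[id_col]]) |>
    dplyr::count(.data$occasion_index, .data$stratum, .data$pass) |>
    tidyr::pivot_wider(names_from = "pass", values_from = "n",
                       names_prefix = "c", values_fill = 0L) |>
    tidyr::complete(occasion_index = occ$occasion_index,
                    stratum = unique(enc$stratum),
                    fill = list(c1 = 0L, c2 = 0L))
  if (!"c1" %in% names(counts)) counts$c1 <- 0L
  if (!"c2" %in% names(counts)) counts$c2 <- 0L
  counts <- counts |>
    dplyr::left_join(occ, by = "occasion_index") |>
    dplyr::select("occasion_index", "date", "season", "year",
                  "stratum", "c1", "c2")
  # 0+ density is defined only for September occasions
  counts <- counts |>
    dplyr::filter(!(.data$stratum == "0+" & .data$season != "September"))
  two_pass_estimate(counts, area_m2 = area_m2) |>
    dplyr::arrange(.data$occasion_index, .data$stratum)
}
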