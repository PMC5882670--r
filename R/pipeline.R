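#' Run the full vital-rates pipeline on a synthetic or supplied dataset
#'
#' Orchestrates the analysis end to end: simulate (or accept) an encounter
#' table, estimate densities by removal sampling, fit the random-effects
#' growth model, the CJS survival model, the first-overwinter survival and
#' its density-dependence regression, recruitment candidates, movement
#' summaries and the cohort-anomaly screen. All randomness derives from the
#' configuration seed, so a given configuration reproduces byte-identical
#' outputs; per-stage seeds are split deterministically from the root seed
#' (`seed + 1000 * stage_index`) so stages can be re-run in isolation.
#'
#' Any stage failure aborts with the stage name after writing a
#' `FAILED_<stage>` marker (when `out_dir` is set) alongside the outputs of
#' the stages already completed.
#'
#' @param config A [sim_config()]; defines both the synthetic population and
#'   the root seed.
#' @param out_dir Optional directory for result CSVs and the run manifest.
#' @param encounters Optional encounter table; when supplied, the simulate
#'   stage is skipped and analyses run on these data (truth-based summaries
#'   are then unavailable).
#' @param temperature Optional daily temperature series; when `NULL` a
#'   synthetic series at the observed stream's thermal regime (annual mean
#'   8.37 degrees C) is generated from a derived seed; `NA` runs without any
#'   temperature series (survival models needing `tbar` then refuse to fit).
#' @param cjs_phi,cjs_p CJS model formulas for the survival stage.
#' @param growth_term Predictor placed on both growth parameters
#'   (`"cohort"` by default; `"1"` for none).
#' @return List of class `"vitalrates_run"` with elements `sim`,
#'   `densities`, `spawners`, `growth`, `cjs`, `early_survival`,
#'   `recruitment`, `lagged_correlation`, `movement`, `anomalies`,
#'   `manifest`.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL,
                         encounters = NULL, temperature = NULL,
                         cjs_phi = ~1, cjs_p = ~time,
                         growth_term = "cohort") {
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  results <- list()
  stage_idx <- 0L
  stage <- function(name, expr) {
    stage_idx <<- stage_idx + 1L
    out <- tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(conditionMessage(e),
                   file.path(out_dir, paste0("FAILED_", name)))
      }
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
    out
  }
  stage_seed <- function(i) (config$seed + 1000L * i) %% .Machine$integer.max
  emit <- function(df, file) {
    if (!is.null(out_dir)) {
      utils::write.csv(df, file.path(out_dir, file), row.names = FALSE)
    }
  }

  sim <- NULL
  enc <- encounters
  occs <- NULL
  if (is.null(enc)) {
    sim <- stage("simulate", simulate_population(config))
    enc <- sim$encounters
    occs <- sim$occasions
    emit(enc, "encounters.csv")
  }
  results$sim <- sim

  no_temp <- length(temperature) == 1 && is.na(temperature)
  if (no_temp) temperature <- NULL
  if (is.null(temperature) && !no_temp) {
    n_days <- as.integer(max(as.Date(enc$date)) - min(as.Date(enc$date))) +
      365L
    temperature <- simulate_temperature(
      8.37, 6, 0.5, n_days,
      start_date = as.Date(paste0(min(year_of(enc$date)), "-01-01")),
      seed = stage_seed(2L))
  }

  dens <- stage("density", density_table(enc, strata = "age_class",
                                         area_m2 = config$area_m2))
  spaw <- stage("density",
                density_table(enc, strata = "length_threshold",
                              area_m2 = config$area_m2,
                              length_threshold = 150))
  emit(dens, "densities.csv"); emit(spaw, "spawner_densities.csv")
  results$densities <- dens
  results$spawners <- spaw

  gdat <- stage("growth", make_growth_data(enc))
  growth <- NULL
  if (dplyr::n_distinct(gdat$cohort) >= 2 || growth_term == "1") {
    growth <- stage("growth",
                    fit_growth(gdat, k_term = growth_term,
                               linf_term = growth_term))
    emit(growth$coefficients, "growth_coefficients.csv")
  }
  results$growth <- growth

  chist <- stage("cjs", build_capture_histories(enc, occasions = occs,
                                                temperature = temperature,
                                                densities = dens))
  cjs <- stage("cjs", fit_cjs(chist, phi = cjs_phi, p = cjs_p))
  emit(cjs$coefficients, "cjs_coefficients.csv")
  results$cjs <- cjs

  ow <- stage("early_survival", overwinter_records(enc, densities = dens))
  early <- stage("early_survival", estimate_sigma0(ow))
  emit(early, "early_survival.csv")
  results$early_survival <- early
  if ("d_mean" %in% names(early) && sum(early$sigma_annual > 0) >= 3) {
    results$early_regression <- stage(
      "early_survival",
      tryCatch(density_dependence_regression(early),
               error = function(e) NULL))
  }

  ann <- stage("recruitment", annual_series(dens, spaw, temperature))
  results$annual_series <- ann
  if (sum(complete.cases(ann[, c("r_t", "d_spawners_prev",
                                 "gdd_spring")])) >= 6) {
    results$recruitment <- stage("recruitment", fit_recruitment(ann))
    emit(results$recruitment |> dplyr::select(-"fit"), "recruitment.csv")
  }
  if (sum(complete.cases(ann[, c("d0", "d_gt0")])) >= 4) {
    results$lagged_correlation <- stage(
      "recruitment", tryCatch(lagged_density_correlation(ann),
                              error = function(e) NULL))
  }

  results$movement <- stage("movement", movement_analysis(enc))
  if (!is.null(results$movement$glm)) {
    emit(results$movement$glm, "movement_glm.csv")
  }

  if (!is.null(growth) && length(fit_cohorts(growth)) >= 3) {
    results$anomalies <- stage("anomalies",
                               flag_anomalous_cohorts(growth,
                                                      reference_age = 3))
    emit(results$anomalies, "anomalies.csv")
  }

  results$manifest <- list(
    config_hash = rlang::hash(config),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("vitalrates")),
    n_encounters = nrow(enc),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  if (!is.null(out_dir)) {
    yaml::write_yaml(results$manifest, file.path(out_dir, "manifest.yaml"))
  }
  structure(results, class = "vitalrates_run")
}

fit_cohorts <- function(growth) {
  growth$design_k$levels %||% growth$design_l$levels %||% character()
}

#' @export
print.vitalrates_run <- function(x, ...) {
  cat("vitalrates pipeline run\n")
  cat(sprintf("  config hash %s (seed %d)\n", x$manifest$config_hash,
              x$manifest$seed))
  cat(sprintf("  %d encounter records; stages: %s\n",
              x$manifest$n_encounters,
              paste(names(Filter(Negate(is.null), x)), collapse = ", ")))
  invisible(x)
}

#' Assemble the annual series used by the recruitment analyses
#'
#' Collapses density tables and a daily temperature series into one row per
#' year: September 0+ density (`r_t` = recruitment, also `d0`),
#' September older-than-0+ density (`d_gt0`), spawner density
#' (September, `> 150 mm`), its previous-year value `d_spawners_prev`,
#' spring degree-days (1 January to 31 May, emergence window) and
#' degree-days to 31 August.
#'
#' @param densities Age-class density table from [density_table()].
#' @param spawners Length-threshold density table (150 mm rule).
#' @param temperature Daily temperature series (`date`, `value`).
#' @param base_temp Base temperature for degree-days.
#' @return Tibble with one row per year.
#' @export
annual_series <- function(densities, spawners, temperature, base_temp = 0) {
  sep <- densities |>
    dplyr::filter(.data$season == "September")
  d0 <- sep |> dplyr::filter(.data$stratum == "0+") |>
    dplyr::select("year", r_t = "density_ha")
  dg <- sep |> dplyr::filter(.data$stratum == ">0+") |>
    dplyr::select("year", d_gt0 = "density_ha")
  ds <- spawners |>
    dplyr::filter(.data$season == "September",
                  startsWith(.data$stratum, ">")) |>
    dplyr::select("year", d_spawners = "density_ha")

  years <- sort(unique(c(d0$year, dg$year, ds$year)))
  gdd_tbl <- purrr::map_dfr(years, function(y) {
    spring <- tryCatch(
      compute_gdd(temperature, c(as.Date(paste0(y, "-01-01")),
                                 as.Date(paste0(y, "-05-31"))),
                  base_temp = base_temp)$gdd,
      error = function(e) NA_real_)
    aug <- tryCatch(
      compute_gdd(temperature, c(as.Date(paste0(y, "-01-01")),
                                 as.Date(paste0(y, "-08-31"))),
                  base_temp = base_temp)$gdd,
      error = function(e) NA_real_)
    tibble::tibble(year = y, gdd_spring = spring, gdd_aug = aug)
  })

  tibble::tibble(year = years) |>
    dplyr::left_join(d0, by = "year") |>
    dplyr::mutate(d0 = .data$r_t) |>
    dplyr::left_join(dg, by = "year") |>
    dplyr::left_join(ds, by = "year") |>
    dplyr::left_join(ds |> dplyr::mutate(year = .data$year + 1L) |>
                       dplyr::rename(d_spawners_prev = "d_spawners"),
                     by = "year") |>
    dplyr::left_join(gdd_tbl, by = "year")
}
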