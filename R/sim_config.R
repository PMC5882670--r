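#' Parameters of the von Bertalanffy growth process
#'
#' Container for the parameters of the growth model used both by the
#' synthetic-data generator (as truth) and by [fit_growth()] (as estimates).
#' Growth follows `L(t) = Linf * (1 - exp(-k * (t - t0)))` with log-links
#' `log(k) = alpha0 + alpha_cohort[j] + alpha2 * x + sigma_u * u` and
#' `log(Linf) = beta0 + beta_cohort[j] + beta2 * x + sigma_v * v`, where
#' `u, v ~ N(0, 1)` are standardised individual random effects and `x` a
#' static, standardised continuous covariate (e.g. density in the first year
#' of life).
#'
#' @param alpha0 Intercept of `log(k)` (`k` in 1/year).
#' @param cohort_k Named numeric vector of cohort effects on `log(k)`
#'   (reference cohorts at 0).
#' @param alpha2 Slope of the static continuous covariate on `log(k)`.
#' @param beta0 Intercept of `log(Linf)` (`Linf` in mm).
#' @param cohort_linf Named numeric vector of cohort effects on `log(Linf)`.
#' @param beta2 Slope of the static continuous covariate on `log(Linf)`.
#' @param gamma0 Shared hypothetical age at length zero `t0` (years).
#' @param sigma_u,sigma_v Standard deviations of the individual random
#'   effects on `log(k)` and `log(Linf)` (>= 0).
#' @param sigma_eps Residual (measurement) standard deviation in mm (>= 0).
#' @return A list of class `"growth_params"`.
#' @examples
#' growth_params(sigma_u = 0.1, sigma_v = 0.1)
#' @export
growth_params <- function(alpha0 = log(0.33), cohort_k = numeric(),
                          alpha2 = 0, beta0 = log(310),
                          cohort_linf = numeric(), beta2 = 0,
                          gamma0 = -0.2, sigma_u = 0.1, sigma_v = 0.1,
                          sigma_eps = 3) {
  if (sigma_u < 0 || sigma_v < 0 || sigma_eps < 0) {
    abort("`sigma_u`, `sigma_v` and `sigma_eps` must be >= 0.")
  }
  structure(
    list(alpha0 = alpha0, cohort_k = cohort_k, alpha2 = alpha2,
         beta0 = beta0, cohort_linf = cohort_linf, beta2 = beta2,
         gamma0 = gamma0, sigma_u = sigma_u, sigma_v = sigma_v,
         sigma_eps = sigma_eps),
    class = "growth_params"
  )
}

#' Configuration for the synthetic source-sink population generator
#'
#' Defines the observation design and the true demographic processes used by
#' [simulate_population()]. Defaults emulate the monitored stream reach:
#' biannual June/September electrofishing with two passes at per-pass capture
#' probability ~0.9, a 115 mm tagging threshold with fin-clipping of all
#' first captures, four stream sectors with a mild upstream growth gradient,
#' local September recruitment, and a steady influx of untagged older fish
#' from an unsampled source reach upstream.
#'
#' @param start_year First sampling year; the first occasion is the September
#'   visit of that year.
#' @param n_occasions Number of biannual occasions (September, June,
#'   September, ...).
#' @param recruitment_mean Expected number of locally recruited 0+ fish
#'   entering each September.
#' @param initial_cohorts Named vector of abundances of pre-study cohorts
#'   present at the first occasion (names are birth years).
#' @param immigration_rate Expected number of older immigrants entering per
#'   occasion (Poisson).
#' @param immigrant_ages Named probability vector over immigrant integer age
#'   classes at entry.
#' @param growth A [growth_params()] object: the true growth process.
#' @param survival Either `list(mode = "constant", phi_annual = )` or
#'   `list(mode = "logit_additive", intercept = , cohort_effects = ,
#'   time_effects = )` with effects on the logit of annual apparent survival
#'   (cohort effects named by birth year; time effects of length
#'   `n_occasions - 1`).
#' @param sigma0_annual Scalar or named per-cohort annual-scale
#'   first-overwinter survival for age-0 fish (September 0+ to June 1+),
#'   typically well below adult survival; `NULL` falls back to the adult
#'   survival process.
#' @param q Per-pass capture probability, in (0, 1].
#' @param tagging_threshold Minimum recorded length (mm) for tagging.
#' @param sectors Number of stream sectors (1 = most downstream).
#' @param sector_multipliers Per-sector multiplicative effect on asymptotic
#'   length (length `sectors`).
#' @param movement_prob Per-interval probability that a fish moves to an
#'   adjacent sector.
#' @param area_m2 Stream surface in square metres.
#' @param seed RNG seed; identical configurations yield byte-identical
#'   output.
#' @return A list of class `"sim_config"`.
#' @examples
#' cfg <- sim_config(n_occasions = 5, seed = 42)
#' @export
sim_config <- function(start_year = 2004,
                       n_occasions = 23,
                       recruitment_mean = 100,
                       initial_cohorts = c("2000" = 30, "2001" = 60,
                                           "2002" = 100, "2003" = 150),
                       immigration_rate = 20,
                       immigrant_ages = c("1" = 0.6, "2" = 0.3, "3" = 0.1),
                       growth = growth_params(),
                       survival = list(mode = "constant", phi_annual = 0.55),
                       sigma0_annual = 0.35,
                       q = 0.9,
                       tagging_threshold = 115,
                       sectors = 4,
                       sector_multipliers = c(0.98, 1.00, 1.02, 1.04),
                       movement_prob = 0.2,
                       area_m2 = 746.27,
                       seed = 1) {
  if (n_occasions < 1) abort("`n_occasions` must be >= 1.")
  if (q <= 0 || q > 1) abort("`q` must be in (0, 1].")
  if (movement_prob < 0 || movement_prob > 1) {
    abort("`movement_prob` must be in [0, 1].")
  }
  if (recruitment_mean < 0) abort("`recruitment_mean` must be >= 0.")
  if (immigration_rate < 0) abort("`immigration_rate` must be >= 0.")
  if (area_m2 <= 0) abort("`area_m2` must be positive.")
  if (!inherits(growth, "growth_params")) {
    abort("`growth` must be a growth_params() object.")
  }
  if (length(sector_multipliers) != sectors) {
    abort("`sector_multipliers` must have one entry per sector.")
  }
  if (abs(sum(immigrant_ages) - 1) > 1e-8) {
    abort("`immigrant_ages` probabilities must sum to 1.")
  }
  if (identical(survival$mode, "constant")) {
    if (survival$phi_annual <= 0 || survival$phi_annual > 1) {
      abort("`phi_annual` must be in (0, 1].")
    }
  } else if (identical(survival$mode, "logit_additive")) {
    te <- survival$time_effects %||% rep(0, n_occasions - 1)
    if (length(te) != n_occasions - 1) {
      abort("`survival$time_effects` must have length n_occasions - 1.")
    }
    survival$time_effects <- te
    survival$cohort_effects <- survival$cohort_effects %||% numeric()
  } else {
    abort("`survival$mode` must be 'constant' or 'logit_additive'.")
  }
  structure(
    list(start_year = start_year, n_occasions = n_occasions,
         recruitment_mean = recruitment_mean,
         initial_cohorts = initial_cohorts,
         immigration_rate = immigration_rate,
         immigrant_ages = immigrant_ages,
         growth = growth, survival = survival,
         sigma0_annual = sigma0_annual,
         q = q, tagging_threshold = tagging_threshold,
         sectors = sectors, sector_multipliers = sector_multipliers,
         movement_prob = movement_prob, area_m2 = area_m2, seed = seed),
    class = "sim_config"
  )
}

#' Biannual occasion schedule implied by a simulation configuration
#'
#' September visits fall on 15 September and June visits on 15 June, giving
#' the unequal ~3 month (June to September) and ~9 month (September to June)
#' intervals of the biannual design.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with `occasion_index`, `date`, `season`, `year`, and
#'   `tau_next`, the length in years of the interval to the next occasion
#'   (`NA` for the last).
#' @export
occasion_schedule <- function(config) {
  k <- config$n_occasions
  idx <- seq_len(k)
  # occasion 1 is September of start_year, then alternate June/September
  year <- config$start_year + (idx %/% 2)
  sept <- idx %% 2 == 1
  date <- as.Date(ifelse(sept, paste0(year, "-09-15"),
                         paste0(year, "-06-15")))
  tau <- c(interval_years(date), NA_real_)
  tibble::tibble(occasion_index = idx, date = date,
                 season = ifelse(sept, "September", "June"),
                 year = year, tau_next = tau)
}

# write/read a sim_config as YAML (growth params flattened)
#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `read_sim_config()` returns a [sim_config()] object.
#' @export
write_sim_config <- function(config, path) {
  as_map <- function(v) if (length(v)) as.list(v) else list()
  x <- unclass(config)
  x$growth <- unclass(x$growth)
  # named vectors must be written as YAML maps to keep their names
  x$initial_cohorts <- as_map(x$initial_cohorts)
  x$immigrant_ages <- as_map(x$immigrant_ages)
  x$growth$cohort_k <- as_map(x$growth$cohort_k)
  x$growth$cohort_linf <- as_map(x$growth$cohort_linf)
  if (!is.null(names(x$sigma0_annual))) {
    x$sigma0_annual <- as_map(x$sigma0_annual)
  }
  if (identical(x$survival$mode, "logit_additive")) {
    x$survival$cohort_effects <- as_map(x$survival$cohort_effects)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  named_num <- function(v) {
    if (is.null(v) || length(v) == 0) numeric() else unlist(v)
  }
  x <- yaml::read_yaml(path)
  x$growth <- do.call(growth_params, within(x$growth, {
    cohort_k <- named_num(cohort_k)
    cohort_linf <- named_num(cohort_linf)
  }))
  x$initial_cohorts <- named_num(x$initial_cohorts)
  x$immigrant_ages <- named_num(x$immigrant_ages)
  if (!is.null(x$sigma0_annual) && is.list(x$sigma0_annual)) {
    x$sigma0_annual <- named_num(x$sigma0_annual)
  }
  x$survival <- lapply(x$survival,
                       function(v) if (is.list(v)) unlist(v) else v)
  do.call(sim_config, x)
}
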