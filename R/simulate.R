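#' Simulate a source-sink tag-recapture dataset with known truth
#'
#' Generates a full synthetic dataset under the observation design described
#' in [sim_config()]: individuals grow along von Bertalanffy trajectories
#' with individual random effects, survive between occasions at an annual
#' rate raised to the interval length in years, move between adjacent
#' sectors, and are sampled by two electrofishing passes with per-pass
#' capture probability `q`. Every first capture is fin-clipped; fish whose
#' recorded length exceeds the tagging threshold receive a persistent tag.
#' Locally recruited fish enter at age 0+ in September; immigrants from the
#' unsampled source reach enter older, with intact adipose fins, and with
#' their own growth random effects.
#'
#' Death and permanent emigration are not distinguished: the generating
#' "survival" is apparent survival, the estimand of the downstream CJS
#' model.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `"sim_population"`:
#' \describe{
#'   \item{encounters}{Long-format encounter tibble, one row per fish x
#'     occasion x pass actually caught: `fish_id`, `tag_id` (`NA` while
#'     untagged), `date`, `occasion_index`, `pass`, `length_mm`, `sector`,
#'     `fin_clipped` (status at capture: 1 if previously captured),
#'     `age_years`, `season`, `year`.}
#'   \item{truth}{Per-fish truth: cohort, origin (`"local"`, `"early"`,
#'     `"late"`), random effects `u`, `v`, entry and death occasions, entry
#'     sector.}
#'   \item{abundance}{True abundance per occasion x cohort (alive and
#'     present fish).}
#'   \item{occasions}{The occasion schedule.}
#'   \item{config}{The configuration used.}
#' }
#' @examples
#' sim <- simulate_population(sim_config(n_occasions = 5, seed = 7))
#' head(sim$encounters)
#' @export
simulate_population <- function(config) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be a sim_config() object.")
  }
  withr::with_seed(config$seed, simulate_population_impl(config))
}

simulate_population_impl <- function(config) {
  occ <- occasion_schedule(config)
  k_occ <- nrow(occ)
  g <- config$growth

  # per-fish state, grown as fish enter
  st <- new.env(parent = emptyenv())
  st$n <- 0L
  for (f in c("cohort", "u", "v", "entry_occ", "death_occ", "sector",
              "sector0", "origin", "birth_date", "alive", "ever_cap",
              "tagged")) {
    assign(f, NULL, envir = st)
  }

  add_fish <- function(n, cohort, origin, entry_occ, sector) {
    if (n <= 0) return(invisible())
    st$cohort <- c(st$cohort, rep(cohort, length.out = n))
    st$u <- c(st$u, rnorm(n))
    st$v <- c(st$v, rnorm(n))
    st$entry_occ <- c(st$entry_occ, rep(entry_occ, n))
    st$death_occ <- c(st$death_occ, rep(NA_integer_, n))
    st$sector <- c(st$sector, rep(sector, length.out = n))
    st$sector0 <- c(st$sector0, rep(sector, length.out = n))
    st$origin <- c(st$origin, rep(origin, length.out = n))
    st$alive <- c(st$alive, rep(TRUE, n))
    st$ever_cap <- c(st$ever_cap, rep(FALSE, n))
    st$tagged <- c(st$tagged, rep(FALSE, n))
    st$n <- st$n + as.integer(n)
    invisible()
  }

  cohort_eff <- function(tbl, cohorts) {
    out <- rep(0, length(cohorts))
    if (length(tbl)) {
      hit <- match(as.character(cohorts), names(tbl))
      out[!is.na(hit)] <- tbl[hit[!is.na(hit)]]
    }
    out
  }

  phi_annual_of <- function(cohorts, interval) {
    sv <- config$survival
    if (identical(sv$mode, "constant")) {
      rep(sv$phi_annual, length(cohorts))
    } else {
      plogis(sv$intercept + cohort_eff(sv$cohort_effects, cohorts) +
               sv$time_effects[interval])
    }
  }

  sigma0_of <- function(cohorts) {
    s0 <- config$sigma0_annual
    if (is.null(s0)) return(NULL)
    if (is.null(names(s0))) return(rep(s0, length(cohorts)))
    out <- s0[as.character(cohorts)]
    unname(ifelse(is.na(out), NA, out))
  }

  # seed initial standing stock (pre-study cohorts, resident fish)
  for (cy in names(config$initial_cohorts)) {
    n0 <- config$initial_cohorts[[cy]]
    add_fish(n0, as.integer(cy), "local", 1L,
             sample.int(config$sectors, n0, replace = TRUE))
  }

  enc <- vector("list", k_occ)
  abund <- vector("list", k_occ)

  for (j in seq_len(k_occ)) {
    # local recruits enter each September at age 0+
    if (occ$season[j] == "September" &&
        !(j == 1L && length(config$initial_cohorts) == 0 &&
          config$recruitment_mean == 0)) {
      n_rec <- rpois(1, config$recruitment_mean)
      add_fish(n_rec, occ$year[j], "local", j,
               sample.int(config$sectors, max(n_rec, 0), replace = TRUE))
    }
    # immigrants from the source reach enter from the second occasion on,
    # at the most upstream sector, with integer age classes at entry
    if (j > 1L && config$immigration_rate > 0) {
      n_imm <- rpois(1, config$immigration_rate)
      if (n_imm > 0) {
        acl <- as.integer(sample(names(config$immigrant_ages), n_imm,
                                 replace = TRUE,
                                 prob = config$immigrant_ages))
        # age-1 fish entering at the June visit were catchable at 1+ in
        # June, hence "early incomers" under the fin-clip classification
        orig <- if (occ$season[j] == "September") {
          rep("late", n_imm)
        } else {
          ifelse(acl == 1L, "early", "late")
        }
        for (a in unique(acl)) {
          sel <- acl == a
          add_fish(sum(sel), occ$year[j] - a, orig[sel], j,
                   rep(config$sectors, sum(sel)))
        }
      }
    }

    idx <- which(st$alive & st$entry_occ <= j)
    if (length(idx) == 0) next
    birth <- as.Date(paste0(st$cohort[idx], "-06-15"))
    age <- as.numeric(occ$date[j] - birth) / 365.25

    # truth abundance by cohort
    coh_j <- sort(unique(st$cohort[idx]))
    abund[[j]] <- tibble::tibble(
      occasion_index = rep(j, length(coh_j)),
      cohort = coh_j,
      n_true = as.integer(table(factor(st$cohort[idx], levels = coh_j))))

    # two removal passes; caught fish are held until both passes are done
    ki <- exp(g$alpha0 + cohort_eff(g$cohort_k, st$cohort[idx]) +
                g$sigma_u * st$u[idx])
    linf <- exp(g$beta0 + cohort_eff(g$cohort_linf, st$cohort[idx]) +
                  g$sigma_v * st$v[idx]) *
      config$sector_multipliers[st$sector0[idx]]
    l_true <- linf * (1 - exp(-ki * (age - g$gamma0)))

    caught1 <- runif(length(idx)) < config$q
    caught2 <- !caught1 & runif(length(idx)) < config$q
    caught <- caught1 | caught2
    if (any(caught)) {
      ci <- idx[caught]
      l_rec <- pmax(1, round(l_true[caught] +
                               rnorm(sum(caught), 0, g$sigma_eps)))
      fin_prev <- st$ever_cap[ci]
      st$ever_cap[ci] <- TRUE
      newtag <- !st$tagged[ci] & l_rec > config$tagging_threshold
      st$tagged[ci[newtag]] <- TRUE
      enc[[j]] <- tibble::tibble(
        fish_id = ci,
        tag_id = ifelse(st$tagged[ci], sprintf("T%05d", ci), NA_character_),
        date = occ$date[j],
        occasion_index = j,
        pass = ifelse(caught1[caught], 1L, 2L),
        length_mm = as.numeric(l_rec),
        sector = st$sector[ci],
        fin_clipped = as.integer(fin_prev),
        age_years = age[caught],
        season = occ$season[j],
        year = occ$year[j]
      )
    }

    # survival and movement over the interval to the next occasion
    if (j < k_occ) {
      tau <- occ$tau_next[j]
      phi_a <- phi_annual_of(st$cohort[idx], j)
      s0 <- sigma0_of(st$cohort[idx])
      is0 <- occ$season[j] == "September" & st$cohort[idx] == occ$year[j]
      if (!is.null(s0)) phi_a <- ifelse(is0 & !is.na(s0), s0, phi_a)
      die <- runif(length(idx)) > phi_a^tau
      st$alive[idx[die]] <- FALSE
      st$death_occ[idx[die]] <- j
      move <- runif(length(idx)) < config$movement_prob & !die
      if (any(move)) {
        step <- sample(c(-1L, 1L), sum(move), replace = TRUE)
        st$sector[idx[move]] <- pmin(pmax(st$sector[idx[move]] + step, 1L),
                                     config$sectors)
      }
    }
  }

  truth <- tibble::tibble(
    fish_id = seq_len(st$n),
    tag_id = ifelse(st$tagged, sprintf("T%05d", seq_len(st$n)),
                    NA_character_),
    cohort = st$cohort,
    origin = st$origin,
    u = st$u, v = st$v,
    birth_date = as.Date(paste0(st$cohort, "-06-15")),
    entry_occ = st$entry_occ,
    death_occ = st$death_occ,
    sector0 = st$sector0
  )

  structure(
    list(
      encounters = dplyr::bind_rows(enc) |>
        dplyr::arrange(.data$occasion_index, .data$pass, .data$fish_id),
      truth = truth,
      abundance = dplyr::bind_rows(abund) |>
        dplyr::left_join(occ |> dplyr::select("occasion_index", "date",
                                              "season", "year"),
                         by = "occasion_index"),
      occasions = occ,
      config = config
    ),
    class = "sim_population"
  )
}

#' @export
print.sim_population <- function(x, ...) {
  cat("Synthetic source-sink tag-recapture dataset\n")
  cat(sprintf("  %d fish (%d tagged), %d occasions, %d encounter records\n",
              nrow(x$truth), sum(!is.na(x$truth$tag_id)),
              nrow(x$occasions), nrow(x$encounters)))
  invisible(x)
}

#' Simulate a daily water-temperature series
#'
#' Seasonal sinusoid plus Gaussian noise: a minimal stand-in for a logger
#' series, adequate for degree-day and interval-mean covariates.
#'
#' @param mean_annual Annual mean temperature (degrees C).
#' @param amplitude Seasonal half-range (degrees C).
#' @param noise_sd Daily Gaussian noise SD (>= 0).
#' @param n_days Number of days (>= 1).
#' @param start_date First day of the series.
#' @param seed RNG seed.
#' @return Tibble with `date` and `value` (degrees C).
#' @examples
#' simulate_temperature(8.37, 6, 0.5, 365)
#' @export
simulate_temperature <- function(mean_annual, amplitude, noise_sd, n_days,
                                 start_date = as.Date("2004-01-01"),
                                 seed = 1) {
  if (n_days < 1) abort("`n_days` must be >= 1.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  withr::with_seed(seed, {
    date <- as.Date(start_date) + seq_len(n_days) - 1
    doy <- as.integer(format(date, "%j"))
    # peak around late July (day ~205)
    value <- mean_annual + amplitude * cos(2 * pi * (doy - 205) / 365.25) +
      rnorm(n_days, 0, noise_sd)
    tibble::tibble(date = date, value = value)
  })
}

#' Simulate per-year overwinter survival records
#'
#' Generates `(n0, s1)` counts for the first-overwinter survival estimator:
#' annual-scale survival follows a power law of mean older-fish density,
#' `sigma_annual = exp(a + b * log(D) + noise)`, truncated to (0, 1); the
#' number of fin-clipped survivors is binomial at the interval-scale
#' survival.
#'
#' @param d_mean Vector of mean older-fish densities `D` (fish/ha), one per
#'   year.
#' @param a,b Intercept and slope of the power law on the log-log scale.
#' @param noise_sd SD of the Gaussian noise on `log(sigma_annual)`.
#' @param n0_mean Expected number of 0+ fish sampled each September
#'   (Poisson).
#' @param interval_days Length of the overwinter interval in days.
#' @param seed RNG seed.
#' @return Tibble with `year`, `n0`, `s1`, `interval_days`, `d_mean` and the
#'   true `sigma_annual`.
#' @export
simulate_overwinter_series <- function(d_mean, a = -24.18, b = 2.70,
                                       noise_sd = 0.3, n0_mean = 100,
                                       interval_days = 273, seed = 1) {
  withr::with_seed(seed, {
    n_yr <- length(d_mean)
    sigma_annual <- pmin(exp(a + b * log(d_mean) +
                               rnorm(n_yr, 0, noise_sd)), 0.99)
    sigma_int <- sigma_annual^(interval_days / 365.25)
    n0 <- rpois(n_yr, n0_mean)
    s1 <- rbinom(n_yr, n0, sigma_int)
    tibble::tibble(year = seq_along(d_mean), n0 = n0, s1 = s1,
                   interval_days = interval_days, d_mean = d_mean,
                   sigma_annual = sigma_annual)
  })
}

#' Simulate September length-at-age data directly from the growth model
#'
#' Draws individual random effects and measurement error from a
#' [growth_params()] truth and returns a dataset ready for [fit_growth()],
#' bypassing the capture process. Used for growth parameter-recovery studies
#' where the sampling design is not at issue.
#'
#' @param params A [growth_params()] truth.
#' @param n_per_cohort Individuals per cohort.
#' @param cohorts Character vector of cohort labels; effects are looked up in
#'   `params$cohort_k` / `params$cohort_linf` (absent labels get effect 0).
#' @param ages Measurement ages (years); each individual is measured at every
#'   age.
#' @param x Optional per-individual static covariate values (recycled).
#' @param seed RNG seed.
#' @return Tibble with `fish_id`, `cohort`, `age_years`, `length_mm`, `x`,
#'   and the true `u`, `v`.
#' @export
simulate_growth_data <- function(params, n_per_cohort = 50,
                                 cohorts = c("2004", "2005"),
                                 ages = c(0.25, 1.25, 2.25, 3.25),
                                 x = 0, seed = 1) {
  if (!inherits(params, "growth_params")) {
    abort("`params` must be a growth_params() object.")
  }
  withr::with_seed(seed, {
    n <- n_per_cohort * length(cohorts)
    ind <- tibble::tibble(
      fish_id = seq_len(n),
      cohort = rep(cohorts, each = n_per_cohort),
      u = rnorm(n), v = rnorm(n),
      x = rep_len(x, n)
    )
    ck <- function(ch) {
      out <- params$cohort_k[ch]
      ifelse(is.na(out), 0, out)
    }
    cl <- function(ch) {
      out <- params$cohort_linf[ch]
      ifelse(is.na(out), 0, out)
    }
    obs <- tidyr::expand_grid(ind, age_years = ages) |>
      dplyr::mutate(
        k = exp(params$alpha0 + ck(.data$cohort) + params$alpha2 * .data$x +
                  params$sigma_u * .data$u),
        linf = exp(params$beta0 + cl(.data$cohort) +
                     params$beta2 * .data$x + params$sigma_v * .data$v),
        length_mm = .data$linf *
          (1 - exp(-.data$k * (.data$age_years - params$gamma0))) +
          rnorm(dplyr::n(), 0, params$sigma_eps)
      ) |>
      dplyr::select("fish_id", "cohort", "age_years", "length_mm", "x",
                    "u", "v")
    obs
  })
}
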