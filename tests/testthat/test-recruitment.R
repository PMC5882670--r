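test_that("incomer proportion is zero without immigration and one without recruitment", {
  closed <- simulate_population(
    sim_config(n_occasions = 7, immigration_rate = 0, seed = 2))
  ip <- incomer_proportion(closed$encounters, min_cohort = 2004)
  expect_true(all(ip$prop_late == 0))

  # all fish come from the source reach, old enough that none is ever
  # catchable at 0+ September or 1+ June (age-1 June entrants would be
  # legitimate early incomers)
  src_only <- simulate_population(
    sim_config(n_occasions = 7, recruitment_mean = 0, initial_cohorts = c(),
               immigration_rate = 25,
               immigrant_ages = c("2" = 0.7, "3" = 0.3), seed = 2))
  ip2 <- incomer_proportion(src_only$encounters, min_cohort = -Inf)
  expect_true(all(ip2$prop_late == 1))
})

test_that("incomer proportion tracks the true late-incomer share", {
  sim <- simulate_population(sim_config(seed = 41))
  ip <- incomer_proportion(sim$encounters, min_cohort = 2004) |>
    dplyr::filter(year >= 2010)
  truth_share <- sim$encounters |>
    dplyr::filter(season == "September", floor(age_years + 0.01) >= 1,
                  year >= 2010) |>
    dplyr::distinct(year, fish_id) |>
    dplyr::left_join(sim$truth, by = "fish_id") |>
    dplyr::filter(cohort >= 2004) |>
    dplyr::summarise(share = mean(origin == "late"), .by = year)
  cmp <- dplyr::inner_join(ip, truth_share, by = "year")
  expect_true(all(abs(cmp$prop_late - cmp$share) < 3 * pmax(cmp$se, 0.02)))
})

test_that("lagged correlations match a hand-computed Pearson r", {
  s <- tibble::tibble(year = 2004:2009,
                      d0 = c(100, 220, 150, 300, 210, 180),
                      d_gt0 = c(500, 400, 600, 450, 700, 520))
  out <- lagged_density_correlation(s, lags = 1)
  d0 <- s$d0[1:5]; d1 <- s$d_gt0[2:6]
  r_hand <- sum((d0 - mean(d0)) * (d1 - mean(d1))) /
    sqrt(sum((d0 - mean(d0))^2) * sum((d1 - mean(d1))^2))
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$n_pairs, 5)

  # an exact copy at lag 1 gives r = 1
  s2 <- tibble::tibble(year = 2004:2010, d0 = c(1, 5, 3, 8, 2, 9, 4))
  s2$d_gt0 <- dplyr::lag(s2$d0)
  expect_equal(lagged_density_correlation(s2, lags = 1)$r, 1)
  expect_error(lagged_density_correlation(s[1:4, ], lags = 2),
               "fewer than 4")
})

test_that("recruitment model selection can prefer no predictor at all", {
  set.seed(8)
  n <- 12
  one_series <- function(signal) {
    s <- tibble::tibble(
      year = 2004 + seq_len(n),
      d_spawners_prev = runif(n, 2500, 4500),
      gdd_spring = runif(n, 300, 500)
    )
    s$r_t <- if (signal) {
      0.2 * s$d_spawners_prev + rnorm(n, 0, 10)
    } else {
      300 + rnorm(n, 0, 40)
    }
    s
  }
  # with no signal the null model should carry in most replicates: ranked
  # first outright or flagged as having equal explanatory power with the
  # top model (the package-wide 2-AIC-point equivalence rule)
  null_wins <- mean(replicate(25, {
    sel <- fit_recruitment(one_series(FALSE))
    sel$equivalent[sel$model == "null"]
  }))
  expect_gte(null_wins, 0.6)
  # with a strong linear spawner effect, the spawner term should carry
  spawner_wins <- replicate(20, fit_recruitment(one_series(TRUE))$model[1])
  expect_gte(mean(spawner_wins == "spawners"), 0.6)
  expect_true(all(grepl("spawners", spawner_wins)))

  sel <- fit_recruitment(one_series(TRUE))
  expect_true(all(sel$delta_aic >= 0) && sel$delta_aic[1] == 0)
  # spline candidates are dropped politely when years are too few
  expect_warning(fit_recruitment(one_series(FALSE)[1:4, ], spline_df = 3),
                 "skipped")
})

test_that("size-at-age-0 models recover a noiseless log-linear density effect", {
  s <- tibble::tibble(
    year = 2004:2012,
    d_gt0 = seq(2500, 6500, length.out = 9),
    gdd_aug = runif(9, 900, 1100)
  ) |>
    dplyr::mutate(l0_mean = exp(5 - 0.25 * log(d_gt0) +
                                  rnorm(9, 0, 1e-3)))
  sel <- fit_size_at_age0(s)
  expect_equal(sel$model[1], "density")
  expect_equal(sel$r_squared[1], 1, tolerance = 1e-3)
  best <- sel$fit[[1]]
  expect_equal(unname(coef(best)[2]), -0.25, tolerance = 1e-2)
  # closed-form OLS oracle
  x <- cbind(1, log(s$d_gt0))
  expect_equal(unname(coef(best)),
               unname(ols_normal_equations(x, log(s$l0_mean))),
               tolerance = 1e-9)
  expect_error(fit_size_at_age0(s[1:3, ]), ">= 5 years")
  s_bad <- s; s_bad$l0_mean[1] <- 0
  expect_error(fit_size_at_age0(s_bad), "positive")
})

test_that("movement summaries degenerate gracefully and match an IRLS oracle", {
  frozen <- simulate_population(
    sim_config(n_occasions = 7, movement_prob = 0, seed = 4))
  expect_warning(mv0 <- movement_analysis(frozen$encounters),
                 "single sector")
  expect_equal(mv0$prop_multi, 0)
  expect_true(mv0$degenerate)

  mobile <- simulate_population(sim_config(n_occasions = 11, seed = 4))
  mv <- movement_analysis(mobile$encounters)
  expect_gt(mv$prop_multi, 0.05)
  slope <- mv$glm$estimate[mv$glm$term == "n_years"]
  expect_gt(slope, 0)    # more years sampled, more chance of moving

  # IRLS oracle on the package's own per-fish table (subset of 20)
  sub <- mv$per_fish[1:20, ]
  x <- cbind(1, sub$n_years)
  g <- glm(multi ~ n_years, family = binomial(), data = sub)
  expect_equal(unname(coef(g)),
               unname(irls_logistic(x, as.numeric(sub$multi))),
               tolerance = 1e-6)
})

test_that("anomaly screening requires enough cohorts and a sane reference age", {
  env <- shared_growth_fit()
  expect_error(flag_anomalous_cohorts(env$fit), ">= 3 cohort")
  # quick 3-cohort fit with one planted fast cohort
  truth <- growth_params(alpha0 = log(0.35), beta0 = log(300),
                         cohort_linf = c("2006" = log(1.25)),
                         gamma0 = -0.2, sigma_u = 0.08, sigma_v = 0.08,
                         sigma_eps = 3)
  d <- simulate_growth_data(truth, n_per_cohort = 40,
                            cohorts = c("2004", "2005", "2006"),
                            ages = c(0.25, 1.25, 2.25, 3.25), seed = 9)
  fit <- fit_growth(d, k_term = "1", linf_term = "cohort")
  expect_error(flag_anomalous_cohorts(fit, reference_age = -1),
               "exceed the fitted t0")
  flags <- flag_anomalous_cohorts(fit, reference_age = 3)
  expect_equal(flags$cohort[flags$flagged], "2006")
  dens <- tibble::tibble(year = 2004:2006, density = c(3000, 3100, 1500))
  flags2 <- flag_anomalous_cohorts(fit, reference_age = 3,
                                   densities = dens)
  expect_true("density_z" %in% names(flags2))
  expect_lt(flags2$density_z[flags2$cohort == "2006"], 0)
})

test_that("identical cohorts are rarely flagged by the anomaly screen", {
  null_truth <- growth_params(alpha0 = log(0.35), beta0 = log(300),
                              gamma0 = -0.2, sigma_u = 0.08,
                              sigma_v = 0.08, sigma_eps = 3)
  n_flags <- vapply(1:5, function(r) {
    d <- simulate_growth_data(null_truth, n_per_cohort = 15,
                              cohorts = as.character(2002:2007),
                              ages = c(0.25, 1.25, 2.25, 3.25),
                              seed = 320 + r)
    fit <- fit_growth(d, k_term = "1", linf_term = "cohort")
    sum(flag_anomalous_cohorts(fit, reference_age = 3)$flagged)
  }, numeric(1))
  expect_gte(mean(n_flags == 0), 0.8)
})
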