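test_that("the growth curve evaluates correctly and respects its asymptote", {
  p <- growth_params(alpha0 = log(0.3), beta0 = log(300), gamma0 = 0,
                     sigma_u = 0, sigma_v = 0)
  expect_equal(vbgf_length(p, t = 0), 0)
  expect_equal(vbgf_length(p, t = 2), 300 * (1 - exp(-0.6)),
               tolerance = 1e-10)
  expect_equal(vbgf_length(p, t = 1e6), 300)
  # strictly increasing in age, bounded by Linf (with random effects too)
  p2 <- growth_params(alpha0 = log(0.4), beta0 = log(280), gamma0 = -0.2,
                      sigma_u = 0.2, sigma_v = 0.15)
  for (v in c(-1, 0, 1.5)) {
    lens <- vbgf_length(p2, t = seq(0, 12, by = 0.5), u = 0.5, v = v)
    expect_true(all(diff(lens) > 0))
    expect_true(all(lens < exp(log(280) + 0.15 * v)))
  }
  # cohort effects shift the curve
  p3 <- growth_params(cohort_k = c("2005" = 0.5), sigma_u = 0, sigma_v = 0)
  expect_gt(vbgf_length(p3, 2, cohort = "2005"), vbgf_length(p3, 2))
})

test_that("with no individual heterogeneity the fit collapses to nonlinear least squares", {
  truth <- growth_params(alpha0 = log(0.4), beta0 = log(290), gamma0 = -0.2,
                         sigma_u = 0, sigma_v = 0, sigma_eps = 2)
  d <- simulate_growth_data(truth, n_per_cohort = 80, cohorts = "2004",
                            ages = c(0.25, 1.25, 2.25, 3.25), seed = 17)
  fit <- fit_growth(d, k_term = "1", linf_term = "1")
  expect_lt(fit$sigma["sigma_u"], 0.02)
  expect_lt(fit$sigma["sigma_v"], 0.02)
  nls_fit <- nls(length_mm ~ linf * (1 - exp(-k * (age_years - g0))),
                 data = d, start = list(linf = 300, k = 0.3, g0 = -0.1))
  co <- coef(nls_fit)
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  expect_equal(exp(est[["log_k:(Intercept)"]]), unname(co["k"]),
               tolerance = 0.02)
  expect_equal(exp(est[["log_linf:(Intercept)"]]), unname(co["linf"]),
               tolerance = 0.02)
  expect_equal(est[["t0"]], unname(co["g0"]), tolerance = 0.05)
})

test_that("cohort effects and variance components are recovered", {
  env <- shared_growth_fit()
  fit <- env$fit
  truth <- env$truth
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  se <- setNames(fit$coefficients$std.error, fit$coefficients$term)
  checks <- c("log_k:(Intercept)" = truth$alpha0,
              "log_k:cohort2005" = unname(truth$cohort_k["2005"]),
              "log_linf:(Intercept)" = truth$beta0,
              "log_linf:cohort2005" = unname(truth$cohort_linf["2005"]),
              "t0" = truth$gamma0)
  for (nm in names(checks)) {
    expect_lt(abs(est[[nm]] - checks[[nm]]), 3 * se[[nm]])
  }
  expect_lt(abs(fit$sigma[["sigma_u"]] - truth$sigma_u) / truth$sigma_u,
            0.35)
  expect_lt(abs(fit$sigma[["sigma_v"]] - truth$sigma_v) / truth$sigma_v,
            0.35)
  # empirical Bayes modes track the true individual effects
  ind <- env$data[!duplicated(env$data$fish_id), ]
  expect_gt(cor(fit$ranef$u_hat, ind$u), 0.5)
  expect_gt(cor(fit$ranef$v_hat, ind$v), 0.5)
})

test_that("mode trajectories sit below the Monte Carlo mean when Linf is heterogeneous", {
  env <- shared_growth_fit()
  fit <- env$fit
  ages <- c(1.25, 3.25, 5.25)
  mode_traj <- predict_mean_trajectory(fit, ages = ages, cohort = "2004")
  expect_equal(mode_traj$trajectory, rep("mode", 3))
  est <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  set.seed(1)
  u <- rnorm(20000); v <- rnorm(20000)
  mc_mean <- vapply(ages, function(t) {
    k <- exp(est[["log_k:(Intercept)"]] + fit$sigma[["sigma_u"]] * u)
    linf <- exp(est[["log_linf:(Intercept)"]] + fit$sigma[["sigma_v"]] * v)
    mean(linf * (1 - exp(-k * (t - est[["t0"]]))))
  }, numeric(1))
  expect_true(all(mode_traj$length_mm < mc_mean))
  # confidence bands bracket the point prediction
  expect_true(all(mode_traj$lower < mode_traj$length_mm))
  expect_true(all(mode_traj$upper > mode_traj$length_mm))
  expect_error(predict_mean_trajectory(fit, ages = 2, cohort = "1999"),
               "not seen")
  expect_error(predict_mean_trajectory(fit, ages = -5, cohort = "2004"),
               "above the fitted t0")
})

test_that("marginal likelihood is invariant to individual relabelling", {
  env <- shared_growth_fit()
  d <- env$data
  set.seed(4)
  relabel <- d |>
    dplyr::mutate(fish_id = match(fish_id, sample(unique(fish_id))))
  fit2 <- fit_growth(relabel, k_term = "cohort", linf_term = "cohort")
  expect_equal(fit2$loglik, env$fit$loglik, tolerance = 1e-4)
})

test_that("model selection ranks candidates and flags ties", {
  env <- shared_growth_fit()
  one <- select_growth_model(env$data,
                             list(list(k = "cohort", linf = "cohort")))
  expect_equal(one$delta_aic, 0)
  two <- select_growth_model(env$data,
                             list(list(k = "1", linf = "1"),
                                  list(k = "1", linf = "1")))
  expect_equal(two$aic[1], two$aic[2], tolerance = 1e-6)
  expect_true(all(two$equivalent))
  # the generating cohort structure should beat the null model
  sel <- select_growth_model(env$data,
                             list(list(k = "cohort", linf = "cohort"),
                                  list(k = "1", linf = "1")))
  expect_equal(sel$model[1], "k(cohort) Linf(cohort)")
})

test_that("growth increments are length differences per day", {
  enc <- tibble::tibble(
    fish_id = c(1, 1, 2),
    tag_id = c("T1", "T1", "T2"),
    date = as.Date(c("2005-06-15", "2005-09-23", "2005-06-15")),
    occasion_index = c(1, 2, 1),
    pass = 1,
    length_mm = c(120, 150, 140),
    age_years = c(1, 1.25, 2),
    sector = 1
  )
  inc <- growth_increment(enc)
  expect_equal(nrow(inc), 1)          # single-capture fish contributes none
  expect_equal(inc$g_d, 30 / 100)
  expect_equal(inc$season, "Summer")
  expect_equal(inc$start_length, 120)

  # noiseless trajectories give declining increments with age
  p <- growth_params(sigma_u = 0, sigma_v = 0, sigma_eps = 0)
  sim <- simulate_population(
    sim_config(n_occasions = 9, recruitment_mean = 30, immigration_rate = 0,
               q = 1, growth = p,
               survival = list(mode = "constant", phi_annual = 1),
               sigma0_annual = 1, movement_prob = 0,
               sector_multipliers = rep(1, 4),
               initial_cohorts = c("2003" = 10), seed = 6))
  inc2 <- growth_increment(sim$encounters) |>
    dplyr::filter(season == "Winter") |>
    dplyr::arrange(fish_id, start_age)
  per_fish <- split(inc2$g_d, inc2$fish_id)
  per_fish <- per_fish[lengths(per_fish) >= 2]
  expect_gt(length(per_fish), 3)
  # rounding to the mm introduces +/-1 mm wiggle; allow for it
  expect_true(all(vapply(per_fish,
                         function(g) all(diff(g) < 0.02), logical(1))))
})

test_that("September growth datasets carry cohort and static sector", {
  sim <- simulate_population(sim_config(n_occasions = 7, seed = 14))
  gd <- make_growth_data(sim$encounters)
  expect_true(all(gd$age_years > 0))
  expect_true(all(table(paste(gd$fish_id, gd$age_years)) == 1))
  joined <- gd |> dplyr::distinct(fish_id, .keep_all = TRUE) |>
    dplyr::mutate(fish_id_num = fish_id) |>
    dplyr::inner_join(sim$truth, by = c("fish_id_num" = "fish_id"))
  expect_true(all(joined$cohort.x == joined$cohort.y |
                    is.na(joined$cohort.y)))
})
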