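test_that("configuration invariants are enforced", {
  expect_error(sim_config(q = 0), "in \\(0, 1\\]")
  expect_error(sim_config(n_occasions = 0), ">= 1")
  expect_error(sim_config(recruitment_mean = -1), ">= 0")
  expect_error(sim_config(movement_prob = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(immigrant_ages = c("1" = 0.5, "2" = 0.2)),
               "sum to 1")
  expect_error(sim_config(survival = list(mode = "constant",
                                          phi_annual = 1.2)), "\\(0, 1\\]")
  expect_error(growth_params(sigma_u = -1), ">= 0")
  occ <- occasion_schedule(sim_config(n_occasions = 23))
  expect_equal(nrow(occ), 23)
  expect_true(all(diff(occ$date) > 0))
  expect_equal(occ$season[1], "September")
  # unequal ~3 and ~9 month intervals
  expect_equal(sort(unique(round(occ$tau_next[-23], 2))), c(0.25, 0.75))
})

test_that("deterministic limit: perfect detection, no mortality, no immigration", {
  cfg <- sim_config(n_occasions = 4, recruitment_mean = 40,
                    immigration_rate = 0, q = 1,
                    survival = list(mode = "constant", phi_annual = 1),
                    sigma0_annual = 1,
                    growth = growth_params(sigma_eps = 0),
                    initial_cohorts = c("2003" = 20), seed = 2)
  sim <- simulate_population(cfg)
  expect_true(all(sim$encounters$pass == 1))
  # every fish is seen at every occasion from its entry on
  seen <- sim$encounters |>
    dplyr::count(fish_id, name = "n_seen") |>
    dplyr::left_join(sim$truth, by = "fish_id")
  expect_equal(seen$n_seen, 4 - seen$entry_occ + 1)
})

test_that("without immigration all fish are clipped after first capture and cohorts only shrink", {
  cfg <- sim_config(n_occasions = 7, recruitment_mean = 80,
                    immigration_rate = 0, q = 1, seed = 8)
  sim <- simulate_population(cfg)
  enc <- sim$encounters |> dplyr::arrange(fish_id, occasion_index)
  recap <- enc |> dplyr::group_by(fish_id) |>
    dplyr::filter(dplyr::row_number() > 1)
  expect_true(all(recap$fin_clipped == 1))
  first <- enc |> dplyr::distinct(fish_id, .keep_all = TRUE)
  expect_true(all(first$fin_clipped == 0))
  # per-cohort sampled counts non-increasing once the cohort has entered
  counts <- enc |>
    dplyr::distinct(occasion_index, fish_id) |>
    dplyr::left_join(sim$truth, by = "fish_id") |>
    dplyr::count(cohort, occasion_index) |>
    dplyr::arrange(cohort, occasion_index)
  for (ch in unique(counts$cohort)) {
    expect_true(all(diff(counts$n[counts$cohort == ch]) <= 0))
  }
})

test_that("realised per-pass capture fraction matches the configured probability", {
  cfg <- sim_config(n_occasions = 1, recruitment_mean = 10000,
                    immigration_rate = 0, initial_cohorts = c(),
                    q = 0.9, seed = 99)
  sim <- simulate_population(cfg)
  n_alive <- sum(sim$abundance$n_true)
  frac1 <- sum(sim$encounters$pass == 1) / n_alive
  se <- sqrt(0.9 * 0.1 / n_alive)
  expect_lt(abs(frac1 - 0.9), 3 * se)
  # second pass removes among the fish missed by the first
  frac2 <- sum(sim$encounters$pass == 2) / (n_alive - sum(sim$encounters$pass == 1))
  expect_lt(abs(frac2 - 0.9), 4 * se / sqrt(0.1))
})

test_that("simulation is deterministic under a fixed seed and conserves identities", {
  cfg <- sim_config(n_occasions = 6, seed = 123)
  s1 <- simulate_population(cfg)
  s2 <- simulate_population(cfg)
  expect_identical(s1$encounters, s2$encounters)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_population(sim_config(n_occasions = 6, seed = 124))
  expect_false(identical(s1$encounters, s3$encounters))

  # every encounter maps to exactly one truth fish, never after death
  joined <- s1$encounters |>
    dplyr::left_join(s1$truth, by = "fish_id")
  expect_true(!any(is.na(joined$cohort)))
  dead <- joined[!is.na(joined$death_occ), ]
  expect_true(all(dead$occasion_index <= dead$death_occ))
  # tagged encounter tag ids all appear in truth
  expect_true(all(na.omit(s1$encounters$tag_id) %in% s1$truth$tag_id))
})

test_that("tagging threshold and September-only 0+ rules hold", {
  sim <- simulate_population(sim_config(n_occasions = 9, seed = 10))
  enc <- sim$encounters
  first_tagged <- enc |> dplyr::filter(!is.na(tag_id)) |>
    dplyr::arrange(occasion_index, pass) |>
    dplyr::distinct(fish_id, .keep_all = TRUE)
  expect_true(all(first_tagged$length_mm > 115))
  age0_june <- enc |> dplyr::filter(season == "June",
                                    floor(age_years + 0.01) == 0)
  expect_equal(nrow(age0_june), 0)
})

test_that("config YAML round trip reproduces the simulation", {
  cfg <- sim_config(n_occasions = 4, seed = 77)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_identical(simulate_population(cfg)$encounters,
                   simulate_population(cfg2)$encounters)
})

test_that("synthetic temperature behaves at its limits", {
  const <- simulate_temperature(8.37, 0, 0, 10)
  expect_equal(const$value, rep(8.37, 10))
  long <- simulate_temperature(8.37, 6, 0.5, 3650, seed = 3)
  expect_equal(nrow(long), 3650)
  expect_gt(mean(long$value), 8.2)
  expect_lt(mean(long$value), 8.5)
  expect_error(simulate_temperature(8, 6, 0.5, 0), ">= 1")
  expect_error(simulate_temperature(8, 6, -0.5, 10), ">= 0")
})

test_that("encounter tables survive a CSV round trip", {
  sim <- simulate_population(sim_config(n_occasions = 3, seed = 5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_encounters(sim$encounters, path)
  back <- read_encounters(path)
  expect_equal(nrow(back), nrow(sim$encounters))
  expect_equal(back$length_mm, sim$encounters$length_mm)
  expect_equal(back$tag_id, sim$encounters$tag_id)
})
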