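test_that("the CJS likelihood reproduces hand-computed history probabilities", {
  th <- c(qlogis(0.5), qlogis(0.8))
  lik_11 <- exp(cjs_loglik(ch_fixture(matrix(c(1, 1), 1)), ~1, ~1, th))
  expect_equal(lik_11, 0.5 * 0.8, tolerance = 1e-10)
  lik_101 <- exp(cjs_loglik(ch_fixture(matrix(c(1, 0, 1), 1)), ~1, ~1, th))
  expect_equal(lik_101, 0.5 * 0.2 * 0.5 * 0.8, tolerance = 1e-10)
  # trailing zero: chi term = (1-phi) + phi (1-p)
  lik_10 <- exp(cjs_loglik(ch_fixture(matrix(c(1, 0), 1)), ~1, ~1, th))
  expect_equal(lik_10, 0.5 + 0.5 * 0.2, tolerance = 1e-10)
})

test_that("CJS probabilities over all continuation histories sum to one", {
  for (k in 3:5) {
    for (f in 1:(k - 1)) {
      phi <- 0.62; p <- 0.74
      th <- c(qlogis(phi), qlogis(p))
      # via the package likelihood
      tails <- expand.grid(rep(list(0:1), k - f))
      probs <- apply(tails, 1, function(tl) {
        h <- c(rep(0, f - 1), 1, as.integer(tl))
        if (sum(h) == 0) return(NA)
        exp(cjs_loglik(ch_fixture(matrix(h, 1)), ~1, ~1, th))
      })
      expect_equal(sum(probs), 1, tolerance = 1e-9)
      # independent enumeration over death times agrees history by history
      oracle <- enumerate_history_probs(k, f, phi, p)
      expect_equal(unname(probs), unname(oracle), tolerance = 1e-9)
    }
  }
})

test_that("the grouped m-array likelihood equals the per-individual product", {
  set.seed(33)
  k <- 6; n <- 120
  ch <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    f <- sample(1:(k - 1), 1)
    ch[i, f] <- 1L
    for (j in (f + 1):k) ch[i, j] <- rbinom(1, 1, 0.4)
  }
  ind <- tibble::tibble(cohort = sample(2002:2004, n, replace = TRUE),
                        origin = sample(c("early", "late"), n,
                                        replace = TRUE))
  chist <- ch_fixture(ch, ind = ind)
  th <- c(0.3, -0.2, 0.4, 0.25, qlogis(0.7), 0.2, -0.1, 0.3, 0.15)
  ll_ind <- cjs_loglik(chist, ~ cohort + origin, ~time, th)
  fit_ll <- local({
    des <- vitalrates:::cjs_designs(chist, ~ cohort + origin, ~time)
    ma <- vitalrates:::cjs_marray(chist)
    rep_rows <- as.vector(sapply(ma$rep_i, function(i) {
      (i - 1) * (k - 1) + seq_len(k - 1)
    }))
    -vitalrates:::cjs_nll_marray(th, des$x_phi[rep_rows, , drop = FALSE],
                                 des$x_p, ma, chist$intervals$tau)
  })
  expect_equal(fit_ll, ll_ind, tolerance = 1e-10)
})

test_that("capture histories are built faithfully from encounters", {
  sim <- simulate_population(sim_config(n_occasions = 7, seed = 44))
  chist <- build_capture_histories(sim$encounters,
                                   occasions = sim$occasions)
  tagged_truth <- sim$truth |> dplyr::filter(!is.na(tag_id))
  expect_equal(nrow(chist$ch), nrow(tagged_truth))
  expect_true(all(rowSums(chist$ch) >= 1))
  # a specific fish: detections match its encounter occasions
  one <- sample(tagged_truth$tag_id, 1)
  occ_seen <- sort(unique(
    sim$encounters$occasion_index[sim$encounters$tag_id %in% one]))
  expect_equal(which(chist$ch[rownames(chist$ch) == one, ] == 1), occ_seen)
  # untagged fish never enter
  expect_false(any(is.na(rownames(chist$ch))))
  # truth origin matches the fin-clip classification for cohorts born
  # after monitoring started (pre-study residents are unclassifiable:
  # they were never catchable at 0+)
  cmp <- chist$ind |>
    dplyr::inner_join(tagged_truth |>
                        dplyr::mutate(truth_late = origin == "late") |>
                        dplyr::select(tag_id, truth_late, cohort),
                      by = c("tag_id", "cohort")) |>
    dplyr::filter(cohort >= 2004)
  agree <- mean((cmp$origin == "late") == cmp$truth_late)
  expect_gt(agree, 0.95)
})

test_that("parameter counts follow the design-matrix convention", {
  set.seed(9)
  k <- 8; n <- 150
  ch <- matrix(0L, n, k)
  first <- sample(1:(k - 1), n, replace = TRUE)
  ch[cbind(1:n, first)] <- 1L
  extra <- cbind(1:n, pmin(first + sample(1:2, n, TRUE), k))
  ch[extra] <- 1L
  cohorts <- sample(2001:2004, n, replace = TRUE)
  chist <- ch_fixture(ch, ind = tibble::tibble(cohort = cohorts))
  fit <- suppressWarnings(fit_cjs(chist, ~ cohort + time, ~time))
  c_lev <- length(unique(cohorts))
  expect_equal(fit$npar, (c_lev - 1) + (k - 2) + 1 + (k - 1))
  expect_equal(fit$aic, 2 * fit$npar - 2 * fit$loglik)
})

test_that("with complete detection the survival estimate is the empirical fraction", {
  set.seed(21)
  n <- 400; k <- 5
  phi_int <- 0.7
  alive <- matrix(0L, n, k)
  alive[, 1] <- 1L
  for (j in 2:k) {
    alive[, j] <- rbinom(n, 1, phi_int) * alive[, j - 1]
  }
  chist <- ch_fixture(alive)
  fit <- fit_cjs(chist, ~1, fix_p = 1)
  emp <- sum(alive[, 2:k]) / sum(alive[, 1:(k - 1)])
  expect_equal(unique(round(fit$phi_table$phi_annual, 10)),
               round(emp, 10), tolerance = 1e-5)
  expect_equal(fit$npar, 1)
})

test_that("annualisation: interval survival equals annual survival to the power tau", {
  set.seed(3)
  sim <- simulate_population(sim_config(n_occasions = 9, seed = 3))
  chist <- build_capture_histories(sim$encounters,
                                   occasions = sim$occasions)
  fit <- fit_cjs(chist, ~season, ~1)
  expect_equal(fit$phi_table$phi_interval,
               fit$phi_table$phi_annual^fit$phi_table$tau)
  # 3-month summer interval survives more than the same annual rate over 9 months
  tab <- fit$phi_table |> dplyr::distinct(season, .keep_all = TRUE)
  expect_true(all(tab$phi_interval >= tab$phi_annual^1))
})

test_that("the likelihood is invariant to row order", {
  sim <- simulate_population(sim_config(n_occasions = 7, seed = 61))
  chist <- build_capture_histories(sim$encounters,
                                   occasions = sim$occasions)
  th <- c(qlogis(0.5), qlogis(0.8))
  ll <- cjs_loglik(chist, ~1, ~1, th)
  perm <- sample(nrow(chist$ch))
  chist2 <- capture_history(chist$ch[perm, ], chist$dates,
                            ind = chist$ind[perm, ],
                            intervals = chist$intervals)
  expect_equal(cjs_loglik(chist2, ~1, ~1, th), ll)
})

test_that("origin comparison returns one annual survival per class, deterministically", {
  sim <- simulate_population(sim_config(n_occasions = 11, seed = 15))
  chist <- build_capture_histories(sim$encounters,
                                   occasions = sim$occasions)
  out1 <- compare_origin_survival(chist)
  out2 <- compare_origin_survival(chist)
  expect_equal(out1$phi_annual, out2$phi_annual)
  expect_setequal(out1$origin, c("early", "late"))
  expect_true(all(out1$lcl < out1$phi_annual & out1$phi_annual < out1$ucl))
  # both classes share the generating survival here: CIs should overlap
  expect_true(out1$lcl[1] < out1$ucl[2] & out1$lcl[2] < out1$ucl[1])
  # single-origin data refuse
  early_only <- chist$ind$origin == "early"
  sub <- capture_history(chist$ch[early_only, ], chist$dates,
                         ind = chist$ind[early_only, ],
                         intervals = chist$intervals)
  expect_error(compare_origin_survival(sub), "both origin classes")
})

test_that("model ranking reports failures and orders by AIC", {
  sim <- simulate_population(sim_config(n_occasions = 7, seed = 19))
  chist <- build_capture_histories(sim$encounters,
                                   occasions = sim$occasions)
  tbl <- rank_cjs_models(chist, list(
    list(phi = ~1, p = ~1),
    list(phi = ~season, p = ~1),
    list(phi = ~tbar, p = ~1)    # tbar not attached: must fail loudly
  ))
  expect_equal(nrow(tbl), 3)
  expect_equal(sum(tbl$status == "ok"), 2)
  expect_true(any(grepl("tbar", tbl$status)))
  ok <- tbl |> dplyr::filter(status == "ok")
  expect_equal(ok$delta_aic[1], 0)
  one <- rank_cjs_models(chist, list(list(phi = ~1, p = ~1)))
  expect_equal(one$delta_aic, 0)
})

test_that("missing interval temperature blocks temperature models only", {
  sim <- simulate_population(sim_config(n_occasions = 5, seed = 23))
  temp <- simulate_temperature(8.37, 6, 0.5, 200,
                               start_date = min(sim$encounters$date))
  expect_warning(
    chist <- build_capture_histories(sim$encounters,
                                     occasions = sim$occasions,
                                     temperature = temp),
    "missing")
  expect_error(fit_cjs(chist, ~tbar, ~1), "missing values")
  expect_s3_class(fit_cjs(chist, ~1, ~1), "cjs_fit")
})
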