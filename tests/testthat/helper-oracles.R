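# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: brute-force grid searches, closed-form
# normal equations, textbook IRLS, and Gauss-Hermite quadrature.

# grid-search conditional MLE of two-pass removal abundance. The two-pass
# likelihood factorises as P(c1, c2 | N, p) =
#   Bin(T; N, p(2-p)) x [split of the T caught fish between passes],
# where T = c1 + c2 and the split depends on p only. The oracle maximises
# the split term over a fine p grid, then the binomial count term over
# integer N at that p.
removal_grid_mle <- function(c1, c2) {
  t_catch <- c1 + c2
  p_grid <- seq(1e-4, 1 - 1e-4, by = 1e-4)
  ll_split <- c1 * log(p_grid / (p_grid * (2 - p_grid))) +
    c2 * log(p_grid * (1 - p_grid) / (p_grid * (2 - p_grid)))
  p_hat <- p_grid[which.max(ll_split)]
  theta <- p_hat * (2 - p_hat)
  n_hat0 <- t_catch / theta
  n_grid <- t_catch:max(ceiling(3 * n_hat0) + 20, t_catch + 20)
  ll_n <- lchoose(n_grid, t_catch) + t_catch * log(theta) +
    (n_grid - t_catch) * log1p(-theta)
  list(n = n_grid[which.max(ll_n)], p = p_hat)
}

# closed-form OLS via the normal equations
ols_normal_equations <- function(x, y) {
  drop(solve(t(x) %*% x, t(x) %*% y))
}

# textbook IRLS for logistic regression
irls_logistic <- function(x, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(x))
  for (i in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- drop(solve(t(x) %*% (w * x), t(x) %*% (w * z)))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# adaptive Gauss-Hermite marginal log-likelihood for the random-effects vBGF,
# independent of the package's Laplace path: per-individual 2-D quadrature
# centred at a numerically located posterior mode (optim + numeric Hessian).
gh_marginal_loglik <- function(data, coefs, k_term, linf_term,
                               design_k_levels = NULL,
                               design_l_levels = NULL, nodes = 9) {
  gh <- pracma::gaussHermite(nodes)
  est <- setNames(coefs$estimate, coefs$term)
  gamma0 <- est[["t0"]]
  sigma_u <- exp(est[["log_sigma_u"]])
  sigma_v <- exp(est[["log_sigma_v"]])
  sigma_eps <- exp(est[["log_sigma_eps"]])
  lin <- function(prefix, term, levels, value) {
    eta <- est[[paste0(prefix, "(Intercept)")]]
    if (term != "1" && !is.null(levels) && as.character(value) != levels[1]) {
      eta <- eta + est[[paste0(prefix, term, as.character(value))]]
    }
    eta
  }
  total <- 0
  for (id in unique(data$fish_id)) {
    rows <- data[data$fish_id == id, ]
    a <- lin("log_k:", k_term, design_k_levels, rows$cohort[1])
    b <- lin("log_linf:", linf_term, design_l_levels, rows$cohort[1])
    neg_joint <- function(z) {
      k <- exp(a + sigma_u * z[1])
      linf <- exp(b + sigma_v * z[2])
      mu <- linf * (1 - exp(-k * (rows$age_years - gamma0)))
      sum((rows$length_mm - mu)^2) / (2 * sigma_eps^2) +
        nrow(rows) / 2 * log(2 * pi * sigma_eps^2) +
        sum(z^2) / 2 + log(2 * pi)
    }
    opt <- optim(c(0, 0), neg_joint, method = "BFGS")
    h <- numeric_hessian_2d(neg_joint, opt$par)
    ch <- chol(solve(h))
    # z = mode + sqrt(2) * t(ch) %*% x ; |J| = 2 / sqrt(det h)
    vals <- matrix(NA_real_, nodes, nodes)
    for (i1 in seq_len(nodes)) {
      for (i2 in seq_len(nodes)) {
        x <- c(gh$x[i1], gh$x[i2])
        z <- opt$par + sqrt(2) * drop(t(ch) %*% x)
        vals[i1, i2] <- gh$w[i1] * gh$w[i2] *
          exp(-neg_joint(z) + sum(x^2))
      }
    }
    total <- total + log(sum(vals) * 2 / sqrt(det(h)))
  }
  total
}

numeric_hessian_2d <- function(f, x, h = 1e-4) {
  out <- matrix(0, 2, 2)
  for (i in 1:2) {
    for (j in 1:2) {
      ei <- c(0, 0); ei[i] <- h
      ej <- c(0, 0); ej[j] <- h
      out[i, j] <- (f(x + ei + ej) - f(x + ei - ej) -
                      f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
    }
  }
  (out + t(out)) / 2
}

# small capture-history fixture with exactly one-year intervals so that
# interval and annual survival coincide
ch_fixture <- function(ch, ind = NULL) {
  k <- ncol(ch)
  capture_history(ch, as.Date("2004-09-15") + round(365.25 * (0:(k - 1))),
                  ind = ind,
                  intervals = tibble::tibble(tau = rep(1, k - 1)))
}

# enumerate all continuation histories after release at occasion `f` and
# return their CJS probabilities under constant parameters (independent
# enumeration oracle; probabilities computed by direct products, no chi)
enumerate_history_probs <- function(k, f, phi_int, p) {
  tails <- expand.grid(rep(list(0:1), k - f))
  apply(tails, 1, function(tl) {
    h <- c(rep(0, f - 1), 1, as.integer(tl))
    last <- max(which(h == 1))
    prob <- 1
    alive_probs <- 0
    # probability summed over death times
    # P(history) = sum over death interval d >= last of
    #   prod_{j=f}^{min(d,k-1)} terms
    total <- 0
    for (death_after in last:k) {
      # fish survives intervals f..death_after-1, dies in interval
      # death_after (or survives to the end when death_after == k)
      pr <- 1
      if (death_after > f) {
        for (j in f:(death_after - 1)) {
          pr <- pr * phi_int *
            (if (h[j + 1] == 1) p else 1 - p)
        }
      }
      pr <- pr * (if (death_after < k) (1 - phi_int) else 1)
      # histories with detections after death are impossible
      if (death_after < k && any(h[(death_after + 1):k] == 1)) pr <- 0
      total <- total + pr
    }
    total
  })
}

# cached medium-sized growth fit shared across growth tests
shared_growth_env <- new.env()
shared_growth_fit <- function() {
  if (is.null(shared_growth_env$fit)) {
    truth <- growth_params(alpha0 = log(0.35), cohort_k = c("2005" = 0.2),
                           beta0 = log(310),
                           cohort_linf = c("2005" = -0.1),
                           gamma0 = -0.2, sigma_u = 0.12, sigma_v = 0.12,
                           sigma_eps = 3)
    data <- simulate_growth_data(truth, n_per_cohort = 60,
                                 cohorts = c("2004", "2005"),
                                 ages = c(0.25, 1.25, 2.25, 3.25),
                                 seed = 31)
    shared_growth_env$truth <- truth
    shared_growth_env$data <- data
    shared_growth_env$fit <- fit_growth(data, k_term = "cohort",
                                        linf_term = "cohort")
  }
  shared_growth_env
}
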