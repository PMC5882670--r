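#' von Bertalanffy length at age with individual random effects
#'
#' Evaluates `L(t) = Linf * (1 - exp(-k * (t - t0)))` with
#' `log(k) = alpha0 + alpha_cohort[j] + alpha2 * x + sigma_u * u` and
#' `log(Linf) = beta0 + beta_cohort[j] + beta2 * x + sigma_v * v`. The
#' log-links keep both parameters positive; `u` and `v` are standardised
#' individual random effects.
#'
#' @param params A [growth_params()] object.
#' @param t Age(s) in years.
#' @param u,v Standardised individual random effects.
#' @param cohort Cohort label(s) for the group effects (absent labels get
#'   effect 0).
#' @param x Static continuous covariate value(s).
#' @return Length(s) in mm.
#' @examples
#' p <- growth_params(alpha0 = log(0.3), beta0 = log(300), gamma0 = 0,
#'                    sigma_u = 0, sigma_v = 0)
#' vbgf_length(p, t = 2)
#' @export
vbgf_length <- function(params, t, u = 0, v = 0, cohort = NULL, x = 0) {
  ck <- if (!is.null(cohort) && length(params$cohort_k)) {
    e <- params$cohort_k[as.character(cohort)]
    ifelse(is.na(e), 0, e)
  } else 0
  cl <- if (!is.null(cohort) && length(params$cohort_linf)) {
    e <- params$cohort_linf[as.character(cohort)]
    ifelse(is.na(e), 0, e)
  } else 0
  k <- exp(params$alpha0 + ck + params$alpha2 * x + params$sigma_u * u)
  linf <- exp(params$beta0 + cl + params$beta2 * x + params$sigma_v * v)
  linf * (1 - exp(-k * (t - params$gamma0)))
}

# ---- internal: design construction -----------------------------------------

# one-term design for log(k) or log(Linf): intercept plus either nothing,
# treatment-coded factor levels, or one centred+scaled continuous column
growth_design <- function(ind, term, scale_info = NULL) {
  n <- nrow(ind)
  if (term == "1") {
    return(list(X = matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")),
                levels = NULL, scale = NULL))
  }
  if (!term %in% names(ind)) {
    abort(sprintf("growth model term '%s' is not a column of the data.", term))
  }
  val <- ind[[term]]
  if (is.character(val) || is.factor(val)) {
    lev <- scale_info$levels %||% sort(unique(as.character(val)))
    bad <- setdiff(unique(as.character(val)), lev)
    if (length(bad)) {
      abort(sprintf("unseen %s level(s): %s", term,
                    paste(bad, collapse = ", ")))
    }
    f <- factor(as.character(val), levels = lev)
    X <- model.matrix(~f)
    colnames(X) <- c("(Intercept)", paste0(term, lev[-1]))
    list(X = X, levels = lev, scale = NULL)
  } else {
    ctr <- scale_info$scale %||% c(mean(val), sd(val))
    if (ctr[2] == 0) ctr[2] <- 1
    X <- cbind(1, (val - ctr[1]) / ctr[2])
    colnames(X) <- c("(Intercept)", paste0(term, "_std"))
    list(X = X, levels = NULL, scale = ctr)
  }
}

# crude least-squares scan for starting values of (k, t0, Linf)
vbgf_start <- function(t, y) {
  best <- NULL
  for (k in exp(seq(log(0.05), log(1.2), length.out = 12))) {
    for (g0 in c(-0.6, -0.3, -0.1)) {
      z <- 1 - exp(-k * (t - g0))
      linf <- sum(z * y) / sum(z^2)
      sse <- sum((y - linf * z)^2)
      if (is.null(best) || sse < best$sse) {
        best <- list(k = k, g0 = g0, linf = max(linf, max(y)), sse = sse)
      }
    }
  }
  best
}

# ---- internal: Laplace-approximated marginal likelihood --------------------

# Vectorised inner problem: for each individual find the mode of the joint
# negative log-density in (u, v) by damped Gauss-Newton, then apply the
# Laplace approximation with the full Hessian at the mode.
# obs: list(y, t, ind); n_ind individuals; a, b: per-individual linear
# predictors of log(k), log(Linf) at u = v = 0.
laplace_marginal <- function(obs, a, b, gamma0, sigma_u, sigma_v, sigma_eps,
                             return_modes = FALSE, max_iter = 50L,
                             tol = 1e-8) {
  y <- obs$y; t <- obs$t; ind <- obs$ind
  n_ind <- length(a)
  n_i <- tabulate(ind, n_ind)
  tau <- t - gamma0
  u <- numeric(n_ind); v <- numeric(n_ind)
  s2 <- sigma_eps^2

  objective <- function(u, v) {
    l_obs <- exp(b[ind] + sigma_v * v[ind]) *
      (1 - exp(-exp(a[ind] + sigma_u * u[ind]) * tau))
    r <- y - l_obs
    rowsum_vec(r^2, ind, n_ind) / (2 * s2) + (u^2 + v^2) / 2
  }

  f_cur <- objective(u, v)
  for (iter in seq_len(max_iter)) {
    k_o <- exp(a[ind] + sigma_u * u[ind])
    linf_o <- exp(b[ind] + sigma_v * v[ind])
    e_o <- exp(-k_o * tau)
    l_o <- linf_o * (1 - e_o)
    r <- y - l_o
    du_o <- sigma_u * linf_o * k_o * tau * e_o
    dv_o <- sigma_v * l_o
    g_u <- -rowsum_vec(r * du_o, ind, n_ind) / s2 + u
    g_v <- -rowsum_vec(r * dv_o, ind, n_ind) / s2 + v
    if (max(abs(c(g_u, g_v))) < tol) break
    # Gauss-Newton Hessian (always positive definite with the unit prior)
    h_uu <- rowsum_vec(du_o^2, ind, n_ind) / s2 + 1
    h_vv <- rowsum_vec(dv_o^2, ind, n_ind) / s2 + 1
    h_uv <- rowsum_vec(du_o * dv_o, ind, n_ind) / s2
    det_h <- h_uu * h_vv - h_uv^2
    step_u <- (h_vv * g_u - h_uv * g_v) / det_h
    step_v <- (h_uu * g_v - h_uv * g_u) / det_h
    lam <- rep(1, n_ind)
    for (half in 1:20) {
      f_new <- objective(u - lam * step_u, v - lam * step_v)
      worse <- f_new > f_cur + 1e-12
      if (!any(worse)) break
      lam[worse] <- lam[worse] / 2
    }
    u <- u - lam * step_u
    v <- v - lam * step_v
    f_cur <- pmin(f_new, f_cur)
  }

  # full Hessian at the mode for the Laplace determinant
  k_o <- exp(a[ind] + sigma_u * u[ind])
  linf_o <- exp(b[ind] + sigma_v * v[ind])
  e_o <- exp(-k_o * tau)
  l_o <- linf_o * (1 - e_o)
  r <- y - l_o
  du_o <- sigma_u * linf_o * k_o * tau * e_o
  dv_o <- sigma_v * l_o
  d2u_o <- sigma_u * du_o * (1 - k_o * tau)   # d2L/du2
  d2v_o <- sigma_v * dv_o                     # d2L/dv2
  duv_o <- sigma_v * du_o                     # d2L/dudv
  h_uu <- rowsum_vec(du_o^2 - r * d2u_o, ind, n_ind) / s2 + 1
  h_vv <- rowsum_vec(dv_o^2 - r * d2v_o, ind, n_ind) / s2 + 1
  h_uv <- rowsum_vec(du_o * dv_o - r * duv_o, ind, n_ind) / s2
  det_h <- h_uu * h_vv - h_uv^2
  bad <- det_h <= 0
  if (any(bad)) {
    # fall back to the Gauss-Newton Hessian where curvature is indefinite
    h_uu_g <- rowsum_vec(du_o^2, ind, n_ind) / s2 + 1
    h_vv_g <- rowsum_vec(dv_o^2, ind, n_ind) / s2 + 1
    h_uv_g <- rowsum_vec(du_o * dv_o, ind, n_ind) / s2
    det_h[bad] <- (h_uu_g * h_vv_g - h_uv_g^2)[bad]
  }
  f_mode <- rowsum_vec(r^2, ind, n_ind) / (2 * s2) + (u^2 + v^2) / 2
  # the N(0, I2) prior's normalising constant 1/(2 pi) cancels the
  # (2 pi)^{d/2} of the 2-D Laplace integral exactly
  ll_i <- -(f_mode + n_i / 2 * log(2 * pi * s2)) - 0.5 * log(det_h)
  out <- sum(ll_i)
  if (return_modes) {
    list(loglik = out, u = u, v = v, loglik_i = ll_i,
         hess = cbind(h_uu = h_uu, h_uv = h_uv, h_vv = h_vv))
  } else {
    out
  }
}

rowsum_vec <- function(x, ind, n) {
  out <- numeric(n)
  got <- rowsum(x, ind)
  out[as.integer(rownames(got))] <- got[, 1]
  out
}

# ---- fitting ---------------------------------------------------------------

#' Fit the random-effects von Bertalanffy growth model
#'
#' Maximises the marginal likelihood of longitudinal length-at-age data under
#' the growth model of [vbgf_length()], integrating the two standardised
#' individual random effects (on `log k` and `log Linf`) out of the Gaussian
#' observation likelihood by the Laplace approximation: for each individual
#' the joint posterior mode of `(u, v)` is found by damped Newton iteration
#' (gradient tolerance 1e-8) and a second-order expansion around it supplies
#' the integral. Standard errors come from the numerically differentiated
#' Hessian of the marginal likelihood; the per-individual posterior modes are
#' returned as empirical Bayes estimates.
#'
#' One predictor may be placed on each growth parameter: a categorical
#' column (e.g. cohort, sector; treatment-coded with the first sorted level
#' as reference) or a continuous column (centred and scaled internally;
#' coefficients are reported on the standardised scale together with the
#' scaling constants).
#'
#' @param data Data frame with columns `fish_id`, `age_years`, `length_mm`,
#'   plus any predictor columns. Ages must be strictly increasing within
#'   individuals.
#' @param k_term,linf_term Name of the predictor column for `log k` /
#'   `log Linf`, or `"1"` for none.
#' @param control List: `max_outer` iteration cap for the outer optimiser
#'   (default 400), `outer_tol` its relative tolerance (default 1e-6).
#' @return Object of class `"growth_fit"`: tidy coefficient table,
#'   `loglik`, `npar`, `aic`, empirical-Bayes modes, variance components and
#'   prediction metadata.
#' @seealso [predict_mean_trajectory()], [select_growth_model()]
#' @export
fit_growth <- function(data, k_term = "1", linf_term = "1",
                       control = list()) {
  assert_columns(data, c("fish_id", "age_years", "length_mm"), "`data`")
  data <- dplyr::arrange(data, .data$fish_id, .data$age_years)
  if (nrow(data) < 2) abort("need at least 2 observations to fit growth.")
  if (any(duplicated(data[, c("fish_id", "age_years")]))) {
    abort("ages must be strictly increasing within individuals.")
  }
  ids <- unique(data$fish_id)
  ind_idx <- match(data$fish_id, ids)
  ind <- data[!duplicated(data$fish_id), , drop = FALSE]

  des_k <- growth_design(ind, k_term)
  des_l <- growth_design(ind, linf_term)
  p_k <- ncol(des_k$X); p_l <- ncol(des_l$X)
  obs <- list(y = data$length_mm, t = data$age_years, ind = ind_idx)

  st <- vbgf_start(data$age_years, data$length_mm)
  start <- c(log(st$k), rep(0, p_k - 1), log(st$linf), rep(0, p_l - 1),
             st$g0, log(0.1), log(0.1), log(max(sqrt(st$sse / nrow(data)), 1)))
  lower <- c(rep(-Inf, p_k + p_l), -3, rep(-7, 3))
  upper <- c(rep(Inf, p_k + p_l), min(data$age_years) - 1e-3, rep(3, 3))

  unpack <- function(theta) {
    list(th_k = theta[seq_len(p_k)],
         th_l = theta[p_k + seq_len(p_l)],
         gamma0 = theta[p_k + p_l + 1],
         sigma_u = exp(theta[p_k + p_l + 2]),
         sigma_v = exp(theta[p_k + p_l + 3]),
         sigma_eps = exp(theta[p_k + p_l + 4]))
  }
  nll <- function(theta) {
    pr <- unpack(theta)
    a <- drop(des_k$X %*% pr$th_k)
    b <- drop(des_l$X %*% pr$th_l)
    val <- -laplace_marginal(obs, a, b, pr$gamma0, pr$sigma_u, pr$sigma_v,
                             pr$sigma_eps)
    if (!is.finite(val)) 1e10 else val
  }

  ctrl <- utils::modifyList(list(max_outer = 400, outer_tol = 1e-6), control)
  opt <- nlminb(start, nll, lower = lower, upper = upper,
                control = list(iter.max = ctrl$max_outer,
                               eval.max = 4 * ctrl$max_outer,
                               rel.tol = ctrl$outer_tol))
  if (opt$convergence != 0 && !grepl("relative convergence|both X", opt$message)) {
    # accept if the gradient is numerically flat, otherwise raise
    gr <- vapply(seq_along(opt$par), function(i) {
      h <- 1e-5 * max(abs(opt$par[i]), 1)
      ei <- replace(numeric(length(opt$par)), i, h)
      (nll(opt$par + ei) - nll(opt$par - ei)) / (2 * h)
    }, numeric(1))
    if (max(abs(gr)) > 0.1) {
      abort(sprintf("growth model did not converge: %s (objective %.3f)",
                    opt$message, opt$objective))
    }
  }

  theta <- opt$par
  pr <- unpack(theta)
  a <- drop(des_k$X %*% pr$th_k)
  b <- drop(des_l$X %*% pr$th_l)
  modes <- laplace_marginal(obs, a, b, pr$gamma0, pr$sigma_u, pr$sigma_v,
                            pr$sigma_eps, return_modes = TRUE)

  hess <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  vc <- if (!is.null(hess)) tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc))) || any(diag(vc) < 0)) {
    warn("singular or indefinite Hessian: standard errors reported as NA.")
    vc <- matrix(NA_real_, length(theta), length(theta))
  }
  se <- sqrt(diag(vc))

  par_names <- c(paste0("log_k:", colnames(des_k$X)),
                 paste0("log_linf:", colnames(des_l$X)),
                 "t0", "log_sigma_u", "log_sigma_v", "log_sigma_eps")
  coefs <- tibble::tibble(term = par_names, estimate = theta,
                          std.error = se)
  npar <- length(theta)
  loglik <- -opt$objective

  label <- sprintf("k(%s) Linf(%s)", k_term, linf_term)
  structure(
    list(coefficients = coefs, vcov = vc, loglik = loglik, npar = npar,
         aic = aic(loglik, npar), label = label,
         k_term = k_term, linf_term = linf_term,
         design_k = des_k[c("levels", "scale")],
         design_l = des_l[c("levels", "scale")],
         sigma = c(sigma_u = pr$sigma_u, sigma_v = pr$sigma_v,
                   sigma_eps = pr$sigma_eps),
         gamma0 = pr$gamma0,
         ranef = tibble::tibble(fish_id = ids, u_hat = modes$u,
                                v_hat = modes$v),
         n_obs = nrow(data), n_ind = length(ids),
         convergence = opt$convergence, message = opt$message),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("Random-effects vBGF fit: %s\n", x$label))
  cat(sprintf("  %d obs, %d individuals; logLik %.2f, AIC %.2f (%d par)\n",
              x$n_obs, x$n_ind, x$loglik, x$aic, x$npar))
  cat(sprintf("  sigma_u %.3f, sigma_v %.3f, sigma_eps %.2f mm, t0 %.3f\n",
              x$sigma["sigma_u"], x$sigma["sigma_v"], x$sigma["sigma_eps"],
              x$gamma0))
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) x$coefficients

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, npar = x$npar,
                 nobs = x$n_obs, n_ind = x$n_ind,
                 sigma_u = unname(x$sigma["sigma_u"]),
                 sigma_v = unname(x$sigma["sigma_v"]),
                 sigma_eps = unname(x$sigma["sigma_eps"]))
}

# linear predictors of log k / log Linf for a new group/covariate setting
growth_linpred <- function(fit, term, design_info, value, what = c("k", "l")) {
  what <- match.arg(what)
  pre <- if (what == "k") "log_k:" else "log_linf:"
  co <- fit$coefficients
  est <- co$estimate[startsWith(co$term, pre)]
  names(est) <- sub(pre, "", co$term[startsWith(co$term, pre)])
  row <- rep(0, length(est)); names(row) <- names(est)
  row["(Intercept)"] <- 1
  if (term != "1") {
    if (!is.null(design_info$levels)) {
      if (is.null(value)) {
        abort(sprintf("a value for '%s' is required for prediction.", term))
      }
      if (!as.character(value) %in% design_info$levels) {
        abort(sprintf("group level '%s' was not seen at fit time.", value))
      }
      cn <- paste0(term, as.character(value))
      if (cn %in% names(row)) row[cn] <- 1
    } else {
      xv <- value %||% 0
      row[paste0(term, "_std")] <-
        (xv - design_info$scale[1]) / design_info$scale[2]
    }
  }
  list(eta = sum(row * est), row = row)
}

#' Predicted average (mode) growth trajectory
#'
#' Trajectory with both individual random effects set to zero, i.e. the
#' modal individual of the group. Because `Linf` is lognormal across
#' individuals, this mode lies below the population mean trajectory whenever
#' `sigma_v > 0` (Jensen's inequality); the output is labelled accordingly.
#' Confidence bands propagate fixed-effect uncertainty by the delta method.
#'
#' @param fit A [fit_growth()] object.
#' @param ages Ages (years) at which to predict; must be >= the fitted `t0`.
#' @param cohort,sector,x Group levels / covariate value matching the fitted
#'   terms (pass the one(s) the model uses).
#' @param level Confidence level (default 0.95).
#' @return Tibble: `age_years`, `length_mm`, `lower`, `upper`, `trajectory`
#'   (= `"mode"`).
#' @export
predict_mean_trajectory <- function(fit, ages, cohort = NULL, sector = NULL,
                                    x = NULL, level = 0.95) {
  if (any(ages < fit$gamma0)) {
    abort("`ages` must be at or above the fitted t0.")
  }
  value_for <- function(term) {
    switch(term, cohort = cohort, sector = sector, "1" = NULL, x)
  }
  lp_k <- growth_linpred(fit, fit$k_term, fit$design_k,
                         value_for(fit$k_term), "k")
  lp_l <- growth_linpred(fit, fit$linf_term, fit$design_l,
                         value_for(fit$linf_term), "l")
  k <- exp(lp_k$eta); linf <- exp(lp_l$eta); g0 <- fit$gamma0
  tau <- ages - g0
  l_hat <- linf * (1 - exp(-k * tau))

  # delta method over (theta_k, theta_l, gamma0)
  p_k <- length(lp_k$row); p_l <- length(lp_l$row)
  idx <- seq_len(p_k + p_l + 1)
  vc <- fit$vcov[idx, idx, drop = FALSE]
  z <- qnorm(1 - (1 - level) / 2)
  se <- vapply(seq_along(ages), function(i) {
    e <- exp(-k * tau[i])
    grad <- c(linf * k * tau[i] * e * lp_k$row,   # d/d theta_k
              l_hat[i] * lp_l$row,                # d/d theta_l
              -linf * k * e)                      # d/d gamma0
    if (any(!is.finite(vc))) return(NA_real_)
    sqrt(drop(t(grad) %*% vc %*% grad))
  }, numeric(1))
  tibble::tibble(age_years = ages, length_mm = l_hat,
                 lower = l_hat - z * se, upper = l_hat + z * se,
                 trajectory = "mode")
}

#' Fit and rank candidate growth models by AIC
#'
#' @param data As for [fit_growth()].
#' @param candidates List of candidate specifications, each a list with
#'   elements `k` and `linf` (term names as in [fit_growth()]).
#' @return Tibble with one row per candidate: label, `loglik`, `npar`,
#'   `aic`, `delta_aic`, `equivalent` flag, `status`
#'   (`"ok"`/error message), and the fit objects in a list-column `fit`.
#'   Failed candidates are reported with `NA` AIC, not dropped.
#' @export
select_growth_model <- function(data, candidates) {
  if (length(candidates) < 1) abort("need at least one candidate model.")
  rows <- purrr::map(candidates, function(cand) {
    fit <- tryCatch(fit_growth(data, k_term = cand$k, linf_term = cand$linf),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      tibble::tibble(model = sprintf("k(%s) Linf(%s)", cand$k, cand$linf),
                     loglik = NA_real_, npar = NA_integer_, aic = NA_real_,
                     status = conditionMessage(fit), fit = list(NULL))
    } else {
      tibble::tibble(model = fit$label, loglik = fit$loglik,
                     npar = fit$npar, aic = fit$aic, status = "ok",
                     fit = list(fit))
    }
  })
  aic_rank(dplyr::bind_rows(rows))
}

#' Mean daily growth increments between captures
#'
#' For every pair of consecutive captures of the same individual (passes
#' collapsed to one record per occasion), computes `G_d = delta L / delta
#' days` in mm/day together with the starting length and age and the season
#' of the interval, ready for regression against interval covariates.
#'
#' @param encounters Encounter table (needs `fish_id` or `tag_id`, `date`,
#'   `occasion_index`, `length_mm`, `age_years`).
#' @return Tibble with one row per consecutive capture pair: `fish_id`,
#'   `start_date`, `end_date`, `days`, `g_d`, `start_length`, `start_age`,
#'   `season` (`"Summer"` for June-September intervals, `"Winter"`
#'   otherwise).
#' @export
growth_increment <- function(encounters) {
  id_col <- if ("fish_id" %in% names(encounters)) "fish_id" else "tag_id"
  assert_columns(encounters, c(id_col, "date", "occasion_index",
                               "length_mm", "age_years"), "`encounters`")
  one <- encounters |>
    dplyr::filter(!is.na(.data[[id_col]])) |>
    dplyr::arrange(.data[[id_col]], .data$date) |>
    dplyr::distinct(.data[[id_col]], .data$occasion_index,
                    .keep_all = TRUE)
  inc <- one |>
    dplyr::group_by(.data[[id_col]]) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::mutate(
      start_date = dplyr::lag(.data$date),
      start_length = dplyr::lag(.data$length_mm),
      start_age = dplyr::lag(.data$age_years)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$start_date)) |>
    dplyr::mutate(
      days = as.numeric(as.Date(.data$date) - as.Date(.data$start_date)),
      g_d = (.data$length_mm - .data$start_length) / .data$days,
      season = ifelse(season_of(.data$start_date) == "June" &
                        season_of(.data$date) == "September",
                      "Summer", "Winter")
    )
  bad <- inc$days <= 0
  if (any(bad)) {
    warn(sprintf("%d capture pair(s) with non-positive day span skipped.",
                 sum(bad)))
    inc <- inc[!bad, , drop = FALSE]
  }
  inc |>
    dplyr::transmute(
      fish_id = .data[[id_col]],
      start_date = .data$start_date, end_date = .data$date,
      days = .data$days, g_d = .data$g_d,
      start_length = .data$start_length, start_age = .data$start_age,
      season = .data$season
    )
}

#' Assemble a September length-at-age dataset for lifetime-growth fitting
#'
#' Selects tagged fish measured in September (one record per fish and
#' occasion, first pass kept), derives the year-of-birth cohort from
#' recorded age, and attaches the sector of first capture as a static
#' covariate.
#'
#' @param encounters Encounter table.
#' @return Tibble with `fish_id`, `cohort`, `sector`, `age_years`,
#'   `length_mm`.
#' @export
make_growth_data <- function(encounters) {
  assert_columns(encounters, c("tag_id", "date", "occasion_index",
                               "length_mm", "age_years"), "`encounters`")
  id_col <- if ("fish_id" %in% names(encounters)) "fish_id" else "tag_id"
  first_sector <- encounters |>
    dplyr::filter(!is.na(.data$tag_id)) |>
    dplyr::arrange(.data$date, .data$pass) |>
    dplyr::distinct(.data[[id_col]], .keep_all = TRUE) |>
    dplyr::select(dplyr::all_of(id_col), sector0 = "sector")
  encounters |>
    dplyr::filter(!is.na(.data$tag_id),
                  season_of(.data$date) == "September") |>
    dplyr::arrange(.data[[id_col]], .data$date, .data$pass) |>
    dplyr::distinct(.data[[id_col]], .data$occasion_index,
                    .keep_all = TRUE) |>
    dplyr::left_join(first_sector, by = id_col) |>
    dplyr::transmute(
      fish_id = .data[[id_col]],
      cohort = as.character(year_of(.data$date) - age_class_of(.data$age_years)),
      sector = as.character(.data$sector0),
      age_years = .data$age_years,
      length_mm = .data$length_mm
    )
}
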