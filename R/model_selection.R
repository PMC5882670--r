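#' Akaike information criterion
#'
#' `aic = 2 * npar - 2 * loglik`. Plain AIC (no small-sample correction) is
#' used throughout the package, with the conventional rule that models within
#' 2 AIC points have equal explanatory power.
#'
#' @param loglik Maximised log-likelihood.
#' @param npar Number of estimated parameters (>= 0).
#' @return The AIC value.
#' @examples
#' aic(-100, 3)
#' @export
aic <- function(loglik, npar) {
  if (any(!is.finite(loglik))) abort("`loglik` must be finite.")
  if (any(npar < 0)) abort("`npar` must be >= 0.")
  2 * npar - 2 * loglik
}

#' Rank a table of fitted models by AIC
#'
#' Adds `delta_aic` (difference from the best model) and an `equivalent` flag
#' for models within `equiv_threshold` AIC points of the best model.
#'
#' @param fits Data frame with at least an `aic` column.
#' @param equiv_threshold AIC difference below which models are flagged as
#'   having equal explanatory power (default 2).
#' @return `fits` sorted by AIC with `delta_aic` and `equivalent` appended.
#'   Rows with `NA` AIC (failed fits) sort last and are not ranked.
#' @export
aic_rank <- function(fits, equiv_threshold = 2) {
  assert_columns(fits, "aic", "`fits`")
  fits |>
    dplyr::arrange(.data$aic) |>
    dplyr::mutate(
      delta_aic = .data$aic - min(.data$aic, na.rm = TRUE),
      equivalent = .data$delta_aic < equiv_threshold
    )
}
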