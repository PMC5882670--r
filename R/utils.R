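#' @importFrom rlang .data abort warn %||%
#' @importFrom stats AIC coef complete.cases cor cor.test lm logLik median
#'   na.omit nlminb optim plogis pnorm qlogis qnorm quantile rbinom rnorm rpois
#'   runif sd setNames var vcov glm binomial predict model.matrix optimHess
#' @importFrom utils head tail
NULL

#' Convert a fish count to a density in fish per hectare
#'
#' Abundance estimates refer to the whole sampled stream surface; densities
#' are reported in fish per hectare, the conventional unit for small-stream
#' salmonid work.
#'
#' @param n Number of fish (count or abundance estimate).
#' @param area_m2 Sampled stream surface in square metres. The default is the
#'   total surface of the monitored stream reach.
#' @return Density in fish per hectare (`n / area_m2 * 1e4`).
#' @examples
#' fish_per_ha(548)
#' @export
fish_per_ha <- function(n, area_m2 = 746.27) {
  if (any(area_m2 <= 0)) abort("`area_m2` must be positive.")
  n / area_m2 * 1e4
}

#' Coefficient of variation as a percentage
#'
#' @param mean Mean of the quantity.
#' @param sd Standard deviation of the quantity.
#' @param digits Digits used when reporting; the default (0) reports whole
#'   percents, the precision at which CVs are conventionally quoted.
#' @return CV in percent, rounded to `digits`.
#' @examples
#' cv_percent(3459, 442)
#' @export
cv_percent <- function(mean, sd, digits = 0) {
  if (any(mean == 0)) abort("CV undefined for zero mean.")
  round(sd / mean * 100, digits = digits)
}

# integer age class (0+, 1+, ...) from an age in years; the small tolerance
# absorbs the leap-year wobble of exact birthday-to-birthday intervals
# (365/365.25 years is age class 1, not 0)
age_class_of <- function(age_years) floor(age_years + 0.01)

# season label from a calendar date: sampling runs in June and September;
# any date in the second half of the year is treated as the September visit.
season_of <- function(date) {
  m <- as.integer(format(as.Date(date), "%m"))
  ifelse(m >= 8, "September", "June")
}

year_of <- function(date) as.integer(format(as.Date(date), "%Y"))

# interval length in years between consecutive dates
interval_years <- function(dates) {
  as.numeric(diff(as.Date(dates))) / 365.25
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}
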