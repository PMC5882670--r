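#' Read and write encounter tables
#'
#' The on-disk encounter format is a plain CSV with header `tag_id, date
#' (ISO-8601), occasion_index, pass, length_mm, sector, fin_clipped,
#' age_years` plus any extra columns present (e.g. `fish_id` for synthetic
#' data, where fish identity is known even before tagging).
#'
#' @param encounters Encounter tibble.
#' @param path File path.
#' @return `read_encounters()` returns a tibble with `date` parsed and
#'   `season`/`year` derived.
#' @export
write_encounters <- function(encounters, path) {
  utils::write.csv(encounters, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @rdname write_encounters
#' @export
read_encounters <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  assert_columns(df, c("tag_id", "date", "occasion_index", "pass",
                       "length_mm", "sector", "fin_clipped", "age_years"),
                 "encounter file")
  tibble::as_tibble(df) |>
    dplyr::mutate(date = as.Date(.data$date),
                  season = season_of(.data$date),
                  year = year_of(.data$date))
}

#' Read a daily environmental series (temperature or rainfall)
#'
#' @param path CSV with columns `date`, `value`.
#' @return Tibble sorted by date.
#' @export
read_env_series <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(df, c("date", "value"), "environmental series file")
  tibble::as_tibble(df) |>
    dplyr::mutate(date = as.Date(.data$date)) |>
    dplyr::arrange(.data$date)
}
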