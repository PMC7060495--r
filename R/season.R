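#' Annual Pollen Integral
#'
#' Sum of the daily mean pollen concentrations over one calendar year, in
#' grains·day/m³. Days absent from the series contribute 0 and are reported
#' with a warning, following the convention that station gaps are treated
#' as pollen-free rather than interpolated.
#'
#' @param pollen A pollen tibble with `date` and `concentration` columns.
#' @param year Calendar year to integrate.
#' @return A single number, the APIn.
#' @examples
#' pollen <- generate_pollen_series(generator_config(seed = 1), 2018)
#' annual_pollen_integral(pollen, 2018)
#' @export
annual_pollen_integral <- function(pollen, year) {
  yr <- pollen %>% filter(format(.data$date, "%Y") == as.character(year))
  if (nrow(yr) == 0) {
    abort(sprintf("No pollen data for year %s.", year),
          class = "pollendiary_season_error")
  }
  if (any(yr$concentration < 0, na.rm = TRUE)) {
    abort("Negative concentrations in pollen series.",
          class = "pollendiary_season_error")
  }
  all_days <- seq(as.Date(paste0(year, "-01-01")),
                  as.Date(paste0(year, "-12-31")), by = "day")
  n_missing <- length(setdiff(all_days, yr$date)) + sum(is.na(yr$concentration))
  if (n_missing > 0) {
    warn(sprintf("%d day(s) missing from year %s treated as 0 concentration.",
                 n_missing, year))
  }
  sum(yr$concentration, na.rm = TRUE)
}

#' Pollen-season window from Annual Pollen Integral percentiles
#'
#' The season starts on the first day whose cumulative concentration sum
#' reaches `start_pct`% of the APIn and ends on the first day reaching
#' `end_pct`% (the standard retrospective 1%-95% definition). Both bounds
#' are inclusive.
#'
#' @inheritParams annual_pollen_integral
#' @param start_pct,end_pct Cumulative percentiles (of APIn) defining the
#'   season bounds; `0 < start_pct < end_pct <= 100`.
#' @return A one-row tibble: `region`, `taxon`, `year`, `start_date`,
#'   `end_date`, `apin`, `start_pct`, `end_pct`.
#' @examples
#' pollen <- generate_pollen_series(generator_config(seed = 1), 2018)
#' season_window(pollen, 2018)
#' @export
season_window <- function(pollen, year, start_pct = 1, end_pct = 95) {
  if (!(start_pct > 0 && start_pct < end_pct && end_pct <= 100)) {
    abort("Require 0 < start_pct < end_pct <= 100.",
          class = "pollendiary_season_error")
  }
  yr <- pollen %>%
    filter(format(.data$date, "%Y") == as.character(year)) %>%
    arrange(.data$date)
  apin <- suppressWarnings(annual_pollen_integral(pollen, year))
  if (apin <= 0) {
    abort(sprintf("APIn is 0 for year %s: no season definable.", year),
          class = "pollendiary_season_error")
  }
  cum <- cumsum(yr$concentration)
  start_idx <- which(cum >= start_pct / 100 * apin)[1]
  end_idx <- which(cum >= end_pct / 100 * apin)[1]
  tibble(
    region = if ("region" %in% names(yr)) yr$region[1] else NA_character_,
    taxon = if ("taxon" %in% names(yr)) yr$taxon[1] else NA_character_,
    year = as.integer(year),
    start_date = yr$date[start_idx],
    end_date = yr$date[end_idx],
    apin = apin,
    start_pct = start_pct,
    end_pct = end_pct
  )
}
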