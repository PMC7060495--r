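#' Pearson correlation with a two-sided t-test p-value
#'
#' Product-moment correlation of two equal-length sequences with the
#' classical two-sided p-value from the t distribution on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return A named list with elements `r`, `p` and `n`.
#' @examples
#' pearson_r(1:10, 2 * (1:10) + 3)$r  # 1
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) {
    abort("`x` and `y` must have equal length.", class = "pollendiary_filter_error")
  }
  if (length(x) < 3) {
    abort("Need at least 3 paired observations.", class = "pollendiary_filter_error")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Correlation undefined for a constant sequence.",
          class = "pollendiary_filter_error")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Select allergy-responsive users by score-pollen correlation
#'
#' Implements the diary's inclusion rule: a user enters the analysis pool
#' when their symptom scores show a significant positive Pearson
#' correlation with the regional pollen concentration (two-sided p below
#' `alpha` and r > 0) and they have at least `min_entries` diary entries
#' inside the pollen season. Correlations pair each in-season entry's score
#' with the same day's concentration (no lag). Users whose in-season scores
#' are constant have no defined correlation and fail.
#'
#' @param scores Score tibble from [score_entries()].
#' @param pollen Pollen tibble covering the season.
#' @param window One-row season tibble from [season_window()].
#' @param min_entries Minimum number of in-season entries (default 15).
#' @param alpha Significance level, conventionally 0.01 or 0.05.
#' @param score_col Which score drives the correlation; the diary's native
#'   combined score (`"phd_raw"`, default) or `"ema_raw"`.
#' @return A tibble of class `"pd_filter"`, one row per user: `user_id`,
#'   `n_entries`, `r`, `p`, `passed`, `alpha`. `r` and `p` are `NA` where
#'   undefined.
#' @examples
#' cfg <- generator_config(n_users = 30, seed = 5)
#' pollen <- generate_pollen_series(cfg, 2018)
#' diary <- generate_diary(generate_users(cfg), pollen, cfg)
#' win <- season_window(pollen, 2018)
#' filter_users(score_entries(diary), pollen, win)
#' @export
filter_users <- function(scores, pollen, window, min_entries = 15,
                         alpha = 0.05, score_col = c("phd_raw", "ema_raw")) {
  score_col <- match.arg(score_col)
  if ("region" %in% names(pollen) && !is.na(window$region[1]) &&
      !all(pollen$region == window$region[1])) {
    abort("Pollen series region does not match the season window.",
          class = "pollendiary_filter_error")
  }
  in_season <- scores %>%
    filter(.data$date >= window$start_date[1], .data$date <= window$end_date[1]) %>%
    left_join(pollen %>% select("date", "concentration"), by = "date")
  res <- in_season %>%
    group_by(.data$user_id) %>%
    summarise(
      n_entries = dplyr::n(),
      test = list(safe_pearson(.data[[score_col]], .data$concentration)),
      .groups = "drop"
    ) %>%
    mutate(
      r = purrr::map_dbl(.data$test, "r"),
      p = purrr::map_dbl(.data$test, "p"),
      passed = .data$n_entries >= min_entries &
        !is.na(.data$r) & .data$r > 0 & !is.na(.data$p) & .data$p < alpha,
      alpha = alpha
    ) %>%
    select("user_id", "n_entries", "r", "p", "passed", "alpha")
  structure(res, class = c("pd_filter", class(res)),
            min_entries = min_entries, score_col = score_col)
}

# Pearson pair for the filter: drops entry days without a pollen value,
# returns NA where the correlation is undefined (constant or too short).
safe_pearson <- function(score, conc) {
  ok <- !is.na(conc) & !is.na(score)
  score <- score[ok]; conc <- conc[ok]
  if (length(score) < 3 || stats::sd(score) == 0 || stats::sd(conc) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(score)))
  }
  pearson_r(score, conc)
}

#' @export
tidy.pd_filter <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @export
glance.pd_filter <- function(x, ...) {
  tibble(
    n_users = nrow(x),
    n_passed = sum(x$passed),
    pass_rate = mean(x$passed),
    alpha = x$alpha[1],
    min_entries = attr(x, "min_entries"),
    score_col = attr(x, "score_col")
  )
}
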