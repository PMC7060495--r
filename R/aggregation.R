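#' Daily pooled mean score series
#'
#' For each day of the season window, the arithmetic mean of the chosen raw
#' score over the pooled users filing an entry that day. Days without any
#' entry carry `NA` and `n_users = 0`.
#'
#' @param scores Score tibble from [score_entries()].
#' @param pool Character vector of user ids in the analysis pool.
#' @param window One-row season tibble from [season_window()].
#' @param method `"phd_raw"` or `"ema_raw"`.
#' @return A tibble: `method`, `date` (every day of the window), `value`,
#'   `n_users`.
#' @export
daily_mean_series <- function(scores, pool, window,
                              method = c("phd_raw", "ema_raw")) {
  method <- match.arg(method)
  if (length(pool) == 0) {
    abort("Empty user pool.", class = "pollendiary_aggregate_error")
  }
  days <- seq(window$start_date[1], window$end_date[1], by = "day")
  daily <- scores %>%
    filter(.data$user_id %in% pool,
           .data$date >= window$start_date[1],
           .data$date <= window$end_date[1]) %>%
    group_by(.data$date) %>%
    summarise(value = mean(.data[[method]]), n_users = dplyr::n(),
              .groups = "drop")
  tibble(date = days) %>%
    left_join(daily, by = "date") %>%
    mutate(method = method,
           n_users = if_else(is.na(.data$n_users), 0L, .data$n_users)) %>%
    select("method", "date", "value", "n_users")
}

#' Daily symptom load index series
#'
#' Normalizes each user's raw score onto a 0-10 index before pooling: per
#' day, the mean over contributing users of
#' `10 * raw / normalizer`. The normalizer is the user's own in-season
#' maximum raw score (`mode = "user_max"`, the default) or the calculation
#' method's theoretical maximum (`mode = "theoretical_max"`; 25.65 for the
#' combined score, 12 for the EMA score under default weights). Pool users
#' whose in-season scores are all zero have no defined per-user maximum;
#' they contribute 0 and are reported in a message.
#'
#' @inheritParams daily_mean_series
#' @param base `"phd"` or `"ema"` — which raw score to normalize.
#' @param mode Normalization mode, `"user_max"` or `"theoretical_max"`.
#' @param weights The [scoring_weights()] used to score the entries; fixes
#'   the theoretical maximum.
#' @return A tibble: `method` (`"phd_sli"` or `"ema_sli"`), `date`,
#'   `value` in \[0, 10\], `n_users`.
#' @export
sli_series <- function(scores, pool, window, base = c("phd", "ema"),
                       mode = c("user_max", "theoretical_max"),
                       weights = scoring_weights()) {
  base <- match.arg(base)
  mode <- match.arg(mode)
  if (length(pool) == 0) {
    abort("Empty user pool.", class = "pollendiary_aggregate_error")
  }
  raw_col <- if (base == "phd") "phd_raw" else "ema_raw"
  theo_max <- theoretical_max(base, weights)
  in_season <- scores %>%
    filter(.data$user_id %in% pool,
           .data$date >= window$start_date[1],
           .data$date <= window$end_date[1])
  normalized <- in_season %>%
    group_by(.data$user_id) %>%
    mutate(user_max = max(.data[[raw_col]])) %>%
    ungroup()
  if (mode == "user_max") {
    n_zero <- dplyr::n_distinct(normalized$user_id[normalized$user_max == 0])
    if (n_zero > 0) {
      message(n_zero, " pool user(s) with all-zero in-season scores contribute 0.")
    }
    normalized <- normalized %>%
      mutate(sli = if_else(.data$user_max == 0, 0,
                           10 * .data[[raw_col]] / .data$user_max))
  } else {
    normalized <- normalized %>% mutate(sli = 10 * .data[[raw_col]] / theo_max)
  }
  days <- seq(window$start_date[1], window$end_date[1], by = "day")
  daily <- normalized %>%
    group_by(.data$date) %>%
    summarise(value = mean(.data$sli), n_users = dplyr::n(), .groups = "drop")
  tibble(date = days) %>%
    left_join(daily, by = "date") %>%
    mutate(method = paste0(base, "_sli"),
           n_users = if_else(is.na(.data$n_users), 0L, .data$n_users)) %>%
    select("method", "date", "value", "n_users")
}

theoretical_max <- function(base, weights = scoring_weights()) {
  organ_max <- weights$severity_max + 4 * weights$symptom_point
  if (base == "phd") {
    3 * organ_max + sum(weights$med_max)
  } else {
    # EMA: nose keeps 4 symptoms, eyes collapse to 2
    (weights$severity_max + 4 * weights$symptom_point) +
      (weights$severity_max + 2 * weights$symptom_point)
  }
}

#' Organ and medication contributions to the pooled score
#'
#' Decomposes the pooled total score over the season into component
#' percentages: each percentage is 100 times the pooled sum of that
#' component's subscore divided by the pooled sum of the base total score.
#' The combined (`"phd"`) base yields eyes / nose / lungs / medication
#' percentages; the `"ema"` base yields eyes / nose.
#'
#' @inheritParams sli_series
#' @return A one-row tibble of percentages (full precision; they sum to 100).
#' @export
organ_contributions <- function(scores, pool, window, base = c("phd", "ema")) {
  base <- match.arg(base)
  in_season <- scores %>%
    filter(.data$user_id %in% pool,
           .data$date >= window$start_date[1],
           .data$date <= window$end_date[1])
  if (base == "phd") {
    total <- sum(in_season$phd_raw)
    if (total <= 0) {
      abort("Zero pooled total score: contributions undefined.",
            class = "pollendiary_aggregate_error")
    }
    tibble(
      base = "phd",
      pct_eyes = 100 * sum(in_season$sub_eyes) / total,
      pct_nose = 100 * sum(in_season$sub_nose) / total,
      pct_lungs = 100 * sum(in_season$sub_lungs) / total,
      pct_med = 100 * sum(in_season$sub_med) / total
    )
  } else {
    total <- sum(in_season$ema_raw)
    if (total <= 0) {
      abort("Zero pooled total score: contributions undefined.",
            class = "pollendiary_aggregate_error")
    }
    tibble(
      base = "ema",
      pct_eyes = 100 * sum(in_season$ema_eyes) / total,
      pct_nose = 100 * sum(in_season$ema_nose) / total
    )
  }
}

#' Seasonal mean of a daily score series
#'
#' Unweighted mean of the daily pooled values over the non-missing days of
#' the window (days without entries are skipped, not zero-filled).
#'
#' @param series A daily series tibble from [daily_mean_series()] or
#'   [sli_series()].
#' @return A single number.
#' @export
seasonal_summary <- function(series) {
  vals <- series$value[!is.na(series$value)]
  if (length(vals) == 0) {
    abort("All days missing: seasonal mean undefined.",
          class = "pollendiary_aggregate_error")
  }
  mean(vals)
}

#' Gender and age-group composition of a user pool
#'
#' @param users User tibble from [generate_users()] (or any table with
#'   `gender` and `age_group` columns).
#' @return A tibble with columns `dimension`, `category`, `n`,
#'   `proportion`; proportions sum to 1 within each dimension.
#' @export
summarize_demographics <- function(users) {
  if (nrow(users) == 0) {
    abort("Empty user table.", class = "pollendiary_aggregate_error")
  }
  one_dim <- function(col) {
    users %>%
      dplyr::count(category = .data[[col]], name = "n") %>%
      mutate(dimension = col, proportion = .data$n / sum(.data$n)) %>%
      select("dimension", "category", "n", "proportion")
  }
  bind_rows(one_dim("gender"), one_dim("age_group"))
}
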