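#' Generate one calendar year of daily pollen concentrations
#'
#' Produces a unimodal, Gaussian-shaped seasonal concentration curve with
#' multiplicative log-normal noise, rescaled so the annual sum (the Annual
#' Pollen Integral) hits `config$target_apin` exactly. This emulates the
#' daily mean concentrations a Hirst-type volumetric trap reports.
#'
#' @param config A [generator_config()].
#' @param year Calendar year to generate.
#' @return A tibble with columns `region`, `taxon`, `date`, `concentration`
#'   (grains/m³), one row per day of the year.
#' @examples
#' pollen <- generate_pollen_series(generator_config(seed = 7), 2018)
#' sum(pollen$concentration)  # equals target_apin
#' @export
generate_pollen_series <- function(config, year) {
  validate_generator_config(config)
  dates <- seq(as.Date(paste0(year, "-01-01")), as.Date(paste0(year, "-12-31")),
               by = "day")
  doy <- seq_along(dates)
  mean_curve <- exp(-0.5 * ((doy - config$peak_day) / config$peak_width)^2)
  conc <- with_stream(config$seed, STREAM_POLLEN, {
    noise <- if (config$noise_scale > 0) {
      exp(rnorm(length(doy), mean = 0, sd = config$noise_scale))
    } else {
      rep(1, length(doy))
    }
    mean_curve * noise
  })
  conc <- conc * (config$target_apin / sum(conc))
  tibble(
    region = config$region,
    taxon = config$taxon,
    date = dates,
    concentration = conc
  )
}

#' Generate the synthetic user pool
#'
#' Draws `n_users` profiles: a responder flag with probability
#' `responder_fraction`, a dose-response sensitivity (uniform on
#' `sensitivity_range` for responders, 0 for non-responders), and gender /
#' age-group labels from the configured mixtures.
#'
#' @inheritParams generate_pollen_series
#' @return A tibble with columns `user_id`, `gender`, `age_group`,
#'   `sensitivity`, `responder`.
#' @examples
#' users <- generate_users(generator_config(n_users = 20, seed = 3))
#' table(users$responder)
#' @export
generate_users <- function(config) {
  validate_generator_config(config)
  n <- config$n_users
  with_stream(config$seed, STREAM_USERS, {
    responder <- runif(n) < config$responder_fraction
    sensitivity <- ifelse(
      responder,
      runif(n, config$sensitivity_range[1], config$sensitivity_range[2]),
      0
    )
    tibble(
      user_id = sprintf("u%04d", seq_len(n)),
      gender = sample(names(config$gender_mix), n, replace = TRUE,
                      prob = config$gender_mix),
      age_group = sample(names(config$age_mix), n, replace = TRUE,
                         prob = config$age_mix),
      sensitivity = sensitivity,
      responder = responder
    )
  })
}

#' Generate diary entries for a user pool against a pollen series
#'
#' Each user files an entry on a given day with probability
#' `config$adherence`. For responders the expected per-organ severity
#' follows a saturating dose-response in that day's concentration,
#' `sensitivity * 3 * c / (c + K)` with `K = half_saturation`, perturbed by
#' Gaussian noise and rounded/clamped to the 0-3 scale. Non-responders draw
#' low-mean severities independent of pollen. Each of an organ's four
#' symptom flags is Bernoulli with probability `severity / 3`; each
#' medication category is Bernoulli with a logistic-in-severity probability,
#' and entries reporting no symptoms at all take no medication.
#'
#' @param users Tibble from [generate_users()].
#' @param pollen Tibble from [generate_pollen_series()].
#' @inheritParams generate_pollen_series
#' @return A diary tibble, one row per (user, entry day), with severity,
#'   symptom-flag and medication-flag columns (see [read_diary_csv()] for
#'   the column dialect).
#' @examples
#' cfg <- generator_config(n_users = 5, seed = 11)
#' diary <- generate_diary(generate_users(cfg), generate_pollen_series(cfg, 2018), cfg)
#' @export
generate_diary <- function(users, pollen, config) {
  validate_generator_config(config)
  if (nrow(users) == 0) {
    return(empty_diary())
  }
  n_days <- nrow(pollen)
  conc <- pollen$concentration
  with_stream(config$seed, STREAM_DIARY, {
    entries <- purrr::map(seq_len(nrow(users)), function(i) {
      present <- runif(n_days) < config$adherence
      if (!any(present)) return(NULL)
      days <- which(present)
      m <- length(days)
      sens <- users$sensitivity[i]
      if (users$responder[i]) {
        mu <- sens * 3 * conc[days] / (conc[days] + config$half_saturation)
        sev <- vapply(SEVERITY_COLS, function(org) {
          clamp_severity(mu + rnorm(m, sd = config$severity_noise))
        }, integer(m))
      } else {
        # pollen-independent background: mostly symptom-free days
        sev <- vapply(SEVERITY_COLS, function(org) {
          sample(0:3, m, replace = TRUE, prob = c(0.70, 0.20, 0.07, 0.03))
        }, integer(m))
      }
      if (m == 1) sev <- matrix(sev, nrow = 1, dimnames = list(NULL, SEVERITY_COLS))
      flags <- flag_draws(sev)
      dplyr::bind_cols(
        tibble(user_id = users$user_id[i], date = pollen$date[days],
               region = config$region),
        as_tibble(sev), flags
      )
    })
    out <- dplyr::bind_rows(entries)
    if (nrow(out) == 0) empty_diary() else out
  })
}

clamp_severity <- function(x) {
  as.integer(pmin(3, pmax(0, round(x))))
}

# Bernoulli symptom flags at probability severity/3 per flag of the organ,
# and logistic-in-severity medication flags gated on any symptom at all.
flag_draws <- function(sev) {
  m <- nrow(sev)
  draw_organ <- function(severity, flag_names) {
    p <- severity / 3
    out <- lapply(flag_names, function(f) runif(m) < p)
    setNames(out, flag_names)
  }
  flags <- c(
    draw_organ(sev[, "severity_eyes"], EYE_FLAGS),
    draw_organ(sev[, "severity_nose"], NOSE_FLAGS),
    draw_organ(sev[, "severity_lungs"], LUNG_FLAGS)
  )
  sev_total <- rowSums(sev)
  p_med <- plogis(-3 + 0.8 * sev_total) * (sev_total > 0)
  meds <- setNames(lapply(MED_FLAGS, function(f) runif(m) < p_med), MED_FLAGS)
  as_tibble(c(flags, meds))
}

empty_diary <- function() {
  out <- tibble(
    user_id = character(), date = as.Date(character()), region = character()
  )
  for (col in SEVERITY_COLS) out[[col]] <- integer()
  for (col in c(EYE_FLAGS, NOSE_FLAGS, LUNG_FLAGS, MED_FLAGS)) out[[col]] <- logical()
  out
}

#' Validate a diary table
#'
#' Checks the diary column layout, the 0-3 severity range, flag types and
#' the one-entry-per-user-day rule.
#'
#' @param diary A diary tibble.
#' @return `diary`, invisibly, if valid; otherwise an error naming the
#'   offending rows.
#' @export
validate_diary <- function(diary) {
  missing_cols <- setdiff(DIARY_COLS, names(diary))
  if (length(missing_cols) > 0) {
    abort(paste0("Diary is missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "pollendiary_parse_error")
  }
  for (col in SEVERITY_COLS) {
    bad <- which(!(diary[[col]] %in% 0:3))
    if (length(bad) > 0) {
      abort(sprintf("Column `%s` out of range 0-3 at row(s) %s.",
                    col, paste(utils::head(bad, 5), collapse = ", ")),
            class = "pollendiary_parse_error")
    }
  }
  dup <- diary %>% dplyr::count(.data$user_id, .data$date) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Duplicate diary entries for (user, date): %s.",
                  paste(paste0(dup$user_id, "/", dup$date)[seq_len(min(3, nrow(dup)))],
                        collapse = "; ")),
          class = "pollendiary_parse_error")
  }
  invisible(diary)
}
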