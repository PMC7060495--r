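#' Run the full diary analysis pipeline
#'
#' Chains the stages end to end: (optionally) simulate a cohort, score the
#' diary, derive the pollen season, filter the user pool, build the four
#' daily score series (combined raw, its symptom load index, EMA raw, its
#' symptom load index), decompose organ/medication contributions, and
#' correlate the detrended series pairwise. All artifacts are written as
#' CSV into `out_dir` together with a JSON manifest echoing the
#' configuration and seed, so a run can be reproduced exactly.
#'
#' @param config A [generator_config()] describing the synthetic cohort
#'   (simulation mode), or `NULL` to read `pollen_csv` / `diary_csv` /
#'   `users_csv` instead. Exactly one input mode must be given.
#' @param year Calendar year to analyse.
#' @param out_dir Output directory, created if absent.
#' @param pollen_csv,diary_csv,users_csv Input paths (file mode).
#' @param alpha Significance level of the user filter.
#' @param min_entries Minimum in-season entries for the filter.
#' @param start_pct,end_pct Season bounds as percentiles of the Annual
#'   Pollen Integral.
#' @param sli_mode Symptom load index normalization mode, passed to
#'   [sli_series()].
#' @param weights A [scoring_weights()].
#' @return Invisibly, a list with every intermediate result (`pollen`,
#'   `users`, `diary`, `scores`, `window`, `filter`, `series`,
#'   `contributions`, `summaries`, `correlations`, `manifest`).
#' @examples
#' \donttest{
#' res <- run_pipeline(generator_config(n_users = 60, seed = 9),
#'                     year = 2018, out_dir = tempfile("run"))
#' res$correlations
#' }
#' @export
run_pipeline <- function(config = NULL, year = 2018, out_dir,
                         pollen_csv = NULL, diary_csv = NULL, users_csv = NULL,
                         alpha = 0.05, min_entries = 15,
                         start_pct = 1, end_pct = 95,
                         sli_mode = c("user_max", "theoretical_max"),
                         weights = scoring_weights()) {
  sli_mode <- match.arg(sli_mode)
  simulate <- !is.null(config)
  files_given <- !is.null(pollen_csv) || !is.null(diary_csv) || !is.null(users_csv)
  if (simulate == files_given) {
    abort("Give exactly one of `config` (simulate) or the three input CSV paths.",
          class = "pollendiary_config_error")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, code) {
    tryCatch(force(code), error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name, conditionMessage(e)),
            class = "pollendiary_pipeline_error", parent = e)
    })
  }

  if (simulate) {
    pollen <- stage("simulate", generate_pollen_series(config, year))
    users <- stage("simulate", generate_users(config))
    diary <- stage("simulate", generate_diary(users, pollen, config))
  } else {
    pollen <- stage("read", read_pollen_csv(pollen_csv))
    diary <- stage("read", read_diary_csv(diary_csv))
    users <- stage("read", read_users_csv(users_csv))
  }

  scores <- stage("score", score_entries(diary, weights))
  window <- stage("season", season_window(pollen, year, start_pct, end_pct))
  filt <- stage("filter",
                filter_users(scores, pollen, window, min_entries, alpha))
  pool <- filt$user_id[filt$passed]
  if (length(pool) == 0) {
    abort("Pipeline stage `filter` failed: no users passed the filter.",
          class = "pollendiary_pipeline_error")
  }

  series <- stage("aggregate", list(
    phd_raw = daily_mean_series(scores, pool, window, "phd_raw"),
    phd_sli = sli_series(scores, pool, window, "phd", sli_mode, weights),
    ema_raw = daily_mean_series(scores, pool, window, "ema_raw"),
    ema_sli = sli_series(scores, pool, window, "ema", sli_mode, weights)
  ))
  contributions <- stage("aggregate", bind_rows(
    organ_contributions(scores, pool, window, "phd"),
    organ_contributions(scores, pool, window, "ema")
  ))
  summaries <- stage("aggregate", tibble(
    method = names(series),
    region = window$region[1],
    taxon = window$taxon[1],
    year = window$year[1],
    sli_mode = sli_mode,
    seasonal_mean = purrr::map_dbl(series, seasonal_summary)
  ))
  correlations <- stage("compare", pairwise_method_correlations(series))

  # write artifacts
  write_pollen_csv(pollen, file.path(out_dir, "pollen.csv"))
  write_diary_csv(diary, file.path(out_dir, "diary.csv"))
  write_users_csv(users, file.path(out_dir, "users.csv"))
  write_scores_csv(scores, file.path(out_dir, "scores.csv"))
  readr::write_csv(window, file.path(out_dir, "season.csv"))
  readr::write_csv(tidy(filt), file.path(out_dir, "filter.csv"))
  readr::write_csv(bind_rows(series), file.path(out_dir, "series.csv"))
  readr::write_csv(
    dplyr::full_join(summaries,
                     tidyr::pivot_longer(contributions, -"base",
                                         names_to = "component",
                                         values_to = "pct") %>%
                       tidyr::drop_na("pct") %>%
                       mutate(method = paste0(.data$base, "_sli")) %>%
                       select(-"base"),
                     by = "method",
                     relationship = "many-to-many"),
    file.path(out_dir, "summary.csv"))
  readr::write_csv(tidy(correlations), file.path(out_dir, "correlations.csv"))

  manifest <- list(
    package_version = as.character(utils::packageVersion("pollendiary")),
    mode = if (simulate) "simulate" else "files",
    config = if (simulate) unclass(config) else
      list(pollen_csv = pollen_csv, diary_csv = diary_csv, users_csv = users_csv),
    year = year, alpha = alpha, min_entries = min_entries,
    start_pct = start_pct, end_pct = end_pct, sli_mode = sli_mode,
    row_counts = list(pollen = nrow(pollen), diary = nrow(diary),
                      users = nrow(users), scores = nrow(scores),
                      pool = length(pool))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(pollen = pollen, users = users, diary = diary,
                 scores = scores, window = window, filter = filt,
                 pool = pool, series = series, contributions = contributions,
                 summaries = summaries, correlations = correlations,
                 manifest = manifest))
}
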