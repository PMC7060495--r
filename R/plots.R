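#' Plot the four daily score series against the pollen curve
#'
#' Overlays the daily pooled score series of each calculation method over
#' the season; optionally adds the (rescaled) pollen concentration as a
#' shaded background, which makes the shared seasonal trend the detrended
#' comparison removes visible.
#'
#' @param series_list Named list of daily series tibbles (as produced by
#'   [run_pipeline()]'s `series` element).
#' @param pollen Optional pollen tibble for the background curve.
#' @return A ggplot object.
#' @export
plot_score_series <- function(series_list, pollen = NULL) {
  df <- bind_rows(series_list) %>% filter(!is.na(.data$value))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value,
                                        colour = .data$method))
  if (!is.null(pollen)) {
    bg <- pollen %>%
      filter(.data$date >= min(df$date), .data$date <= max(df$date)) %>%
      mutate(scaled = .data$concentration / max(.data$concentration) *
               max(df$value))
    p <- p + ggplot2::geom_area(data = bg,
                                ggplot2::aes(x = .data$date, y = .data$scaled),
                                inherit.aes = FALSE, fill = "grey85")
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "daily pooled score",
                  colour = "method",
                  title = "Score calculation methods over the pollen season")
}

#' Plot a pollen year with its season window
#'
#' @param pollen Pollen tibble (one year).
#' @param window Optional one-row season tibble from [season_window()];
#'   drawn as a shaded band.
#' @return A ggplot object.
#' @export
plot_pollen_season <- function(pollen, window = NULL) {
  p <- ggplot2::ggplot(pollen, ggplot2::aes(x = .data$date,
                                            y = .data$concentration))
  if (!is.null(window)) {
    p <- p + ggplot2::annotate("rect",
                               xmin = window$start_date[1],
                               xmax = window$end_date[1],
                               ymin = -Inf, ymax = Inf,
                               fill = "goldenrod", alpha = 0.2)
  }
  p + ggplot2::geom_line() +
    ggplot2::labs(x = NULL, y = "grains/m³",
                  title = "Daily pollen concentration",
                  subtitle = if (!is.null(window)) {
                    sprintf("season %s to %s (%g%%-%g%% of APIn)",
                            window$start_date[1], window$end_date[1],
                            window$start_pct[1], window$end_pct[1])
                  } else NULL)
}

#' Plot per-user filter results
#'
#' Correlation against in-season entry count, coloured by pass/fail, with
#' the entry-minimum rule drawn as a vertical line.
#'
#' @param x A `pd_filter` object from [filter_users()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pd_filter <- function(x, ...) {
  df <- tidy(x) %>% filter(!is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_entries, y = .data$r,
                                   colour = .data$passed)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = attr(x, "min_entries"), linetype = 2) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::labs(x = "in-season entries", y = "score-pollen Pearson r",
                  colour = "passed",
                  title = "User filter: correlation vs entry count")
}
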