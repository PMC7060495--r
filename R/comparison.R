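#' First-difference a daily score series
#'
#' Replaces a daily series by its day-to-day changes to remove the shared
#' seasonal trend before correlating score calculation methods. Only
#' differences between consecutive calendar days with both values present
#' are kept; pairs spanning a gap (a missing day or a missing value) are
#' dropped and counted.
#'
#' @param series A daily series tibble (`date`, `value`).
#' @return A tibble with columns `date` (the later day of each pair) and
#'   `diff`, with attribute `n_dropped` counting unusable day pairs.
#' @export
first_difference <- function(series) {
  if (nrow(series) < 2) {
    abort("Need at least 2 days to difference.",
          class = "pollendiary_compare_error")
  }
  s <- series %>% arrange(.data$date)
  consecutive <- as.integer(diff(s$date)) == 1L
  both_present <- !is.na(s$value[-1]) & !is.na(s$value[-nrow(s)])
  usable <- consecutive & both_present
  if (!any(usable)) {
    abort("Fewer than 2 usable consecutive days.",
          class = "pollendiary_compare_error")
  }
  out <- tibble(
    date = s$date[-1][usable],
    diff = (s$value[-1] - s$value[-nrow(s)])[usable]
  )
  attr(out, "n_dropped") <- sum(!usable)
  out
}

#' Pairwise Pearson correlations of the four score calculation methods
#'
#' Correlates the four daily score series (combined raw, its symptom load
#' index, EMA raw, its symptom load index) pairwise after first
#' differencing each, pairing the differenced days shared by each pair
#' separately. High coefficients indicate the calculation methods move
#' together day to day even with the common seasonal trend removed.
#'
#' @param series_list Named list of four daily series tibbles; names are
#'   the method labels (conventionally `ema_raw`, `ema_sli`, `phd_raw`,
#'   `phd_sli`).
#' @param difference If `FALSE`, correlate the undifferenced daily values
#'   (as a pre-analysis; trend-driven coefficients are typically higher).
#' @return An object of class `"pd_method_cor"`: the correlation matrix
#'   with the per-pair day counts attached. `tidy()` returns one row per
#'   method pair; `autoplot()` draws a heat map.
#' @export
pairwise_method_correlations <- function(series_list, difference = TRUE) {
  stopifnot(is.list(series_list), length(series_list) >= 2,
            !is.null(names(series_list)))
  prepared <- purrr::map(series_list, function(s) {
    if (difference) {
      d <- first_difference(s)
      tibble(date = d$date, value = d$diff)
    } else {
      s %>% filter(!is.na(.data$value)) %>% select("date", "value")
    }
  })
  methods <- names(prepared)
  k <- length(methods)
  r_mat <- diag(1, k, k, names = FALSE)
  n_mat <- matrix(NA_integer_, k, k)
  dimnames(r_mat) <- dimnames(n_mat) <- list(methods, methods)
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      joined <- inner_join(prepared[[i]], prepared[[j]], by = "date",
                           suffix = c("_i", "_j"))
      if (nrow(joined) < 3) {
        abort(sprintf("Fewer than 3 common differenced days for pair %s x %s.",
                      methods[i], methods[j]),
              class = "pollendiary_compare_error")
      }
      r_mat[i, j] <- r_mat[j, i] <- cor(joined$value_i, joined$value_j)
      n_mat[i, j] <- n_mat[j, i] <- nrow(joined)
    }
  }
  diag(n_mat) <- purrr::map_int(prepared, nrow)
  structure(list(r = r_mat, n_pairs = n_mat, differenced = difference),
            class = "pd_method_cor")
}

#' @export
print.pd_method_cor <- function(x, digits = 3, ...) {
  cat(if (x$differenced) "First-differenced" else "Undifferenced",
      "pairwise Pearson correlations of score methods:\n")
  print(round(x$r, digits))
  invisible(x)
}

#' @export
tidy.pd_method_cor <- function(x, ...) {
  methods <- rownames(x$r)
  pairs <- utils::combn(seq_along(methods), 2)
  tibble(
    method_a = methods[pairs[1, ]],
    method_b = methods[pairs[2, ]],
    r = x$r[t(pairs)],
    n_pairs = x$n_pairs[t(pairs)],
    differenced = x$differenced
  )
}

#' @export
glance.pd_method_cor <- function(x, ...) {
  td <- tidy(x)
  tibble(
    n_methods = nrow(x$r),
    mean_r = mean(td$r),
    min_r = min(td$r),
    differenced = x$differenced
  )
}

#' @export
autoplot.pd_method_cor <- function(object, ...) {
  td <- tidy(object)
  td_full <- bind_rows(
    td,
    td %>% dplyr::rename(method_a = "method_b", method_b = "method_a"),
    tibble(method_a = rownames(object$r), method_b = rownames(object$r),
           r = 1, n_pairs = NA_integer_, differenced = object$differenced)
  )
  ggplot2::ggplot(td_full,
                  ggplot2::aes(x = .data$method_a, y = .data$method_b,
                               fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r))) +
    ggplot2::scale_fill_gradient(limits = c(-1, 1), low = "white",
                                 high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "r",
                  title = if (object$differenced) {
                    "Detrended method agreement"
                  } else {
                    "Raw method agreement"
                  })
}
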