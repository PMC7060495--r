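#' Read and write the pipeline's CSV tables
#'
#' All tables travel as UTF-8 CSV with a mandatory header row and ISO-8601
#' dates. Flag columns are written as 0/1 and read back as logical.
#' Malformed rows (missing columns, unparseable dates, severities outside
#' 0-3) raise errors naming the offending row and column.
#'
#' @param path File path.
#' @return The table as a tibble (readers) or `path` invisibly (writers).
#' @name diary_io
NULL

#' @rdname diary_io
#' @export
read_pollen_csv <- function(path) {
  out <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           region = readr::col_character(),
                           taxon = readr::col_character(),
                           date = readr::col_date(),
                           concentration = readr::col_double()
                         )))
  check_parse_problems(out, path)
  bad <- which(is.na(out$date))
  if (length(bad) > 0) {
    abort(sprintf("Unparseable date in %s at row(s) %s.", path,
                  paste(utils::head(bad, 5), collapse = ", ")),
          class = "pollendiary_parse_error")
  }
  if (any(out$concentration < 0, na.rm = TRUE)) {
    bad <- which(out$concentration < 0)
    abort(sprintf("Negative concentration at row(s) %s of %s.",
                  paste(utils::head(bad, 5), collapse = ", "), path),
          class = "pollendiary_parse_error")
  }
  out
}

#' @rdname diary_io
#' @param pollen Pollen tibble.
#' @export
write_pollen_csv <- function(pollen, path) {
  readr::write_csv(pollen, path)
  invisible(path)
}

#' @rdname diary_io
#' @export
read_diary_csv <- function(path) {
  flag_cols <- c(EYE_FLAGS, NOSE_FLAGS, LUNG_FLAGS, MED_FLAGS)
  spec <- c(
    list(user_id = readr::col_character(), date = readr::col_date(),
         region = readr::col_character()),
    setNames(rep(list(readr::col_integer()), 3), SEVERITY_COLS),
    setNames(rep(list(readr::col_integer()), length(flag_cols)), flag_cols)
  )
  out <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                         col_types = do.call(readr::cols, spec)))
  check_parse_problems(out, path)
  for (col in flag_cols) out[[col]] <- out[[col]] != 0L
  validate_diary(out)
  out
}

#' @rdname diary_io
#' @param diary Diary tibble.
#' @export
write_diary_csv <- function(diary, path) {
  out <- diary
  for (col in c(EYE_FLAGS, NOSE_FLAGS, LUNG_FLAGS, MED_FLAGS)) {
    out[[col]] <- as.integer(out[[col]])
  }
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname diary_io
#' @export
read_users_csv <- function(path) {
  out <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           user_id = readr::col_character(),
                           gender = readr::col_character(),
                           age_group = readr::col_character(),
                           .default = readr::col_guess()
                         )))
  check_parse_problems(out, path)
  out
}

#' @rdname diary_io
#' @param users User tibble.
#' @export
write_users_csv <- function(users, path) {
  readr::write_csv(users, path)
  invisible(path)
}

#' @rdname diary_io
#' @param scores Score tibble.
#' @export
write_scores_csv <- function(scores, path) {
  readr::write_csv(scores, path)
  invisible(path)
}

#' @rdname diary_io
#' @export
read_scores_csv <- function(path) {
  out <- suppressWarnings(readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           user_id = readr::col_character(),
                           date = readr::col_date(),
                           .default = readr::col_double()
                         )))
  check_parse_problems(out, path)
  out
}

check_parse_problems <- function(tbl, path) {
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(sprintf("Malformed %s: row %d, column %d (%s).", path,
                  probs$row[1], probs$col[1], probs$expected[1]),
          class = "pollendiary_parse_error")
  }
  invisible(tbl)
}
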