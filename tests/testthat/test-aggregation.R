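tiny_window <- function(start = "2018-04-01", end = "2018-04-30") {
  tibble::tibble(region = "AT-wien", taxon = "birch", year = 2018,
                 start_date = as.Date(start), end_date = as.Date(end),
                 apin = 1000, start_pct = 1, end_pct = 95)
}

scores_from <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(user_id = r$u, date = as.Date(r$d), phd_raw = r$phd,
                   ema_raw = r$ema %||% r$phd,
                   sub_eyes = r$phd / 4, sub_nose = r$phd / 4,
                   sub_lungs = r$phd / 4, sub_med = r$phd / 4,
                   ema_eyes = (r$ema %||% r$phd) / 2,
                   ema_nose = (r$ema %||% r$phd) / 2)
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("daily means pool users per day and mark empty days missing", {
  sc <- scores_from(list(u = "a", d = "2018-04-02", phd = 4),
                    list(u = "b", d = "2018-04-02", phd = 6),
                    list(u = "a", d = "2018-04-05", phd = 2))
  ser <- daily_mean_series(sc, c("a", "b"), tiny_window())
  expect_equal(ser$value[ser$date == as.Date("2018-04-02")], 5)
  expect_equal(ser$n_users[ser$date == as.Date("2018-04-02")], 2L)
  expect_true(is.na(ser$value[ser$date == as.Date("2018-04-03")]))
  expect_equal(ser$n_users[ser$date == as.Date("2018-04-03")], 0L)
  expect_equal(nrow(ser), 30)
  expect_error(daily_mean_series(sc, character(), tiny_window()),
               class = "pollendiary_aggregate_error")
})

test_that("daily means match a brute-force double loop on random data", {
  set.seed(50)
  users <- sprintf("u%02d", 1:50)
  days <- as.Date("2018-04-01") + 0:29
  grid <- expand.grid(user_id = users, date = days, stringsAsFactors = FALSE)
  grid <- grid[runif(nrow(grid)) < 0.6, ]
  sc <- tibble::tibble(user_id = grid$user_id, date = grid$date,
                       phd_raw = runif(nrow(grid), 0, 25.65))
  sc$ema_raw <- sc$phd_raw
  ser <- daily_mean_series(sc, users, tiny_window())
  for (d in sample(seq_along(days), 8)) {
    vals <- c()
    for (i in seq_len(nrow(sc))) {
      if (sc$date[i] == days[d]) vals <- c(vals, sc$phd_raw[i])
    }
    if (length(vals) == 0) {
      expect_true(is.na(ser$value[ser$date == days[d]]))
    } else {
      expect_equal(ser$value[ser$date == days[d]], mean(vals))
    }
  }
})

test_that("the symptom load index stays in 0-10 and hits its bounds", {
  # every user at the theoretical maximum each day -> SLI 10 in either mode
  days <- as.Date("2018-04-01") + 0:9
  diary <- dplyr::bind_rows(lapply(1:3, function(i) {
    dplyr::bind_rows(lapply(days, function(d) {
      max_diary_entry(user_id = sprintf("u%d", i), date = d)
    }))
  }))
  sc <- score_entries(diary)
  win <- tiny_window(end = "2018-04-10")
  for (mode in c("user_max", "theoretical_max")) {
    for (base in c("phd", "ema")) {
      ser <- sli_series(sc, unique(sc$user_id), win, base, mode)
      expect_equal(ser$value[ser$date %in% days], rep(10, 10))
      expect_true(all(ser$value[!is.na(ser$value)] >= 0 &
                        ser$value[!is.na(ser$value)] <= 10))
    }
  }
  # all-zero scores -> 0 (user_max logs zero-max users)
  zc <- sc
  zc[, c("phd_raw", "ema_raw", "sub_eyes", "sub_nose", "sub_lungs",
         "sub_med", "ema_eyes", "ema_nose")] <- 0
  expect_message(zser <- sli_series(zc, unique(zc$user_id), win, "phd",
                                    "user_max"), "all-zero")
  expect_true(all(zser$value[!is.na(zser$value)] == 0))
})

test_that("user_max normalization puts each lone user's best day at 10", {
  set.seed(51)
  days <- as.Date("2018-04-01") + 0:19
  sc <- tibble::tibble(user_id = "solo", date = days,
                       phd_raw = runif(20, 1, 20))
  sc$ema_raw <- sc$phd_raw
  win <- tiny_window(end = "2018-04-20")
  ser <- sli_series(sc, "solo", win, "phd", "user_max")
  expect_equal(max(ser$value, na.rm = TRUE), 10)
  expect_equal(ser$date[which.max(ser$value)], sc$date[which.max(sc$phd_raw)])
  # per-user normalization oracle: value = 10 * raw / max(raw)
  expect_equal(ser$value[!is.na(ser$value)], 10 * sc$phd_raw / max(sc$phd_raw))
})

test_that("SLI in 0-10 for random pools in both modes", {
  fxcfg <- generator_config(n_users = 40, seed = 14)
  pollen <- generate_pollen_series(fxcfg, 2018)
  diary <- generate_diary(generate_users(fxcfg), pollen, fxcfg)
  sc <- score_entries(diary)
  win <- season_window(pollen, 2018)
  pool <- unique(sc$user_id)
  for (mode in c("user_max", "theoretical_max")) {
    ser <- suppressMessages(sli_series(sc, pool, win, "phd", mode))
    v <- ser$value[!is.na(ser$value)]
    expect_true(all(v >= 0 & v <= 10))
  }
})

test_that("organ contributions are component shares summing to 100", {
  # nose-only pool
  entry <- max_diary_entry()
  entry$severity_eyes <- 0L; entry$severity_lungs <- 0L
  for (col in c(EYE_F, LUNG_F, MED_F)) entry[[col]] <- FALSE
  sc <- score_entries(entry)
  win <- tiny_window(start = "2018-04-20", end = "2018-04-21")
  ctr <- organ_contributions(sc, entry$user_id, win, "phd")
  expect_equal(ctr$pct_nose, 100)
  expect_equal(ctr$pct_eyes + ctr$pct_lungs + ctr$pct_med, 0)

  # mixed random pool: matches independent subscore accumulation, sums to 100
  diary <- random_diary(300, seed = 15, start = as.Date("2018-04-02"))
  msc <- score_entries(diary)
  wide <- tiny_window()
  pool <- unique(msc$user_id)
  phd <- organ_contributions(msc, pool, wide, "phd")
  expect_equal(phd$pct_eyes + phd$pct_nose + phd$pct_lungs + phd$pct_med, 100,
               tolerance = 1e-9)
  in_win <- diary$date >= wide$start_date & diary$date <= wide$end_date
  expect_equal(phd$pct_med,
               100 * sum(oracle_scores(diary[in_win, ])[, "sub_med"]) /
                 sum(msc$phd_raw[in_win]),
               tolerance = 1e-9)
  ema <- organ_contributions(msc, pool, wide, "ema")
  expect_equal(ema$pct_eyes + ema$pct_nose, 100, tolerance = 1e-9)

  zc <- msc
  zc[, c("phd_raw", "sub_eyes", "sub_nose", "sub_lungs", "sub_med")] <- 0
  expect_error(organ_contributions(zc, pool, wide, "phd"),
               class = "pollendiary_aggregate_error")
})

test_that("medication-weight rescaling propagates consistently", {
  diary <- random_diary(200, seed = 16, start = as.Date("2018-04-02"))
  w2 <- scoring_weights(eye_pair = 2, eye_other = 1, eye_homeopathic = 0.6,
                        nose_pair = 2, nose_eye_drops = 0.5, nose_other = 1,
                        nose_homeopathic = 0.6, lung_tablets = 0.5,
                        lung_other = 0.5, lung_homeopathic = 0.6)
  s1 <- score_entries(diary)
  s2 <- score_entries(diary, w2)
  expect_equal(s2$sub_med, 2 * s1$sub_med, tolerance = 1e-9)
  win <- tiny_window()
  c2 <- organ_contributions(s2, unique(s2$user_id), win, "phd")
  expect_equal(c2$pct_eyes + c2$pct_nose + c2$pct_lungs + c2$pct_med, 100,
               tolerance = 1e-9)
})

test_that("seasonal summary is the mask-aware mean of daily values", {
  ser <- tibble::tibble(method = "phd_raw",
                        date = as.Date("2018-04-01") + 0:4,
                        value = c(2, 4, NA, 4, 4), n_users = c(1, 1, 0, 1, 1))
  expect_equal(seasonal_summary(ser), oracle_mean_skip_na(ser$value))
  expect_equal(seasonal_summary(ser[1:2, ]), 3)
  const <- ser; const$value <- 4
  expect_equal(seasonal_summary(const), 4)
  empty <- ser; empty$value <- NA_real_
  expect_error(seasonal_summary(empty), class = "pollendiary_aggregate_error")
})

test_that("demographic summary tallies proportions per dimension", {
  users <- tibble::tibble(
    user_id = sprintf("u%d", 1:8),
    gender = c(rep("male", 8)),
    age_group = rep(c("under21", "21to40", "over40", "unknown"), 2)
  )
  dem <- summarize_demographics(users)
  expect_equal(dem$proportion[dem$dimension == "gender"], 1)
  expect_equal(sort(dem$proportion[dem$dimension == "age_group"]),
               rep(0.25, 4))
  # random mixture matches a counting oracle
  set.seed(52)
  rnd <- tibble::tibble(
    user_id = sprintf("u%d", 1:500),
    gender = sample(c("male", "female", "unknown"), 500, replace = TRUE),
    age_group = sample(c("under21", "21to40", "over40", "unknown"), 500,
                       replace = TRUE)
  )
  dem2 <- summarize_demographics(rnd)
  for (g in unique(rnd$gender)) {
    n <- 0
    for (x in rnd$gender) if (x == g) n <- n + 1
    expect_equal(dem2$n[dem2$dimension == "gender" & dem2$category == g], n)
  }
  expect_equal(sum(dem2$proportion[dem2$dimension == "gender"]), 1)
  expect_equal(sum(dem2$proportion[dem2$dimension == "age_group"]), 1)
  expect_error(summarize_demographics(users[0, ]),
               class = "pollendiary_aggregate_error")
})
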