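test_that("generators are deterministic given the seed", {
  cfg <- generator_config(n_users = 30, seed = 17)
  expect_identical(generate_pollen_series(cfg, 2018),
                   generate_pollen_series(cfg, 2018))
  expect_identical(generate_users(cfg), generate_users(cfg))
  users <- generate_users(cfg)
  pollen <- generate_pollen_series(cfg, 2018)
  expect_identical(generate_diary(users, pollen, cfg),
                   generate_diary(users, pollen, cfg))
})

test_that("pollen series integrates to the target APIn and is a full year", {
  cfg <- generator_config(noise_scale = 0, target_apin = 10000, seed = 2)
  pollen <- generate_pollen_series(cfg, 2018)
  expect_equal(nrow(pollen), 365)
  expect_equal(sum(pollen$concentration), 10000, tolerance = 1e-3)
  expect_true(all(pollen$concentration >= 0))
  expect_true(all(diff(pollen$date) == 1))
  # noisy series also rescaled exactly
  noisy <- generate_pollen_series(generator_config(seed = 2), 2018)
  expect_equal(sum(noisy$concentration), 10000, tolerance = 1e-3)
})

test_that("the 1%-95% window captures about 94% of the APIn mass", {
  cfg <- generator_config(seed = 5)
  pollen <- generate_pollen_series(cfg, 2018)
  orc <- oracle_season(pollen$date, pollen$concentration, 1, 95)
  inside <- sum(pollen$concentration[pollen$date >= orc$start &
                                       pollen$date <= orc$end])
  frac <- inside / orc$apin
  expect_gte(frac, 0.94)
  expect_lt(frac, 0.97)
})

test_that("user pool follows the configured mixtures", {
  cfg <- generator_config(n_users = 10000, responder_fraction = 1, seed = 8)
  users <- generate_users(cfg)
  expect_true(all(users$responder))
  expect_true(all(users$sensitivity >= 0.5 & users$sensitivity <= 1))
  # binomial check: observed male fraction within 3 s.e. of 0.55
  se <- sqrt(0.55 * 0.45 / 10000)
  expect_lt(abs(mean(users$gender == "male") - 0.55), 3 * se)
  zero <- generate_users(generator_config(n_users = 100,
                                          responder_fraction = 0, seed = 8))
  expect_true(all(!zero$responder))
  expect_true(all(zero$sensitivity == 0))
})

test_that("diary respects adherence, invariants and the null dose-response", {
  cfg <- generator_config(n_users = 10, adherence = 1, seed = 4)
  users <- generate_users(cfg)
  pollen <- generate_pollen_series(cfg, 2018)
  diary <- generate_diary(users, pollen, cfg)
  # full adherence: one entry per user per day
  expect_equal(nrow(diary), 10 * 365)
  expect_silent(validate_diary(diary))
  expect_true(all(unlist(diary[c("severity_eyes", "severity_nose",
                                 "severity_lungs")]) %in% 0:3))

  # sensitivity 0 everywhere + zero severity noise -> all-zero diary
  cfg0 <- generator_config(n_users = 10, responder_fraction = 1,
                           sensitivity_range = c(0, 0), severity_noise = 0,
                           adherence = 1, seed = 4)
  users0 <- generate_users(cfg0)
  diary0 <- generate_diary(users0, pollen, cfg0)
  expect_true(all(diary0$severity_eyes == 0 & diary0$severity_nose == 0 &
                    diary0$severity_lungs == 0))
  expect_true(all(!unlist(diary0[ALL_FLAGS])))

  expect_equal(nrow(generate_diary(users[0, ], pollen, cfg)), 0)
})

test_that("responder severities climb with pollen, non-responder ones do not", {
  cfg <- generator_config(n_users = 60, responder_fraction = 1,
                          adherence = 1, seed = 12)
  users <- generate_users(cfg)
  pollen <- generate_pollen_series(cfg, 2018)
  diary <- generate_diary(users, pollen, cfg)
  ord <- order(pollen$concentration)
  low_days <- pollen$date[utils::head(ord, 10)]
  high_days <- pollen$date[utils::tail(ord, 10)]
  sev <- diary$severity_eyes + diary$severity_nose + diary$severity_lungs
  expect_gt(mean(sev[diary$date %in% high_days]),
            mean(sev[diary$date %in% low_days]))

  # responders correlate with pollen more often than non-responders
  cfg2 <- generator_config(n_users = 200, responder_fraction = 0.5, seed = 13)
  users2 <- generate_users(cfg2)
  diary2 <- generate_diary(users2, pollen, cfg2)
  sc <- score_entries(diary2)
  per_user_r <- sc |>
    dplyr::left_join(pollen[, c("date", "concentration")], by = "date") |>
    dplyr::group_by(user_id) |>
    dplyr::summarise(r = suppressWarnings(cor(phd_raw, concentration)),
                     .groups = "drop") |>
    dplyr::left_join(users2[, c("user_id", "responder")], by = "user_id")
  pos <- tapply(per_user_r$r > 0.3, per_user_r$responder, mean, na.rm = TRUE)
  expect_gt(pos[["TRUE"]], pos[["FALSE"]] + 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(generator_config(adherence = 1.5),
               class = "pollendiary_config_error")
  expect_error(generator_config(target_apin = -1),
               class = "pollendiary_config_error")
  expect_error(generator_config(gender_mix = c(male = 0.9, female = 0.9,
                                               unknown = 0.1)),
               class = "pollendiary_config_error")
  expect_error(generator_config(sensitivity_range = c(0.8, 0.2)),
               class = "pollendiary_config_error")
})
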