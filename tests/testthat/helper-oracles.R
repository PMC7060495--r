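# Independent brute-force oracles. These re-derive expected values by direct
# enumeration / explicit loops, deliberately sharing no code with the package.

EYE_F  <- c("eye_itching", "eye_foreign_body", "eye_redness", "eye_watering")
NOSE_F <- c("nose_itching", "nose_sneezing", "nose_running", "nose_blocked")
LUNG_F <- c("lung_wheezing", "lung_shortness_of_breath", "lung_cough", "lung_asthma")
MED_F  <- c("med_eye_drops", "med_nose_drops", "med_tablets", "med_other",
            "med_homeopathic")
ALL_FLAGS <- c(EYE_F, NOSE_F, LUNG_F, MED_F)

random_diary <- function(n, seed = 99, start = as.Date("2018-04-01")) {
  set.seed(seed)
  out <- tibble::tibble(
    user_id = sprintf("u%03d", seq_len(n)),
    date = start + seq_len(n) %% 60,
    region = "AT-wien",
    severity_eyes = sample(0:3, n, replace = TRUE),
    severity_nose = sample(0:3, n, replace = TRUE),
    severity_lungs = sample(0:3, n, replace = TRUE)
  )
  for (col in ALL_FLAGS) out[[col]] <- sample(c(TRUE, FALSE), n, replace = TRUE)
  out
}

# Hand-summation over the printed weight table, one entry at a time.
oracle_score_row <- function(row) {
  flags <- function(cols) sum(vapply(cols, function(f) isTRUE(row[[f]]), logical(1)))
  med_eyes <- (if (isTRUE(row$med_eye_drops) || isTRUE(row$med_tablets)) 1 else 0) +
    0.5 * isTRUE(row$med_other) + 0.3 * isTRUE(row$med_homeopathic)
  med_nose <- (if (isTRUE(row$med_nose_drops) || isTRUE(row$med_tablets)) 1 else 0) +
    0.25 * isTRUE(row$med_eye_drops) +
    0.5 * isTRUE(row$med_other) + 0.3 * isTRUE(row$med_homeopathic)
  med_lungs <- 0.25 * isTRUE(row$med_tablets) + 0.25 * isTRUE(row$med_other) +
    0.3 * isTRUE(row$med_homeopathic)
  sub_eyes <- row$severity_eyes + flags(EYE_F)
  sub_nose <- row$severity_nose + flags(NOSE_F)
  sub_lungs <- row$severity_lungs + flags(LUNG_F)
  ema_eyes <- row$severity_eyes + isTRUE(row$eye_watering) +
    (isTRUE(row$eye_itching) || isTRUE(row$eye_foreign_body) ||
       isTRUE(row$eye_redness))
  ema_nose <- row$severity_nose + flags(NOSE_F)
  list(
    phd_raw = sub_eyes + sub_nose + sub_lungs + med_eyes + med_nose + med_lungs,
    ema_raw = ema_eyes + ema_nose,
    sub_med = med_eyes + med_nose + med_lungs,
    med_eyes = med_eyes, med_nose = med_nose, med_lungs = med_lungs
  )
}

oracle_scores <- function(diary) {
  t(vapply(seq_len(nrow(diary)), function(i) {
    s <- oracle_score_row(as.list(diary[i, ]))
    c(phd_raw = s$phd_raw, ema_raw = s$ema_raw, sub_med = s$sub_med)
  }, c(phd_raw = 0, ema_raw = 0, sub_med = 0)))
}

# Cumulative-sum season oracle: explicit day loop.
oracle_season <- function(dates, conc, start_pct, end_pct) {
  apin <- 0
  for (c in conc) apin <- apin + c
  cum <- 0
  start <- end <- NA
  for (i in seq_along(conc)) {
    cum <- cum + conc[i]
    if (is.na(start) && cum >= start_pct / 100 * apin) start <- dates[i]
    if (is.na(end) && cum >= end_pct / 100 * apin) end <- dates[i]
  }
  list(start = start, end = end, apin = apin)
}

# Permutation p-value for the Pearson correlation.
oracle_perm_p <- function(x, y, n_perm = 20000, seed = 4) {
  set.seed(seed)
  r_obs <- cor(x, y)
  r_null <- replicate(n_perm, cor(x, sample(y)))
  mean(abs(r_null) >= abs(r_obs))
}

# Mask-aware mean by explicit loop.
oracle_mean_skip_na <- function(v) {
  s <- 0; k <- 0
  for (x in v) if (!is.na(x)) { s <- s + x; k <- k + 1 }
  if (k == 0) NA_real_ else s / k
}
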