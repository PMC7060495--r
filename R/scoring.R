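#' Scoring weights for the combined symptom and medication score
#'
#' The weighted medication table assigns more points to medications that act
#' on more organs. Per organ the contributions are: eyes — 1 point for eye
#' drops *or* tablets (the pair is capped at its single shared point even if
#' both are taken), 0.5 for other medication, 0.3 for homeopathic (organ
#' maximum 1.8); nose — 1 point for nose drops *or* tablets, 0.25 for eye
#' drops, 0.5 for other, 0.3 for homeopathic (maximum 2.05); lungs — 0.25
#' each for tablets and other, 0.3 for homeopathic (maximum 0.8). All
#' medication together amounts to 4.65 points, and with the 21 symptom
#' points this caps the combined score at 25.65.
#'
#' @param symptom_point Points per selected symptom flag.
#' @param severity_max Maximum per-organ severity grade.
#' @param eye_pair,nose_pair Shared point for the drops-or-tablets pair of
#'   the organ.
#' @param eye_other,eye_homeopathic,nose_eye_drops,nose_other,nose_homeopathic,lung_tablets,lung_other,lung_homeopathic
#'   Individual medication weights, as printed in the table above.
#' @return A list of class `"scoring_weights"` with the per-organ medication
#'   maxima attached.
#' @examples
#' w <- scoring_weights()
#' w$med_max  # eyes 1.8, nose 2.05, lungs 0.8
#' @export
scoring_weights <- function(symptom_point = 1,
                            severity_max = 3,
                            eye_pair = 1, eye_other = 0.5, eye_homeopathic = 0.3,
                            nose_pair = 1, nose_eye_drops = 0.25,
                            nose_other = 0.5, nose_homeopathic = 0.3,
                            lung_tablets = 0.25, lung_other = 0.25,
                            lung_homeopathic = 0.3) {
  w <- list(
    symptom_point = symptom_point,
    severity_max = severity_max,
    eye_pair = eye_pair, eye_other = eye_other, eye_homeopathic = eye_homeopathic,
    nose_pair = nose_pair, nose_eye_drops = nose_eye_drops,
    nose_other = nose_other, nose_homeopathic = nose_homeopathic,
    lung_tablets = lung_tablets, lung_other = lung_other,
    lung_homeopathic = lung_homeopathic
  )
  w$med_max <- c(
    eyes = eye_pair + eye_other + eye_homeopathic,
    nose = nose_pair + nose_eye_drops + nose_other + nose_homeopathic,
    lungs = lung_tablets + lung_other + lung_homeopathic
  )
  class(w) <- "scoring_weights"
  w
}

#' Medication score of diary entries
#'
#' Sums the organ-specific medication weights for the categories flagged in
#' each entry. For eyes and nose the drops/tablets pair contributes at most
#' its single shared point even when both are taken.
#'
#' @param diary A diary tibble (one or more entries).
#' @param weights A [scoring_weights()].
#' @param by_organ If `TRUE`, return a tibble with per-organ columns
#'   `med_eyes`, `med_nose`, `med_lungs` and the `total`; otherwise the
#'   total as a numeric vector.
#' @return Numeric vector of medication points (or a tibble if
#'   `by_organ = TRUE`); at most 4.65 per entry under the default weights.
#' @examples
#' entry <- max_diary_entry()
#' medication_score(entry)  # 4.65
#' @export
medication_score <- function(diary, weights = scoring_weights(), by_organ = FALSE) {
  eye_drops <- diary$med_eye_drops
  nose_drops <- diary$med_nose_drops
  tablets <- diary$med_tablets
  other <- diary$med_other
  homeo <- diary$med_homeopathic
  med_eyes <- weights$eye_pair * as.numeric(eye_drops | tablets) +
    weights$eye_other * other + weights$eye_homeopathic * homeo
  med_nose <- weights$nose_pair * as.numeric(nose_drops | tablets) +
    weights$nose_eye_drops * eye_drops +
    weights$nose_other * other + weights$nose_homeopathic * homeo
  med_lungs <- weights$lung_tablets * tablets + weights$lung_other * other +
    weights$lung_homeopathic * homeo
  if (by_organ) {
    tibble(med_eyes = med_eyes, med_nose = med_nose, med_lungs = med_lungs,
           total = med_eyes + med_nose + med_lungs)
  } else {
    med_eyes + med_nose + med_lungs
  }
}

#' Score diary entries under both raw calculation methods
#'
#' Computes, per entry, the combined symptom and medication score (PHD raw)
#' and the eyes-and-nose EMA raw score, together with their subscores.
#'
#' The PHD raw score adds, per organ, the 0-3 severity grade and one point
#' per selected specific symptom (four per organ, so up to 7 points per
#' organ and 21 symptom points in total), plus the weighted medication score
#' (up to 4.65), for a maximum of 25.65. The EMA raw score covers eyes and
#' nose only: the nose keeps its four symptoms (severity + 4 flags, max 7),
#' while the four eye symptoms collapse to the directive's two — tearing
#' (the watering flag) and itching/grittiness/redness (the OR of the other
#' three) — giving severity + 2 flags, max 5, and an overall maximum of 12.
#'
#' @param diary A diary tibble; validated before scoring, so duplicate
#'   (user, date) pairs or out-of-range severities raise an error.
#' @param weights A [scoring_weights()].
#' @return A tibble with one row per entry, in input order: `user_id`,
#'   `date`, `phd_raw`, `ema_raw`, subscores `sub_eyes`, `sub_nose`,
#'   `sub_lungs`, `sub_med`, and EMA components `ema_eyes`, `ema_nose`.
#' @examples
#' score_entries(max_diary_entry())[, c("phd_raw", "ema_raw")]  # 25.65, 12
#' @export
score_entries <- function(diary, weights = scoring_weights()) {
  validate_diary(diary)
  if (nrow(diary) == 0) {
    return(tibble(user_id = character(), date = as.Date(character()),
                  phd_raw = numeric(), ema_raw = numeric(),
                  sub_eyes = numeric(), sub_nose = numeric(),
                  sub_lungs = numeric(), sub_med = numeric(),
                  ema_eyes = numeric(), ema_nose = numeric()))
  }
  sp <- weights$symptom_point
  count_flags <- function(cols) rowSums(as.matrix(diary[, cols]))
  sub_eyes <- diary$severity_eyes + sp * count_flags(EYE_FLAGS)
  sub_nose <- diary$severity_nose + sp * count_flags(NOSE_FLAGS)
  sub_lungs <- diary$severity_lungs + sp * count_flags(LUNG_FLAGS)
  sub_med <- medication_score(diary, weights)
  # EMA eye collapse: watering -> tearing; itching/foreign-body/redness OR'd.
  ema_eyes <- diary$severity_eyes +
    as.numeric(diary$eye_watering) +
    as.numeric(diary$eye_itching | diary$eye_foreign_body | diary$eye_redness)
  ema_nose <- diary$severity_nose + count_flags(NOSE_FLAGS)
  tibble(
    user_id = diary$user_id,
    date = diary$date,
    phd_raw = sub_eyes + sub_nose + sub_lungs + sub_med,
    ema_raw = ema_eyes + ema_nose,
    sub_eyes = sub_eyes, sub_nose = sub_nose, sub_lungs = sub_lungs,
    sub_med = sub_med, ema_eyes = ema_eyes, ema_nose = ema_nose
  )
}

#' A maximal diary entry
#'
#' One entry with the highest severity on all three organs, all twelve
#' symptom flags selected and every medication category taken — the entry
#' that attains the score maxima (25.65 combined, 12 EMA).
#'
#' @param user_id,date,region Identifiers stamped on the entry.
#' @return A one-row diary tibble.
#' @export
max_diary_entry <- function(user_id = "u0001", date = as.Date("2018-04-20"),
                            region = "AT-wien") {
  entry <- tibble(user_id = user_id, date = date, region = region,
                  severity_eyes = 3L, severity_nose = 3L, severity_lungs = 3L)
  for (col in c(EYE_FLAGS, NOSE_FLAGS, LUNG_FLAGS, MED_FLAGS)) entry[[col]] <- TRUE
  entry
}
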