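#' Configuration for the synthetic diary cohort generator
#'
#' Bundles every tunable of the synthetic-data module: cohort size, the
#' responder mixture, the seasonal pollen curve (peak day, width, annual
#' integral), the dose-response half-saturation, diary adherence, noise
#' scales, demographic mixtures and the master seed. The defaults describe a
#' single-taxon, single-region cohort with a spring (birch-like) pollen
#' season and a user pool whose demographic mix matches what large
#' crowdsourced hayfever diaries report: a small male majority (about 55%)
#' and roughly one user in five not stating an age group.
#'
#' @param n_users Number of diary users to simulate.
#' @param responder_fraction Proportion of users whose symptoms follow the
#'   pollen curve; the rest report pollen-independent background noise.
#' @param peak_day Day of year of the pollen-season peak.
#' @param peak_width Standard deviation, in days, of the Gaussian-shaped
#'   seasonal concentration curve.
#' @param target_apin Annual Pollen Integral the generated year is rescaled
#'   to, in grains·day/m³.
#' @param half_saturation Concentration (grains/m³) at which the saturating
#'   dose-response reaches half its maximum.
#' @param adherence Per-day probability that a user files an entry.
#' @param noise_scale Standard deviation of the multiplicative log-normal
#'   noise on the pollen curve (0 gives the smooth curve).
#' @param severity_noise Standard deviation of the Gaussian noise added to
#'   the expected severity before rounding to the 0-3 scale.
#' @param sensitivity_range Length-2 numeric; responders draw their
#'   sensitivity uniformly from this sub-interval of \[0, 1\].
#' @param gender_mix Named probability vector over
#'   `c("male", "female", "unknown")`; must sum to 1.
#' @param age_mix Named probability vector over
#'   `c("under21", "21to40", "over40", "unknown")`; must sum to 1.
#' @param region Region identifier stamped on all generated records.
#' @param taxon Pollen taxon, `"birch"` or `"grass"`.
#' @param seed Master seed; each generator operation derives its own RNG
#'   stream from it by a fixed offset, so outputs are reproducible and
#'   stable across stages.
#'
#' @return A list of class `"generator_config"`.
#' @examples
#' cfg <- generator_config(n_users = 50, seed = 42)
#' cfg$responder_fraction
#' @export
generator_config <- function(n_users = 200,
                             responder_fraction = 0.5,
                             peak_day = 120,
                             peak_width = 20,
                             target_apin = 10000,
                             half_saturation = 50,
                             adherence = 0.7,
                             noise_scale = 0.3,
                             severity_noise = 0.5,
                             sensitivity_range = c(0.5, 1),
                             gender_mix = c(male = 0.55, female = 0.43, unknown = 0.02),
                             age_mix = c(under21 = 0.10, `21to40` = 0.35,
                                         over40 = 0.35, unknown = 0.20),
                             region = "AT-wien",
                             taxon = c("birch", "grass"),
                             seed = 1L) {
  taxon <- match.arg(taxon)
  cfg <- list(
    n_users = as.integer(n_users),
    responder_fraction = responder_fraction,
    peak_day = peak_day,
    peak_width = peak_width,
    target_apin = target_apin,
    half_saturation = half_saturation,
    adherence = adherence,
    noise_scale = noise_scale,
    severity_noise = severity_noise,
    sensitivity_range = sensitivity_range,
    gender_mix = gender_mix,
    age_mix = age_mix,
    region = region,
    taxon = taxon,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (is.na(cfg$n_users) || cfg$n_users < 0) {
    abort("`n_users` must be a nonnegative integer.", class = "pollendiary_config_error")
  }
  probs <- c(responder_fraction = cfg$responder_fraction, adherence = cfg$adherence)
  bad <- probs < 0 | probs > 1
  if (any(bad)) {
    abort(paste0("Probabilities out of [0, 1]: ",
                 paste(names(probs)[bad], collapse = ", ")),
          class = "pollendiary_config_error")
  }
  if (!is.numeric(cfg$target_apin) || cfg$target_apin <= 0) {
    abort("`target_apin` must be positive.", class = "pollendiary_config_error")
  }
  if (cfg$peak_width <= 0) {
    abort("`peak_width` must be positive.", class = "pollendiary_config_error")
  }
  if (cfg$half_saturation <= 0) {
    abort("`half_saturation` must be positive.", class = "pollendiary_config_error")
  }
  if (cfg$noise_scale < 0 || cfg$severity_noise < 0) {
    abort("Noise scales must be nonnegative.", class = "pollendiary_config_error")
  }
  check_mixture <- function(mix, levels, name) {
    if (!setequal(names(mix), levels) || any(mix < 0) ||
        abs(sum(mix) - 1) > 1e-8) {
      abort(paste0("`", name, "` must be a probability vector over {",
                   paste(levels, collapse = ", "), "} summing to 1."),
            class = "pollendiary_config_error")
    }
  }
  check_mixture(cfg$gender_mix, c("male", "female", "unknown"), "gender_mix")
  check_mixture(cfg$age_mix, c("under21", "21to40", "over40", "unknown"), "age_mix")
  sr <- cfg$sensitivity_range
  if (length(sr) != 2 || sr[1] > sr[2] || sr[1] < 0 || sr[2] > 1) {
    abort("`sensitivity_range` must be an ordered pair inside [0, 1].",
          class = "pollendiary_config_error")
  }
  invisible(cfg)
}

# Run `code` under a dedicated RNG stream derived from the master seed by a
# fixed per-operation offset, restoring the caller's RNG state afterwards.
# Fixed offsets keep one stage's draws stable when another stage's
# parameters change.
with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed((as.integer(seed) + offset) %% 2147483647L)
  force(code)
}

STREAM_POLLEN <- 101L
STREAM_USERS  <- 202L
STREAM_DIARY  <- 303L
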