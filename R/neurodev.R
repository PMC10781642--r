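#' Translating-time species parameters
#'
#' The cross-mammalian neurodevelopmental clock maps an event score
#' (a shared \[0, 1\] ordering of neurodevelopmental events) to the
#' natural-log post-conception day via a species-specific line:
#' `Y = intercept + slope * score (+ 0.263 for cortical neurogenesis events
#' in non-glire species)`, with
#' `intercept = 1.241 + 0.368 * ln(gestation days)` and
#' `slope = 1.474 + 0.257 * ln(adult brain mass g)`. Natural logarithms
#' throughout.
#'
#' @param gestation gestation length in days (> 0), vectorized.
#' @param brain_mass adult brain mass in grams (> 0), vectorized.
#' @return a tibble with `gestation`, `brain_mass`, `intercept`, `slope`.
#' @examples
#' species_params(275, 1330)   # human-like values
#' species_params(227, 390)    # chimpanzee-like values
#' @export
species_params <- function(gestation, brain_mass) {
  if (any(gestation <= 0) || any(brain_mass <= 0)) {
    abort("gestation and brain mass must be > 0")
  }
  tibble(
    gestation = gestation,
    brain_mass = brain_mass,
    intercept = 1.241 + 0.368 * log(gestation),
    slope = 1.474 + 0.257 * log(brain_mass)
  )
}

interaction_term <- 0.263

#' Post-conception day and pre/postnatal classification of events
#'
#' Evaluates the translating-time line for each species-event combination and
#' subtracts the gestation length: `signed_day = exp(Y) - gestation`, negative
#' for prenatal events, positive for postnatal ones (a signed day of exactly
#' 0 is classified prenatal).
#'
#' @param params a tibble from [species_params()] (one row per species; a
#'   `species` column is carried through if present).
#' @param events a tibble of events with columns `label`, `score`, and
#'   optionally `cortical_neurogenesis` (0/1).
#' @param non_glire add the cortical-neurogenesis interaction term (0.263)
#'   for flagged events; applies to primates and other non-glire mammals.
#' @return a tibble with one row per species-event pair: event columns plus
#'   `post_conception_day`, `signed_day`, `classification`.
#' @export
event_day <- function(params, events, non_glire = TRUE) {
  if (any(events$score < 0 | events$score > 1)) {
    abort("event scores must lie in [0, 1]")
  }
  out <- tidyr::expand_grid(
    dplyr::mutate(params, .sp = dplyr::row_number()),
    dplyr::select(events, dplyr::any_of(c("label", "score", "cortical_neurogenesis")))
  )
  cn_flag <- if ("cortical_neurogenesis" %in% names(out)) {
    out$cortical_neurogenesis
  } else {
    0
  }
  Y <- out$intercept + out$slope * out$score +
    ifelse(non_glire & cn_flag > 0, interaction_term, 0)
  out$post_conception_day <- exp(Y)
  out$signed_day <- out$post_conception_day - out$gestation
  out$classification <- ifelse(out$signed_day > 0, "postnatal", "prenatal")
  dplyr::select(out, -".sp")
}

#' Event score at which a species is born
#'
#' Inverts the translating-time line at the day of birth: the event score
#' whose predicted post-conception day equals the gestation length,
#' `score = (ln(gestation) - intercept) / slope`. Decreases with brain mass
#' at fixed gestation (bigger brains are born earlier on the shared scale)
#' and increases with gestation at fixed brain mass.
#'
#' @inheritParams species_params
#' @return numeric vector of birth event scores.
#' @examples
#' birth_event_score(275, 1330)  # ~0.695: the human birth score
#' @export
birth_event_score <- function(gestation, brain_mass) {
  p <- species_params(gestation, brain_mass)
  (log(gestation) - p$intercept) / p$slope
}

#' Gestation length implied by a birth event score
#'
#' Solves the translating-time line for the gestation length at which a
#' species would be born with event score `score`.
#'
#' `fixed_intercept` mode keeps the species intercept at the value implied by
#' its observed gestation and returns `exp(intercept_obs + slope * score)` —
#' the printed-form inversion used to ask, e.g., how long human gestation
#' would need to be to reach the great apes' birth score. `self_consistent`
#' mode solves for a gestation that also feeds the intercept:
#' `ln(G) = (1.241 + slope * score) / (1 - 0.368)`, the exact algebraic
#' inverse of [birth_event_score()].
#'
#' @param score target birth event score in \[0, 1\].
#' @param brain_mass adult brain mass (g).
#' @param observed_gestation observed gestation (days); required in
#'   `fixed_intercept` mode.
#' @param mode `"fixed_intercept"` (default) or `"self_consistent"`.
#' @return gestation length in days.
#' @export
gestation_for_event_score <- function(score, brain_mass,
                                      observed_gestation = NULL,
                                      mode = c("fixed_intercept", "self_consistent")) {
  mode <- match.arg(mode)
  if (any(score < 0 | score > 1)) abort("score must lie in [0, 1]")
  slope <- 1.474 + 0.257 * log(brain_mass)
  if (mode == "fixed_intercept") {
    if (is.null(observed_gestation)) {
      abort("fixed_intercept mode needs the observed gestation")
    }
    intercept <- 1.241 + 0.368 * log(observed_gestation)
    exp(intercept + slope * score)
  } else {
    exp((1.241 + slope * score) / (1 - 0.368))
  }
}

#' Raw hominin gestation lengths from neonatal body mass
#'
#' Fossil gestation lengths are estimated as neonatal body mass divided by a
#' prenatal growth rate (g/day); the minimum and maximum neonatal mass
#' estimates give a raw error range.
#'
#' @param hominins a tibble from [read_hominin_table()] (or of the same
#'   shape).
#' @param growth_rate prenatal growth rate in g/day (> 0); a configured
#'   constant, see [neurodev_config()].
#' @return the input with `raw_mean`, `raw_min`, `raw_max` gestation columns
#'   (days).
#' @export
estimate_hominin_gestation <- function(hominins, growth_rate) {
  if (is.null(growth_rate) || growth_rate <= 0) {
    abort("growth_rate must be a positive number of g/day")
  }
  dplyr::mutate(
    hominins,
    raw_mean = .data$neonatal_body_mean / growth_rate,
    raw_min = .data$neonatal_body_min / growth_rate,
    raw_max = .data$neonatal_body_max / growth_rate
  )
}

#' Rescale raw gestation lengths onto a plausible interval
#'
#' Linear min-max map of the raw per-species gestation means onto
#' `bounds` (default 245-275 days: the reconstructed chimp-human ancestor
#' value to the modern human value); the smallest raw value maps exactly to
#' the lower bound and the largest to the upper bound.
#'
#' @param raw_means numeric vector of raw gestation means (days).
#' @param bounds length-2 numeric `(lo, hi)`.
#' @return numeric vector of adjusted means.
#' @export
rescale_gestations <- function(raw_means, bounds = c(245, 275)) {
  if (length(raw_means) < 2 || diff(range(raw_means)) == 0) {
    abort("need at least 2 distinct raw gestation values")
  }
  lo <- bounds[1]
  hi <- bounds[2]
  lo + (raw_means - min(raw_means)) * (hi - lo) / diff(range(raw_means))
}

#' Propagate the raw gestation error band onto the adjusted mean
#'
#' The percentage of the raw mean represented by the raw minimum and maximum
#' is applied multiplicatively to the adjusted mean:
#' `adjusted_min = adjusted_mean * raw_min / raw_mean` (and likewise for the
#' maximum).
#'
#' @param raw_mean,raw_min,raw_max raw gestation values (days), vectorized,
#'   with `raw_min <= raw_mean <= raw_max`.
#' @param adjusted_mean adjusted mean gestation (days).
#' @return a tibble with `adjusted_min`, `adjusted_mean`, `adjusted_max`.
#' @export
propagate_gestation_error <- function(raw_mean, raw_min, raw_max, adjusted_mean) {
  if (any(!(raw_min <= raw_mean & raw_mean <= raw_max))) {
    abort("need raw_min <= raw_mean <= raw_max")
  }
  tibble(
    adjusted_min = adjusted_mean * raw_min / raw_mean,
    adjusted_mean = adjusted_mean,
    adjusted_max = adjusted_mean * raw_max / raw_mean
  )
}

#' Endocranial volume to brain mass
#'
#' Applies a configured conversion from endocranial volume (cc) to brain mass
#' (g): either a power law `a * ecv^b` or an identity-times-density fallback.
#'
#' @param ecv endocranial volume in cc (> 0).
#' @param coefficients list: `method = "power"` with `a`, `b`, or
#'   `method = "identity"` with `density` (g/cc).
#' @return brain mass in grams.
#' @export
ecv_to_brain_mass <- function(ecv, coefficients = list(method = "identity", density = 1)) {
  if (any(ecv <= 0)) abort("ecv must be > 0")
  m <- coefficients$method %||% "identity"
  switch(m,
    power = {
      if (is.null(coefficients$a) || is.null(coefficients$b)) {
        abort("power conversion needs coefficients a and b")
      }
      coefficients$a * ecv^coefficients$b
    },
    identity = ecv * (coefficients$density %||% 1),
    abort(paste0("unknown conversion method: ", m))
  )
}

#' Events whose pre/postnatal occurrence shifts across a species set
#'
#' An event shifts iff its signed day is strictly negative (prenatal) in at
#' least one species and strictly positive (postnatal) in at least one other
#' — equivalently, iff its score lies strictly between the minimum and
#' maximum birth event scores across the species set. Both characterizations
#' are computed and must agree; events exactly at a species' birth score
#' (signed day 0) count as prenatal and do not shift on their own.
#'
#' @param species_set a tibble with columns `species`, `gestation` (days) and
#'   `brain_mass` (g); optional `gestation_min` / `gestation_max` columns give
#'   per-species error bands.
#' @param events event tibble (see [fixture_event_table()]).
#' @param band which gestation value to use per species: `"mean"` (default),
#'   `"widest"` (minimum gestation for the lower window endpoint and maximum
#'   for the upper: the widest shift window the error bands allow) or
#'   `"narrowest"` (the reverse).
#' @return a tibble of events with `shifts` (logical, both characterizations),
#'   plus attributes `window` (min/max birth scores used) and
#'   `birth_scores` (per-species tibble).
#' @export
classify_event_shifts <- function(species_set, events,
                                  band = c("mean", "widest", "narrowest")) {
  band <- match.arg(band)
  if (nrow(species_set) < 2) abort("need at least 2 species")
  s <- species_set
  if (!all(c("gestation_min", "gestation_max") %in% names(s))) {
    s$gestation_min <- s$gestation
    s$gestation_max <- s$gestation
  }
  score_at <- function(g) birth_event_score(g, s$brain_mass)
  bs_mean <- score_at(s$gestation)
  bs_lo <- score_at(s$gestation_min) # shorter gestation -> lower birth score
  bs_hi <- score_at(s$gestation_max)
  window <- switch(band,
    mean = range(bs_mean),
    widest = c(min(bs_lo), max(bs_hi)),
    narrowest = c(min(bs_hi), max(bs_lo))
  )
  ## (a "narrowest" window can be empty: window[1] > window[2] means no
  ## event can shift under that reading of the bands)
  g_use_lo <- switch(band, mean = s$gestation, widest = s$gestation_min,
    narrowest = s$gestation_max
  )
  g_use_hi <- switch(band, mean = s$gestation, widest = s$gestation_max,
    narrowest = s$gestation_min
  )
  ## sign-flip characterization: for each event, prenatal day in at least one
  ## species and postnatal in another, using the same per-species gestation
  ## choice as the window (lower endpoint choice for the postnatal side,
  ## upper for the prenatal side)
  ## a day within floating-point noise of birth counts as day 0 (prenatal)
  shifts_signflip <- vapply(events$score, function(sc) {
    day_lo <- exp(1.241 + 0.368 * log(g_use_lo) +
      (1.474 + 0.257 * log(s$brain_mass)) * sc) - g_use_lo
    day_hi <- exp(1.241 + 0.368 * log(g_use_hi) +
      (1.474 + 0.257 * log(s$brain_mass)) * sc) - g_use_hi
    any(day_lo > 1e-8 * g_use_lo) && any(day_hi < -1e-8 * g_use_hi)
  }, logical(1))
  ## strict interiority, with the same floating-point guard as the day signs
  shifts_window <- events$score > window[1] + 1e-9 &
    events$score < window[2] - 1e-9
  if (!all(shifts_signflip == shifts_window)) {
    abort("internal inconsistency: sign-flip and window characterizations disagree")
  }
  out <- dplyr::mutate(events, shifts = shifts_window)
  attr(out, "window") <- window
  attr(out, "birth_scores") <- tibble(
    species = s$species, birth_score = bs_mean,
    birth_score_min = bs_lo, birth_score_max = bs_hi
  )
  out
}

#' Neurodevelopmental-clock configuration
#'
#' Reads the packaged configuration of external constants: the prenatal
#' growth rate (g/day) used for fossil gestation estimates, the rescaling
#' bounds, and the endocranial-volume conversion. The shipped values are a
#' synthetic, documented configuration (see the packaged
#' `hominins_synthetic.csv`): the growth rate and ECV coefficients are
#' back-solved so that the synthetic hominin fixture reproduces the published
#' gestation extremes, not measured constants.
#'
#' @param path YAML file; defaults to the packaged
#'   `extdata/neurodev_config.yaml`.
#' @return a list with `growth_rate`, `rescale_bounds`, `ecv_to_mass`.
#' @export
neurodev_config <- function(path = system.file("extdata", "neurodev_config.yaml",
                                               package = "altrix")) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$growth_rate) || cfg$growth_rate <= 0) {
    abort("config must provide a positive growth_rate (g/day)")
  }
  cfg$rescale_bounds <- as.numeric(cfg$rescale_bounds %||% c(245, 275))
  cfg
}

#' Full hominin gestation workflow
#'
#' Raw gestation estimates from neonatal mass, min-max rescaling onto the
#' configured bounds, and multiplicative error propagation, in one call.
#' Species with an `observed_gestation` keep it (with a zero-width band
#' unless raw bounds are given).
#'
#' @param hominins tibble from [read_hominin_table()].
#' @param config list from [neurodev_config()].
#' @return the input plus raw and adjusted gestation columns.
#' @export
hominin_gestations <- function(hominins, config = neurodev_config()) {
  h <- estimate_hominin_gestation(hominins, config$growth_rate)
  est <- is.na(h$observed_gestation %||% rep(NA_real_, nrow(h)))
  if (!"observed_gestation" %in% names(h)) {
    h$observed_gestation <- NA_real_
    est <- rep(TRUE, nrow(h))
  }
  adj <- rescale_gestations(h$raw_mean[est], config$rescale_bounds)
  h$adjusted_mean <- h$observed_gestation
  h$adjusted_mean[est] <- adj
  bands <- propagate_gestation_error(
    h$raw_mean, h$raw_min, h$raw_max, h$adjusted_mean
  )
  h$adjusted_min <- bands$adjusted_min
  h$adjusted_max <- bands$adjusted_max
  h
}
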