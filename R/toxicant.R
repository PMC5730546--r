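#' Hill immobilization probability
#'
#' Two-parameter Hill response `F(c) = c^h / (ec50^h + c^h)`, the fraction of
#' animals immobilized at concentration `c`. `F(0) = 0`, `F(ec50) = 0.5`
#' exactly, and the ceiling is 1.
#'
#' @param concentration concentration(s), same units as `ec50`; must be >= 0.
#' @param ec50 half-effect concentration (> 0).
#' @param hill_slope Hill slope `h` (> 0).
#' @return immobilization probability in `[0, 1)`.
#' @examples
#' hill_probability(0.45, ec50 = 0.15, hill_slope = 2)  # 0.9
#' @export
hill_probability <- function(concentration, ec50, hill_slope) {
  check_number(ec50, "ec50", min = 0, strict_min = TRUE)
  check_number(hill_slope, "hill_slope", min = 0, strict_min = TRUE)
  check_number(concentration, "concentration", min = 0,
               len = length(concentration))
  ## logistic form in log concentration; exact 0 at c = 0
  ifelse(concentration == 0, 0,
         plogis(hill_slope * (log(concentration) - log(ec50))))
}

#' Toxicant effect model
#'
#' Couples the two population-level effects of a toxicant that the assay
#' measures: (i) immobilization, drawn per animal from the Hill model with
#' parameters `ec50` and `hill_slope`, and (ii) modulation of locomotor
#' activity, a multiplier on the hop initiation rate as a function of
#' concentration and exposure time. Multipliers above 1 encode hyperactivity,
#' below 1 hypoactivity, 0 complete cessation.
#'
#' @param ec50 immobilization half-effect concentration (units of the assay,
#'   e.g. mg/L or % v/v).
#' @param hill_slope dimensionless Hill slope (> 0).
#' @param activity_curve function `(concentration, time_h)` returning a
#'   non-negative multiplier on `hop_rate_hz`; default 1 (no behavioral
#'   effect).
#' @param onset_lag_h delay (hours) before activity modulation applies.
#' @return An object of class `toxicant_effect`.
#' @examples
#' # copper-like: strong hypoactivity at high dose
#' eff <- toxicant_effect(ec50 = 0.15, hill_slope = 2,
#'                        activity_curve = function(c, t) 1 / (1 + (c / 0.6)^1.5))
#' @export
toxicant_effect <- function(ec50, hill_slope,
                            activity_curve = function(concentration, time_h) 1,
                            onset_lag_h = 0) {
  check_number(ec50, "ec50", min = 0, strict_min = TRUE)
  check_number(hill_slope, "hill_slope", min = 0, strict_min = TRUE)
  check_number(onset_lag_h, "onset_lag_h", min = 0)
  if (!is.function(activity_curve)) {
    stop("'activity_curve' must be a function(concentration, time_h)",
         call. = FALSE)
  }
  structure(list(
    ec50 = ec50,
    hill_slope = hill_slope,
    activity_curve = activity_curve,
    onset_lag_h = onset_lag_h
  ), class = "toxicant_effect")
}

#' Apply a dose to locomotion parameters
#'
#' Returns the locomotion parameters of an exposed animal: the hop initiation
#' rate is multiplied by `activity_curve(concentration, time_h)` once the
#' exposure time has reached `onset_lag_h`; all other fields are preserved.
#' A zero concentration is the null dose and returns the parameters
#' unchanged for all times.
#'
#' @param params a [locomotion_params()] object (control kinematics).
#' @param effect a [toxicant_effect()] object.
#' @param concentration exposure concentration (>= 0).
#' @param time_h exposure time in hours (>= 0).
#' @return a [locomotion_params()] object with the dosed hop rate.
#' @export
apply_dose <- function(params, effect, concentration, time_h) {
  stopifnot(inherits(params, "locomotion_params"),
            inherits(effect, "toxicant_effect"))
  check_number(concentration, "concentration", min = 0)
  check_number(time_h, "time_h", min = 0)
  mult <- if (concentration == 0 || time_h < effect$onset_lag_h) {
    1
  } else {
    m <- effect$activity_curve(concentration, time_h)
    if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0) {
      stop("activity multiplier must be a finite number >= 0", call. = FALSE)
    }
    m
  }
  if (mult == 1) return(params)
  out <- params
  out$hop_rate_hz <- params$hop_rate_hz * mult
  ## keep the renewal process well defined at strong hyperactivity: shorten
  ## the burst if the dosed rate would leave no rest period
  if (out$hop_rate_hz > 0 && out$hop_rate_hz * out$hop_duration_s >= 1) {
    out$hop_duration_s <- 0.5 / out$hop_rate_hz
  }
  out
}

#' Draw per-animal immobilization outcomes
#'
#' Each of `n_animals` is immobilized independently with the Hill probability
#' `concentration^h / (ec50^h + concentration^h)`.
#'
#' @param effect a [toxicant_effect()] object.
#' @param concentration exposure concentration (>= 0).
#' @param n_animals number of animals (>= 1).
#' @param seed explicit integer seed; draws are reproducible.
#' @return logical vector of length `n_animals`; `TRUE` = immobile.
#' @export
sample_immobilization <- function(effect, concentration, n_animals, seed) {
  stopifnot(inherits(effect, "toxicant_effect"))
  check_number(n_animals, "n_animals", min = 1)
  p <- hill_probability(concentration, effect$ec50, effect$hill_slope)
  with_seed(seed, runif(n_animals) < p)
}
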