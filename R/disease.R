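#' Natural-history progression parameters
#'
#' BCVA (logMAR, higher is worse) is constant until the patient's onset age
#' and then worsens by `bcva_age_coeff` per year up to `bcva_cap`; the
#' Goldmann III4e visual field shrinks linearly by `vf_slope` sum total
#' degrees per year down to `vf_floor`.
#'
#' @param bcva_age_coeff Annual logMAR increase after onset (default 0.0436).
#' @param vf_slope Annual VF change, degrees (default -25; the published
#'   alternative rate is -24.3).
#' @param bcva_cap,bcva_floor Bounds of the tracked BCVA state, logMAR.
#' @param vf_floor Lower bound of the VF state, degrees.
#' @return An object of class `progression_params`.
#' @export
progression_params <- function(bcva_age_coeff = 0.0436, vf_slope = -25,
                               bcva_cap = 2.3, bcva_floor = -0.3,
                               vf_floor = 0) {
  check_number(bcva_age_coeff, "bcva_age_coeff", lo = 0)
  check_number(vf_slope, "vf_slope", hi = 0)
  if (bcva_floor > bcva_cap) stop_config("bcva_floor must be <= bcva_cap")
  structure(
    list(bcva_age_coeff = bcva_age_coeff, vf_slope = vf_slope,
         bcva_cap = bcva_cap, bcva_floor = bcva_floor, vf_floor = vf_floor),
    class = "progression_params"
  )
}

#' First-cycle treatment-effect distributions
#'
#' Per-arm year-1 changes observed in the phase-III trial, applied once in
#' the first model cycle: VN patients draw their BCVA/VF change from the
#' VN distributions, SoC patients from the SoC distributions.
#'
#' @param bcva_change_mean,bcva_change_sd Named (`VN`, `SoC`) means/SDs of
#'   the first-cycle BCVA change, logMAR.
#' @param vf_change_mean,vf_change_sd Named (`VN`, `SoC`) means/SDs of the
#'   first-cycle VF change, degrees.
#' @return An object of class `trial_effect`.
#' @export
trial_effect <- function(bcva_change_mean = c(VN = -0.163, SoC = -0.312),
                         bcva_change_sd = c(VN = 0.336, SoC = 0.097),
                         vf_change_mean = c(VN = 302.1, SoC = -76.7),
                         vf_change_sd = c(VN = 289.6, SoC = 258.7)) {
  for (nm in c("bcva_change_mean", "bcva_change_sd",
               "vf_change_mean", "vf_change_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || !all(c("VN", "SoC") %in% names(v))) {
      stop_config(nm, " must be a numeric vector with names 'VN' and 'SoC'")
    }
  }
  if (any(bcva_change_sd < 0) || any(vf_change_sd < 0)) {
    stop_config("effect SDs must be >= 0")
  }
  structure(
    list(bcva_change_mean = bcva_change_mean[c("VN", "SoC")],
         bcva_change_sd = bcva_change_sd[c("VN", "SoC")],
         vf_change_mean = vf_change_mean[c("VN", "SoC")],
         vf_change_sd = vf_change_sd[c("VN", "SoC")]),
    class = "trial_effect"
  )
}

#' Treatment-effect-duration scenario
#'
#' `"lifetime"` freezes the treated patient's post-first-cycle state for
#' life. `"waning"` holds the full effect for `plateau_years` after
#' treatment, then decays it exponentially over `waning_years` toward the
#' patient's own counterfactual standard-of-care trajectory, reaching
#' `residual_floor` of the original effect at the end of the waning window
#' and 0 afterwards.
#'
#' @param kind `"lifetime"` or `"waning"`.
#' @param plateau_years Years of full effect after treatment.
#' @param waning_years Duration of the exponential decay window, years.
#' @param residual_floor Residual effect fraction at the end of waning,
#'   after which the effect is snapped to zero.
#' @return An object of class `effect_scenario`.
#' @export
effect_scenario <- function(kind = c("lifetime", "waning"),
                            plateau_years = 10, waning_years = 10,
                            residual_floor = 0.05) {
  kind <- match.arg(kind)
  check_number(plateau_years, "plateau_years")
  check_number(waning_years, "waning_years")
  if (plateau_years <= 0 || waning_years <= 0) {
    stop_config("plateau_years and waning_years must be > 0")
  }
  check_number(residual_floor, "residual_floor", lo = 0)
  if (residual_floor >= 1) stop_config("residual_floor must be < 1")
  structure(
    list(kind = kind, plateau_years = plateau_years,
         waning_years = waning_years, residual_floor = residual_floor),
    class = "effect_scenario"
  )
}

#' Utility-mapping parameters
#'
#' Health-state utility is linear in two clamped, normalised visual-function
#' scores: `s_va = clamp((bcva_worst - bcva) / bcva_ref, 0, 1)` and
#' `s_vf = clamp(vf / vf_ref, 0, 1)`, combined as
#' `u = u_min + (u_max - u_min) * (w_va * s_va + w_vf * s_vf)` with
#' `w_vf = 1 - w_va`. The anchors and weights are model inputs (see
#' [calibrate_utility()]).
#'
#' @param u_max Utility of the best tracked state (BCVA at floor, full VF).
#' @param u_min Utility of the worst tracked state (BCVA at cap, VF 0).
#' @param w_va Weight of the acuity score; the VF score gets `1 - w_va`.
#' @param bcva_ref LogMAR span used to normalise acuity (default 2.3).
#' @param bcva_worst LogMAR anchor of the zero-acuity score (default 2.3).
#' @param vf_ref VF value (degrees) mapping to a full field score.
#' @return An object of class `utility_params`.
#' @export
utility_params <- function(u_max = 0.85, u_min = 0.40, w_va = 0.5,
                           bcva_ref = 2.3, bcva_worst = 2.3, vf_ref = 1000) {
  check_number(u_max, "u_max", 0, 1)
  check_number(u_min, "u_min", 0, 1)
  if (u_min >= u_max) stop_config("u_min must be < u_max")
  check_number(w_va, "w_va", 0, 1)
  check_number(bcva_ref, "bcva_ref")
  check_number(vf_ref, "vf_ref")
  if (bcva_ref <= 0 || vf_ref <= 0) stop_config("bcva_ref and vf_ref must be > 0")
  structure(
    list(u_max = u_max, u_min = u_min, w_va = w_va, w_vf = 1 - w_va,
         bcva_ref = bcva_ref, bcva_worst = bcva_worst, vf_ref = vf_ref),
    class = "utility_params"
  )
}

#' One year of natural BCVA progression
#'
#' @param bcva Current BCVA, logMAR.
#' @param age Current age, years.
#' @param onset_age Age at which natural BCVA decline begins.
#' @param p A [progression_params()].
#' @return Updated BCVA: unchanged before onset, else increased by
#'   `bcva_age_coeff` and capped at `bcva_cap`. Vectorised.
#' @export
natural_bcva_step <- function(bcva, age, onset_age, p = progression_params()) {
  ifelse(age < onset_age, bcva, pmin(bcva + p$bcva_age_coeff, p$bcva_cap))
}

#' One year of natural visual-field loss
#'
#' @param vf Current VF, sum total degrees (>= 0).
#' @param p A [progression_params()].
#' @return `max(vf + vf_slope, vf_floor)`. Vectorised.
#' @export
natural_vf_step <- function(vf, p = progression_params()) {
  pmax(vf + p$vf_slope, p$vf_floor)
}

#' Apply the first-cycle trial effect to a patient
#'
#' Draws the patient's arm-specific first-cycle BCVA and VF changes and
#' applies them, clamped to the progression bounds. Both arms receive their
#' trial deltas (the SoC arm's printed year-1 changes included).
#'
#' @param patient A one-row patient data.frame (columns `bcva`, `vf`, `arm`).
#' @param eff A [trial_effect()].
#' @param p A [progression_params()] supplying the clamping bounds.
#' @param deltas Optional resolved draws `c(bcva, vf)`; when `NULL` they are
#'   drawn from the arm's normal distributions.
#' @return The patient with updated `bcva` and `vf`.
#' @export
apply_first_cycle_effect <- function(patient, eff = trial_effect(),
                                     p = progression_params(), deltas = NULL) {
  arm <- patient$arm
  if (is.null(deltas)) {
    deltas <- c(
      stats::rnorm(1, eff$bcva_change_mean[arm], eff$bcva_change_sd[arm]),
      stats::rnorm(1, eff$vf_change_mean[arm], eff$vf_change_sd[arm])
    )
  }
  patient$bcva <- clamp(patient$bcva + deltas[1], p$bcva_floor, p$bcva_cap)
  patient$vf <- pmax(patient$vf + deltas[2], p$vf_floor)
  patient
}

#' Residual treatment-effect fraction
#'
#' @param scenario An [effect_scenario()].
#' @param years_since_treatment Whole years since the treatment cycle
#'   (>= 1). Vectorised.
#' @return Fraction in `[0, 1]`: 1 under the lifetime scenario; under
#'   waning, 1 through the plateau, `exp(-k * (t - plateau))` with
#'   `k = -log(residual_floor) / waning_years` during the waning window,
#'   and 0 afterwards.
#' @export
residual_effect_fraction <- function(scenario, years_since_treatment) {
  t <- years_since_treatment
  if (any(t < 1)) stop("years_since_treatment must be >= 1")
  if (scenario$kind == "lifetime") {
    return(rep(1, length(t)))
  }
  k <- -log(scenario$residual_floor) / scenario$waning_years
  r <- ifelse(t <= scenario$plateau_years, 1,
              exp(-k * (t - scenario$plateau_years)))
  r[t > scenario$plateau_years + scenario$waning_years] <- 0
  r
}

#' Blend a treated state with its counterfactual
#'
#' Interpolates componentwise between the frozen post-treatment state and
#' the patient's shadow standard-of-care state:
#' `shadow + residual * (frozen - shadow)`, clamped to the model bounds.
#'
#' @param frozen_state,shadow_state Lists (or one-row data.frames) with
#'   elements `bcva` and `vf`.
#' @param residual Residual effect fraction in `[0, 1]`.
#' @param p A [progression_params()].
#' @return A list with elements `bcva` and `vf`.
#' @export
treated_state <- function(frozen_state, shadow_state, residual,
                          p = progression_params()) {
  stopifnot(all(residual >= 0 & residual <= 1))
  list(
    bcva = clamp(shadow_state$bcva + residual * (frozen_state$bcva - shadow_state$bcva),
                 p$bcva_floor, p$bcva_cap),
    vf = pmax(shadow_state$vf + residual * (frozen_state$vf - shadow_state$vf),
              p$vf_floor)
  )
}

#' Health-state utility from visual function
#'
#' @param bcva BCVA, logMAR. Vectorised.
#' @param vf VF, sum total degrees. Vectorised.
#' @param u A [utility_params()].
#' @return Utility in `[u_min, u_max]`.
#' @examples
#' state_utility(0.987, 427.1, utility_params())
#' @export
state_utility <- function(bcva, vf, u = utility_params()) {
  s_va <- clamp((u$bcva_worst - bcva) / u$bcva_ref, 0, 1)
  s_vf <- clamp(vf / u$vf_ref, 0, 1)
  u$u_min + (u$u_max - u$u_min) * (u$w_va * s_va + u$w_vf * s_vf)
}
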