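# Shared fixtures: small deterministic configurations used across tests.

# A degenerate, fully deterministic setup: no randomness in baselines or
# effects, mortality effectively disabled below the terminal age.
deterministic_config <- function(age = 30, bcva_vn = 1.137, bcva_soc = 0.987,
                                 vf_vn = 332.9, vf_soc = 427.1,
                                 onset = c(15, 15), n_patients = 2L,
                                 scenario = effect_scenario("lifetime"),
                                 discount = discount_params(),
                                 include_indirect = TRUE,
                                 max_age = 100L) {
  zero_death <- make_life_table(gm_params(A = 1e-12, B = 1e-12, C = 1e-6),
                                sex_ratio_adjust = 1, max_age = max_age)
  scenario_config(
    cohort = cohort_spec(
      n_patients = n_patients, fraction_female = 1,
      age_mean = age, age_sd = 0, age_range = c(age, age),
      bcva_mean = c(VN = bcva_vn, SoC = bcva_soc),
      bcva_sd = c(VN = 0, SoC = 0),
      vf_mean = c(VN = vf_vn, SoC = vf_soc),
      vf_sd = c(VN = 0, SoC = 0),
      onset_window = onset),
    effects = trial_effect(
      bcva_change_sd = c(VN = 0, SoC = 0),
      vf_change_sd = c(VN = 0, SoC = 0)),
    scenario = scenario,
    discount = discount,
    include_indirect = include_indirect,
    life_table = zero_death,
    n_sims = 2L, master_seed = 7L
  )
}

# A small Monte Carlo configuration for fast stochastic tests.
small_config <- function(n_sims = 30L, master_seed = 11L, ...) {
  scenario_config(n_sims = n_sims, master_seed = master_seed, ...)
}

# Null-effect control: identical baselines, identical first-cycle deltas in
# both arms, and natural progression switched off, so the frozen treated
# state coincides with the evolving standard-of-care state and the arms
# differ only in the year-1 treatment bundle.
null_effect_config <- function() {
  cfg <- deterministic_config(bcva_vn = 0.987, bcva_soc = 0.987,
                              vf_vn = 427.1, vf_soc = 427.1)
  modify_config(
    cfg,
    progression = progression_params(bcva_age_coeff = 0, vf_slope = 0),
    effects = trial_effect(
      bcva_change_mean = c(VN = -0.312, SoC = -0.312),
      bcva_change_sd = c(VN = 0, SoC = 0),
      vf_change_mean = c(VN = -76.7, SoC = -76.7),
      vf_change_sd = c(VN = 0, SoC = 0)))
}

one_patient <- function(age = 30, sex = "female", bcva = 0.987, vf = 427.1,
                        onset_age = 17, arm = "SoC", id = 1L) {
  data.frame(id = id, age = age, sex = sex, bcva = bcva, vf = vf,
             onset_age = onset_age, arm = arm, stringsAsFactors = FALSE)
}

# Straight-line (per-cycle, scalar) reference implementation of the cycle
# accounting, independent of the vectorised engine. Takes the resolved
# number of survived cycles and the resolved effect draws, and walks the
# state forward one cycle at a time exactly as the model rules read.
reference_patient_totals <- function(patient, config, eff, n_alive) {
  p <- config$progression
  u <- config$utility
  # frozen post-treatment state (VN deltas)
  bf <- min(max(patient$bcva + eff[1], p$bcva_floor), p$bcva_cap)
  vff <- max(patient$vf + eff[2], p$vf_floor)
  # shadow state evolved under SoC rules
  bs <- min(max(patient$bcva + eff[3], p$bcva_floor), p$bcva_cap)
  vs <- max(patient$vf + eff[4], p$vf_floor)
  qaly <- 0
  cost <- 0
  for (t in seq_len(n_alive)) {
    age_t <- patient$age + t - 1
    if (t > 1) {
      bs <- natural_bcva_step(bs, age_t, patient$onset_age, p)
      vs <- natural_vf_step(vs, p)
    }
    if (patient$arm == "SoC") {
      bcva_t <- bs
      vf_t <- vs
    } else if (config$scenario$kind == "lifetime") {
      bcva_t <- bf
      vf_t <- vff
    } else {
      r <- if (t == 1) 1 else residual_effect_fraction(config$scenario, t - 1)
      st <- treated_state(list(bcva = bf, vf = vff),
                          list(bcva = bs, vf = vs), r, p)
      bcva_t <- st$bcva
      vf_t <- st$vf
    }
    util <- state_utility(bcva_t, vf_t, u)
    cd <- direct_cost(patient$arm, t, config$direct_costs)
    ci <- if (config$include_indirect) {
      indirect_annual_cost(bcva_band(bcva_t), config$indirect_costs, "mean")
    } else 0
    qaly <- qaly + util * discount_factor(t, config$discount$rate_qalys)
    cost <- cost + (cd + ci) * discount_factor(t, config$discount$rate_costs)
  }
  list(qaly = qaly, cost = cost)
}
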