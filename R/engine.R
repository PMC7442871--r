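# Annual-cycle microsimulation engine.
#
# Per patient: the mortality draw is a single uniform inverted against the
# cumulative survival curve from the current age (distributionally the same
# as one Bernoulli draw per cycle); the state trajectory is then computed
# over the accrued cycles in closed form. Death is evaluated at the start
# of each cycle, so a patient dying in cycle t accrues nothing in t.

# Number of accrued (survived) cycles given a uniform draw.
accrued_cycles <- function(age0, sex, death_u, life_table) {
  a0 <- floor(age0)
  if (a0 >= life_table$max_age) return(0L)
  ages <- a0:(life_table$max_age)
  q <- annual_death_prob(life_table, ages, sex)
  s <- cumprod(1 - q)
  sum(s > death_u)
}

# Per-cycle state/accrual vectors for one patient over cycles 1..n_alive,
# given resolved first-cycle effect draws for both arms
# (eff = c(bcva_vn, vf_vn, bcva_soc, vf_soc)).
patient_cycles <- function(patient, config, eff, n_alive) {
  if (n_alive < 1L) {
    return(list(t = integer(0), age = numeric(0), bcva = numeric(0),
                vf = numeric(0), utility = numeric(0),
                cost_direct = numeric(0), cost_indirect = numeric(0),
                disc_qaly = numeric(0), disc_cost = numeric(0)))
  }
  p <- config$progression
  t <- seq_len(n_alive)
  age <- patient$age + t - 1

  # shadow / standard-of-care trajectory (includes the SoC year-1 deltas)
  b1 <- clamp(patient$bcva + eff[3], p$bcva_floor, p$bcva_cap)
  v1 <- pmax(patient$vf + eff[4], p$vf_floor)
  inc <- c(0, p$bcva_age_coeff * (age[-1] >= patient$onset_age))
  bcva_soc <- pmin(b1 + cumsum(inc), p$bcva_cap)
  vf_soc <- pmax(v1 + p$vf_slope * (t - 1), p$vf_floor)

  if (patient$arm == "SoC") {
    bcva <- bcva_soc
    vf <- vf_soc
  } else {
    bf <- clamp(patient$bcva + eff[1], p$bcva_floor, p$bcva_cap)
    vff <- pmax(patient$vf + eff[2], p$vf_floor)
    if (config$scenario$kind == "lifetime") {
      bcva <- rep(bf, n_alive)
      vf <- rep(vff, n_alive)
    } else {
      r <- c(1, residual_effect_fraction(config$scenario, t[-1] - 1))
      bcva <- clamp(bcva_soc + r * (bf - bcva_soc), p$bcva_floor, p$bcva_cap)
      vf <- pmax(vf_soc + r * (vff - vf_soc), p$vf_floor)
    }
  }

  util <- state_utility(bcva, vf, config$utility)
  cd <- direct_cost(patient$arm, t, config$direct_costs)
  ci <- if (config$include_indirect) {
    indirect_annual_cost(bcva_band(bcva), config$indirect_costs,
                         config$indirect_mode)
  } else {
    numeric(n_alive)
  }
  list(
    t = t, age = age, bcva = bcva, vf = vf, utility = util,
    cost_direct = cd, cost_indirect = ci,
    disc_qaly = util * discount_factor(t, config$discount$rate_qalys),
    disc_cost = (cd + ci) * discount_factor(t, config$discount$rate_costs)
  )
}

#' Simulate one patient over a lifetime horizon
#'
#' Runs the annual-cycle two-state (alive/dead) microsimulation for one
#' patient: a start-of-cycle mortality evaluation against the age- and
#' sex-specific life table, the first-cycle treatment effect, natural
#' progression or the treatment-effect-duration rules thereafter, and
#' per-cycle utility and discounted cost/QALY accruals. Dead cycles accrue
#' nothing; the returned trajectory ends with the death cycle.
#'
#' @param patient A one-row patient data.frame (see [sample_cohort()]).
#' @param config A [scenario_config()].
#' @param draws Optional resolved randomness: a list with `eff` (numeric
#'   `c(bcva_vn, vf_vn, bcva_soc, vf_soc)` first-cycle change draws) and
#'   `death_u` (uniform in `[0,1]` for the mortality inversion). Drawn from
#'   the current RNG stream when `NULL`.
#' @return A `data.frame` with one row per cycle: `cycle, age, bcva, vf,
#'   alive, utility, cost_direct, cost_indirect, disc_qaly, disc_cost`.
#'   The final row is the death cycle (`alive = FALSE`, zero accruals).
#' @export
simulate_patient <- function(patient, config, draws = NULL) {
  if (is.null(draws)) {
    e <- config$effects
    draws <- list(
      eff = c(stats::rnorm(1, e$bcva_change_mean["VN"], e$bcva_change_sd["VN"]),
              stats::rnorm(1, e$vf_change_mean["VN"], e$vf_change_sd["VN"]),
              stats::rnorm(1, e$bcva_change_mean["SoC"], e$bcva_change_sd["SoC"]),
              stats::rnorm(1, e$vf_change_mean["SoC"], e$vf_change_sd["SoC"])),
      death_u = stats::runif(1)
    )
  }
  n_alive <- accrued_cycles(patient$age, patient$sex, draws$death_u,
                            config$life_table)
  cyc <- patient_cycles(patient, config, draws$eff, n_alive)
  alive_rows <- data.frame(
    cycle = cyc$t, age = cyc$age, bcva = cyc$bcva, vf = cyc$vf,
    alive = rep(TRUE, n_alive), utility = cyc$utility,
    cost_direct = cyc$cost_direct, cost_indirect = cyc$cost_indirect,
    disc_qaly = cyc$disc_qaly, disc_cost = cyc$disc_cost
  )
  death_row <- data.frame(
    cycle = n_alive + 1L, age = patient$age + n_alive,
    bcva = if (n_alive) cyc$bcva[n_alive] else patient$bcva,
    vf = if (n_alive) cyc$vf[n_alive] else patient$vf,
    alive = FALSE, utility = 0, cost_direct = 0, cost_indirect = 0,
    disc_qaly = 0, disc_cost = 0
  )
  rbind(alive_rows, death_row)
}

#' Run one Monte Carlo replicate
#'
#' Samples a fresh cohort, simulates every patient to death (or the
#' life-table terminal age) and aggregates to per-arm mean discounted
#' QALYs and costs. Three independent substreams (cohort, first-cycle
#' effects, mortality) are derived from `sim_seed`, so toggling scenario
#' parameters never shifts the random draws of the other sources — the
#' basis of the common-random-numbers design.
#'
#' @param config A [scenario_config()].
#' @param sim_seed Integer seed for this replicate.
#' @param sim_id Identifier stored in the result row.
#' @return A one-row `data.frame`: `sim_id, qaly_vn, qaly_soc, cost_vn,
#'   cost_soc, delta_qaly, delta_cost, icur`.
#' @export
run_simulation <- function(config, sim_seed, sim_id = 1L) {
  seeds <- derive_seeds(sim_seed, 3L)
  set.seed(seeds[1])
  cohort <- sample_cohort(config$cohort, config$progression)
  n <- nrow(cohort)

  e <- config$effects
  set.seed(seeds[2])
  eff <- cbind(
    stats::rnorm(n, e$bcva_change_mean["VN"], e$bcva_change_sd["VN"]),
    stats::rnorm(n, e$vf_change_mean["VN"], e$vf_change_sd["VN"]),
    stats::rnorm(n, e$bcva_change_mean["SoC"], e$bcva_change_sd["SoC"]),
    stats::rnorm(n, e$vf_change_mean["SoC"], e$vf_change_sd["SoC"])
  )
  set.seed(seeds[3])
  death_u <- stats::runif(n)

  qaly <- numeric(n)
  cost <- numeric(n)
  for (i in seq_len(n)) {
    pat <- list(age = cohort$age[i], sex = cohort$sex[i],
                bcva = cohort$bcva[i], vf = cohort$vf[i],
                onset_age = cohort$onset_age[i], arm = cohort$arm[i])
    n_alive <- accrued_cycles(pat$age, pat$sex, death_u[i], config$life_table)
    cyc <- patient_cycles(pat, config, eff[i, ], n_alive)
    qaly[i] <- sum(cyc$disc_qaly)
    cost[i] <- sum(cyc$disc_cost)
  }
  vn <- cohort$arm == "VN"
  qaly_vn <- mean(qaly[vn])
  qaly_soc <- mean(qaly[!vn])
  cost_vn <- mean(cost[vn])
  cost_soc <- mean(cost[!vn])
  dq <- qaly_vn - qaly_soc
  dc <- cost_vn - cost_soc
  data.frame(
    sim_id = sim_id, qaly_vn = qaly_vn, qaly_soc = qaly_soc,
    cost_vn = cost_vn, cost_soc = cost_soc,
    delta_qaly = dq, delta_cost = dc,
    icur = if (dq != 0) dc / dq else NA_real_
  )
}

#' Run the Monte Carlo ensemble
#'
#' Repeats [run_simulation()] over independent per-replicate seeds derived
#' from the master seed (default 1000 replicates of 70 patients).
#'
#' @param config A [scenario_config()].
#' @param n_sims Number of replicates; defaults to `config$n_sims`.
#' @param master_seed Master seed; defaults to `config$master_seed`.
#' @param verbose Print progress every 200 replicates?
#' @return A `data.frame` of class `vn_ensemble` (one row per replicate,
#'   columns as in [run_simulation()]) with the config fingerprint and
#'   master seed stored as attributes.
#' @export
run_monte_carlo <- function(config, n_sims = config$n_sims,
                            master_seed = config$master_seed,
                            verbose = FALSE) {
  stopifnot(n_sims >= 1)
  rep_seeds <- derive_seeds(master_seed, n_sims)
  rows <- vector("list", n_sims)
  for (s in seq_len(n_sims)) {
    rows[[s]] <- run_simulation(config, rep_seeds[s], sim_id = s)
    if (verbose && s %% 200 == 0) {
      message("replicate ", s, "/", n_sims)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "fingerprint") <- config_fingerprint(config)
  attr(out, "master_seed") <- as.integer(master_seed)
  class(out) <- c("vn_ensemble", "data.frame")
  out
}

#' @export
print.vn_ensemble <- function(x, ...) {
  cat(sprintf(
    "<vn_ensemble> %d replicates (seed %d)\n  mean dQALY %.3f, mean dCost %.0f, ICUR %.0f\n",
    nrow(x), attr(x, "master_seed"), mean(x$delta_qaly), mean(x$delta_cost),
    mean(x$delta_cost) / mean(x$delta_qaly)))
  invisible(x)
}
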