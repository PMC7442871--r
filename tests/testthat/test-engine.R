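test_that("three-cycle SoC accounting matches the hand-computed oracle", {
  # SoC patient age 30, onset already passed, all SDs zero, mortality
  # disabled; expected values computed by explicit arithmetic
  cfg <- deterministic_config()
  pat <- one_patient(age = 30, bcva = 0.987, vf = 427.1, onset_age = 17,
                     arm = "SoC")
  traj <- simulate_patient(pat, cfg,
                           draws = list(eff = c(-0.163, 302.1, -0.312, -76.7),
                                        death_u = 0))
  first3 <- traj[1:3, ]

  b <- c(0.987 - 0.312, 0.987 - 0.312 + 0.0436, 0.987 - 0.312 + 2 * 0.0436)
  v <- c(427.1 - 76.7, 427.1 - 76.7 - 25, 427.1 - 76.7 - 50)
  u <- 0.40 + 0.45 * (0.5 * (2.3 - b) / 2.3 + 0.5 * v / 1000)
  # decimal acuity 10^-b is ~0.19-0.21: band C, indirect 13,336/yr
  cost <- 220 + 13336
  df <- 1.03^-(0:2)

  expect_equal(first3$bcva, b, tolerance = 1e-9)
  expect_equal(first3$vf, v, tolerance = 1e-9)
  expect_equal(first3$utility, u, tolerance = 1e-9)
  expect_equal(first3$cost_direct, rep(220, 3))
  expect_equal(first3$cost_indirect, rep(13336, 3))
  expect_equal(sum(first3$disc_qaly), sum(u * df), tolerance = 1e-9)
  expect_equal(sum(first3$disc_cost), sum(cost * df), tolerance = 1e-9)
})

test_that("three-cycle VN accounting matches the hand-computed oracle", {
  cfg <- deterministic_config()
  pat <- one_patient(age = 30, bcva = 1.137, vf = 332.9, onset_age = 17,
                     arm = "VN")
  traj <- simulate_patient(pat, cfg,
                           draws = list(eff = c(-0.163, 302.1, -0.312, -76.7),
                                        death_u = 0))
  first3 <- traj[1:3, ]
  b <- 1.137 - 0.163 # frozen for life under the lifetime scenario
  v <- 332.9 + 302.1
  u <- 0.40 + 0.45 * (0.5 * (2.3 - b) / 2.3 + 0.5 * v / 1000)
  expect_equal(first3$bcva, rep(b, 3), tolerance = 1e-12)
  expect_equal(first3$vf, rep(v, 3), tolerance = 1e-12)
  expect_equal(first3$cost_direct, c(831660, 220, 220))
  expect_equal(first3$cost_indirect, rep(13336, 3)) # decimal 0.106: band C
  expect_equal(sum(first3$disc_qaly), sum(u * 1.03^-(0:2)), tolerance = 1e-9)
  expect_equal(sum(first3$disc_cost),
               sum((c(831660, 220, 220) + 13336) * 1.03^-(0:2)),
               tolerance = 1e-9)
})

test_that("undiscounted QALYs with a frozen state equal utility times years", {
  cfg <- deterministic_config(discount = discount_params(0, 0))
  pat <- one_patient(age = 30, bcva = 1.137, vf = 332.9, onset_age = 17,
                     arm = "VN")
  traj <- simulate_patient(pat, cfg,
                           draws = list(eff = c(-0.163, 302.1, -0.312, -76.7),
                                        death_u = 0))
  alive <- traj[traj$alive, ]
  u <- alive$utility[1]
  expect_equal(sum(alive$disc_qaly), u * nrow(alive), tolerance = 1e-9)
  # discounted QALYs never exceed life-years lived
  expect_lte(sum(alive$disc_qaly), nrow(alive))
})

test_that("a patient at the terminal age accrues nothing", {
  cfg <- deterministic_config()
  pat <- one_patient(age = 100, arm = "SoC")
  traj <- simulate_patient(pat, cfg,
                           draws = list(eff = rep(0, 4), death_u = 0.5))
  expect_equal(sum(traj$alive), 0)
  expect_equal(sum(traj$disc_qaly), 0)
  expect_equal(sum(traj$disc_cost), 0)
})

test_that("death ends the trajectory with a zero-accrual absorbing record", {
  cfg <- small_config()
  pat <- one_patient(age = 60, sex = "male", arm = "SoC")
  traj <- simulate_patient(pat, cfg,
                           draws = list(eff = rep(0, 4), death_u = 0.9))
  expect_false(traj$alive[nrow(traj)])
  expect_true(all(traj$alive[-nrow(traj)]))
  last <- traj[nrow(traj), ]
  expect_equal(last$utility + last$disc_qaly + last$disc_cost, 0)
})

test_that("replicates are bit-identical under a fixed seed", {
  cfg <- small_config()
  r1 <- run_simulation(cfg, sim_seed = 123)
  r2 <- run_simulation(cfg, sim_seed = 123)
  expect_identical(r1, r2)
  e1 <- run_monte_carlo(cfg, n_sims = 5, master_seed = 3)
  e2 <- run_monte_carlo(cfg, n_sims = 5, master_seed = 3)
  expect_identical(as.data.frame(e1), as.data.frame(e2))
  expect_identical(r1$icur, r1$delta_cost / r1$delta_qaly)
})

test_that("null treatment effect isolates the discounted treatment bundle", {
  # both arms draw the SoC deltas from identical baselines with natural
  # progression switched off and no mortality: the frozen treated state
  # equals the standard-of-care state, so the arms differ only in the
  # year-1 direct cost bundle
  res <- run_simulation(null_effect_config(), sim_seed = 1)
  expect_equal(res$delta_qaly, 0, tolerance = 1e-12)
  expect_equal(res$delta_cost, 831660 - 220, tolerance = 1e-9)

  # with indirect costs disabled, the ensemble-level incremental cost under
  # full defaults is the discounted treatment bundle up to follow-up noise
  cfg <- small_config(n_sims = 20L)
  ens <- run_monte_carlo(modify_config(cfg, include_indirect = FALSE))
  expect_lt(abs(mean(ens$delta_cost) - (831660 - 220)) / (831660 - 220), 0.01)
})

test_that("engine agrees with the straight-line reference on random patients", {
  for (kind in c("lifetime", "waning")) {
    cfg <- small_config()
    cfg <- modify_config(cfg, scenario = effect_scenario(kind))
    set.seed(77)
    for (i in 1:10) {
      pat <- one_patient(
        age = runif(1, 4, 44), sex = sample(c("female", "male"), 1),
        bcva = runif(1, 0, 2.2), vf = runif(1, 0, 1100),
        onset_age = runif(1, 15, 20), arm = sample(c("VN", "SoC"), 1))
      eff <- c(rnorm(1, -0.163, 0.336), rnorm(1, 302.1, 289.6),
               rnorm(1, -0.312, 0.097), rnorm(1, -76.7, 258.7))
      u <- runif(1)
      traj <- simulate_patient(pat, cfg, draws = list(eff = eff, death_u = u))

      # independent survival walk to resolve the death cycle
      n_alive <- 0
      s <- 1
      repeat {
        q <- annual_death_prob(cfg$life_table, pat$age + n_alive, pat$sex)
        s <- s * (1 - q)
        if (s > u) n_alive <- n_alive + 1 else break
      }
      ref <- reference_patient_totals(pat, cfg, eff, n_alive)
      expect_equal(sum(traj$alive), n_alive)
      expect_equal(sum(traj$disc_qaly), ref$qaly, tolerance = 1e-9)
      expect_equal(sum(traj$disc_cost), ref$cost, tolerance = 1e-9)
    }
  }
})

test_that("ensemble-mean standard error shrinks like one over sqrt(n)", {
  cfg <- scenario_config(cohort = cohort_spec(n_patients = 10L),
                         n_sims = 320L, master_seed = 5L)
  ens <- run_monte_carlo(cfg)
  dq <- ens$delta_qaly
  means10 <- vapply(split(dq, rep(1:32, each = 10)), mean, numeric(1))
  means80 <- vapply(split(dq, rep(1:4, each = 80)), mean, numeric(1))
  # block means of 8x the size should have ~sqrt(8) ~ 2.8x smaller spread
  ratio <- sd(means10) / sd(means80)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 6)
})
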