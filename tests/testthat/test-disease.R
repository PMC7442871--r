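test_that("natural BCVA progression is flat before onset, then linear to cap", {
  p <- progression_params()
  expect_equal(natural_bcva_step(0.987, 10, 17, p), 0.987)
  expect_equal(natural_bcva_step(0.987, 25, 17, p), 1.0306)
  expect_equal(natural_bcva_step(2.3, 90, 17, p), 2.3)
  # closed-form trajectory check: flat until onset, slope 0.0436/yr after
  bcva <- 0.5
  ages <- 10:60
  traj <- numeric(length(ages))
  for (i in seq_along(ages)) {
    traj[i] <- bcva
    bcva <- natural_bcva_step(bcva, ages[i] + 1, 18, p)
  }
  expected <- pmin(0.5 + 0.0436 * pmax(ages - 17, 0), 2.3)
  expect_equal(traj, expected, tolerance = 1e-12)
})

test_that("natural VF loss is linear with a floor at zero", {
  p <- progression_params()
  expect_equal(natural_vf_step(332.9, p), 307.9)
  expect_equal(natural_vf_step(10, p), 0)
  p2 <- progression_params(vf_slope = -24.3)
  expect_equal(natural_vf_step(427.1, p2), 402.8)
})

test_that("first-cycle effects apply the arm-specific deltas with clamping", {
  eff <- trial_effect(bcva_change_sd = c(VN = 0, SoC = 0),
                      vf_change_sd = c(VN = 0, SoC = 0))
  vn <- apply_first_cycle_effect(one_patient(bcva = 1.137, vf = 332.9,
                                             arm = "VN"), eff)
  expect_equal(vn$bcva, 1.137 - 0.163)
  expect_equal(vn$vf, 332.9 + 302.1)
  soc <- apply_first_cycle_effect(one_patient(bcva = 0.987, vf = 427.1,
                                              arm = "SoC"), eff)
  expect_equal(soc$bcva, 0.987 - 0.312)
  expect_equal(soc$vf, 427.1 - 76.7)
  floored <- apply_first_cycle_effect(one_patient(vf = 20, arm = "SoC"), eff)
  expect_equal(floored$vf, 0)
})

test_that("residual effect fraction follows the plateau/exponential/zero form", {
  lifetime <- effect_scenario("lifetime")
  expect_equal(residual_effect_fraction(lifetime, 60), 1)
  waning <- effect_scenario("waning")
  k <- log(20) / 10 # -log(0.05)/10
  expect_equal(residual_effect_fraction(waning, 10), 1)
  expect_equal(residual_effect_fraction(waning, 15), exp(-k * 5))
  expect_equal(residual_effect_fraction(waning, 20), 0.05, tolerance = 1e-12)
  expect_equal(residual_effect_fraction(waning, 21), 0)
  r <- residual_effect_fraction(waning, 1:40)
  expect_true(all(diff(r) <= 0))
  expect_true(all(r >= 0 & r <= 1))
  expect_error(residual_effect_fraction(waning, 0.5), ">= 1")
})

test_that("treated_state blends frozen and shadow states componentwise", {
  p <- progression_params()
  frozen <- list(bcva = 0.9, vf = 600)
  shadow <- list(bcva = 1.5, vf = 100)
  expect_equal(treated_state(frozen, shadow, 1, p), frozen)
  expect_equal(treated_state(frozen, shadow, 0, p), shadow)
  mid <- treated_state(frozen, shadow, 0.5, p)
  expect_equal(mid$vf, 350)
  expect_equal(mid$bcva, 1.2)
})

test_that("utility is linear, anchored and monotone in both arguments", {
  u <- utility_params()
  expect_equal(state_utility(-0.3, 1200, u), 0.85)
  expect_equal(state_utility(2.3, 0, u), 0.40)
  expect_equal(state_utility(0.987, 427.1, u),
               0.40 + 0.45 * (0.5 * (2.3 - 0.987) / 2.3 + 0.5 * 0.4271),
               tolerance = 1e-12)
  grid_b <- seq(-0.3, 2.3, length.out = 40)
  grid_v <- seq(0, 1100, length.out = 40)
  for (v in c(0, 300, 1000)) {
    expect_true(all(diff(state_utility(grid_b, v, u)) <= 0))
  }
  for (b in c(0, 1, 2.3)) {
    expect_true(all(diff(state_utility(b, grid_v, u)) >= 0))
  }
  vals <- outer(grid_b, grid_v, state_utility, u = u)
  expect_true(all(vals >= 0.40 & vals <= 0.85))
})

test_that("SoC trajectories with zero SDs follow the closed form", {
  cfg <- deterministic_config(age = 20, onset = c(18, 18))
  pat <- one_patient(age = 20, bcva = 0.987, vf = 427.1, onset_age = 18,
                     arm = "SoC")
  traj <- simulate_patient(pat, cfg,
                           draws = list(eff = c(-0.163, 302.1, -0.312, -76.7),
                                        death_u = 0))
  alive <- traj[traj$alive, ]
  t <- alive$cycle
  # year 1 applies the SoC deltas; natural slopes from cycle 2 onward
  expect_equal(alive$bcva,
               pmin(0.987 - 0.312 + 0.0436 * (t - 1), 2.3), tolerance = 1e-12)
  expect_equal(alive$vf,
               pmax(427.1 - 76.7 - 25 * (t - 1), 0), tolerance = 1e-12)
})

test_that("waning states stay between shadow and frozen visual function", {
  cfg <- deterministic_config(scenario = effect_scenario("waning"))
  set.seed(5)
  for (i in 1:10) {
    pat <- one_patient(age = runif(1, 5, 40), bcva = runif(1, 0.3, 1.8),
                       vf = runif(1, 0, 900), onset_age = runif(1, 15, 20),
                       arm = "VN")
    eff <- c(rnorm(1, -0.163, 0.336), rnorm(1, 302.1, 289.6),
             rnorm(1, -0.312, 0.097), rnorm(1, -76.7, 258.7))
    traj <- simulate_patient(pat, cfg, draws = list(eff = eff, death_u = 0))
    soc_pat <- pat
    soc_pat$arm <- "SoC"
    shadow <- simulate_patient(soc_pat, cfg,
                               draws = list(eff = eff, death_u = 0))
    a <- traj$alive
    expect_true(all(traj$vf[a] >= shadow$vf[a] - 1e-9 |
                      traj$vf[a] >= pmin(shadow$vf[a], traj$vf[1]) - 1e-9))
    frozen_b <- traj$bcva[1]
    expect_true(all(traj$bcva[a] <= pmax(shadow$bcva[a], frozen_b) + 1e-9))
    expect_true(all(traj$bcva[a] >= pmin(shadow$bcva[a], frozen_b) - 1e-9))
  }
})

test_that("increasing the VF weight increases base-case incremental QALYs", {
  cfg <- small_config(n_sims = 8L)
  dq <- vapply(seq(0.1, 0.9, by = 0.2), function(w) {
    c2 <- modify_config(cfg, utility = utility_params(w_va = 1 - w))
    mean(run_monte_carlo(c2)$delta_qaly)
  }, numeric(1))
  expect_true(all(diff(dq) > 0))
})
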