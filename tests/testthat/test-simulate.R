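test_that("compiled and reference R integrators agree to machine precision", {
  p <- pac_parameters_optimized()
  for (pair in study_pairs) {
    cond <- pac_study_conditions(pair)
    a <- simulate_pac(p, cond, engine = "cpp")
    b <- simulate_pac(p, cond, engine = "R")
    expect_lt(max(abs(as.matrix(a[, -1]) - as.matrix(b[, -1]))), 1e-12)
  }
})

test_that("trajectory starts at the initial state on a strictly increasing grid", {
  cond <- pac_study_conditions("50/60")
  traj <- simulate_pac(pac_parameters_optimized(), cond)
  expect_equal(traj$time_min[1], 0)
  expect_true(all(diff(traj$time_min) > 0))
  first <- as.numeric(traj[1, c("pac_mM", "pyruvate_mM", "benzaldehyde_mM",
                                "acetaldehyde_mM", "acetoin_mM",
                                "enzyme_pct")])
  expect_equal(first, unname(cond$initial[c("P", "A", "B", "Q", "R", "E")]))
  # the lag node is part of the grid so the branch switches exactly there
  expect_true(any(abs(traj$time_min - 0.42) < 1e-12))
  expect_equal(nrow(sampled_states(traj)), 8)
})

test_that("linear invariants are conserved at every Euler step", {
  p <- pac_parameters_optimized()
  for (pair in study_pairs) {
    traj <- simulate_pac(p, pac_study_conditions(pair))
    bp <- traj$benzaldehyde_mM + traj$pac_mM
    ap <- traj$pyruvate_mM + traj$pac_mM + traj$acetaldehyde_mM +
      2 * traj$acetoin_mM
    expect_lt(max(abs(bp - bp[1])), 1e-9)
    expect_lt(max(abs(ap - ap[1])), 1e-9)
  }
})

test_that("a dead initial system stays at its initial state", {
  p <- pac_parameters_optimized()
  p0 <- kinetic_parameters(V_p = p[["V_p"]], K_b = p[["K_b"]], h = p[["h"]],
                           K_ma = p[["K_ma"]], V_q = p[["V_q"]],
                           V_r = p[["V_r"]], k_d1 = p[["k_d1"]],
                           k_d2 = p[["k_d2"]], k_a = 0, t_lag = 0)
  cond <- reaction_conditions(Ph_b = 250,
                              initial = c(P = 0, A = 36, B = 30, E = 0),
                              t_end = 210, sampling_interval = 30)
  s <- sampled_states(simulate_pac(p0, cond))
  for (cl in c("pac_mM", "acetaldehyde_mM", "acetoin_mM", "enzyme_pct")) {
    expect_true(all(s[[cl]] == s[[cl]][1]))
  }
  expect_true(all(s$pyruvate_mM == 36) && all(s$benzaldehyde_mM == 30))
})

test_that("enzyme activity is exactly constant during the lag period", {
  p <- pac_parameters_optimized()
  pl <- kinetic_parameters(V_p = p[["V_p"]], K_b = p[["K_b"]], h = p[["h"]],
                           K_ma = p[["K_ma"]], V_q = p[["V_q"]],
                           V_r = p[["V_r"]], k_d1 = p[["k_d1"]],
                           k_d2 = p[["k_d2"]], k_a = p[["k_a"]], t_lag = 15)
  traj <- simulate_pac(pl, pac_study_conditions("100/120"))
  pre <- traj$enzyme_pct[traj$time_min < 15]
  expect_true(all(pre == 114))
  post <- traj$enzyme_pct[traj$time_min > 15.5]
  expect_true(all(post < 114))
})

test_that("with constant benzaldehyde the activity approaches its fixed point", {
  # switch off all conversion so B stays constant; the deactivation ODE is
  # then linear with fixed point k_a Ph_b / (k_d1 + k_d2 B)
  p <- kinetic_parameters(V_p = 0, K_b = 1.01e-4, h = 1.94, K_ma = 0.7,
                          V_q = 0, V_r = 0, k_d1 = 5.99e-3, k_d2 = 1.33e-5,
                          k_a = 9.38e-6, t_lag = 0)
  B0 <- 100; Ph_b <- 250
  lambda <- p[["k_d1"]] + p[["k_d2"]] * B0
  floor_E <- p[["k_a"]] * Ph_b / lambda
  t10 <- 10 / lambda
  t_end <- ceiling(t10 / 30) * 30
  cond <- reaction_conditions(Ph_b = Ph_b,
                              initial = c(P = 0, A = 116, B = B0, E = 5),
                              t_end = t_end, sampling_interval = 30)
  s <- sampled_states(simulate_pac(p, cond))
  E_end <- s$enzyme_pct[nrow(s)]
  expect_lt(abs(E_end - floor_E) / floor_E, 0.01)
})

test_that("halving the integration step changes sampled states by less than 0.5%", {
  p <- pac_parameters_optimized()
  for (pair in study_pairs) {
    cond <- pac_study_conditions(pair)
    m1 <- sampled_matrix(simulate_pac(p, cond, step = 0.6))
    m2 <- sampled_matrix(simulate_pac(p, cond, step = 0.3))
    expect_lt(max_rel_dev(m1, m2), 0.005)
  }
})

test_that("Euler trajectories track a high-order adaptive integrator within 1%", {
  p <- pac_parameters_optimized()
  for (pair in study_pairs) {
    cond <- pac_study_conditions(pair)
    eul <- sampled_matrix(simulate_pac(p, cond))
    ora <- ode_oracle(p, cond)
    expect_lt(max_rel_dev(eul, ora), 0.01)
  }
})

test_that("invalid integration grids are rejected", {
  p <- pac_parameters_optimized()
  cond <- pac_study_conditions("30/36")
  expect_error(simulate_pac(p, cond, step = 0),
               class = "packinetics_config_error")
  expect_error(simulate_pac(p, cond, step = 31),
               class = "packinetics_config_error")
  expect_error(simulate_pac(p, cond, step = 0.7),   # does not divide 30
               class = "packinetics_config_error")
})

test_that("severe negative overshoot triggers a step-size warning and clamping", {
  # a huge formation rate with a coarse step overshoots substrate depletion
  p <- kinetic_parameters(V_p = 10, K_b = 1.01e-4, h = 1.94, K_ma = 0.7,
                          V_q = 0, V_r = 0, k_d1 = 0, k_d2 = 0,
                          k_a = 0, t_lag = 0)
  cond <- reaction_conditions(Ph_b = 250,
                              initial = c(P = 0, A = 36, B = 30, E = 100),
                              t_end = 210, sampling_interval = 30)
  expect_warning(traj <- simulate_pac(p, cond, step = 30),
                 class = "packinetics_clamp_warning")
  expect_true(all(as.matrix(traj[, -1]) >= 0))
})
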