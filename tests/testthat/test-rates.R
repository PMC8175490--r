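test_that("PAC formation rate matches direct evaluation and vanishes at zero inputs", {
  p <- pac_parameters_optimized()
  # frozen value from an independent high-precision evaluation of the rate law
  expect_equal(pac_rate(c(A = 116, B = 100, E = 114), p), 3.2984128208164227,
               tolerance = 1e-12)
  expect_identical(pac_rate(c(A = 0, B = 100, E = 114), p), 0)
  expect_identical(pac_rate(c(A = 116, B = 0, E = 114), p), 0)
  expect_identical(pac_rate(c(A = 116, B = 100, E = 0), p), 0)
  expect_error(pac_rate(c(A = NaN, B = 1, E = 1), p),
               class = "packinetics_invalid_argument")
})

test_that("Hill factor saturates: large benzaldehyde recovers the Michaelis limit", {
  p <- pac_parameters_optimized()
  r <- pac_rate(c(A = 116, B = 1e6, E = 114), p)
  limit <- p[["V_p"]] * 114 * 116 / (p[["K_ma"]] + 116)
  expect_lt(abs(r - limit) / limit, 1e-3)
})

test_that("by-product rates follow the decarboxylation/carboligation laws", {
  p <- pac_parameters_optimized()
  r <- byproduct_rates(c(A = 116, Q = 1, E = 114), p)
  # frozen independent arithmetic: V_q A E - V_r A Q E and V_r A Q E
  expect_equal(unname(r["dQ"]), 0.14202576, tolerance = 1e-12)
  expect_equal(unname(r["dR"]), 0.08013744, tolerance = 1e-12)
  expect_equal(unname(byproduct_rates(c(A = 0, Q = 5, E = 80), p)),
               c(0, 0))
  expect_equal(unname(byproduct_rates(c(A = 116, Q = 1, E = 0), p)),
               c(0, 0))
  # algebraic steady state of the acetaldehyde pool at Q = V_q / V_r
  qs <- p[["V_q"]] / p[["V_r"]]
  expect_equal(unname(byproduct_rates(c(A = 50, Q = qs, E = 90), p)["dQ"]),
               0, tolerance = 1e-15)
})

test_that("substrate consumption satisfies the stoichiometric identities exactly", {
  expect_equal(unname(substrate_rates(0.5, 0.1, 0.05)), c(-0.70, -0.50))
  expect_equal(unname(substrate_rates(0, 0, 0)), c(0, 0))
  set.seed(42)
  for (i in 1:25) {
    r <- stats::runif(3, 0, 10)
    s <- substrate_rates(r[1], r[2], r[3])
    expect_equal(s[["dA"]] + r[1] + r[2] + 2 * r[3], 0)
    expect_equal(s[["dB"]] + r[1], 0)
  }
})

test_that("enzyme deactivation has a lag branch and a buffer activation term", {
  p <- pac_parameters_optimized()
  cond <- pac_study_conditions("100/120")
  # inside the lag period the activity is frozen
  expect_identical(enzyme_rate(c(B = 100, E = 114), p, cond, t = 0.2), 0)
  # past the lag: -(k_d1 + k_d2 B) E + k_a Ph_b, frozen independent value
  expect_equal(enzyme_rate(c(B = 100, E = 114), p, cond, t = 1),
               -0.832135, tolerance = 1e-9)
  # pure activation: zero deactivation constants leave k_a * Ph_b
  p0 <- kinetic_parameters(V_p = p[["V_p"]], K_b = p[["K_b"]], h = p[["h"]],
                           K_ma = p[["K_ma"]], V_q = p[["V_q"]],
                           V_r = p[["V_r"]], k_d1 = 0, k_d2 = 0,
                           k_a = 9.38e-6, t_lag = 0.42)
  expect_equal(enzyme_rate(c(B = 100, E = 114), p0, cond, t = 1),
               2.345e-3, tolerance = 1e-12)
  expect_error(enzyme_rate(c(B = 1, E = 1), p, cond, t = -1),
               class = "packinetics_invalid_argument")
})

test_that("assembled derivatives agree with the individual rate laws", {
  p <- pac_parameters_optimized()
  cond <- pac_study_conditions("30/36")
  st <- c(P = 5, A = 30, B = 25, Q = 1, R = 0.5, E = 80)
  d <- pac_derivatives(t = 10, st, p, cond)
  expect_equal(d[["P"]], pac_rate(st, p))
  bp <- byproduct_rates(st, p)
  expect_equal(d[["Q"]], bp[["dQ"]])
  expect_equal(d[["R"]], bp[["dR"]])
  expect_equal(d[["A"]] + d[["P"]] + d[["Q"]] + 2 * d[["R"]], 0)
  expect_equal(d[["B"]] + d[["P"]], 0)
  # before the lag only the enzyme derivative is switched off
  d0 <- pac_derivatives(t = 0.1, st, p, cond)
  expect_identical(d0[["E"]], 0)
  expect_equal(d0[["P"]], d[["P"]])
  # dead system: no enzyme, no activation
  p_noact <- kinetic_parameters(V_p = p[["V_p"]], K_b = p[["K_b"]],
                                h = p[["h"]], K_ma = p[["K_ma"]],
                                V_q = p[["V_q"]], V_r = p[["V_r"]],
                                k_d1 = p[["k_d1"]], k_d2 = p[["k_d2"]],
                                k_a = 0, t_lag = 0)
  dd <- pac_derivatives(t = 10, c(P = 5, A = 30, B = 25, Q = 1, R = 0.5,
                                  E = 0), p_noact, cond)
  expect_true(all(dd == 0))
})
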