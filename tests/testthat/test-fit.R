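truth <- pac_parameters_optimized()
fit_profiles <- list(
  generate_noiseless_profile(truth, pac_study_conditions("30/36")),
  generate_noiseless_profile(truth, pac_study_conditions("100/120"))
)

test_that("starting at the truth terminates immediately with parameters unchanged", {
  fit <- grid_search_fit(fit_profiles, start = truth)
  expect_identical(as.numeric(fit$parameters), as.numeric(truth))
  expect_equal(fit$value, 0)
  expect_true(fit$converged)
  expect_lte(nrow(fit$trace), 1)
})

test_that("the RSS trace is non-increasing and ends at or below the start", {
  # modest perturbation, small budget: checks monotonicity, not recovery
  start <- kinetic_parameters(V_p = truth[["V_p"]] * 3,
                              K_b = truth[["K_b"]], h = truth[["h"]],
                              K_ma = truth[["K_ma"]] * 2,
                              V_q = truth[["V_q"]], V_r = truth[["V_r"]],
                              k_d1 = truth[["k_d1"]] / 2,
                              k_d2 = truth[["k_d2"]], k_a = truth[["k_a"]],
                              t_lag = truth[["t_lag"]])
  ctl <- search_control(max_sweeps = 25, profile_param = NULL)
  fit <- grid_search_fit(fit_profiles, start = start, control = ctl)
  expect_true(all(diff(fit$trace$RSS_T) <= 1e-9))
  expect_lte(fit$value, fit$start_value)
  expect_lt(fit$value, fit$start_value / 10)
})

test_that("fitted parameters respect the bounds; out-of-bounds starts error", {
  start <- kinetic_parameters(V_p = truth[["V_p"]], K_b = truth[["K_b"]],
                              h = 2.9, K_ma = truth[["K_ma"]],
                              V_q = truth[["V_q"]], V_r = truth[["V_r"]],
                              k_d1 = truth[["k_d1"]], k_d2 = truth[["k_d2"]],
                              k_a = truth[["k_a"]], t_lag = truth[["t_lag"]])
  ctl <- search_control(max_sweeps = 10, profile_param = NULL)
  fit <- grid_search_fit(fit_profiles, start = start, control = ctl)
  expect_lte(fit$parameters[["h"]], 3)
  expect_gt(fit$parameters[["h"]], 1)

  bnds <- lapply(as.list(unclass(truth)), function(v) c(v / 1000, v * 1000))
  bnds$V_p <- c(1, 2)   # excludes the starting V_p
  bad <- search_control(max_sweeps = 5, profile_param = NULL, bounds = bnds)
  expect_error(grid_search_fit(fit_profiles, start = truth, control = bad),
               class = "packinetics_config_error")
})

test_that("validation reports near-zero residual at the truth and penalizes corruption", {
  val <- generate_noiseless_profile(truth, pac_study_conditions("50/60"))
  st <- validate_fit(truth, val)
  expect_lt(st$RSS_T, 1e-10)
  expect_equal(st$R2, 1, tolerance = 1e-9)
  corrupt <- unclass(truth)
  corrupt["V_p"] <- corrupt["V_p"] * 10
  st_bad <- validate_fit(do.call(kinetic_parameters, as.list(corrupt)), val)
  expect_gt(st_bad$RSS_T, st$RSS_T)
})

test_that("noisy validation MSE is consistent with the injected noise level", {
  noise <- noise_model(zero_byproducts = FALSE)
  noisy <- generate_noisy_dataset(truth, study_design(pairs = "50/60",
                                                      seed = 11),
                                  noise)[[1]]
  st <- validate_fit(truth, noisy)
  # expected RSS: sum over points of Var(replicate mean) = sd^2 / n_rep
  sim <- sampled_states(simulate_pac(truth, pac_study_conditions("50/60")))
  cols <- c("pac_mM", "pyruvate_mM", "benzaldehyde_mM", "acetaldehyde_mM",
            "acetoin_mM", "enzyme_pct")
  floors <- c(0.1, 0.1, 0.1, 0.1, 0.1, 0.5)
  expected <- 0
  for (j in seq_along(cols)) {
    sdj <- pmax(noise$cv * sim[[cols[j]]], floors[j])
    expected <- expected + sum(sdj^2 / noise$replicates)
  }
  expect_gt(st$RSS_T, 0.4 * expected)
  expect_lt(st$RSS_T, 2.0 * expected)
})

test_that("zero observation errors give zero parameter errors", {
  ctl <- search_control(max_sweeps = 3, profile_param = NULL)
  fit <- grid_search_fit(fit_profiles, start = truth, control = ctl)
  expect_message(fit <- parameter_errors(fit), class = "packinetics_log")
  expect_true(all(fit$std_errors == 0))
  td <- tidy(fit)
  expect_identical(names(td), c("term", "estimate", "std.error"))
})

test_that("parameter errors from noisy data are positive and bootstrap-consistent", {
  noise <- noise_model()
  noisy <- generate_noisy_dataset(truth,
                                  study_design(pairs = c("30/36", "100/120"),
                                               seed = 5), noise)
  ctl <- search_control(max_sweeps = 120, profile_param = NULL)
  fit <- grid_search_fit(noisy, start = truth, control = ctl)
  fit <- parameter_errors(fit, refit_sweeps = 200)
  expect_true(all(fit$std_errors >= 0))
  expect_true(fit$std_errors[["V_p"]] > 0)

  # parametric bootstrap oracle. The +/- SE half-range scheme responds to a
  # coherent shift of all observations, so it is only commensurable with the
  # bootstrap spread for constants whose uncertainty is noise-dominated
  # rather than driven by the V_p/K_ma compensation valley.
  n_boot <- 12
  idx <- c(V_q = 5, V_r = 6, k_d2 = 8, k_a = 9)
  boots <- matrix(NA_real_, n_boot, length(idx),
                  dimnames = list(NULL, names(idx)))
  for (b in seq_len(n_boot)) {
    ds <- generate_noisy_dataset(truth,
                                 study_design(pairs = c("30/36", "100/120"),
                                              seed = 100 + b), noise)
    fb <- grid_search_fit(ds, start = truth,
                          control = search_control(max_sweeps = 60,
                                                   profile_param = NULL))
    boots[b, ] <- as.numeric(fb$parameters)[idx]
  }
  for (nm in colnames(boots)) {
    ratio <- fit$std_errors[[nm]] / stats::sd(boots[, nm])
    expect_gt(ratio, 1 / 5)
    expect_lt(ratio, 5)
  }
})

test_that("glance summarizes the combined statistics", {
  ctl <- search_control(max_sweeps = 3, profile_param = NULL)
  fit <- grid_search_fit(fit_profiles, start = truth, control = ctl)
  g <- glance(fit)
  expect_equal(g$n_profiles, 2)
  expect_equal(g$RSS_T, 0)
  expect_equal(g$R2, 1)
})
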