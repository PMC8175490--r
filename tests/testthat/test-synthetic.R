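truth <- pac_parameters_optimized()

test_that("noiseless profiles equal the sampled trajectory on the study grid", {
  cond <- pac_study_conditions("100/120")
  prof <- generate_noiseless_profile(truth, cond)
  expect_equal(prof$time_min, seq(0, 210, by = 30))
  expect_equal(nrow(prof), 8)
  s <- sampled_states(simulate_pac(truth, cond))
  for (cl in c("pac_mM", "pyruvate_mM", "benzaldehyde_mM",
               "acetaldehyde_mM", "acetoin_mM", "enzyme_pct")) {
    expect_identical(prof[[cl]], s[[cl]])
    expect_true(all(prof[[paste0(cl, "_se")]] == 0))
  }
  # and it tracks the adaptive-integrator oracle within 1% at the end point
  ora <- ode_oracle(truth, cond)
  expect_lt(abs(prof$pac_mM[8] - ora[8, "P"]) / ora[8, "P"], 0.01)
})

test_that("the noisy generator is a pure function of its seed", {
  ds1 <- generate_noisy_dataset(truth, study_design(seed = 42))
  ds2 <- generate_noisy_dataset(truth, study_design(seed = 42))
  expect_identical(ds1, ds2)
  ds3 <- generate_noisy_dataset(truth, study_design(seed = 43))
  expect_false(identical(ds1, ds3))
  expect_named(ds1, c("30/36", "50/60", "100/120"))
})

test_that("zero noise reproduces the noiseless profile exactly", {
  design <- study_design(pairs = "50/60", seed = 1)
  ds <- generate_noisy_dataset(truth, design,
                               noise_model(cv = 0, floor_conc = 0,
                                           floor_enzyme = 0,
                                           zero_byproducts = FALSE))
  ref <- generate_noiseless_profile(truth, pac_study_conditions("50/60"))
  for (cl in c("pac_mM", "pyruvate_mM", "benzaldehyde_mM", "enzyme_pct")) {
    expect_equal(ds[[1]][[cl]], ref[[cl]])
  }
})

test_that("replicate noise has the configured coefficient of variation", {
  # benzaldehyde starts at exactly 100 mM in the 100/120 pair; with CV 2%
  # and no floor the replicate sd there should be near 2 mM
  ds <- generate_noisy_dataset(truth,
                               study_design(pairs = "100/120", seed = 202),
                               noise_model(cv = 0.02, floor_conc = 0,
                                           floor_enzyme = 0,
                                           replicates = 1000,
                                           truncate_at_zero = FALSE))
  sd_B0 <- ds[[1]]$benzaldehyde_mM_se[1] * sqrt(1000)
  expect_gt(sd_B0, 1.8)
  expect_lt(sd_B0, 2.2)
})

test_that("standard errors shrink as one over the square root of replicates", {
  d5 <- generate_noisy_dataset(truth, study_design(pairs = "30/36", seed = 9),
                               noise_model(replicates = 5,
                                           zero_byproducts = FALSE))[[1]]
  d500 <- generate_noisy_dataset(truth, study_design(pairs = "30/36", seed = 9),
                                 noise_model(replicates = 500,
                                             zero_byproducts = FALSE))[[1]]
  se5 <- mean(as.matrix(d5[, grepl("_se$", names(d5))]))
  se500 <- mean(as.matrix(d500[, grepl("_se$", names(d500))]))
  ratio <- se5 / se500
  expect_gt(ratio, 10 * 0.8)
  expect_lt(ratio, 10 * 1.2)
})

test_that("by-product observations are zeroed when detection-limit emulation is on", {
  ds <- generate_noisy_dataset(truth, study_design(pairs = "100/120", seed = 3),
                               noise_model(zero_byproducts = TRUE))[[1]]
  expect_true(all(ds$acetaldehyde_mM == 0))
  expect_true(all(ds$acetoin_mM == 0))
  ds2 <- generate_noisy_dataset(truth, study_design(pairs = "100/120", seed = 3),
                                noise_model(zero_byproducts = FALSE))[[1]]
  expect_gt(max(ds2$acetaldehyde_mM), 0)
})

test_that("custom condition pairs are parsed and use the design enzyme range", {
  design <- study_design(pairs = "80/96", seed = 21)
  ds <- generate_noisy_dataset(truth, design)
  cond <- profile_conditions(ds[[1]])
  expect_equal(unname(cond$initial[["B"]]), 80)
  expect_equal(unname(cond$initial[["A"]]), 96)
  E0 <- cond$initial[["E"]]
  expect_gte(E0, 89); expect_lte(E0, 114)
})
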