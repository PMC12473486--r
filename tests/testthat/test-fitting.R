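test_that("objective is zero at the truth, positive away from it, and a plain SSR", {
  prot <- dip_protocol(20, 100)
  par <- fixture_kinetic_params(fx, "dipyridamole", 20, 100)
  drug <- dip_drug()
  ds <- generate_bechecker_dataset(par, prot, drug, use_fmol = TRUE,
                                   use_fmic = TRUE)
  s0 <- fit_objective(par, ds, prot, drug, use_fmol = TRUE, use_fmic = TRUE)
  expect_lt(s0, 1e-10 * prot$dose^2)

  up <- kinetic_params(par$z_gastric * 1.1, par$z_intestinal, par$k0, par$X,
                       precipitation_enabled = TRUE)
  expect_gt(fit_objective(up, ds, prot, drug, use_fmol = TRUE, use_fmic = TRUE),
            s0)

  # two-point toy series with residuals 1 and 2 mg -> SSR 5
  toy_par <- kinetic_params(0, 0)
  toy <- observed_dataset(c(1, 2, 3, 4), c(0, 0, 1, 2), dose = 20)
  expect_equal(fit_objective(toy_par, toy, met_protocol(), met_drug()), 5)
})

test_that("fit is invariant to observation order via its dataset contract", {
  # the dataset constructor enforces increasing times, so order cannot leak in
  expect_error(observed_dataset(c(2, 1, 3, 4), c(1, 1, 1, 1), dose = 20),
               "increasing")
  expect_error(observed_dataset(c(1, 2, 3, 4), c(1, 1, 1, 30), dose = 20),
               "dose")
})

test_that("noiseless synthetic data refits to the generating z factors", {
  prot <- dip_protocol(10, 100)
  truth <- fixture_kinetic_params(fx, "dipyridamole", 10, 100)
  drug <- dip_drug()
  ds <- generate_bechecker_dataset(truth, prot, drug, use_fmol = TRUE,
                                   use_fmic = TRUE)
  fit <- fit_bechecker_params(ds, prot, drug, mode = "with_precipitation",
                              n_starts = 8, seed = 11, use_fmol = TRUE,
                              use_fmic = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(fit$params$z_gastric - truth$z_gastric) / truth$z_gastric,
            0.01)
  # the intestinal z of this condition is indistinguishable from zero: the
  # donor is supersaturated after the phase switch, so the dissolution term
  # is inactive and the objective is flat in z_intestinal
  zeroed <- kinetic_params(fit$params$z_gastric, 1e-16, fit$params$k0,
                           fit$params$X, precipitation_enabled = TRUE)
  expect_equal(fit_objective(zeroed, ds, prot, drug, use_fmol = TRUE,
                             use_fmic = TRUE),
               fit$ssr, tolerance = 1e-6)
  expect_lte(fit$ssr, 1e-8 * prot$dose^2)
})

test_that("best fit beats the +/-1 percent perturbed truth on noiseless data", {
  prot <- met_protocol()
  truth <- fixture_kinetic_params(fx, "metoprolol", 10, 100)
  drug <- met_drug()
  ds <- generate_bechecker_dataset(truth, prot, drug)
  fit <- fit_bechecker_params(ds, prot, drug, mode = "dissolution_only",
                              n_starts = 6, seed = 3)
  for (s in c(0.99, 1.01)) {
    pert <- kinetic_params(truth$z_gastric * s, truth$z_intestinal * s)
    expect_lte(fit$ssr, fit_objective(pert, ds, prot, drug))
  }
})

test_that("degenerate all-zero data drives the z estimates to the lower bounds", {
  prot <- met_protocol()
  ds <- observed_dataset(c(5, 15, 30, 60, 90, 120), rep(0, 6), dose = prot$dose)
  fit <- fit_bechecker_params(ds, prot, met_drug(), mode = "dissolution_only",
                              n_starts = 4, seed = 5)
  expect_true("log10_zg" %in% fit$bounds_hit)
  expect_equal(fit$ssr, 0, tolerance = 1e-12)
})

test_that("withholding the permeated series does not degrade the dissolved fit", {
  prot <- dip_protocol(20, 200)
  truth <- fixture_kinetic_params(fx, "dipyridamole", 20, 200)
  drug <- dip_drug()
  full <- generate_bechecker_dataset(truth, prot, drug, use_fmol = TRUE,
                                     use_fmic = TRUE)
  donor_only <- observed_dataset(full$times, full$dissolved_obs,
                                 dose = prot$dose)
  fit <- fit_bechecker_params(donor_only, prot, drug,
                              mode = "with_precipitation", n_starts = 8,
                              seed = 7, use_fmol = TRUE, use_fmic = TRUE)
  expect_lt(abs(fit$params$z_gastric - truth$z_gastric) / truth$z_gastric,
            0.02)
})
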