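test_that("noiseless generation equals the simulator at the sample times", {
  prot <- met_protocol()
  par <- fixture_kinetic_params(fx, "metoprolol", 10, 100)
  ds <- generate_bechecker_dataset(par, prot, met_drug())
  tc <- simulate_bechecker(prot, met_drug(), par, dt = 0.05)
  expect_equal(ds$dissolved_obs,
               approx(tc$time_min, tc$dissolved_mg, ds$times)$y)
  expect_equal(ds$permeated_obs,
               approx(tc$time_min, tc$permeated_mg, ds$times)$y)
})

test_that("the same seed reproduces the identical dataset and noise shrinks to zero", {
  prot <- met_protocol()
  par <- fixture_kinetic_params(fx, "metoprolol", 10, 100)
  n1 <- noise_model("multiplicative_lognormal", 0.05, seed = 42)
  a <- generate_bechecker_dataset(par, prot, met_drug(), noise = n1)
  b <- generate_bechecker_dataset(par, prot, met_drug(), noise = n1)
  expect_identical(a$dissolved_obs, b$dissolved_obs)
  expect_identical(a$permeated_obs, b$permeated_obs)

  clean <- generate_bechecker_dataset(par, prot, met_drug())
  for (cv in c(0.02, 0.001)) {
    noisy <- generate_bechecker_dataset(par, prot, met_drug(),
                                        noise = noise_model("multiplicative_lognormal",
                                                            cv, seed = 42))
    expect_lt(max(abs(noisy$dissolved_obs - clean$dissolved_obs)) /
                max(clean$dissolved_obs), 5 * cv)
  }
})

test_that("generation does not perturb the caller's random stream", {
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_bechecker_dataset(
    fixture_kinetic_params(fx, "metoprolol", 10, 100), met_protocol(),
    met_drug(), noise = noise_model("multiplicative_lognormal", 0.1, seed = 1)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("dialysis curves round-trip the generating permeability", {
  ds <- generate_dialysis_dataset(2.27e-4, SA = 7.6, C0 = 100)
  expect_equal(apparent_permeability(ds), 2.27e-4, tolerance = 1e-12)

  flat <- generate_dialysis_dataset(0, SA = 7.6, C0 = 100)
  expect_true(all(flat$permeated_amounts == 0))

  lagged <- generate_dialysis_dataset(2.27e-4, SA = 7.6, C0 = 100,
                                      lag = 300,
                                      linear_window = c(600, 7200))
  expect_equal(apparent_permeability(lagged), 2.27e-4, tolerance = 1e-12)
})

test_that("fixture library transcribes the published constants", {
  f <- builtin_fixtures()
  expect_equal(f$solubility$dipyridamole[["FaSSGF_pH1.6"]], 11.16)
  expect_equal(f$solubility$dipyridamole[["FaSSIF_pH6.5"]], 0.0118)
  z <- fixture_kinetic_params(f, "metoprolol", 10, 200)
  expect_equal(z$z_gastric, 2.89e-3)
  d <- fixture_kinetic_params(f, "dipyridamole", 20, 50)
  expect_equal(d$X, 10.8)
  expect_equal(d$k0, 2.64e-2)
  expect_equal(f$physiology$GER, 2.8)
  expect_equal(f$disposition$metoprolol$V1, 331432)
  expect_equal(f$disposition$dipyridamole$K21, 1.34)
  expect_equal(f$precipitation_model2$k0_per_h, 1.803e-3)
  expect_equal(f$observed_pk$dipyridamole$Cmax, 2.18)
  expect_error(fixture_kinetic_params(f, "metoprolol", 20, 50), "no fitted")
  expect_match(attr(f$z_dipyridamole, "source"), "dipyridamole")
})
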