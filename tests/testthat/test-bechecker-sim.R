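test_that("inert solid and sealed membrane limits behave trivially", {
  prot <- met_protocol()
  drug <- met_drug()
  inert <- simulate_bechecker(prot, drug, kinetic_params(0, 0), dt = 0.05)
  expect_true(all(inert$dissolved_mg == 0))
  expect_true(all(inert$permeated_mg == 0))
  expect_equal(tail(inert$undissolved_mg, 1), prot$dose)

  sealed_drug <- drug_properties("sealed", drug$pKa, drug$Cs_gastric,
                                 drug$Cs_intestinal, drug$Cs_neutral_no_micelle,
                                 Papp = 1e-30, Peff_human = 1e-30)
  sealed <- simulate_bechecker(prot, sealed_drug,
                               kinetic_params(3.54e-4, 2.69e-3), dt = 0.05)
  expect_lt(max(sealed$permeated_mg), 1e-20)
  expect_true(all(diff(sealed$dissolved_mg) >= -1e-12))
})

test_that("mass is conserved and the wetted area is monotone then constant", {
  prot <- dip_protocol(20, 100)
  tc <- simulate_bechecker(prot, dip_drug(),
                           fixture_kinetic_params(fx, "dipyridamole", 20, 100),
                           dt = 0.01, use_fmol = TRUE, use_fmic = TRUE)
  mb <- tc$undissolved_mg + tc$dissolved_mg + tc$precipitated_mg + tc$permeated_mg
  expect_lt(max(abs(mb - prot$dose)), 1e-6 * prot$dose)
  expect_true(all(tc$dissolved_mg >= 0 & tc$precipitated_mg >= 0))

  S <- tc$wetted_area_cm2
  expect_true(all(diff(S) >= -1e-12))
  after <- tc$time_min >= prot$t_infusion
  expect_equal(max(S[after]) - min(S[after]), 0)
  expect_equal(max(S), prot$A_filter_max, tolerance = 1e-9)

  # volume trajectory: V0 + q*min(t, t_infusion)
  expect_equal(tc$volume_mL,
               prot$V0 + prot$q * pmin(tc$time_min, prot$t_infusion))
})

test_that("dissolved amount is non-decreasing without precipitation and unlimited solubility", {
  prot <- met_protocol()
  rich <- drug_properties("rich", 9.51, 1e6, 1e6, 1e6, Papp = 1e-30,
                          Peff_human = 1e-30)
  tc <- simulate_bechecker(prot, rich, kinetic_params(1e-3, 1e-3), dt = 0.05)
  expect_true(all(diff(tc$dissolved_mg) >= -1e-12))
})

test_that("halving the step changes the solution by less than 1e-4 relative", {
  prot <- dip_protocol(20, 100)
  par <- fixture_kinetic_params(fx, "dipyridamole", 20, 100)
  a <- simulate_bechecker(prot, dip_drug(), par, dt = 0.01,
                          use_fmol = TRUE, use_fmic = TRUE)
  b <- simulate_bechecker(prot, dip_drug(), par, dt = 0.005, sample_every = 2,
                          use_fmol = TRUE, use_fmic = TRUE)
  expect_equal(a$time_min, b$time_min)
  for (col in c("dissolved_mg", "permeated_mg", "precipitated_mg"))
    expect_lt(max(abs(a[[col]] - b[[col]])) / max(b[[col]], 1e-12),
              1e-4)
})

test_that("RK4 core agrees with a plain-R explicit-Euler oracle", {
  prot <- dip_protocol(20, 100, t_end = 120)
  par <- fixture_kinetic_params(fx, "dipyridamole", 20, 100)
  drug <- dip_drug()
  rk <- simulate_bechecker(prot, drug, par, dt = 0.01, use_fmol = TRUE,
                           use_fmic = TRUE)
  eu <- euler_bechecker(prot, drug, par, dt = 1e-3, t_end = 5,
                        use_fmol = TRUE, use_fmic = TRUE)
  at <- eu$time_min[eu$time_min %in% seq(0.5, 5, by = 0.5)]
  for (col in c("undissolved_mg", "dissolved_mg", "permeated_mg")) {
    rk_v <- approx(rk$time_min, rk[[col]], at)$y
    eu_v <- eu[[col]][match(at, eu$time_min)]
    expect_lt(max(abs(rk_v - eu_v)) / max(abs(eu_v), 1e-9), 1e-3)
  }
})

test_that("precipitation with inverted solubilities warns instead of failing", {
  prot <- met_protocol()
  expect_warning(
    simulate_bechecker(prot, met_drug(),
                       kinetic_params(1e-3, 1e-3, k0 = 1e-3,
                                      precipitation_enabled = TRUE),
                       dt = 0.05),
    "precipitation")
})

test_that("timecourse CSV round-trips in mg and percent-of-dose forms", {
  prot <- met_protocol()
  tc <- simulate_bechecker(prot, met_drug(),
                           fixture_kinetic_params(fx, "metoprolol", 10, 100),
                           dt = 0.05, sample_every = 100)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_timecourse_csv(tc, f1)
  write_timecourse_csv(tc, f2, percent = TRUE)
  d1 <- read.csv(f1); d2 <- read.csv(f2)
  expect_equal(d1$dissolved_mg / prot$dose * 100, d2$dissolved_pct)
  obs <- read_observed_csv(f1, dose = prot$dose)
  expect_s3_class(obs, "observed_dataset")
  expect_equal(obs$dissolved_obs, d1$dissolved_mg)
  unlink(c(f1, f2))
})
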