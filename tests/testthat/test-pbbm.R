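test_that("gastric emptying flux is first order with the published constant", {
  expect_equal(gastric_emptying_rate(0, 2.8), 0)
  expect_equal(gastric_emptying_rate(100, 2.8), 280)
  expect_equal(log(2) / 2.8, 0.2476, tolerance = 1e-3)  # half-emptying time, h
})

test_that("no permeability means no plasma exposure", {
  drug <- drug_properties("blocked", 9.51, 20, 20, 20, Papp = 1e-30,
                          Peff_human = 1e-30)
  prof <- simulate_pbbm(drug, kinetic_params(1e-3, 1e-3), physiology_config(),
                        met_dispo(20), precipitation_model("none"),
                        dose = 20, t_end = 12, dt = 0.05)
  expect_lt(max(prof$conc), 1e-12)
  expect_lt(prof$fa_final, 1e-12)
})

test_that("instantaneous absorption approaches the oral-bolus closed form", {
  fast <- drug_properties("fast", 9.51, 1e4, 1e4, 1e4, Papp = 1, Peff_human = 1)
  dispo <- met_dispo(20)
  prof <- simulate_pbbm(fast, kinetic_params(10, 10), physiology_config(),
                        dispo, precipitation_model("none"), dose = 20,
                        t_end = 36, dt = 0.01, conc_unit = "ng/mL")
  expect_equal(prof$fa_final, 1, tolerance = 1e-5)
  auc_closed <- dispo$FgFh * 20 / (dispo$V1 * dispo$K10) * 1e6  # ng*h/mL
  expect_equal(nca(prof)$AUC_inf, auc_closed, tolerance = 0.005)
})

test_that("gastrointestinal mass balance holds to 1e-6 of the dose", {
  for (cond in list(c(10, 50), c(30, 200))) {
    par <- fixture_kinetic_params(fx, "dipyridamole", cond[1], cond[2])
    prof <- simulate_pbbm(dip_drug(), par, physiology_config(), dip_dispo(),
                          precipitation_model("model1"), dose = 100,
                          t_end = 48, dt = 0.02)
    expect_lt(max(abs(pbbm_mass_balance(prof) - 100)), 1e-6 * 100)
  }
})

test_that("fraction absorbed is monotone in z factors and permeability", {
  run_fa <- function(zg = 2e-3, zi = 1e-4, peff = 2e-4) {
    drug <- drug_properties("sweep", 9.51, 11.16, 0.0118, 0.0118,
                            Papp = peff, Peff_human = peff)
    simulate_pbbm(drug, kinetic_params(zg, zi), physiology_config(),
                  dip_dispo(), precipitation_model("none"), dose = 100,
                  t_end = 24, dt = 0.05)$fa_final
  }
  expect_true(all(diff(sapply(c(5e-4, 2e-3, 8e-3), function(z) run_fa(zg = z))) > 0))
  expect_true(all(diff(sapply(c(1e-5, 1e-4, 1e-3), function(z) run_fa(zi = z))) > 0))
  expect_true(all(diff(sapply(c(5e-5, 2e-4, 8e-4), function(p) run_fa(peff = p))) > 0))
})

test_that("1-compartment AUC equals FgFh * Fa * dose / CL", {
  par <- fixture_kinetic_params(fx, "metoprolol", 10, 100)
  dispo <- met_dispo(20)
  prof <- simulate_pbbm(met_drug(), par, physiology_config(), dispo,
                        precipitation_model("none"), dose = 20, t_end = 36,
                        dt = 0.01, conc_unit = "ng/mL")
  auc_sim <- nca(prof)$AUC_inf
  auc_th <- dispo$FgFh * prof$fa_final * 20 / (dispo$V1 * dispo$K10) * 1e6
  expect_equal(auc_sim, auc_th, tolerance = 0.005)
})

test_that("two-compartment disposition matches the matrix-exponential bolus solution", {
  skip_if_not_installed("Matrix")
  dispo <- dip_dispo(FgFh = 1)
  A <- matrix(c(-(dispo$K10 + dispo$K12), dispo$K21,
                dispo$K12, -dispo$K21), 2, 2, byrow = TRUE)
  ts <- seq(0, 24, by = 0.5)
  sim <- simulate_disposition(dispo = dispo, bolus = 50, times = ts)
  expm_conc <- sapply(ts, function(t)
    (as.matrix(Matrix::expm(A * t)) %*% c(50, 0))[1, 1] / dispo$V1 * 1e3)
  expect_equal(sim$conc, expm_conc, tolerance = 1e-8)
})

test_that("disposition of a zero input is zero and of a rate profile is linear", {
  dispo <- met_dispo(20)
  ts <- seq(0, 10, by = 0.1)
  zero <- simulate_disposition(data.frame(time_h = ts, rate_mg_h = 0), dispo)
  expect_true(all(zero$conc == 0))
  inp <- data.frame(time_h = ts, rate_mg_h = ifelse(ts < 2, 5, 0))
  one <- simulate_disposition(inp, dispo)
  two <- simulate_disposition(transform(inp, rate_mg_h = 2 * rate_mg_h), dispo)
  expect_equal(two$conc, 2 * one$conc)

  # 1-cpt bolus textbook form: C(t) = D/V1 * exp(-K10 t)
  bol <- simulate_disposition(dispo = disposition_params(1, dispo$V1, dispo$K10),
                              bolus = 20, times = ts, conc_unit = "ng/mL")
  expect_equal(bol$conc, 20 / dispo$V1 * exp(-dispo$K10 * ts) * 1e6,
               tolerance = 1e-10)
})

test_that("disabling precipitation equals model1 with k0 = 0", {
  par0 <- kinetic_params(1.79e-2, 0, k0 = 0, X = 0, precipitation_enabled = TRUE)
  a <- simulate_pbbm(dip_drug(), par0, physiology_config(), dip_dispo(),
                     precipitation_model("model1"), dose = 100, t_end = 24,
                     dt = 0.05)
  b <- simulate_pbbm(dip_drug(), par0, physiology_config(), dip_dispo(),
                     precipitation_model("none"), dose = 100, t_end = 24,
                     dt = 0.05)
  expect_equal(a$conc, b$conc)
})

test_that("first-pass back-calculation is consistent with its own inputs", {
  fp <- dipyridamole_first_pass(fx)
  expect_equal(fp$F_oral, 1.16 * 14677 * 4.25 / 1e5)
  expect_equal(fp$FgFh, fp$F_oral / fp$Fa_ref)
  expect_true(fp$FgFh > fp$F_oral && fp$FgFh <= 1)
})
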