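test_that("ionization follows the Henderson-Hasselbalch curve for a base", {
  expect_equal(fraction_unionized(6.3, 6.3), 0.5)
  expect_equal(fraction_unionized(6.5, 6.3), 1 / (1 + 10^(-0.2)))
  expect_equal(fraction_unionized(6.5, 6.3), 0.6131, tolerance = 1e-4)
  expect_equal(fraction_unionized(1.6, 6.3), 1 / (1 + 10^4.7))
  expect_equal(fraction_unionized(1.6, 6.3), 1.995e-5, tolerance = 1e-3)
  expect_error(fraction_unionized(-1, 6.3), "pH")

  # strictly increasing in pH, and 10^dpH behavior far from the pKa
  pH <- seq(0, 14, by = 0.25)
  expect_true(all(diff(fraction_unionized(pH, 7)) > 0))
  lo <- fraction_unionized(5, 7); hi <- fraction_unionized(9, 7)
  odds <- function(f) f / (1 - f)
  expect_equal(odds(hi) / odds(lo), 1e4, tolerance = 1e-9)
})

test_that("micelle-free fraction is the solubility ratio with guarded inputs", {
  expect_equal(free_fraction_micelle(0.0118, 0.0118), 1)
  expect_equal(free_fraction_micelle(0.0043, 0.0118), 0.3644, tolerance = 1e-3)
  expect_equal(free_fraction_micelle(0.0059, 0.0118), 0.5)
  expect_error(free_fraction_micelle(0.02, 0.0118), "inconsistent")
  expect_error(free_fraction_micelle(-1, 1), "C_minus")
})

test_that("micelle-free fraction ramps linearly over the infusion window", {
  f_end <- free_fraction_micelle(0.0043, 0.0118)
  expect_equal(fmic_timecourse(0, 10, f_end), 1)
  expect_equal(fmic_timecourse(c(10, 25, 1e6), 10, f_end), rep(f_end, 3))
  expect_equal(fmic_timecourse(5, 10, 0.3644), (1 + 0.3644) / 2)
})

test_that("apparent permeability is the window slope over SA * C0", {
  times <- seq(0, 7200, by = 300)
  # 55 ug gained over the 2700 s window used for the slope
  rate <- 55 / 2700
  ds <- dialysis_dataset(times, rate * times, SA = 7.6, C0 = 100,
                         linear_window = c(900, 3600))
  expect_equal(apparent_permeability(ds), 55 / (7.6 * 100 * 2700))
  expect_equal(apparent_permeability(ds), 2.68e-5, tolerance = 1e-3)

  # slope-based: invariant to a constant offset, inversely proportional to C0
  ds_off <- dialysis_dataset(times, rate * times + 12, SA = 7.6, C0 = 100,
                             linear_window = c(900, 3600))
  expect_equal(apparent_permeability(ds_off), apparent_permeability(ds))
  ds_2c <- dialysis_dataset(times, rate * times, SA = 7.6, C0 = 200,
                            linear_window = c(900, 3600))
  expect_equal(apparent_permeability(ds_2c), apparent_permeability(ds) / 2)

  flat <- dialysis_dataset(times, rep(0, length(times)), SA = 7.6, C0 = 100,
                           linear_window = c(900, 3600))
  expect_equal(apparent_permeability(flat), 0)
  expect_error(
    apparent_permeability(dialysis_dataset(times, rate * times, 7.6, 100,
                                           c(100, 200))),
    "at least 2")
})

test_that("intrinsic permeability divides out both fractions and round-trips", {
  expect_equal(intrinsic_permeability(2.27e-4, 1, 1), 2.27e-4)
  f_mol <- fraction_unionized(6.5, 6.3)
  f_mic <- free_fraction_micelle(0.0043, 0.0118)
  p_int <- intrinsic_permeability(2.27e-4, f_mol, f_mic)
  expect_equal(p_int, 1.016e-3, tolerance = 1e-3)
  expect_gte(p_int, 2.27e-4)
  expect_equal(p_int * f_mol * f_mic, 2.27e-4)  # exact round trip
  expect_equal(intrinsic_permeability(2.27e-4, f_mol, f_mic / 2), 2 * p_int)
  expect_error(intrinsic_permeability(1e-4, 0, 1), "f_mol")
})

test_that("drug properties validate the micelle-solubility ordering", {
  expect_error(drug_properties("x", 6.3, 10, 0.01, 0.02, 1e-4, 1e-4),
               "micelle")
  d <- dip_drug()
  expect_s3_class(d, "drug_properties")
  expect_output(print(d), "dipyridamole")
})
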