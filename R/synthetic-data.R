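#' Measurement-noise model for synthetic datasets
#'
#' Multiplicative lognormal noise is the default for amount data (amounts
#' are positive with roughly proportional error); additive Gaussian noise is
#' available for series that hover near zero. The same seed always
#' reproduces the same dataset.
#'
#' @param kind `"none"`, `"multiplicative_lognormal"` or `"additive_gaussian"`.
#' @param cv_or_sd Coefficient of variation (multiplicative) or standard
#'   deviation in the data unit (additive).
#' @param seed Integer seed.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "multiplicative_lognormal",
                                 "additive_gaussian"),
                        cv_or_sd = 0, seed = 1L) {
  kind <- match.arg(kind)
  stop_if_not_scalar_number(cv_or_sd, "cv_or_sd", 0)
  structure(list(kind = kind, cv_or_sd = cv_or_sd, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(x, noise) {
  switch(noise$kind,
         none = x,
         multiplicative_lognormal = {
           sdlog <- sqrt(log(1 + noise$cv_or_sd^2))
           x * rlnorm(length(x), meanlog = -sdlog^2 / 2, sdlog = sdlog)
         },
         additive_gaussian = pmax(x + rnorm(length(x), 0, noise$cv_or_sd), 0))
}

#' Default apparatus sampling schedule
#'
#' Densely sampled early (where dissolution and the phase transition act),
#' sparser later, matching common transfer-dissolution sampling practice.
#'
#' @param t_end Horizon, min.
#' @return Sampling times in min.
#' @export
default_sample_times <- function(t_end = 120) {
  t <- c(2, 5, 10, 15, 20, 30, 45, 60, 90, 120)
  t[t <= t_end]
}

#' Generate a noisy apparatus dataset from known kinetic parameters
#'
#' Simulates the transfer-dissolution apparatus, samples the donor dissolved
#' and receiver permeated series at `sample_times`, and applies the noise
#' model (independently to each series). Deterministic given the noise seed;
#' with `kind = "none"` the values equal the simulator output exactly.
#'
#' @param params A [kinetic_params()] (the generating truth).
#' @param protocol A [be_protocol()].
#' @param drug A [drug_properties()].
#' @param sample_times Sampling times, min, within the protocol horizon.
#' @param noise A [noise_model()].
#' @param dt Simulation step, min.
#' @param ... Passed to [simulate_bechecker()].
#' @return An [observed_dataset()] ready for [fit_bechecker_params()].
#' @export
generate_bechecker_dataset <- function(params, protocol, drug,
                                       sample_times = default_sample_times(protocol$t_end),
                                       noise = noise_model("none"),
                                       dt = 0.05, ...) {
  stopifnot(inherits(noise, "noise_model"))
  if (max(sample_times) > protocol$t_end)
    stop("sample_times must lie within the protocol horizon", call. = FALSE)
  tc <- simulate_bechecker(protocol, drug, params, dt = dt, ...)
  sim <- sim_at_times(tc, sample_times)
  vals <- with_preserved_seed(noise$seed, {
    list(dis = apply_noise(sim$dissolved, noise),
         per = apply_noise(sim$permeated, noise))
  })
  observed_dataset(times = sample_times,
                   dissolved_obs = pmin(vals$dis, protocol$dose),
                   permeated_obs = vals$per,
                   dose = protocol$dose,
                   condition_label = sprintf("%gmin_%s", protocol$t_infusion,
                                             protocol$rpm_label))
}

#' Generate a synthetic dialysis-cell permeation curve
#'
#' Cumulative permeated amount growing linearly at `Papp * SA * C0` after an
#' optional lag, with measurement noise. On the noiseless output,
#' [apparent_permeability()] recovers `Papp` exactly when the linear window
#' starts after the lag.
#'
#' @param Papp True apparent permeability, cm/s.
#' @param SA Membrane area, cm^2.
#' @param C0 Initial donor concentration, microgram/mL.
#' @param times Sampling times, s.
#' @param lag Lag before permeation starts, s.
#' @param noise A [noise_model()].
#' @param linear_window Window passed to the dataset (defaults to the span
#'   after the lag).
#' @return A [dialysis_dataset()].
#' @export
generate_dialysis_dataset <- function(Papp, SA, C0, times = seq(0, 7200, 300),
                                      lag = 0, noise = noise_model("none"),
                                      linear_window = c(max(lag, min(times[times > lag])),
                                                        max(times))) {
  stop_if_not_scalar_number(Papp, "Papp", 0)
  stop_if_not_scalar_number(SA, "SA", 0, TRUE)
  stop_if_not_scalar_number(C0, "C0", 0, TRUE)
  amounts <- Papp * SA * C0 * pmax(times - lag, 0)
  amounts <- with_preserved_seed(noise$seed, apply_noise(amounts, noise))
  amounts <- cummax(amounts)  # keep the cumulative series monotone under noise
  dialysis_dataset(times, amounts, SA = SA, C0 = C0,
                   linear_window = linear_window)
}

#' Apparatus protocol for a fixture condition
#'
#' Builds the [be_protocol()] for a (drug, infusion time) condition using
#' printed geometry and the assumed operating volumes of the fixture
#' library; the phase-transition time is the end of infusion for
#' non-precipitating drugs and the (partly assumed) precipitation onset for
#' precipitating drugs.
#'
#' @param fixtures A [builtin_fixtures()] library.
#' @param drug `"metoprolol"` or `"dipyridamole"`.
#' @param infusion_min Infusion duration, min.
#' @param rpm Paddle speed (label only).
#' @param t_end Horizon, min.
#' @return A [be_protocol()].
#' @export
fixture_protocol <- function(fixtures, drug, infusion_min, rpm, t_end = 120) {
  stopifnot(inherits(fixtures, "fixture_library"))
  a <- fixtures$apparatus
  q <- (a$final_volume - a$V0) / infusion_min
  t_trans <- if (drug == "dipyridamole")
    a$precipitation_onset_min[[as.character(infusion_min)]] else infusion_min
  be_protocol(V0 = a$V0, q = q, t_infusion = infusion_min,
              R = a$vessel_radius, A_filter_max = a$A_filter_max,
              t_transition = t_trans, dose = a$dose_mg[[drug]],
              t_end = t_end, rpm_label = as.character(rpm))
}
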