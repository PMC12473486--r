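#' Transfer-dissolution apparatus protocol
#'
#' Geometry and schedule of the two-chamber gastric-to-intestinal transfer
#' apparatus: an initial gastric-medium volume receives a zero-order infusion
#' of concentrated intestinal medium for `t_infusion` minutes, the liquid
#' level rises over the hydrophilic filter that separates donor from the
#' octanol receiver, and the model switches dissolution phase (z factor and
#' solubility) at `t_transition`.
#'
#' `V0` and `q` have no defaults on purpose: they are apparatus operating
#' values that must come from the experiment configuration.
#'
#' @param V0 Initial gastric-medium volume, mL.
#' @param q Infusion rate of the concentrated intestinal medium, mL/min.
#' @param t_infusion Infusion duration, min (10, 20 or 30 in the experiments
#'   modeled here, but any positive value is accepted).
#' @param R Donor vessel radius, cm.
#' @param A_filter_max Full filter area, cm^2; the filter radius is derived
#'   as `sqrt(A_filter_max / pi)`.
#' @param t_filter_contact Time at which the rising liquid first touches the
#'   filter base, min.
#' @param t_transition Gastric-to-intestinal phase switch, min. End of
#'   infusion for drugs without precipitation; observed precipitation onset
#'   for precipitating weak bases.
#' @param dose Dose in the donor chamber, mg.
#' @param t_end Simulation horizon, min.
#' @param rpm_label Paddle-speed label, metadata only (hydrodynamics enter
#'   the model only through the fitted rate constants).
#' @return An object of class `be_protocol`.
#' @export
be_protocol <- function(V0, q, t_infusion, R = 2.3, A_filter_max = 6.6,
                        t_filter_contact = 0, t_transition = t_infusion,
                        dose, t_end = 120, rpm_label = "") {
  stop_if_not_scalar_number(V0, "V0", 0, TRUE)
  stop_if_not_scalar_number(q, "q", 0, TRUE)
  stop_if_not_scalar_number(t_infusion, "t_infusion", 0, TRUE)
  stop_if_not_scalar_number(R, "R", 0, TRUE)
  stop_if_not_scalar_number(A_filter_max, "A_filter_max", 0, TRUE)
  stop_if_not_scalar_number(dose, "dose", 0, TRUE)
  stop_if_not_scalar_number(t_end, "t_end", 0, TRUE)
  if (t_filter_contact < 0 || t_filter_contact > t_transition ||
      t_transition > t_end)
    stop("need 0 <= t_filter_contact <= t_transition <= t_end", call. = FALSE)
  structure(list(V0 = V0, q = q, t_infusion = t_infusion, R = R,
                 r = sqrt(A_filter_max / pi), A_filter_max = A_filter_max,
                 t_filter_contact = t_filter_contact,
                 t_transition = t_transition, dose = dose, t_end = t_end,
                 rpm_label = as.character(rpm_label)),
            class = "be_protocol")
}

#' Formulation-specific kinetic parameters
#'
#' The z-factor dissolution rate constants of the gastric and intestinal
#' phases and, for precipitating weak bases, the two constants of the
#' concentration-dependent precipitation rate `kp = k0 * exp(X * C)`.
#'
#' @param z_gastric,z_intestinal Dissolution rate constants,
#'   mL mg^-1 min^-1.
#' @param k0 Precipitation rate constant at infinite dilution, min^-1.
#' @param X Concentration coefficient of the precipitation rate, mL/mg.
#' @param precipitation_enabled Whether the precipitation process is active
#'   (intestinal phase only; precipitated drug never redissolves).
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(z_gastric, z_intestinal, k0 = 0, X = 0,
                           precipitation_enabled = k0 > 0) {
  stop_if_not_scalar_number(z_gastric, "z_gastric", 0)
  stop_if_not_scalar_number(z_intestinal, "z_intestinal", 0)
  stop_if_not_scalar_number(k0, "k0", 0)
  stop_if_not_scalar_number(X, "X", 0)
  structure(list(z_gastric = z_gastric, z_intestinal = z_intestinal,
                 k0 = k0, X = X,
                 precipitation_enabled = isTRUE(precipitation_enabled)),
            class = "kinetic_params")
}

#' Liquid height above the filter base during infusion
#'
#' The infused volume `q * T` spreads over the donor cross-section
#' `pi * R^2`; the height is capped at `2 r` (filter fully submerged).
#'
#' @param q Infusion rate, mL/min.
#' @param R Donor vessel radius, cm.
#' @param T_elapsed Elapsed time since the liquid first contacted the filter,
#'   min. Vectorized.
#' @param r Filter radius, cm; used only for the cap (default `Inf`, no cap).
#' @return Height in cm.
#' @export
wetted_filter_height <- function(q, R, T_elapsed, r = Inf) {
  if (any(T_elapsed < 0)) stop("elapsed time must be non-negative", call. = FALSE)
  stop_if_not_scalar_number(q, "q", 0, TRUE)
  stop_if_not_scalar_number(R, "R", 0, TRUE)
  pmin(q * T_elapsed / (pi * R^2), 2 * r)
}

#' Wetted area of a circular filter at liquid height h
#'
#' Circular-segment area: `theta = 2 acos(1 - h/r)`,
#' `S = (theta/2) r^2 - (r - h) sqrt(h (2r - h))`. Monotonically increasing
#' from 0 (dry) through `pi r^2 / 2` at half height to `pi r^2` (submerged).
#'
#' @param h Liquid height above the filter base, cm, in `[0, 2r]`. Vectorized.
#' @param r Filter radius, cm.
#' @return Wetted area, cm^2.
#' @export
wetted_filter_area <- function(h, r) {
  stop_if_not_scalar_number(r, "r", 0, TRUE)
  if (any(h < -1e-12) || any(h > 2 * r + 1e-12))
    stop("h must lie within [0, 2r]", call. = FALSE)
  h <- pmin(pmax(h, 0), 2 * r)
  theta <- 2 * acos(1 - h / r)
  theta / 2 * r^2 - (r - h) * sqrt(h * (2 * r - h))
}

#' Noyes-Whitney z-factor dissolution rate
#'
#' `dW/dt = z (W_dis + W_undis)^(1/3) W_undis^(2/3) (Cs - W_dis/V)`, clamped
#' at zero from below: a negative driving force (supersaturation) contributes
#' no dissolution flux, and supersaturation decay is handled exclusively by
#' the precipitation term.
#'
#' @param W_dis Dissolved amount, mg.
#' @param W_undis Undissolved amount, mg.
#' @param Cs Saturation solubility of the current phase, mg/mL.
#' @param V Fluid volume, mL.
#' @param z Dissolution rate constant, mL mg^-1 min^-1.
#' @return Dissolution rate, mg/min (non-negative).
#' @export
dissolution_rate <- function(W_dis, W_undis, Cs, V, z) {
  stopifnot(W_dis >= 0, W_undis >= 0, Cs >= 0, V > 0, z >= 0)
  if (W_undis == 0) return(0)
  rate <- z * (W_dis + W_undis)^(1 / 3) * W_undis^(2 / 3) * (Cs - W_dis / V)
  max(rate, 0)
}

#' Supersaturation-driven precipitation rate of a weak base
#'
#' `dW_pre/dt = kp (C - Cs) V` with the concentration-dependent rate constant
#' `kp = k0 exp(X C)`. Zero at or below saturation; precipitated drug never
#' redissolves.
#'
#' @param C Dissolved concentration, mg/mL.
#' @param Cs Saturation solubility (intestinal phase), mg/mL.
#' @param V Fluid volume, mL.
#' @param k0 Rate constant, min^-1.
#' @param X Concentration coefficient, mL/mg.
#' @return Precipitation rate, mg/min.
#' @export
precipitation_rate <- function(C, Cs, V, k0, X) {
  stopifnot(C >= 0, Cs >= 0, V > 0, k0 >= 0, X >= 0)
  if (C <= Cs) return(0)
  k0 * exp(X * C) * (C - Cs) * V
}

#' Permeation rate through the wetted filter into the octanol receiver
#'
#' `dA/dt = Papp f_mol f_mic S_t (W_dis / V)`, with the permeability given in
#' cm/s and the rate returned in mg/min (factor 60). The receiver is a
#' perfect sink. For drugs without ionization/micelle corrections
#' `f_mol = f_mic = 1`.
#'
#' @param W_dis Dissolved amount in the donor, mg.
#' @param V Donor fluid volume, mL.
#' @param S_t Wetted filter area, cm^2.
#' @param Papp Permeability, cm/s.
#' @param f_mol,f_mic Molecular-form and micelle-free fractions, (0, 1].
#' @return Permeation rate, mg/min.
#' @export
permeation_rate <- function(W_dis, V, S_t, Papp, f_mol = 1, f_mic = 1) {
  stopifnot(W_dis >= 0, V > 0, S_t >= 0, Papp >= 0, f_mol > 0, f_mic > 0)
  Papp * 60 * f_mol * f_mic * S_t * W_dis / V
}

#' Simulate the transfer-dissolution apparatus
#'
#' Integrates the coupled donor/receiver mass balances with fixed-step
#' fourth-order Runge-Kutta: z-factor dissolution with a phase switch at
#' `t_transition`, optional supersaturation-driven precipitation in the
#' intestinal phase, and permeation through the partially wetted filter into
#' a perfect-sink octanol receiver. The donor volume grows as
#' `V0 + q * min(t, t_infusion)`. When ionization/micelle corrections are
#' active, the donor pH ramps linearly from `pH_gastric` to `pH_intestinal`
#' over the infusion window (consistent with the linear treatment of the
#' micelle-free fraction).
#'
#' Mass is exchanged only between the four pools (undissolved, dissolved,
#' precipitated, permeated), so the integrator conserves the dose to
#' round-off at any step size; step size controls accuracy, not balance.
#'
#' @param protocol A [be_protocol()].
#' @param drug A [drug_properties()].
#' @param params A [kinetic_params()].
#' @param dt Integration step, min; must satisfy `dt <= t_infusion / 10`.
#' @param use_fmol,use_fmic Apply the ionization / micelle-free-fraction
#'   corrections to the permeation flux (both off for pH-insensitive drugs).
#' @param pH_gastric,pH_intestinal Donor pH before infusion and after the
#'   intestinal medium is fully established.
#' @param sample_every Output stride in integration steps (1 = every step).
#' @return A data frame of class `be_timecourse` with columns `time_min`,
#'   `undissolved_mg`, `dissolved_mg`, `precipitated_mg`, `permeated_mg`,
#'   `volume_mL`, `wetted_area_cm2`.
#' @export
simulate_bechecker <- function(protocol, drug, params, dt = 0.05,
                               use_fmol = FALSE, use_fmic = FALSE,
                               pH_gastric = 1.6, pH_intestinal = 6.5,
                               sample_every = 1L) {
  stopifnot(inherits(protocol, "be_protocol"),
            inherits(drug, "drug_properties"),
            inherits(params, "kinetic_params"))
  stop_if_not_scalar_number(dt, "dt", 0, TRUE)
  if (dt > protocol$t_infusion / 10 + 1e-12)
    stop("dt must not exceed t_infusion / 10", call. = FALSE)
  if (params$precipitation_enabled && drug$Cs_intestinal >= drug$Cs_gastric)
    warning("precipitation enabled although intestinal solubility is not ",
            "below gastric solubility; the precipitation term will stay inactive")

  fmic_i <- free_fraction_micelle(drug$Cs_neutral_no_micelle, drug$Cs_intestinal)
  out <- .bechecker_rk4_core(
    dose = protocol$dose, V0 = protocol$V0, q = protocol$q,
    t_infusion = protocol$t_infusion, vessel_radius = protocol$R,
    filter_radius = protocol$r, t_filter_contact = protocol$t_filter_contact,
    t_transition = protocol$t_transition, t_end = protocol$t_end, dt = dt,
    z_gastric = params$z_gastric, z_intestinal = params$z_intestinal,
    k0 = params$k0, X = params$X,
    precipitation_enabled = params$precipitation_enabled,
    Cs_gastric = drug$Cs_gastric, Cs_intestinal = drug$Cs_intestinal,
    Papp = drug$Papp, use_fmol = use_fmol, pKa = drug$pKa,
    pH_gastric = pH_gastric, pH_intestinal = pH_intestinal,
    use_fmic = use_fmic, fmic_intestinal = fmic_i,
    sample_stride = as.integer(sample_every))
  if (!all(is.finite(out)))
    stop("non-finite state in apparatus simulation; check parameter scales",
         call. = FALSE)
  res <- as.data.frame(out)
  class(res) <- c("be_timecourse", "data.frame")
  attr(res, "dose") <- protocol$dose
  res
}

#' Write an apparatus time course to CSV
#'
#' @param tc A `be_timecourse` from [simulate_bechecker()].
#' @param path Output path.
#' @param percent Write dissolved/permeated/precipitated as percent of dose
#'   instead of mg.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path, percent = FALSE) {
  stopifnot(inherits(tc, "be_timecourse"))
  d <- data.frame(time_min = tc$time_min, dissolved_mg = tc$dissolved_mg,
                  permeated_mg = tc$permeated_mg,
                  precipitated_mg = tc$precipitated_mg,
                  volume_mL = tc$volume_mL)
  if (percent) {
    dose <- attr(tc, "dose")
    d$dissolved_mg <- NULL; d$permeated_mg <- NULL; d$precipitated_mg <- NULL
    d$dissolved_pct <- 100 * tc$dissolved_mg / dose
    d$permeated_pct <- 100 * tc$permeated_mg / dose
    d$precipitated_pct <- 100 * tc$precipitated_mg / dose
  }
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}
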