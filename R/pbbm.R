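#' Human gastrointestinal physiology configuration
#'
#' Fasted-state physiology of the absorption model: initial gastric and
#' small-intestinal fluid volumes, co-administered water, first-order gastric
#' emptying, small-intestinal residence time, and the effective absorptive
#' surface area. Fluid volumes are floored at their initial values: the
#' stomach relaxes from `V_stomach_init + water_intake` back to
#' `V_stomach_init` as `V0 + water * exp(-GER * t)`, and the small intestine
#' operates at `V_SI_init` (inflow transits through).
#'
#' Small-intestinal residence is modeled as a transit-time delay: material
#' leaves the intestine `SITT` hours after entering it (approximated by an
#' Erlang chain of `n_transit` age stages), while dissolution, precipitation
#' and absorption act on the lumped well-stirred luminal pools. A first-order
#' exit at `1/SITT` would remove dissolvable drug far too early and make the
#' predicted extent of absorption depend on where dissolution happens, which
#' contradicts the transit-time semantics of the parameter.
#'
#' @param V_stomach_init Initial (floor) gastric fluid volume, mL.
#' @param V_SI_init Initial (floor) small-intestinal fluid volume, mL.
#' @param water_intake Water taken with the dose at t = 0, mL.
#' @param GER Gastric emptying rate constant, h^-1; applies identically to
#'   dissolved drug, undissolved drug, and gastric fluid.
#' @param SITT Small-intestinal transit time, h.
#' @param S_abs Effective absorptive surface area, cm^2.
#' @param n_transit Number of Erlang age stages approximating the transit
#'   delay (higher = closer to a sharp delay).
#' @return An object of class `physiology_config`.
#' @export
physiology_config <- function(V_stomach_init = 26, V_SI_init = 43,
                              water_intake = 240, GER = 2.8, SITT = 4,
                              S_abs = 800, n_transit = 7L) {
  for (nm in c("V_stomach_init", "V_SI_init", "water_intake", "GER", "SITT",
               "S_abs"))
    stop_if_not_scalar_number(get(nm), nm, 0, nm != "water_intake")
  n_transit <- as.integer(n_transit)
  if (n_transit < 1L) stop("n_transit must be >= 1", call. = FALSE)
  structure(list(V_stomach_init = V_stomach_init, V_SI_init = V_SI_init,
                 water_intake = water_intake, GER = GER, SITT = SITT,
                 S_abs = S_abs, n_transit = n_transit),
            class = "physiology_config")
}

#' Systemic disposition parameters
#'
#' One- or two-compartment linear disposition with a lumped first-pass
#' availability `FgFh` (gut wall x liver). For the one-compartment model the
#' absorbed amount is multiplied by `FgFh` on entry to the central
#' compartment; for the two-compartment model the central volume is divided
#' by `FgFh` (both conventions scale plasma concentration by `FgFh / V1`).
#'
#' @param n_compartments 1 or 2.
#' @param V1 Central volume of distribution, mL (before any FgFh adjustment).
#' @param K10 Elimination rate constant, h^-1.
#' @param K12,K21 Inter-compartment rate constants, h^-1 (2-compartment only).
#' @param FgFh First-pass availability, (0, 1].
#' @return An object of class `disposition_params`.
#' @export
disposition_params <- function(n_compartments, V1, K10, K12 = NULL, K21 = NULL,
                               FgFh = 1) {
  if (!n_compartments %in% c(1, 2)) stop("n_compartments must be 1 or 2", call. = FALSE)
  stop_if_not_scalar_number(V1, "V1", 0, TRUE)
  stop_if_not_scalar_number(K10, "K10", 0, TRUE)
  stop_if_not_scalar_number(FgFh, "FgFh", 0, TRUE)
  if (FgFh > 1) stop("FgFh must be in (0, 1]", call. = FALSE)
  if (n_compartments == 2) {
    stop_if_not_scalar_number(K12, "K12", 0, TRUE)
    stop_if_not_scalar_number(K21, "K21", 0, TRUE)
  } else {
    K12 <- 0; K21 <- 0
  }
  structure(list(n_compartments = as.integer(n_compartments), V1 = V1,
                 K10 = K10, K12 = K12, K21 = K21, FgFh = FgFh),
            class = "disposition_params")
}

#' Intestinal precipitation model choice
#'
#' `"model1"` uses the apparatus-fitted precipitation constants carried in
#' the [kinetic_params()] (per-minute units, converted internally);
#' `"model2"` uses literature constants from a gastric "dumping" study
#' (`k0` printed per hour); `"none"` disables precipitation.
#'
#' @param model `"model1"`, `"model2"` or `"none"`.
#' @param k0 Rate constant; per minute for model1 (default: taken from the
#'   kinetic parameters), per hour for model2 (default 1.803e-3).
#' @param X Concentration coefficient, mL/mg (model2 default 38.42).
#' @return An object of class `precipitation_model`.
#' @export
precipitation_model <- function(model = c("model1", "model2", "none"),
                                k0 = NULL, X = NULL) {
  model <- match.arg(model)
  if (model == "model2") {
    if (is.null(k0)) k0 <- 1.803e-3
    if (is.null(X)) X <- 38.42
  }
  structure(list(model = model, k0 = k0, X = X), class = "precipitation_model")
}

#' First-order gastric emptying flux
#'
#' `dG/dt = GER * X`, applied identically to dissolved drug, undissolved
#' drug, and gastric fluid.
#'
#' @param amount Amount remaining in the stomach (mg or mL). Vectorized.
#' @param GER Gastric emptying rate constant, h^-1.
#' @return Emptying flux per hour.
#' @export
gastric_emptying_rate <- function(amount, GER) {
  if (any(amount < 0)) stop("amount must be non-negative", call. = FALSE)
  stop_if_not_scalar_number(GER, "GER", 0)
  GER * amount
}

# RHS of the gastrointestinal + disposition ODE system (time unit: hours).
pbbm_rhs <- function(t, y, p) {
  n <- p$n_transit
  St_sol <- y[1]; St_dis <- y[2]
  sol <- y[2 + seq_len(n)]
  dis <- y[2 + n + seq_len(n)]
  pre <- y[2 + 2 * n + seq_len(n)]
  A1 <- y[3 + 3 * n + 2]; A2 <- y[3 + 3 * n + 3]

  Vst <- p$V_st0 + p$water * exp(-p$GER * t)
  Cst <- St_dis / Vst
  dis_st <- if (St_sol > 0)
    p$zg_h * max(St_sol + St_dis, 0)^(1 / 3) * max(St_sol, 0)^(2 / 3) *
      max(p$Cs_g - Cst, 0) else 0
  emp_sol <- p$GER * St_sol
  emp_dis <- p$GER * St_dis

  Ssum <- sum(sol); Dsum <- sum(dis)
  Csi <- Dsum / p$V_si
  dis_si <- if (Ssum > 0)
    p$zi_h * max(Ssum + Dsum, 0)^(1 / 3) * max(Ssum, 0)^(2 / 3) *
      max(p$Cs_i - Csi, 0) else 0
  prec <- if (p$precip && Csi > p$Cs_i)
    min(p$k0_h * exp(min(p$X * Csi, 500)), 1e8) * (Csi - p$Cs_i) * p$V_si else 0
  abs_rate <- p$Peff_h * p$S_abs * Csi

  ktr <- n / p$SITT
  wS <- if (Ssum > 0) sol / Ssum else rep(0, n)
  wD <- if (Dsum > 0) dis / Dsum else rep(0, n)

  dsol <- c(emp_sol, ktr * sol[-n]) - ktr * sol - dis_si * wS
  ddis <- c(emp_dis, ktr * dis[-n]) - ktr * dis - (abs_rate + prec) * wD
  ddis[1] <- ddis[1] + dis_si
  dpre <- c(prec, ktr * pre[-n]) - ktr * pre
  transited <- ktr * (sol[n] + dis[n] + pre[n])

  input <- if (p$one_cpt) p$FgFh * abs_rate else abs_rate
  dA1 <- input - (p$K10 + p$K12) * A1 + p$K21 * A2
  dA2 <- p$K12 * A1 - p$K21 * A2

  list(c(-dis_st - emp_sol, dis_st - emp_dis, dsol, ddis, dpre,
         abs_rate, transited, dA1, dA2))
}

#' Simulate the human oral-absorption PBBM
#'
#' Couples gastric dissolution and first-order emptying, small-intestinal
#' dissolution, optional supersaturation-driven precipitation, and
#' permeability-limited absorption over a fixed effective surface area to a
#' 1- or 2-compartment systemic disposition. The apparatus-fitted z factors
#' (and, for precipitation model 1, `k0` and `X`) are applied unchanged,
#' converted from per-minute to per-hour internally.
#'
#' Drug emptied from the stomach in solution stays in solution in the
#' intestine (supersaturated if above the intestinal solubility), subject
#' only to precipitation; precipitated drug never redissolves. Material that
#' outlives the intestinal residence time leaves unabsorbed.
#'
#' @param drug A [drug_properties()]; `Peff_human` drives absorption.
#' @param params A [kinetic_params()] (per-minute units, as fitted).
#' @param physio A [physiology_config()].
#' @param dispo A [disposition_params()].
#' @param precip A [precipitation_model()].
#' @param dose Dose, mg.
#' @param t_end Horizon, h.
#' @param dt Output resolution, h.
#' @param conc_unit `"ug/mL"` or `"ng/mL"` for the plasma concentrations.
#' @return An object of class `plasma_profile`: list with `times` (h),
#'   `conc`, `conc_unit`, `dose`, `fa_final` (fraction of dose absorbed by
#'   the horizon), and `states` (full state trajectories, for diagnostics).
#' @export
simulate_pbbm <- function(drug, params, physio = physiology_config(),
                          dispo, precip = precipitation_model("none"),
                          dose, t_end = 48, dt = 0.01,
                          conc_unit = c("ug/mL", "ng/mL")) {
  stopifnot(inherits(drug, "drug_properties"),
            inherits(params, "kinetic_params"),
            inherits(physio, "physiology_config"),
            inherits(dispo, "disposition_params"),
            inherits(precip, "precipitation_model"))
  conc_unit <- match.arg(conc_unit)
  stop_if_not_scalar_number(dose, "dose", 0, TRUE)

  k0_h <- switch(precip$model,
                 none = 0,
                 model1 = (if (is.null(precip$k0)) params$k0 else precip$k0) * 60,
                 model2 = precip$k0)  # model2 constants are printed per hour
  X <- switch(precip$model,
              none = 0,
              model1 = if (is.null(precip$X)) params$X else precip$X,
              model2 = precip$X)

  n <- physio$n_transit
  p <- list(n_transit = n, V_st0 = physio$V_stomach_init,
            water = physio$water_intake, V_si = physio$V_SI_init,
            GER = physio$GER, SITT = physio$SITT, S_abs = physio$S_abs,
            zg_h = params$z_gastric * 60, zi_h = params$z_intestinal * 60,
            k0_h = k0_h, X = X, precip = precip$model != "none" && k0_h > 0,
            Cs_g = drug$Cs_gastric, Cs_i = drug$Cs_intestinal,
            Peff_h = drug$Peff_human * 3600,
            one_cpt = dispo$n_compartments == 1L, FgFh = dispo$FgFh,
            K10 = dispo$K10, K12 = dispo$K12, K21 = dispo$K21)

  y0 <- c(dose, 0, rep(0, 3 * n), 0, 0, 0, 0)
  times <- seq(0, t_end, by = dt)
  out <- deSolve::lsoda(y0, times, pbbm_rhs, p, rtol = 1e-8, atol = 1e-10,
                        maxsteps = 100000)
  if (attr(out, "istate")[1] < 0 || !all(is.finite(out)))
    stop("PBBM integration failed (non-finite state or solver error)",
         call. = FALSE)

  nm <- c("stomach_solid", "stomach_dissolved",
          paste0("si_solid_", seq_len(n)), paste0("si_dissolved_", seq_len(n)),
          paste0("si_precip_", seq_len(n)),
          "absorbed", "transited", "central", "peripheral")
  states <- as.data.frame(out)
  names(states) <- c("time_h", nm)

  A1 <- states$central
  conc_mg_ml <- if (dispo$n_compartments == 1L) A1 / dispo$V1
                else A1 / (dispo$V1 / dispo$FgFh)
  scale <- if (conc_unit == "ug/mL") 1e3 else 1e6
  structure(list(times = states$time_h, conc = conc_mg_ml * scale,
                 conc_unit = conc_unit, dose = dose,
                 fa_final = tail(states$absorbed, 1) / dose,
                 states = states),
            class = "plasma_profile")
}

#' @export
print.plasma_profile <- function(x, ...) {
  cat(sprintf("<plasma_profile> dose %.3g mg, %d points over %.3g h, Fa %.3f\n",
              x$dose, length(x$times), max(x$times), x$fa_final))
  cat(sprintf("  Cmax %.4g %s at t %.3g h\n", max(x$conc), x$conc_unit,
              x$times[which.max(x$conc)]))
  invisible(x)
}

#' Linear disposition of an absorption input-rate profile
#'
#' Propagates a piecewise-constant input rate through the 1- or
#' 2-compartment disposition model exactly, interval by interval, using the
#' eigen-decomposition of the rate matrix (no ODE solver error). The FgFh
#' conventions of [disposition_params()] apply.
#'
#' @param input Data frame with columns `time_h` and `rate_mg_h`
#'   (rate held constant from each time to the next), or `NULL` together
#'   with `bolus` for an intravenous-bolus solution.
#' @param dispo A [disposition_params()].
#' @param bolus Optional bolus amount (mg) placed in the central compartment
#'   at t = 0 (bypasses the first-pass scaling; used for disposition-only
#'   analyses).
#' @param times Output times, h (defaults to the input grid).
#' @param conc_unit `"ug/mL"` or `"ng/mL"`.
#' @return Data frame `time_h`, `conc`.
#' @export
simulate_disposition <- function(input = NULL, dispo, bolus = 0,
                                 times = NULL, conc_unit = c("ug/mL", "ng/mL")) {
  stopifnot(inherits(dispo, "disposition_params"))
  conc_unit <- match.arg(conc_unit)
  if (is.null(input) && is.null(times))
    stop("supply an input profile or output times", call. = FALSE)
  if (!is.null(input)) {
    stopifnot(all(c("time_h", "rate_mg_h") %in% names(input)))
    if (any(input$rate_mg_h < 0)) stop("input rates must be non-negative", call. = FALSE)
    if (is.null(times)) times <- input$time_h
  }

  A <- matrix(c(-(dispo$K10 + dispo$K12), dispo$K21,
                dispo$K12, -dispo$K21), 2, 2, byrow = TRUE)
  if (dispo$n_compartments == 1L) A <- matrix(c(-dispo$K10, 0, 0, -1), 2, 2)
  eg <- eigen(A)
  E <- eg$vectors; Einv <- solve(E); lam <- eg$values

  prop <- function(x, u, dt_h) {
    # exact step: x' = A x + b u, u constant over the interval
    if (dt_h == 0) return(x)
    edl <- exp(lam * dt_h)
    hom <- E %*% (edl * (Einv %*% x))
    if (u == 0) return(as.numeric(hom))
    phi <- (edl - 1) / lam  # integral of e^(lam s) ds over the step
    part <- E %*% (phi * (Einv %*% c(u, 0)))
    as.numeric(hom + part)
  }

  grid <- sort(unique(c(0, if (!is.null(input)) input$time_h, times)))
  rate_at <- function(t) {
    if (is.null(input)) return(0)
    i <- findInterval(t, input$time_h)
    if (i < 1) 0 else input$rate_mg_h[i]
  }
  scale_in <- if (dispo$n_compartments == 1L) dispo$FgFh else 1
  x <- c(bolus, 0)
  central <- numeric(length(grid)); central[1] <- x[1]
  for (i in seq_along(grid)[-1]) {
    u <- scale_in * rate_at(grid[i - 1])
    x <- prop(x, u, grid[i] - grid[i - 1])
    central[i] <- x[1]
  }
  V1eff <- if (dispo$n_compartments == 1L) dispo$V1 else dispo$V1 / dispo$FgFh
  conc <- approx(grid, central, times, rule = 2)$y / V1eff
  scale <- if (conc_unit == "ug/mL") 1e3 else 1e6
  data.frame(time_h = times, conc = conc * scale)
}

#' Mass balance of a PBBM simulation
#'
#' Sum of all gastrointestinal pools, cumulative absorbed amount and
#' transited-unabsorbed amount at every output time; equals the dose up to
#' integrator tolerance.
#'
#' @param profile A `plasma_profile` from [simulate_pbbm()].
#' @return Numeric vector (mg) along the output grid.
#' @export
pbbm_mass_balance <- function(profile) {
  s <- profile$states
  gi <- grep("^(stomach_|si_)", names(s))
  rowSums(s[gi]) + s$absorbed + s$transited
}
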