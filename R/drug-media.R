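#' Drug and medium properties
#'
#' Bundles the physicochemical inputs of the transfer-dissolution and PBBM
#' models: saturation solubility in the gastric- and intestinal-phase media,
#' the micelle-free solubility used to estimate the free fraction, the base
#' pKa, and the two permeability coefficients (apparent, from the
#' filter/octanol dialysis system, and effective human intestinal).
#'
#' @param name Drug name (metadata only).
#' @param pKa Basic pKa (monoprotic base). Both model drugs here are bases;
#'   the ionization routine [fraction_unionized()] assumes a base.
#' @param Cs_gastric Saturation solubility in the gastric-phase medium
#'   (FaSSGF-like, pH 1.6), mg/mL.
#' @param Cs_intestinal Saturation solubility in the intestinal-phase medium
#'   (FaSSIF-like, pH 6.5), mg/mL.
#' @param Cs_neutral_no_micelle Saturation solubility in a micelle-free medium
#'   at intestinal pH, mg/mL. Must not exceed `Cs_intestinal` (micelles can
#'   only add solubility). Used by [free_fraction_micelle()].
#' @param Papp Apparent membrane permeability in the hydrophilic
#'   filter/octanol system, cm/s.
#' @param Peff_human Effective human intestinal permeability (or its
#'   unstirred-water-layer-limited value), cm/s.
#' @param molecular_weight Optional, g/mol; reporting only.
#'
#' @return An object of class `drug_properties` (a validated list).
#' @examples
#' dipyridamole <- drug_properties(
#'   name = "dipyridamole", pKa = 6.3,
#'   Cs_gastric = 11.16, Cs_intestinal = 0.0118,
#'   Cs_neutral_no_micelle = 0.0043,
#'   Papp = 2.27e-4, Peff_human = 7.09e-4)
#' @export
drug_properties <- function(name, pKa, Cs_gastric, Cs_intestinal,
                            Cs_neutral_no_micelle = Cs_intestinal,
                            Papp, Peff_human = Papp,
                            molecular_weight = NA_real_) {
  stop_if_not_scalar_number(pKa, "pKa")
  stop_if_not_scalar_number(Cs_gastric, "Cs_gastric", 0, TRUE)
  stop_if_not_scalar_number(Cs_intestinal, "Cs_intestinal", 0, TRUE)
  stop_if_not_scalar_number(Cs_neutral_no_micelle, "Cs_neutral_no_micelle", 0, TRUE)
  stop_if_not_scalar_number(Papp, "Papp", 0, TRUE)
  stop_if_not_scalar_number(Peff_human, "Peff_human", 0, TRUE)
  if (Cs_neutral_no_micelle > Cs_intestinal)
    stop("Cs_neutral_no_micelle must not exceed Cs_intestinal ",
         "(micelles can only increase solubility)", call. = FALSE)
  structure(list(name = as.character(name), pKa = pKa,
                 Cs_gastric = Cs_gastric, Cs_intestinal = Cs_intestinal,
                 Cs_neutral_no_micelle = Cs_neutral_no_micelle,
                 Papp = Papp, Peff_human = Peff_human,
                 molecular_weight = molecular_weight),
            class = "drug_properties")
}

#' @export
print.drug_properties <- function(x, ...) {
  cat(sprintf("<drug_properties> %s (base, pKa %.2f)\n", x$name, x$pKa))
  cat(sprintf("  Cs gastric / intestinal / micelle-free: %.4g / %.4g / %.4g mg/mL\n",
              x$Cs_gastric, x$Cs_intestinal, x$Cs_neutral_no_micelle))
  cat(sprintf("  Papp %.3g cm/s, Peff(human) %.3g cm/s\n", x$Papp, x$Peff_human))
  invisible(x)
}

#' Fraction of a monoprotic base in the non-ionized (molecular) form
#'
#' Henderson-Hasselbalch ionization for a monoprotic base:
#' `f_mol = 1 / (1 + 10^(pKa - pH))`. Strictly increasing in pH; equals 0.5
#' at `pH == pKa`.
#'
#' @param pH Medium pH, in `[0, 14]`. Vectorized.
#' @param pKa Basic pKa.
#' @return Fraction in (0, 1).
#' @examples
#' fraction_unionized(6.5, 6.3)  # 0.613: dipyridamole at intestinal pH
#' @export
fraction_unionized <- function(pH, pKa) {
  if (any(!is.finite(pH)) || any(pH < 0 | pH > 14))
    stop("pH must be within [0, 14]", call. = FALSE)
  stop_if_not_scalar_number(pKa, "pKa")
  1 / (1 + 10^(pKa - pH))
}

#' Fraction of dissolved drug not incorporated into bile-salt micelles
#'
#' Estimated as the ratio of saturation solubilities in a neutral micelle-free
#' medium and a micelle-containing medium at the same pH:
#' `f_mic = C_minus / C_plus`.
#'
#' @param C_minus Solubility in the micelle-free medium, mg/mL.
#' @param C_plus Solubility in the micelle-containing medium, mg/mL.
#' @return Free fraction in (0, 1].
#' @examples
#' free_fraction_micelle(0.0043, 0.0118)  # dipyridamole, ~0.364
#' @export
free_fraction_micelle <- function(C_minus, C_plus) {
  stop_if_not_scalar_number(C_minus, "C_minus", 0, TRUE)
  stop_if_not_scalar_number(C_plus, "C_plus", 0, TRUE)
  if (C_plus < C_minus)
    stop("inconsistent solubilities: micelle-containing medium must dissolve ",
         "at least as much drug as the micelle-free medium", call. = FALSE)
  C_minus / C_plus
}

#' Time course of the micelle-free fraction during medium transfer
#'
#' During the zero-order infusion of concentrated intestinal medium the bile
#' micelle content of the donor fluid rises from zero (gastric medium, where
#' `f_mic = 1`) to its final intestinal-medium value. The free fraction is
#' interpolated linearly over the infusion window and held constant after.
#'
#' @param t Time since infusion start, min. Vectorized.
#' @param t_gastric_end End of the infusion window, min.
#' @param fmic_intestinal Free fraction in the fully established intestinal
#'   medium (see [free_fraction_micelle()]).
#' @return Free fraction in `[fmic_intestinal, 1]`.
#' @export
fmic_timecourse <- function(t, t_gastric_end, fmic_intestinal) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  stop_if_not_scalar_number(t_gastric_end, "t_gastric_end", 0, TRUE)
  stop_if_not_scalar_number(fmic_intestinal, "fmic_intestinal", 0, TRUE)
  if (fmic_intestinal > 1) stop("fmic_intestinal must be <= 1", call. = FALSE)
  frac <- pmin(t / t_gastric_end, 1)
  1 + (fmic_intestinal - 1) * frac
}

#' Dialysis-cell permeation dataset
#'
#' A permeation time course from the equilibrium dialysis cell used to measure
#' apparent permeability: cumulative amount in the octanol receiver versus
#' time, plus the membrane area, initial donor concentration and the window
#' over which permeation is linear.
#'
#' @param times Sampling times, s.
#' @param permeated_amounts Cumulative permeated amounts, micrograms;
#'   non-negative and non-decreasing.
#' @param SA Membrane surface area, cm^2.
#' @param C0 Initial donor concentration, microgram/mL.
#' @param linear_window Length-2 numeric `(t_start, t_end)` in s, within the
#'   observed times, over which the profile is treated as linear.
#' @return An object of class `dialysis_dataset`.
#' @export
dialysis_dataset <- function(times, permeated_amounts, SA, C0, linear_window) {
  if (length(times) != length(permeated_amounts))
    stop("times and permeated_amounts must have equal length", call. = FALSE)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(permeated_amounts < 0) || any(diff(permeated_amounts) < -1e-9 * max(permeated_amounts, 1)))
    stop("permeated_amounts must be non-negative and non-decreasing", call. = FALSE)
  stop_if_not_scalar_number(SA, "SA", 0, TRUE)
  stop_if_not_scalar_number(C0, "C0", 0, TRUE)
  if (length(linear_window) != 2L || linear_window[1] >= linear_window[2])
    stop("linear_window must be (t_start, t_end) with t_start < t_end", call. = FALSE)
  if (linear_window[1] < min(times) || linear_window[2] > max(times))
    stop("linear_window must lie within the observed times", call. = FALSE)
  structure(list(times = as.numeric(times),
                 permeated_amounts = as.numeric(permeated_amounts),
                 SA = SA, C0 = C0, linear_window = as.numeric(linear_window)),
            class = "dialysis_dataset")
}

#' Read a dialysis permeation time course from CSV
#'
#' Expects columns `time_s` and `permeated_ug`; area, donor concentration and
#' the linear window are supplied by the caller (they come from the assay
#' configuration, not the data file).
#'
#' @param path CSV file path.
#' @inheritParams dialysis_dataset
#' @return A [dialysis_dataset()].
#' @export
read_dialysis_csv <- function(path, SA, C0, linear_window) {
  d <- read.csv(path)
  if (!all(c("time_s", "permeated_ug") %in% names(d)))
    stop("CSV must contain columns time_s and permeated_ug", call. = FALSE)
  dialysis_dataset(d$time_s, d$permeated_ug, SA = SA, C0 = C0,
                   linear_window = linear_window)
}

#' Apparent membrane permeability from a dialysis time course
#'
#' The permeated amount grows linearly once a pseudo-steady state is reached;
#' the apparent permeability is the slope of that linear portion normalized by
#' membrane area and initial donor concentration,
#' `Papp = slope / (SA * C0)`. A least-squares slope over the linear window is
#' used rather than a two-point difference; for perfectly linear data the two
#' coincide, and the regression is insensitive to a constant offset (e.g. an
#' initial lag).
#'
#' @param data A [dialysis_dataset()].
#' @return Apparent permeability in cm/s (inputs in micrograms, cm^2,
#'   microgram/mL, s).
#' @export
apparent_permeability <- function(data) {
  stopifnot(inherits(data, "dialysis_dataset"))
  sel <- data$times >= data$linear_window[1] & data$times <= data$linear_window[2]
  if (sum(sel) < 2L)
    stop("linear window must contain at least 2 samples", call. = FALSE)
  slope <- unname(coef(lm(data$permeated_amounts[sel] ~ data$times[sel]))[2])
  slope / (data$SA * data$C0)
}

#' Intrinsic permeability of the free molecular species
#'
#' The measured apparent permeability reflects only the non-ionized,
#' micelle-free species; dividing by both fractions gives the permeability of
#' that species, used when the medium composition (pH, bile micelles) changes
#' over the experiment.
#'
#' @param Papp Apparent permeability, cm/s.
#' @param f_mol Non-ionized fraction in the assay medium, (0, 1].
#' @param f_mic Micelle-free fraction in the assay medium, (0, 1].
#' @return Intrinsic permeability, cm/s; always `>= Papp`.
#' @export
intrinsic_permeability <- function(Papp, f_mol, f_mic) {
  stop_if_not_scalar_number(Papp, "Papp", 0, TRUE)
  stop_if_not_scalar_number(f_mol, "f_mol", 0, TRUE)
  stop_if_not_scalar_number(f_mic, "f_mic", 0, TRUE)
  if (f_mol > 1 || f_mic > 1) stop("fractions must be <= 1", call. = FALSE)
  Papp / (f_mol * f_mic)
}
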