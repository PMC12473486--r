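#' Non-compartmental analysis of a concentration-time profile
#'
#' Cmax and Tmax (earliest time of the maximum), AUC to the last point by
#' the linear trapezoid rule, terminal slope lambda_z by log-linear
#' regression on the terminal points, and
#' `AUC_inf = AUC_last + C_last / lambda_z`.
#'
#' The terminal window starts at the last `n_terminal` points and is extended
#' backwards (never past Tmax) while the adjusted R-squared of the log-linear
#' fit improves. A non-decreasing tail makes lambda_z non-identifiable; then
#' `AUC_inf` is withheld (`NA`).
#'
#' @param profile A `plasma_profile` from [simulate_pbbm()], or a data frame
#'   with columns `time_h` and `conc`.
#' @param n_terminal Minimum number of terminal points (default 3).
#' @return An object of class `nca_result`: list with `Cmax`, `Tmax`,
#'   `AUC_last`, `AUC_inf`, `lambda_z`, `extrapolated_fraction`, `n_terminal`.
#' @export
nca <- function(profile, n_terminal = 3) {
  if (inherits(profile, "plasma_profile")) {
    tm <- profile$times; cc <- profile$conc
  } else {
    stopifnot(all(c("time_h", "conc") %in% names(profile)))
    tm <- profile$time_h; cc <- profile$conc
  }
  if (length(tm) < 3) stop("need at least 3 points", call. = FALSE)
  if (any(diff(tm) <= 0)) stop("times must be strictly increasing", call. = FALSE)

  Cmax <- max(cc)
  imax <- which.max(cc)  # earliest occurrence by definition of which.max
  Tmax <- tm[imax]
  AUC_last <- sum(diff(tm) * (head(cc, -1) + tail(cc, -1)) / 2)

  n <- length(cc)
  fit_lz <- function(k) {
    idx <- seq(n - k + 1, n)
    if (any(cc[idx] <= 0)) return(NULL)
    f <- lm(log(cc[idx]) ~ tm[idx])
    r2 <- suppressWarnings(summary(f)$adj.r.squared)  # exact fits are fine here
    list(lambda = -unname(coef(f)[2]), r2 = r2, k = k)
  }
  best <- fit_lz(min(n_terminal, n - 1))
  if (!is.null(best)) {
    k <- best$k
    while (n - (k + 1) + 1 > imax) {
      cand <- fit_lz(k + 1)
      if (is.null(cand) || cand$r2 <= best$r2) break
      best <- cand; k <- k + 1
    }
  }
  if (is.null(best) || !is.finite(best$lambda) || best$lambda <= 0) {
    lambda_z <- NA_real_; AUC_inf <- NA_real_; extrap <- NA_real_
    n_term <- NA_integer_
  } else {
    lambda_z <- best$lambda
    AUC_inf <- AUC_last + cc[n] / lambda_z
    extrap <- (AUC_inf - AUC_last) / AUC_inf
    n_term <- best$k
  }
  structure(list(Cmax = Cmax, Tmax = Tmax, AUC_last = AUC_last,
                 AUC_inf = AUC_inf, lambda_z = lambda_z,
                 extrapolated_fraction = extrap, n_terminal = n_term),
            class = "nca_result")
}

#' @export
print.nca_result <- function(x, ...) {
  cat(sprintf("<nca> Cmax %.4g at Tmax %.3g h; AUC_last %.4g, AUC_inf %.4g (%.2f%% extrapolated)\n",
              x$Cmax, x$Tmax, x$AUC_last, x$AUC_inf,
              100 * x$extrapolated_fraction))
  invisible(x)
}

#' Percent prediction error
#'
#' `%PE = (predicted - observed) / observed * 100`.
#'
#' @param predicted,observed Values on the same scale; `observed` non-zero.
#' @return Percent error. Vectorized.
#' @export
prediction_error <- function(predicted, observed) {
  if (any(observed == 0)) stop("observed must be non-zero", call. = FALSE)
  (predicted - observed) / observed * 100
}

#' Predict the PK-parameter grid over apparatus conditions
#'
#' Runs the PBBM once per apparatus condition (one set of fitted kinetic
#' parameters each), computes Cmax / Tmax / AUC_inf by [nca()], scores each
#' against the observed values with [prediction_error()], and flags cells
#' with `|PE| <= pe_threshold` for both Cmax and AUC_inf as accurately
#' predicted. If the extrapolated AUC fraction exceeds 5% the simulation is
#' repeated with a doubled horizon so that AUC_inf does not depend on the
#' initial horizon choice.
#'
#' @param condition_params Named list of [kinetic_params()] (or `be_fit`
#'   objects, whose `$params` are taken), one per condition.
#' @param drug A [drug_properties()].
#' @param physio A [physiology_config()].
#' @param dispo A [disposition_params()].
#' @param precip A [precipitation_model()].
#' @param dose Dose, mg.
#' @param observed Named numeric vector with elements `Cmax`, `AUC_inf` and
#'   optionally `Tmax` (observed means).
#' @param t_end Initial simulation horizon, h.
#' @param pe_threshold Accuracy flag threshold in percent (default 15).
#' @param conc_unit Concentration unit for simulation and reporting.
#' @return Data frame with one row per condition: predicted and observed
#'   Cmax/AUC_inf (and Tmax difference when observed Tmax is given), their
#'   percent prediction errors, and the `good` flag.
#' @export
condition_grid_report <- function(condition_params, drug,
                                  physio = physiology_config(), dispo,
                                  precip = precipitation_model("none"),
                                  dose, observed, t_end = 48,
                                  pe_threshold = 15,
                                  conc_unit = c("ug/mL", "ng/mL")) {
  conc_unit <- match.arg(conc_unit)
  stopifnot(length(condition_params) >= 1, !is.null(names(condition_params)))
  rows <- lapply(names(condition_params), function(cond) {
    par <- condition_params[[cond]]
    if (inherits(par, "be_fit")) par <- par$params
    prof <- simulate_pbbm(drug, par, physio, dispo, precip, dose,
                          t_end = t_end, conc_unit = conc_unit)
    res <- nca(prof)
    if (is.finite(res$extrapolated_fraction) &&
        res$extrapolated_fraction > 0.05) {
      prof <- simulate_pbbm(drug, par, physio, dispo, precip, dose,
                            t_end = 2 * t_end, conc_unit = conc_unit)
      res <- nca(prof)
    }
    pe_c <- prediction_error(res$Cmax, observed[["Cmax"]])
    pe_a <- prediction_error(res$AUC_inf, observed[["AUC_inf"]])
    data.frame(condition = cond,
               Cmax_pred = res$Cmax, Cmax_obs = observed[["Cmax"]],
               pe_Cmax = pe_c,
               AUC_pred = res$AUC_inf, AUC_obs = observed[["AUC_inf"]],
               pe_AUC = pe_a,
               Tmax_pred = res$Tmax,
               dTmax = if ("Tmax" %in% names(observed))
                 res$Tmax - observed[["Tmax"]] else NA_real_,
               good = abs(pe_c) <= pe_threshold & abs(pe_a) <= pe_threshold)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Format a grid report as aligned text
#'
#' @param report Output of [condition_grid_report()].
#' @return Character vector of lines (also printed).
#' @export
format_grid_report <- function(report) {
  lines <- c(sprintf("%-14s %10s %9s %10s %9s %6s %5s",
                     "condition", "Cmax_pred", "PE_Cmax", "AUC_pred",
                     "PE_AUC", "dTmax", "good"),
             sprintf("%-14s %10.3g %8.0f%% %10.3g %8.0f%% %6.2f %5s",
                     report$condition, report$Cmax_pred, round(report$pe_Cmax),
                     report$AUC_pred, round(report$pe_AUC), report$dTmax,
                     ifelse(report$good, "yes", "no")))
  cat(lines, sep = "\n")
  invisible(lines)
}
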