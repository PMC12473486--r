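# Shared builders for the test suite. Everything is generated in code; the
# fixture library holds the published constants.

fx <- builtin_fixtures()

met_drug <- function() fixture_drug(fx, "metoprolol")
dip_drug <- function() fixture_drug(fx, "dipyridamole")

met_protocol <- function(t_end = 120)
  fixture_protocol(fx, "metoprolol", 10, 100, t_end = t_end)

dip_protocol <- function(infusion_min = 20, rpm = 100, t_end = 120)
  fixture_protocol(fx, "dipyridamole", infusion_min, rpm, t_end = t_end)

met_dispo <- function(dose = 20)
  disposition_params(1, fx$disposition$metoprolol$V1,
                     fx$disposition$metoprolol$K10,
                     FgFh = fx$disposition$metoprolol$FgFh_by_dose[[as.character(dose)]])

dip_dispo <- function(FgFh = 0.9) {
  d <- fx$disposition$dipyridamole
  disposition_params(2, d$V1, d$K10, d$K12, d$K21, FgFh = FgFh)
}

# Plain-R explicit-Euler integration of the apparatus model, built from the
# exported rate functions; the independent cross-check for the RK4 core.
euler_bechecker <- function(protocol, drug, params, dt, t_end,
                            use_fmol = FALSE, use_fmic = FALSE) {
  n <- round(t_end / dt)
  y <- c(undis = protocol$dose, dis = 0, pre = 0, per = 0)
  out <- matrix(NA_real_, n + 1, 5)
  fmic_i <- free_fraction_micelle(drug$Cs_neutral_no_micelle, drug$Cs_intestinal)
  for (i in 0:n) {
    t <- i * dt
    V <- protocol$V0 + protocol$q * min(t, protocol$t_infusion)
    out[i + 1, ] <- c(t, y)
    if (i == n) break
    gastric <- t < protocol$t_transition
    z <- if (gastric) params$z_gastric else params$z_intestinal
    Cs <- if (gastric) drug$Cs_gastric else drug$Cs_intestinal
    dd <- dissolution_rate(max(y["dis"], 0), max(y["undis"], 0), Cs, V, z)
    C <- y[["dis"]] / V
    pp <- if (params$precipitation_enabled && !gastric)
      precipitation_rate(max(C, 0), drug$Cs_intestinal, V, params$k0, params$X) else 0
    te <- min(t, protocol$t_infusion) - protocol$t_filter_contact
    S <- if (te > 0)
      wetted_filter_area(wetted_filter_height(protocol$q, protocol$R, te,
                                              r = protocol$r), protocol$r) else 0
    frac <- min(t / protocol$t_infusion, 1)
    fmol <- if (use_fmol)
      fraction_unionized(1.6 + (6.5 - 1.6) * frac, drug$pKa) else 1
    fmic <- if (use_fmic) fmic_timecourse(t, protocol$t_infusion, fmic_i) else 1
    pr <- permeation_rate(max(y[["dis"]], 0), V, S, drug$Papp, fmol, fmic)
    y <- y + dt * c(-dd, dd - pp - pr, pp, pr)
  }
  colnames(out) <- c("time_min", "undissolved_mg", "dissolved_mg",
                     "precipitated_mg", "permeated_mg")
  as.data.frame(out)
}
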