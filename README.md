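# bepbbm

Mechanistic translation of in-vitro transfer-dissolution experiments into
predicted human pharmacokinetics.

A two-chamber transfer-dissolution apparatus simulates gastric-to-intestinal
transit: a tablet dissolves in simulated gastric fluid while concentrated
intestinal medium is infused (pH 1.6 → 6.5, volume growing, bile micelles
appearing) and dissolved drug permeates a hydrophilic filter into an octanol
receiver. The measured donor/receiver curves are rich in formulation
information but cannot be read as absorption predictions directly — the
permeated fraction is far below the in-vivo fraction absorbed.

`bepbbm` implements the full in-vitro → in-silico chain:

1. **Apparatus model** — coupled ODEs for z-factor dissolution
   (`dW/dt = z (W_dis+W_undis)^{1/3} W_undis^{2/3} (Cs − W_dis/V)`),
   supersaturation-driven precipitation of weak bases
   (`dW_pre/dt = k₀ e^{XC}(C − Cs)V`), and permeation through the partially
   wetted filter (circular-segment geometry as the liquid level rises),
   integrated with fixed-step RK4 in C++.
2. **Parameter estimation** — bounded multistart nonlinear least squares in
   log space (printed z and k₀ estimates span ~17 decades), with
   dispersion/bound diagnostics for the flat directions such fits have.
3. **Human PBBM** — fasted-state stomach + small intestine (first-order
   gastric emptying at 2.8 h⁻¹, 4 h intestinal residence implemented as a
   transit-time delay, absorption over 800 cm² at the drug's effective
   permeability, optional intestinal precipitation) coupled to 1- or
   2-compartment disposition with a lumped first-pass factor Fg·Fh.
4. **PK metrics** — non-compartmental analysis (Cmax, Tmax, AUC_last,
   AUC_inf via terminal log-linear regression) and percent prediction error
   `%PE = (pred − obs)/obs × 100`, with a condition-grid report flagging
   |PE| ≤ 15% for both Cmax and AUC_inf.
5. **Synthetic data + fixtures** — seeded generators for apparatus and
   dialysis-cell curves, and a fixture library of every published constant
   (solubilities, fitted rate constants per condition, physiology,
   disposition, observed PK means).

## Worked example

Predict the plasma profile of 100 mg oral dipyridamole from the kinetic
constants fitted under the 30 min infusion / 200 rpm apparatus condition:

```r
library(bepbbm)

fx     <- builtin_fixtures()
drug   <- fixture_drug(fx, "dipyridamole")
params <- fixture_kinetic_params(fx, "dipyridamole", 30, 200)

# first-pass availability: oral bioavailability F = K10·V1·AUC_obs/dose,
# divided by the model-predicted fraction absorbed of the reference condition
fp <- dipyridamole_first_pass(fx)
#> fp$F_oral = 0.7236, fp$Fa_ref = 0.8160, fp$FgFh = 0.8867

d     <- fx$disposition$dipyridamole
dispo <- disposition_params(2, d$V1, d$K10, d$K12, d$K21, FgFh = fp$FgFh)

prof <- simulate_pbbm(drug, params, physiology_config(), dispo,
                      precipitation_model("model1"), dose = 100)
nca(prof)
#> <nca> Cmax 2.073 at Tmax 0.53 h; AUC_last 4.25, AUC_inf 4.25 (0.00% extrapolated)
```

So this condition predicts Cmax ≈ 2.07 µg/mL at ~0.5 h with AUC_inf ≈
4.25 µg·h/mL, against observed means of 2.18 µg/mL and 4.25 µg·h/mL
(prediction errors −5% and 0%): the high-agitation, slow-infusion condition
reproduces the observed exposure. Repeating this over all nine apparatus
conditions (`analysis/04_prediction_errors.R`) shows that only the 20- and
30-min / 200 rpm conditions predict both Cmax and AUC_inf within ±15%,
while the 10 min / 50 rpm condition underpredicts by ~80% — the apparatus
operating condition, not the model, is what determines predictive accuracy.

The same pipeline fits parameters from (synthetic or measured) curves:

```r
prot  <- fixture_protocol(fx, "dipyridamole", 30, 200)
obs   <- generate_bechecker_dataset(params, prot, drug,
           noise = noise_model("multiplicative_lognormal", 0.05, seed = 7),
           use_fmol = TRUE, use_fmic = TRUE)
fit   <- fit_bechecker_params(obs, prot, drug, mode = "with_precipitation",
                              n_starts = 8, seed = 1,
                              use_fmol = TRUE, use_fmic = TRUE)
```

## Analysis workflow

Numbered scripts under `analysis/` run the study end to end and write plain
CSV tables under `results/`:

| script | what it does |
|---|---|
| `01_bechecker_simulations.R` | apparatus time courses for all 12 published conditions |
| `02_parameter_recovery.R` | noiseless and 5%-noise recovery of known constants |
| `03_pbbm_predictions.R` | predicted Cmax/Tmax/AUC_inf for every condition and precipitation model |
| `04_prediction_errors.R` | %PE scoring against observed means, ±15% accuracy map |

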