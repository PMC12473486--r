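---
title: "From transfer-dissolution curves to human plasma profiles: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From transfer-dissolution curves to human plasma profiles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bepbbm)
```

# The problem

A two-chamber transfer-dissolution apparatus mimics gastric-to-intestinal
transit in vitro: a tablet disperses in simulated gastric fluid while a
concentrated intestinal-medium infusion gradually converts the donor fluid
to intestinal composition (pH 1.6 to 6.5, bile micelles appearing, volume
growing), and dissolved drug permeates through a hydrophilic filter into an
octanol receiver. The apparatus yields two curves per condition — donor
dissolved amount and receiver permeated amount — but the permeated fraction
is orders of magnitude below the in-vivo fraction absorbed, so the curves
cannot be read as absorption predictions directly.

`bepbbm` closes that gap in two stages:

1. a mechanistic model of the apparatus is fitted to the donor/receiver
   curves, yielding formulation-specific dissolution (and, for precipitating
   weak bases, precipitation) rate constants;
2. those constants are carried unchanged into a physiologically based
   biopharmaceutics model (PBBM) of the human fasted gastrointestinal tract
   coupled to systemic disposition, producing plasma concentration profiles
   and the non-compartmental parameters (Cmax, Tmax, AUC) used for
   bioequivalence reasoning.

The package is exercised with two classical model drugs: metoprolol (a
highly soluble, pH-insensitive base — absorption is dissolution-paced but
essentially complete) and dipyridamole (a weakly basic, strongly
pH-dependent compound that supersaturates and precipitates on the gastric
to intestinal pH shift).

# The apparatus model

## Dissolution

Dissolution follows a Noyes–Whitney *z*-factor form,

$$\frac{dW_{dis}}{dt} = z\,(W_{dis}+W_{undis})^{1/3}\,W_{undis}^{2/3}
  \left(C_s - \frac{W_{dis}}{V_t}\right),$$

with separate constants $z_{gastric}$ and $z_{intestinal}$ (mL mg$^{-1}$
min$^{-1}$) and phase-specific solubilities. The driving force is clamped at
zero from below: when the medium is supersaturated the dissolution term is
inactive, and the decay of supersaturation is carried exclusively by the
precipitation term. This separation keeps the two fitted processes
orthogonal.

The phase switch (both $z$ and $C_s$) happens at a protocol-level time
`t_transition`: the end of infusion for drugs that do not precipitate, and
the observed onset of precipitation for those that do. Only the 10-minute
infusion onset (~9 min) is reported for dipyridamole; the package scales the
20- and 30-minute onsets proportionally (18 and 27 min). These are
configurable protocol inputs, not model constants.

## Precipitation

Above intestinal saturation, a weak base precipitates at

$$\frac{dW_{pre}}{dt} = k_0\,e^{X C}\,(C-C_s)\,V_t,$$

with the empirical concentration dependence $k_p = k_0 e^{XC}$. Precipitated
drug never redissolves. Fitted $k_0$ values span many orders of magnitude
across conditions; where the exponent is numerically extreme the
implementation caps $XC$ at 500 (the rate is astronomically fast either way)
to avoid floating-point overflow without changing any realistic trajectory.

## Permeation and the wetted-filter geometry

Permeation into the (perfect-sink) octanol receiver is

$$\frac{dA_t}{dt} = P_{app}\,f_{mol}\,f_{mic}\,S_t\,\frac{W_{dis}}{V_t},$$

with $P_{app}$ in cm/s converted to a per-minute flux. The wetted filter
area $S_t$ grows as the liquid level rises during infusion: height
$h = qT/(\pi R^2)$ (infused volume over vessel cross-section, capped at the
filter diameter) and circular-segment area
$S = (\theta/2) r^2 - (r-h)\sqrt{h(2r-h)}$, $\theta = 2\cos^{-1}(1-h/r)$.

For ionizable, micelle-bound drugs two corrections multiply the flux: the
non-ionized fraction $f_{mol}$ (Henderson–Hasselbalch, with donor pH ramping
linearly from 1.6 to 6.5 over the infusion window — chosen for consistency
with the linear treatment of $f_{mic}$, and configurable) and the
micelle-free fraction $f_{mic}$, estimated as the ratio of micelle-free to
micelle-containing solubility at intestinal pH and interpolated linearly
from 1 at infusion start to its intestinal value at infusion end. For
metoprolol both corrections are off ($f_{mol}=f_{mic}=1$).

## Numerical integration

The four mass pools (undissolved, dissolved, precipitated, permeated)
exchange mass only with one another, so any consistent one-step integrator
conserves the dose to round-off *by construction* — step size buys accuracy,
never balance. The integrator is fixed-step fourth-order Runge–Kutta
(default `dt = 0.05` min; the fitting objective uses the same), implemented
in C++ because the multistart fit evaluates the simulation thousands of
times. Step-halving changes trajectories by well under $10^{-4}$ relative,
and an independent plain-R explicit-Euler integration built from the
exported rate functions agrees to 0.1%.

## Apparatus inputs that are not published

The initial gastric volume `V0` and infusion rate `q` are operating values
of the instrument, not printed with the model constants; they are therefore
*required* protocol arguments with no hidden defaults. The fixture library
ships assumed values (30 mL initial, 100 mL final — the printed vessel
volume — hence `q = 70 mL / t_infusion`), clearly labelled as assumptions.
The full filter area is taken as the printed 6.6 cm² bound.

# Parameter estimation

Fitting minimizes the unweighted sum of squared residuals (mg²) over the
dissolved series plus, when available, the permeated series, with the
simulation sampled at the observation times by linear interpolation of the
dense grid. Published estimates of $z$ and $k_0$ span roughly 17 orders of
magnitude, so the optimizer works in log10 space for those parameters
(bounds $z \in [10^{-16}, 10]$, $k_0 \in [10^{-20}, 10]$) and linear space
for $X \in [0, 100]$.

A single local fit in such a space is fragile, so the default is 32
Latin-hypercube starting points (seeded, reproducible) plus two
deterministic ones: the box center and a method-of-moments start in which
the early donor slope estimates $z_{gastric} \approx
\dot W / (\text{dose}\cdot C_s)$. The latter reliably lands in the correct
basin even when random starts miss it. Each start runs bounded
quasi-Newton optimization (`nlminb`).

Two diagnostics expose the overfitting risk inherent in simultaneous
multiparameter estimation: the dispersion of the best-quartile optima in
the (normalized) transformed space, and the list of parameters that ended
on a bound. Flat directions are real and expected — after the phase switch
a supersaturated donor has no active dissolution term, so
$z_{intestinal}$ can be unidentifiable; the tests assert flatness rather
than a value in that case.

# The human absorption model

## Structure

Stomach and small intestine are well-stirred compartments:

* **Stomach** — dissolution at gastric solubility in the current gastric
  fluid volume; first-order emptying (rate constant `GER` = 2.8 h⁻¹)
  applied identically to dissolved drug, undissolved drug and fluid. The
  240 mL of water taken with the dose joins the gastric fluid at $t=0$.
* **Small intestine** — dissolution at intestinal solubility; optional
  precipitation (same law as in vitro); absorption flux
  $P_{eff}\,S_{abs}\,C_{SI}$ over a fixed effective surface area
  $S_{abs}$ = 800 cm²; residence limited by the small-intestinal transit
  time `SITT` = 4 h. Drug arriving in solution above intestinal saturation
  stays in (supersaturated) solution subject only to precipitation.
* **Disposition** — absorbed drug enters a 1- or 2-compartment linear
  model. First-pass availability `FgFh` multiplies the absorbed amount
  (1-compartment convention) or divides the central volume
  (2-compartment convention); both scale plasma concentration identically.

In-vitro constants are per minute, physiology per hour; the conversion
(×60, and cm/s → cm/h ×3600) is centralized and tested
(`convert_units()`).

## Transit as a residence time, not a first-order loss

A first-order exit at $1/SITT$ would remove dissolved and dissolvable drug
from the very first moment it enters the intestine, making the predicted
extent of absorption depend strongly on *where* dissolution happens even
for a freely dissolving, well-absorbed drug — which contradicts the meaning
of a transit *time*. The package instead treats intestinal exit as a
residence-time delay, approximated by an Erlang chain of `n_transit`
(default 7) age stages per species, while all concentration-dependent
processes (dissolution, precipitation, absorption) act on the *lumped*
well-stirred amounts in the single intestinal volume. Material that is
neither absorbed nor dissolved within its ~4 h residence leaves unabsorbed.

Consequences worth knowing: a freely soluble, permeable drug approaches
complete absorption regardless of where it dissolves (its dissolution
kinetics still shape Cmax and Tmax); an insoluble solid is removed ~4 h
after entry; and because the lumped concentration drives precipitation, the
supersaturation dynamics are identical to a single well-stirred lumen.

## Fluid volumes

Gastric and intestinal fluid volumes are constrained not to fall below
their initial values (26 and 43 mL). The stomach relaxes from
26 + 240 mL back to its floor in closed form,
$V_{st}(t) = 26 + 240\,e^{-GER\,t}$ (integrating a discontinuously gated
volume state made the stiff solver stall exactly at the floor crossing).
The small intestine operates at its 43 mL floor, with inflowing fluid
transiting through rather than accumulating: letting the water bolus swell
the intestinal volume dilutes the absorption driving force and visibly
delays the predicted Tmax of a fast-absorbing drug, while the fixed
operating volume reproduces absorption timing across all tested conditions.

## First-pass availability of the weak base

For metoprolol, dose-specific `FgFh` values (0.31, 0.41, 0.46 for
20/50/100 mg) are published inputs. For dipyridamole no first-pass factor
is published. The oral AUC identity gives the *full* bioavailability

$$F = F_a \cdot F_g F_h = \frac{K_{10} V_1 \cdot AUC_{obs}}{dose} \approx 0.72,$$

and equating $F_gF_h$ to $F$ would silently assume $F_a = 1$ — inconsistent
with the absorption model itself, which predicts incomplete absorption even
under the best apparatus condition. The package therefore back-calculates

$$F_gF_h = F / F_a^{ref},$$

where $F_a^{ref}$ is the model-predicted fraction absorbed under the
reference condition (30 min infusion / 200 rpm, the condition identified as
matching the in-vivo profile). $F_a$ does not depend on `FgFh`, so no
iteration is needed. `dipyridamole_first_pass()` implements the chain and
is configurable; with the shipped constants it yields `FgFh` ≈ 0.89.

## Metoprolol solubility in vivo

Only a lower bound (> 2 mg/mL) is published for metoprolol tartrate. The
default is 20 mg/mL. Sensitivity is asymmetric and worth stating: predicted
AUC is insensitive (absorption is essentially complete from ~10 mg/mL
upward under the residence-delay transit model), but Cmax and Tmax retain
sensitivity because gastric dissolution remains rate-limiting at low paddle
speeds — much larger values collapse the stirring-speed differences that
the data clearly show. The value is a flagged configuration input.

## Precipitation models

Model 1 applies the apparatus-fitted $k_0$ (per minute) and $X$; model 2
applies literature constants from a gastric dumping study
($k_0 = 1.803\times10^{-3}$ h⁻¹ — per hour, as printed — and
$X = 38.42$ mL/mg). With `precipitation_model("none")`, or model 1 with
$k_0 = 0$, the precipitation term vanishes identically (tested as an exact
continuity property).

## Integration

The PBBM right-hand side is moderately stiff (the model-2 exponential
concentration dependence especially), so it is integrated with `lsoda`
(deSolve) at `rtol = 1e-8`, `atol = 1e-10`, dense output every 0.01 h.
Mass balance over gastrointestinal pools + absorbed + transited-unabsorbed
holds to better than $10^{-6}$ of the dose. The disposition block is also
available standalone (`simulate_disposition()`) as an *exact*
piecewise-constant propagator built on the eigen-decomposition of the rate
matrix; tests verify it against a matrix-exponential bolus solution to
$10^{-8}$ relative.

# Non-compartmental analysis

`nca()` computes Cmax, Tmax (earliest time of the maximum — the tie-break
the tables imply), trapezoid `AUC_last`, and `AUC_inf` by log-linear
terminal regression. The terminal window starts at the last 3 points and
extends backwards (never past Tmax) while the adjusted R² improves. A
non-decreasing tail withholds `AUC_inf` rather than reporting a negative
extrapolation. For simulated profiles the grid report re-simulates with a
doubled horizon whenever the extrapolated fraction exceeds 5%, so reported
`AUC_inf` values do not depend on the initial horizon choice (24 h for the
1-compartment drug, 48 h for the 2-compartment one).

# Synthetic data: what it does and does not emulate

`generate_bechecker_dataset()` produces apparatus curves from known
constants — two-phase dissolution, optional precipitation, saturable
permeation through the growing filter area — sampled on a dense-early
schedule (2, 5, 10, 15, 20, 30, 45, 60, 90, 120 min) with multiplicative
lognormal noise (default for positive, heteroscedastic amount data;
additive Gaussian available for near-zero permeation tails). Identical
seeds give identical datasets, and generation restores the caller's RNG
state. `generate_dialysis_dataset()` produces linear dialysis permeation
curves with an optional lag; the apparent-permeability estimator recovers
the generating value exactly on noiseless output.

What the generator deliberately does not emulate: tablet disintegration or
dispersion kinetics (assumed non-rate-limiting), sampling-volume losses,
inter-run variability in the infusion schedule, drifting permeability
during medium conversion, or analytical detection limits. Passing recovery
tests on synthetic data therefore demonstrates that the estimation
machinery is correct and well-conditioned under the stated noise model —
not that real apparatus data are free of structural misspecification.

# Problem sizes and runtime choices

The test suite runs the apparatus simulator at `dt = 0.01–0.05` min over
120 min horizons, multistart fits with 4–8 starts, a 20-replicate noisy
recovery study at 5% CV, and the full 9-condition PBBM grid at 0.01 h
output resolution over 48 h — sizes chosen so the entire suite completes in
well under a minute per module while still exercising every code path at
the accuracy levels quoted above.

# Known limitations

* Hydrodynamics enter only through the fitted constants; paddle speed is a
  label, and constants fitted on one apparatus geometry do not transfer to
  another.
* The ionization routine covers monoprotic bases only (both study drugs are
  bases); acids and zwitterions would need a different species model.
* The intestine is a single effective compartment with one solubility; no
  regional pH gradient, no colonic absorption.
* First-pass is a lumped scalar: no transporter saturation, no
  dose-dependent gut-wall metabolism mechanism (dose dependence enters only
  through dose-specific published values).
* No inter-individual variability; predictions target the average fasted
  adult profile.
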