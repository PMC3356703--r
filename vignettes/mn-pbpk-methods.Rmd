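---
title: "Methods: a multi-species PBPK model for dietary and inhaled manganese"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a multi-species PBPK model for dietary and inhaled manganese}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model structure

`mnpbpk` models whole-body manganese kinetics in the adult rat, rhesus
monkey and adult human with fourteen compartments: blood, liver, gut
lumen, gut epithelium, lung epithelium, nasal olfactory and respiratory
epithelia, olfactory bulb, a basal-ganglia target region (striatum in
the rat, globus pallidus in the primates), cerebellum, pituitary, bone,
kidney and rest of body.  State variables are *amounts* (µg) of free and
bound Mn per compartment; concentrations (µg/g, density fixed at
1 g/mL) are derived.  Working in amounts makes conservation exact: at
every output time, body burden plus cumulative fecal excretion equals
the initial burden plus cumulative intake, and `check_mass_balance()`
audits this to below 10⁻⁶ relative on all shipped scenarios.

Free Mn in tissue *i* exchanges with blood by asymmetric diffusion,
`k_in · C_blood − k_out · C_free` with flows in L/h acting on µg/L, the
influx capped at the tissue blood flow (diffusion cannot outrun
delivery).  Free Mn binds to a finite tissue capacity
`B_max · mass` with association/dissociation constants `k_a`
(g µg⁻¹ h⁻¹) and `k_d` (h⁻¹).  Binding is the slow pool: basal tissue
Mn is almost entirely bound, free Mn is cleared within hours of
exposure ceasing, and the week-scale rise and washout of brain Mn is
governed by `k_d` (≈0.0018 h⁻¹ in the primates, a ~3-week time
constant; faster, 0.0025 h⁻¹, in the rat, consistent with the rapid
post-exposure return of rat brain Mn).

### Exposure routes

* **Diet** enters the gut lumen continuously at `mg/day · 1000 / 24`
  µg/h.  All scenarios of interest run for 90 days or more, so meal
  structure is irrelevant at the timescale of the bound pool and a
  continuous rate keeps the system autonomous between inhalation
  transitions.
* **Gut uptake** is first-order in lumen Mn at trace levels and
  inhibited by a Hill term in the lumen amount,
  `k_abs·A / (1 + (A/K_inh)^n)`, reproducing the falling absorbed
  fraction (Fdietup) with rising dietary Mn.  Lumen Mn not absorbed
  transits to feces (`k_fec`).  Absorbed Mn resides in the gut
  epithelium, where enterocyte sloughing (`k_slough`) returns a fixed
  share `k_slough/(k_slough + k_blood)` to feces without ever reaching
  the systemic circulation.
* **Inhalation** deposits `air · Q_p · f_region` on the nasal olfactory,
  nasal respiratory and lung epithelia while the schedule is on; the
  rest is exhaled and never counted as intake.  Deposition fractions are
  lumped species constants — no particle-size model — calibrated
  together with the kinetic anchors.  Epithelial Mn absorbs to blood at
  `k_epith_absorb` (0.5 h⁻¹), except a small olfactory fraction
  `k_olf/(k_olf + k_epith_absorb)` (≈1%) delivered directly to the
  olfactory bulb.
* **Elimination** is biliary: liver free Mn is cleared into the gut
  lumen at `k_bile_c` multiplied by a Hill induction factor
  `1 + i_max · C^n/(c50^n + C^n)` of the liver free concentration.
  Bile-borne Mn re-enters the lumen and may be reabsorbed
  (enterohepatic recirculation; a switch on the parameter set disables
  it for sensitivity work).  Urinary excretion is omitted — Mn is
  eliminated almost entirely in feces — and this is a documented
  limitation rather than a fitted choice.

### The homeostat, and why induction is steep

Two observations constrain the induction term tightly.  Occupational
simulations must show a *near-linear* ~5% pallidal rise at 0.01 mg/m³
yet only ~36% at the twenty-fold higher TLV of 0.2 mg/m³, and the
hepatobiliary-impairment scenario (biliary clearance and liver blood
flow both halved) must raise the end-of-exposure pallidal concentration
by only ~25% rather than the ~doubling a fixed clearance would give.
Both demand a damping mechanism that is weak at basal liver Mn and
strong just above it — i.e. an induction curve positioned slightly
*below* its half-maximum at basal, with high cooperativity.  The
shipped rodent and monkey sets use `i_max = 8` and `n_ind = 6`; the
jointly calibrated human set sharpens this to `i_max = 12` and
`n_ind = 8`, with `c50_ind` about a third above the basal human liver
free concentration.  The paper trail for induction in the
literature is qualitative ("dose-dependent elimination from liver"),
so the functional form is this package's modelling choice; the
steepness should be read as "switch-like homeostatic induction", not as
a measured enzyme cooperativity.  In the monkey, whose 133-ppm chow
already saturates the induction curve, elimination is effectively
linear — which is exactly what lets pallidal Mn climb six-fold during
high-dose inhalation while the human response stays clamped.

The liver is modelled diffusion-limited (`k_in,liver` below the liver
blood flow, with `k_out` scaled to preserve the basal liver/blood
ratio).  The hepatic-impairment scenario halves liver flow and biliary
clearance; with `k_in,liver` calibrated between half and full liver
flow, the flow cut partially engages the delivery cap, and the degree
of engagement was the one free lever used to match the impaired
scenario without touching the unimpaired dose–response.

## Species parameter sets and provenance

Human physiology uses the reference adult: 70 kg; blood 8%, bone 12%,
brain 2%, liver 3%, lung 1% of body weight; bone 4%, brain 11%, liver
23%, nose 1% of cardiac output; cardiac output 13 and ventilation
20 L/h/kg.  Monkey (3 kg, 133 ppm diet at 100 g feed/day) and rat
(0.25 kg, 125 ppm at 18 g/day) use standard laboratory values; body
weights and feed rates are assumptions recorded in each YAML file's
provenance block.

Binding constants and per-gram capacities are shared across species
(capacities scale with tissue volume); brain and tissue diffusional
flux coefficients scale allometrically as BW^0.75 between species (the
shipped human brain `k_in`/`k_out` are the monkey values times
(70/3)^0.75, asserted in the tests).  Dietary-uptake parameters and the
basal biliary clearance are calibrated *per species* to the measured
anchors — the same adjustment the underlying experimental program made,
and a necessity: monkey basal pallidal Mn of 0.48 µg/g on a 133-ppm
diet and human ~0.5 µg/g on 2.43 mg/day cannot be reconciled with a
single allometrically scaled clearance.

Calibration anchors (all retrievable via `packaged_anchors()`):

* monkey — basal globus pallidus 0.48 µg/g; 1.92/2.41/2.94 µg/g after
  15/33/65 exposure days at 1.5 mg/m³ (6 h/d, 5 d/wk); duration ratio
  1.06 at 0.2 mg/m³ continuous;
* human — basal globus pallidus ≈0.5 µg/g (mid normal range
  0.15–4 µg/g, which all shipped solid tissues respect at basal diet);
  ~5% rise at 0.01 mg/m³; 0.68 (control) and 0.85 µg/g (impaired) after
  one occupational year at 0.2 mg/m³;
* rat — basal striatum ≈0.4 µg/g; aged scenario (minute volume ×0.75)
  strictly below the adult at every exposure.

Every calibrated entry is tagged `calibrated:` in the YAML provenance;
everything else is tagged `assumed:` or `reference:`.

## Scenarios, metrics and CSAFs

`apply_scenario()` applies multiplicative modifiers by parameter path
(rejecting unknown paths and factors that would drive the rest-of-body
residual flow negative; liver-flow changes re-balance that residual).
Shipped scenarios: `scenario_hepatic_impaired()` (liver flow ×0.5,
biliary clearance ×0.5) and `scenario_aged()` (minute volume ×0.75).
Dose metrics are end-of-exposure concentration (the end of the last
on-phase, or the final time for continuous schedules), trapezoidal
average daily AUC over a trailing window, Cmax, and percent change from
basal; a pharmacokinetic CSAF is the ratio of a metric in a susceptible
subpopulation to baseline.  All metrics default to *total* (free +
bound) concentration, matching how tissue Mn is measured.

One reading choice: the dose–response claim "more than 30% above
0.1 mg/m³" is evaluated as the minimum end-of-exposure rise over
simulated air levels strictly above 0.1 (0.2, 0.5, 1.0 mg/m³); at
exactly 0.1 the shipped model gives ≈25%.

## Monte Carlo population variability

`run_population()` reproduces the population analysis: dietary intake
Normal(2.43, 1.8) mg/day hard-bounded to [0.07, 6.2]; body weight,
tissue volumes and blood flows with CV 0.30; cardiac output and
ventilation with CV 0.50; every distribution truncated at ±2 SD;
no parameter correlations.  Sampling is by rejection; derived
quantities are recomputed per subject (masses with body weight,
capacities with mass, flows with cardiac output, clearances and
diffusional fluxes as BW^0.75), and infeasible subjects (negative
residual mass or flow) are redrawn.  Each subject starts from its own
diet-only steady state — the reported quantities are steady-state
concentrations, so the pre-equilibration is a shortcut, not an
approximation — and is simulated for 365 days of continuous exposure
per air level.  The reference population size is 10,000; the test suite
runs n = 500 over six air levels, at which the median and the 5th/95th
percentiles are stable to well under the 2% flatness margin used in the
threshold property (median flat below 0.001 mg/m³, strictly increasing
above 0.01 mg/m³).

## Calibration machinery and synthetic data

`calibrate_parameters()` minimizes weighted squared *log* residuals
(concentrations span orders of magnitude) over named parameter paths,
optimized on the log scale with Nelder–Mead (Brent in one dimension),
optional seeded multistart, and a finite-difference rank check that
warns when the anchor set cannot identify all free parameters.  The
synthetic-data module supplies everything needed to verify this
machinery without external data: a one-compartment infusion–elimination
fixture with closed-form solution `A(t) = (R/k)(1 − e^{−kt})` realized
*inside* the full model (the infusion is the dietary input, the loss is
lumen fecal transit), and `generate_synthetic_observations()`, which
overlays multiplicative lognormal noise (`σ = sqrt(log(1 + cv²))`,
default CV 0.15, matching the SEM/mean magnitude of the measured monkey
data) on simulated time courses while retaining the noiseless truth.
Parameter recovery is exercised two ways: noise-free steady-state
anchors across a 45-fold dietary range recover `k_bile_c` and `K_inh`
to better than 1%; at 10% noise the recovery study switches to a
well-identified pair (`k_bile_c` from liver anchors, the target-tissue
`k_in` from brain anchors) because homeostasis makes the
(`k_bile_c`, `K_inh`) pair nearly collinear in concentration space —
an instructive identifiability failure that the rank check flags.

The generator emulates tissue-sampling designs (times, tissues, assay
noise) but *not* inter-animal physiological variability (that belongs
to the population module) nor any systematic assay bias; passing
recovery tests therefore demonstrate correctness of the estimation
machinery, not robustness to structurally misspecified data.

## Numerical choices

* Integration: `deSolve::lsoda` over a compiled C right-hand side,
  relative tolerance 10⁻⁸, absolute tolerance 10⁻¹⁰ µg, restarted at
  every exposure on/off transition so the forcing is exactly piecewise
  constant (no event root-finding).  Population runs loosen to
  10⁻⁶/10⁻⁸ for throughput; the summaries are insensitive at that
  level.
* A pure-R right-hand side (`evaluate_rhs()`) is the executable
  specification; tests assert equality with the compiled path to
  10⁻¹², agreement of the adaptive solver with fixed-step RK4
  (dt = 0.001 h) to 10⁻⁵, and agreement with the closed-form fixture
  to 10⁻⁶.
* Steady states: long pre-run (20,000-h chunks, convergence when the
  maximum relative change drops below 10⁻⁶ per 100 h — several
  multiples of the slowest ≈3,000-h binding time constant) followed by
  a damped-Newton polish on the algebraic system; the two routes agree
  to 0.1% and both are exposed.
* Degenerate inputs are rejected at construction (negative rates,
  deposition fractions summing above 1, empty truncation intervals,
  unknown compartments or parameter paths); Hill terms guard against
  overflow at extreme concentrations by clamping to full induction.
* Output grids include all segment boundaries; end-of-exposure sampling
  is grid-independent (asserted against a dense grid).

## Known limitations

* No urinary excretion, no ⁵⁴Mn tracer bookkeeping, no CFD airway
  deposition (lumped fractions instead), no gestation/lactation or
  neonatal parameter sets, no nanoparticle kinetics, no iron–manganese
  transporter interaction, and no pharmacodynamic (neurotoxicity)
  layer.
* The aged scenario is parameterized for the rat only (reduced minute
  volume); extrapolating aged physiology to humans would require
  additional liver-volume, biliary and gastrointestinal changes and is
  deliberately out of scope.
* The induction Hill form, its steepness, and the degree of liver
  flow-limitation are identifiable only in combination from the
  available anchors; alternative parameterizations matching the same
  anchors exist, so individual kinetic constants should not be
  over-interpreted.
* Monte Carlo draws are independent; real covariation (body weight with
  cardiac output, for instance) would narrow the population spread.
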