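---
title: "Methods: daptomycin exposure and dose adjustment in renal impairment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: daptomycin exposure and dose adjustment in renal impairment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(daptosim)
```

## Scope and model structure

`daptosim` models daptomycin disposition across renal-function stages in
adults and children with a deliberately reduced structure: one clearance
decomposition plus a linear two-compartment disposition model. Daptomycin
justifies the reduction — its kinetics are linear over the clinical dose
range, plasma protein binding (~90–93%, albumin) is
concentration-independent, it is not metabolized by liver microsomes, and
its distribution volume of roughly 0.1 L/kg confines it essentially to
plasma and extracellular water. A whole-body, permeability-limited tissue
model adds little for plasma-exposure questions and cannot be reproduced
without proprietary physiology tables; this package therefore targets
plasma AUC, Cmax and trough only, and makes no claims about tissue
concentrations.

### Clearance

Renal elimination is treated as pure glomerular filtration of unbound
drug. The structural identity

    CL_renal = CL_filt + CL_sec − CL_reabs

is carried in the `clearance_model` object with secretion and
reabsorption present but fixed at zero: there is no evidence of tubular
handling for daptomycin, and keeping the terms makes the identity
testable and leaves room for future drugs. Total clearance is

    CL = fup · GFR + CL_H

`CL_H`, the non-renal route, is interpreted as biliary excretion handled
as liver clearance. It is not independently identifiable, so it is
*calibrated*: `CL_H = CL_ref − fup·GFR`, with `CL_ref = dose/AUC` taken
from the healthy-adult multiple-dose anchor (6 mg/kg daily, steady-state
AUC 580 µg·h/mL, hence CL_ref = 0.724 L/h and CL_H = 0.134 L/h). An
alternative anchor would be the ~78% urinary recovery figure, which
implies a somewhat larger renal share; the two cannot both be matched
exactly. We calibrate on AUC because every downstream quantity (PTA,
CFR, exposure ratios) is an AUC functional, which keeps the pipeline
self-consistent; the recovery figure is treated as corroborating, not
binding.

Under renal impairment only the filtration term changes
(`apply_renal_impairment()`); `CL_H` is frozen. The unbound fraction
rises slightly with disease stage — 0.08 healthy, 0.09 mild, 0.10 from
moderate through ESRD — and is corrected to 0.09 for the healthy state
of the elderly reference cohort, whose serum albumin runs low.

### Pediatric scaling

Children (1–17 y; below 1 y is out of scope for safety reasons) get
their renal clearance from their own `fup · GFR`, with healthy
normalized GFR following a Hill maturation curve in postmenstrual age
(`hill = 3.4`, half-maturation at 47.7 weeks PMA, adult plateau 120
mL/min/1.73 m²) — near-adult filtration by age two. Non-renal clearance
scales by holding the adult non-renal:renal ratio fixed and anchoring it
at the child's healthy renal clearance, then freezing it across
impairment stages. A consequence worth stating plainly: the renal share
of elimination is the same for every age group by construction, so
relative exposure changes under impairment are nearly age-independent in
this model (see *Limitations*).

### Renal staging parameters

The conventional normalized-GFR bands define the stages; since only band
edges are conventional, each stage needs a representative value for
typical-subject construction. We use band midpoints (MILD 75, MODERATE
45, SEVERE 22.5, ESRD 7.5 mL/min/1.73 m²) and 120 for healthy adults —
an unbiased within-band choice, exposed as the `representative` argument
of `renal_category()` so a user can move within bands without touching
code.

### Disposition

Distribution uses Vss = 0.1 L/kg split between a central and a
peripheral compartment. Two parameters control the split: the central
fraction (`central_fraction`, default 0.6) and the inter-compartmental
clearance per kilogram (`q_per_kg`, default 0.00714 L/h/kg, i.e. 0.5 L/h
at 70 kg). These defaults were fixed once so the calibrated healthy
adult's terminal half-life lands at 8.8 h, inside the reported 8–9 h
range; they are not refit per subject. Infusions default to 30 min (the
2-min injection is selectable via `infusion_duration_h = 2/60`).

Profiles are computed from the closed-form solution of the zero-order
infusion input, superposed across doses — exact on the grid, no ODE
solver in the production path. An independent numerical integrator
(deSolve) is used in the test suite as an oracle and agrees to better
than 0.1%.

## Numerical choices

* **Grid**: 0.05 h default step; the simulator refuses steps coarser
  than a third of the infusion duration so the peak is resolved.
* **AUC**: log-linear trapezoid (linear up, log down) on the grid.
* **Trough**: defined as the concentration at the end of the dose
  interval (the pre-dose trough), not the within-interval minimum, which
  for a first dose would trivially be zero.
* **AUC(0–24) for q48h regimens**: defined as half the steady-state 48-h
  interval AUC — the *average daily exposure*. Whether a published
  "AUC(0–24)" for a 48-h interval means the first, second, or averaged
  24-h window is genuinely ambiguous; averaging keeps AUC/MIC indices
  comparable across intervals and is used consistently everywhere,
  including in the dose-adjustment ratios.
* **Steady-state dose counting** uses the analytic accumulation formula
  on the trough sequence (smallest `k` with trough(k) ≥ tolerance ×
  trough(∞)); the brute-force simulated equivalent is cross-checked in
  the tests. The calibrated healthy adult reaches 90% of the
  steady-state trough by dose 2–3 at q24h, later as clearance falls.
* **Calibrators** (`calibrate_total_clearance()`,
  `calibrate_central_fraction()`) solve on the full simulated profile by
  root finding, so they absorb residual accumulation and grid effects
  instead of relying on the analytic `dose/CL` shortcut.

## Monte-Carlo pharmacodynamics

Population variability enters as per-subject log-normal multipliers on
clearance and volume with median 1. No inter-individual variability
magnitudes are published for this compound's population simulator, so
the defaults — 25% CV on clearance, 15% on volume — are conventional
population-PK magnitudes for a renally cleared drug; they are plain
function arguments, stated in every stochastic output together with `n`
and the seed. Exposures use the analytic steady-state forms (interval
AUC = dose/CL exactly; analytic trough), which makes 10,000-subject runs
(the default `n`) essentially instantaneous.

PTA at a MIC is the fraction of subjects with total-drug AUC(0–24)/MIC
above the target (666 MRSA, 143 *E. faecium*; an unbound-fraction
variant can be had by scaling the samples by `fup`, but total drug is
the primary convention here). CFR is the frequency-weighted PTA across
the doubling-dilution grid 0.125–8 mg/L. Troughs at or above 24.3 mg/L
— the level associated with creatine-phosphokinase elevation — are
reported as a fraction and a typical-subject flag.

## The dose-recommendation rule

Baseline (healthy-children) regimens are the label doses: cSSSI
5/7/9/10 mg/kg q24h for 12–17/7–11/2–6/1–2 y; bacteremia 7/9/12 mg/kg
q24h for 12–17/7–11/1–6 y. The adjustment logic is:

* mild/moderate impairment — no change;
* severe — keep the dose, extend q24h → q48h;
* ESRD — extend to q48h, then reduce in 1 mg/kg steps (floor 4 mg/kg)
  until the average-daily-AUC ratio versus the healthy baseline is
  ≤ 1.8 **and** CFR(MRSA) ≥ 0.90; infeasibility is returned explicitly.

Two design decisions here were genuinely open and deserve prominence.

**The threshold.** The originating analysis never states a numeric
adjustment criterion. Reverse-engineering its exposure table shows that
regimens kept unchanged had impaired-to-healthy AUC ratios up to 1.74
while reduced ones started at 2.13–2.20, so 1.8 is the natural separating
default; it is a plain argument (`ratio_threshold`), not a constant.

**The exposure source.** `recommend()` can compute ratios from its own
mechanistic models (`auc_source = "model"`) or from the packaged
published pediatric exposure table (`auc_source = "reference"`, the
default, scaled linearly in dose). The default is the reference table
because the reduced model *cannot* reproduce the age-heterogeneity of
the published ratios: as noted above, its renal share is age-independent
by construction, so its ESRD/healthy daily-AUC ratio is ~2.0 for every
age group, whereas the published whole-body model spreads from 1.33
(adolescents) to 2.20 (young children). CFR, troughs and safety flags
are always recomputed mechanistically.

**A documented irreproducibility.** Even with the published ratios as
input, no single threshold reproduces the full published 14-cell
recommendation grid: matching the 2–6 y cSSSI cell (9 → 7 mg/kg,
requiring the threshold in [1.71, 1.95)) contradicts the 1–2 y cell
(10 → 6 mg/kg, requiring [1.28, 1.49)). The default rule reproduces 12
of 14 cells and selects 8 mg/kg (ratio 1.70) where the published grid
prints 6, and 9 mg/kg (1.65) where it prints 8, in the two youngest
ESRD cells. The originating selection evidently weighed something
beyond a single exposure-ratio cap — plausibly extra caution in
infants — and we prefer a transparent rule that is explicit about this
divergence over per-cell special-casing that would merely transcribe
the published grid.

## Synthetic data: what it does and does not cover

`generate_virtual_trial()` produces concentration observations with the
standard proportional-plus-additive residual model,
`obs = pred · exp(ε) + ε_add` truncated at zero, with the proportional
term parameterised mean-one (meanlog −σ²/2) so observations are unbiased
around the model prediction. Defaults: 15% proportional CV, 0.5 mg/L
additive floor — typical assay-plus-model residual magnitudes for an LC
assay in this concentration range. `recover_clearance()` closes the loop
non-compartmentally (dose over trapezoid AUC of the final interval); the
test suite shows median bias under 3% across 200 seeded trials at the
default noise. Sampling designs must resolve the infusion peak — an
hourly-only design biases the trapezoid AUC low by several percent,
which is a property of sparse sampling, not of the estimator.

`generate_mic_distribution()` provides seeded synthetic MIC frequency
fixtures: `MRSA_LIKE` concentrates ≥ 90% of mass at ≤ 0.5 mg/L (where
daptomycin is highly active), `EFAECIUM_LIKE` sits one to two dilutions
higher. These are structural stand-ins for surveillance data, not
surveillance data; CFR values computed from them are meaningful for
rank comparisons and qualitative statements (e.g. CFR > 90% at
recommended doses, PTA collapse at MIC 2 mg/L) but their absolute
percentages should not be quoted against surveillance-based results.
Passing tests therefore demonstrate correctness of the machinery and
qualitative PD behaviour, not real-world coverage estimates.

## Problem sizes used in the checks

The packaged checks run at desk scale by choice: Monte-Carlo PD checks
use 2,000 subjects (the engine default is 10,000), brute-force PTA
enumeration uses 100, the recovery study uses 200 trials of 16 samples,
and simulated profiles use the 0.05-h grid over 5–12 doses. These sizes
give Monte-Carlo standard errors well inside the asserted tolerances.

## Known limitations

* Plasma only; no tissue concentrations, no dialysis modeling, no
  nonlinear elimination, no transporter kinetics.
* Age-independent renal share under the ratio-based pediatric scaling,
  discussed above; ESRD exposure heterogeneity across ages is carried by
  the reference table, not the mechanism.
* The Cmax behaviour of the published whole-body model under impairment
  (peaks *falling* as renal function declines, driven by distribution
  changes) is not reproduced by a fixed central-fraction model and is
  not claimed.
* MIC fixtures are synthetic (above); absolute CFR is illustrative.
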