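---
title: "Model and methods: the venlafaxine–bupropion CYP2D6 interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: the venlafaxine-bupropion CYP2D6 interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model structure, the parameter conventions,
the deliberate simplifications and the numerical choices behind
`venbupddi`, in the spirit of a model-methods appendix.  Nothing stated
here goes beyond what the package's tests and the acceptance script
compute.

## 1. Model structure and assumptions

Six compounds — venlafaxine (VEN), O-desmethylvenlafaxine (ODV),
bupropion (BUP), hydroxybupropion (OHB), threo- and
erythrohydrobupropion (THB, EHB) — share one whole-body circulation with
twelve compartments: arterial and venous blood, lung, gut lumen, gut
tissue, liver, kidney, muscle, skin, fat, bone and a lumped "rest".
The set is deliberately reduced from the 17-plus compartments of full
platform models: the active-moiety equation needs arterial blood, bone,
fat, muscle and skin explicitly; gut, liver and kidney are mechanistic
(absorption, metabolism, excretion); every other organ contributes only
distribution volume and is pooled into "rest".  All organs are
flow-limited (perfusion-rate-limited): the emergent venous concentration
of organ $i$ is $C_i/K_{p,i}$ and

$$V_i \frac{dC_i}{dt} = Q_i \left(C_{art} - \frac{C_i}{K_{p,i}}\right).$$

Blood:plasma ratios default to 1 for all compounds (plasma concentrations
are what the model is evaluated against; a ratio of one keeps blood and
plasma interchangeable and is conservative), overridable per compound in
the configuration.

**Metabolism is exclusively hepatic.**  Every enzymatic step — the three
CYP routes of VEN O-demethylation, VEN's three sink routes, ODV
glucuronidation, BUP hydroxylation/reduction and the metabolite
conjugations; eighteen kinetic entries in total — runs on the unbound
concentration at the liver outflow, with intracellular unbound assumed
equal to plasma unbound.  Michaelis–Menten processes use
$v = k_{cat} E \, C_u / (K_M \alpha + C_u)$ where the competitive
inhibition factor $\alpha = 1 + \sum_j I_{u,j}/K_{i,j}$ collects the
unbound liver concentrations of BUP, OHB, THB and EHB over their
inhibition constants (0.46, 0.41, 0.15, 0.04 µM).  Whether inhibition
should read unbound or total inhibitor concentration is not fixed by the
source material; unbound is the declared choice, consistent with the
free-drug hypothesis.  Linear (intrinsic-clearance) processes use
$v = Cl_{int} V_{liver} C_u$ per unit reference abundance and are not
subject to inhibition.

**Renal elimination** acts on unbound plasma at the kidney outflow and
accumulates in a urine container.  The printed specific renal clearances
carry no unit; the default contract reads them as **L/h per kg body
weight**, scaled by the individual's glomerular filtration relative to a
same-weight reference adult.  An alternative reading — specific clearance
per liter kidney volume (1/min), the kidney-process convention of
platform PBPK tools — is selectable via
`units$renal_clearance = "per_L_kidney_min"` in the configuration.  The
trade-off: the default reproduces the unchanged-urine fraction of
venlafaxine (a few percent of the dose, the tested property), while the
per-kidney-volume reading better matches the literature exposure ratios
of the bupropion carbonyl metabolites; it could not do both, and the
tested quantity won.

## 2. Absorption

Both drugs are modeled as extended-release oral forms.  Dissolution
follows a Weibull profile
$F(t) = 1 - \exp(-\ln 2\, ((t - t_{lag})/t_{diss50})^{b})$, i.e. the
scale is parameterized so that $t_{diss50}$ *is* the 50 % dissolution
time (VEN: 338 min, lag 81.2 min, shape 0.92; BUP: 170 min, shape 1.52,
lag 0 — no lag is printed for BUP and zero is the declared default).
Dissolved drug permeates into gut tissue with a first-order rate constant
from a monotone logP/Mr heuristic
(`ka = 0.05 * sqrt(250/Mr) * 10^(0.15 (logP - 2.5))` 1/min, clamped to
[0.005, 0.2]); because release is dissolution-rate limited, this constant
plays a minor kinetic role and peak timing is governed by the fitted
Weibull parameters.  Aqueous solubility caps the lumen concentration
(dissolution stalls at saturation); at the solubilities of these
compounds the cap never binds.  Food effects are not modeled, matching
the fasted single-intake labeling of both products.

## 3. Tissue partitioning

Partition coefficients come from the compound's assigned method
(VEN/ODV/THB/EHB Berezhkovskiy-type, BUP Schmitt-type, OHB
Rodgers–Rowland-type; "charge-dependent Schmitt" is recorded as a
permeability tag on THB/EHB and computes with the Berezhkovskiy
composition formula).  All three are implemented in ratio form — tissue
affinity over plasma affinity from a bundled water/lipid/phospholipid
composition table — so that a hypothetical pure-water tissue against
pure-water plasma gives exactly $K_p = 1$.  The lipid terms of the
composition method use the ionization-corrected distribution coefficient
at plasma pH ($D = P \cdot f_{neutral}$), not the intrinsic $P$: these
compounds are predominantly ionized bases (pKa 7.7–9.6) and the neutral
species drives lipid partitioning; using $P$ directly would overestimate
adipose uptake roughly ten-fold and delay attainment of steady state
beyond what the observed accumulation half-lives support.  The
Rodgers–Rowland variant adds ionic binding to acidic phospholipids with
an association constant proportional to lipophilicity — a documented
heuristic, since blood-cell binding data are not among the inputs.

## 4. Physiology and populations

A bundled reference adult (male, 30 y, 73 kg, 176 cm, BMI 23.57 kg/m²)
carries organ volumes, fractional blood flows (summing exactly to
cardiac output, 5.6 L/min) and GFR 110 mL/min.  Volumes scale linearly
with body weight; flows and GFR scale with weight^0.75 (switchable to
linear for testing).  Beyond age 40, GFR declines 0.7 %/yr and cardiac
output 0.5 %/yr, linearly — explicit, simple stand-ins for the internal
age physiology of platform tools, not a claim of equivalence; enzyme
abundances do not change with age.  Sex enters through hematocrit only;
body composition differences are not modeled.

Populations sample age, weight and height uniformly within stratum
ranges (young: 20–63 y, 52–140 kg, 152–193 cm, 58 % female; elderly:
65–78 y, 65–112 kg, 160–181 cm, 53.8 % female), with the stratum median
individual always included as subject 1.  Inter-individual kinetic
variability applies lognormal multipliers to each process turnover with
CV equal to the reported relative SD of its maximal velocity, and to
renal clearances (lognormal for ±SD spreads, uniform for min–max
ranges).  All sampling is seeded and leaves the caller's RNG state
untouched.

## 5. Enzyme abundances and calibration

Turnover numbers are per amount of enzyme, but absolute hepatic enzyme
contents are not part of the printed inputs — this is the model's one
deliberate gap-filler.  Each enzyme receives a liver amount
$E = a_{ref} \times V_{liver} \times s$, with reference abundances
$a_{ref}$ (µmol/L liver) fixed once from independent exposure
relationships: the average venlafaxine plasma level at 225 mg/day, the
~13/7/1 exposure ratios of OHB/THB/EHB to bupropion, and the
fraction-metabolized via CYP2D6 implied by a 2.31-fold exposure change
under complete inhibition.  The scalars $s$ default to 1;
`calibrate()` then fits the CYP2D6 scalar and a single global
inhibitor-potency multiplier (scaling all four $1/K_i$ terms identically,
preserving their rank order) to two targets: baseline
$MR_{AUC} = AUC_{ODV}/AUC_{VEN} = 2.40$ and a 2.31-fold VEN AUC increase
under 300 mg/day BUP.  The optimizer is bounded and derivative-free
(golden-section for one scalar, Nelder–Mead on the log scale otherwise),
minimizes weighted squared relative errors, and is fully deterministic;
non-convergence returns the best-so-far scalars with a flag rather than
an error.  Everything downstream — the ODV exposure drop, the
active-moiety stability, the trough locations, the urinary fraction — is
emergent, not fitted.

## 6. Study protocols and reporting conventions

Encoded designs: `ddi_150`/`ddi_300` (225 mg/day VEN days 1–18, BUP
added days 5–18, exposures compared day 4 vs day 18), `mddi`
(VEN days 1–27, 300 mg BUP days 7–27, 100 mg of a generic strong CYP3A4
inhibitor twice daily days 21–27, compared on days 4/17/27), `ven_itra`
(the CYP3A4 inhibitor without BUP) and `ven_alone`.  Day $N$ means the
window $[24(N-1), 24N)$ h; troughs are read immediately before the next
dose.  "AUC of the median" is computed as NCA on the pointwise-median
population profile (the primary statistic); medians of individual AUCs
are also emitted.  The generic CYP3A4 inhibitor ships with placeholder,
azole-like parameters, is labeled non-validated, and its scenarios are
what-if output only.

The active moiety is the flow-weighted mean of the molar concentrations
over arterial blood, bone, fat, muscle and skin, converted to mass per
compound and summed.  As typeset in its source, the combination lacks a
visible normalization; it is implemented as a flow-weighted *mean*
(divide by $\sum fQ$) because the quantity must carry concentration
units and reduce to the plasma concentration when all organs agree.  The
literal unnormalized sum remains available (`am_raw_sum = TRUE`) for
sensitivity analysis.  Boundary conventions are inclusive and tested:
therapeutic exactly on 100 and 400 ng/mL, strong inhibition exactly at
5-fold, moderate at 2-fold, weak at 1.25-fold.  Report rounding follows
the tables being mirrored: ratios to two decimals, percent changes to
three significant figures.

Monitored troughs are dose-normalized linearly to 225 mg/day — a
declared linear-kinetics assumption, applied before stratified
aggregation (the alternative order is configurable).  Sampling days cap
at day 10 of concomitant use, when the perpetrator and its metabolites
have reached steady state.

## 7. Synthetic monitoring data

The generator emulates a routine TDM extract: per-patient demographics
from the stratum ranges, VEN/BUP doses, days since the last
perpetrator-dose change, and VEN/ODV troughs equal to the assigned
virtual individual's simulated troughs times independent lognormal noise
(default GSD 1.8, matching the wide observed ranges).  Contaminated
records each violate exactly one exclusion rule — strong
CYP2D6-inhibitor or PPI comedication, missing demographics or
concentrations, immediate-release formulation, dose change fewer than
three days before sampling ("fewer than three": day 3 itself is kept),
or a documentation flag, the latter operationalized as a boolean since
no finer criterion is given — and a ground-truth log records which.
What the generator does *not* emulate: real covariate correlations
(age–dose, adherence), assay error structure, genotype distributions, or
multiple visits per patient.  Passing the self-consistency tests
therefore shows the pipeline recovers its own truth under noise, not
that the model fits any particular clinical population.

## 8. Numerical choices

* Internal units: µmol, µM, minutes, L/min; doses convert mg→µmol via
  molecular weight at intake; reports convert µM→ng/mL via molecular
  weight.
* Solver: `deSolve::lsoda` on a compiled C right-hand side;
  rtol 1e-6, atol 1e-9 µmol; default output grid 0.25 h (0.5 h in
  population studies), always including dose times.  Solver failures
  surface as errors with diagnostics, never as silent NaN; concentrations
  a rounding error below zero are clamped to 0.
* The Weibull rate at the lag boundary (singular for shape < 1) is
  evaluated at max(t − t_lag, 1e-12); mass balance over a full 27-day
  protocol closes to ~1e-7 relative (tested bound 0.5 %).
* Intravenous boluses at t = 0 enter through the initial state; later
  boluses via solver events.  Trapezoidal NCA on a fixed grid cannot
  resolve the minutes-scale venous mixing spike after a bolus — tests
  that need an exact AUC against a closed form use oral input, for which
  plasma AUC equals Dose/(fu·Clint) exactly for a liver-only-cleared
  compound.
* Ties in `tmax` resolve to the earliest grid point; empirical
  percentiles use the linear-interpolation convention with a closed
  [p5, p95] interval.
* Problem sizes in the shipped tests are chosen for a laptop-class
  single-core run: populations of 2–8 individuals for study reports,
  500 synthetic records over a recycled 3-individual population for the
  self-consistency check, 0.5–1 h output grids where profiles are only
  aggregated.  The calibration itself runs on a single reference adult
  (one 18-day simulation per objective evaluation, ~0.3 s each).

## 9. Known limitations

* No stereoselective kinetics: racemic VEN is treated as one species,
  although the enantiomers respond differently to CYP2D6 inhibition.
* No extra-hepatic metabolism, transporters, auto-inhibition/induction
  or enterohepatic recycling; no permeability-limited organs.
* The age model is a two-parameter linear decline; renal or hepatic
  impairment, pediatric physiology and pregnancy are out of scope.
* CYP2D6 phenotype enters only through the turnover switch
  (nd 29.16, em 64.8, pm 0 min⁻¹); other polymorphisms are not modeled.
* The generic CYP3A4 inhibitor is a placeholder parameterization; triple
  -interaction output is qualitative.
* Absolute enzyme abundances are calibrated constructs: simulated
  absolute exposures inherit the two calibration targets, and only
  relative/emergent statistics should be compared across
  parameterizations.
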