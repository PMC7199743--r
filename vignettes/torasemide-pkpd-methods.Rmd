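---
title: "Population PK/PD of oral torasemide in dogs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK/PD of oral torasemide in dogs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torapkpd)
```

Torasemide is a loop diuretic used once daily in dogs with congestive heart
failure. Because both torasemide and furosemide act from the luminal side of
the thick ascending limb, the pharmacologically relevant exposure is the
amount of drug reaching the urine, not the plasma concentration. This package
implements a complete population PK/PD analysis chain for that situation:
mechanistic models for plasma kinetics, daily diuresis and daily natriuresis;
nonlinear mixed-effects estimation; a synthetic crossover-trial generator;
model-independent (NCA) summaries; and the dose-finding computation that
turns a target daily urine output into a once-daily dose.

## The structural models

### Pharmacokinetics

A two-compartment model with first-order oral absorption. Total clearance
`CL` (L/h) is partitioned into a urinary route `CL * Fu` feeding a cumulative
urinary-excretion compartment, and a non-urinary route `CL * (1 - Fu)`. The
partition is observable because the designs collect interval urinary drug
amounts alongside plasma samples. Oral bioavailability `F` is treated as a
known constant (0.98, estimated precisely in a dedicated earlier
bioavailability study) — with only extravascular dosing, `F` cannot be
separated from `CL` and the volumes.

The system is linear, so the package solves it in closed form (the hybrid
disposition eigenvalues give a tri-exponential solution per dose, superposed
over dose events). The production kernels use an O(n) recursive-decay
superposition; a naive superposition (`pk_state()`) and a generic ODE
integrator are kept as independent cross-checks in the test suite. Mass
balance — gut + central + peripheral + cumulative urinary + cumulative
non-renal equals `F` times the dose given — holds to machine precision.

Default typical values (a ~10 kg Beagle): `ka` 1.66 /h, `CL` 0.077 L/h
(7.7 mL/kg/h at 10 kg), `Fu` 0.611, `Vc` 0.145 L, `Q` 0.262 L/h,
`Vp` 0.935 L. One caveat the package surfaces rather than hides: these
parameters imply a terminal half-life near 12 h, while an elimination
half-life read off the bulk of an observed profile is nearer 6 h.
`pk_half_lives()` therefore reports the distribution, effective (mean
residence time based) and terminal half-lives side by side and does not
force agreement.

### Diuresis

Daily urine volume responds directly to the daily urinary torasemide amount
`Q_urine` (ug/day) through a power model,

\[ E = \mathrm{baseline} + 10^{\mathrm{slope}_{log10}} \, Q_{urine}^{\alpha}, \]

with typicals baseline 221 mL/day, slope −4.11 log10 mL/ug and α 2.05.
Rival direct-response forms (linear, Emax, sigmoid-Emax) are implemented for
likelihood-ratio model selection (`compare_pd_models()`); the nesting
identities (power with α = 1 equals linear; sigmoid-Emax with Hill 1 equals
Emax) hold exactly, which is what makes those comparisons valid.

The driver is the *model-predicted* individual daily urinary amount, not the
observed one: collection-timing artefacts bias observed urine, and the
predicted amount is defined for every study day. Days are aligned to 24 h
dosing intervals; diuresis is modelled only at the daily level, which is the
level at which urine chemistry is aggregated.

### Natriuresis

Daily sodium output cannot be described by a direct-response model: it peaks
on the first treatment day and then falls toward a plateau despite constant
daily drug exposure. The package models the sodium output rate `E_Na`
(mEq/h) as a turnover process with zero-order production `kforNa` and
first-order dissipation `kabsNa`; the drug stimulates production through a
sigmoid-Emax function of the daily urinary amount. A resistance state
`R_Na` in [0, 1] scales the achievable maximum (`Emax * (1 - R_Na)`) and
builds up with zero-order rate `kResON` (first-order loss `kResOFF`) — but
only while the stimulus exceeds an estimated `threshold`; otherwise the
activation term is zero and resistance decays.

The on/off rule is implemented literally, with event-located switching: the
integrator is piecewise analytic within each regime and locates threshold
crossings exactly, so the no-resistance limit (threshold above Emax) is
reproduced without error. When the literal rule would chatter (activation
pulls the stimulus below the threshold, deactivation pushes it back), the
integrator uses the exact sliding solution with the stimulus pinned at the
threshold; a chattering fixed-step RK4 oracle confirms both branches in the
tests.

Two documented readings of the published parameterisation are adopted here:
`kResON` is used with units 1/h driving the unitless resistance fraction
(consistent as printed), and the activation threshold is compared against
the instantaneous stimulus value. At the published typical values the
stimulus at the lowest study dose (~0.93) already exceeds the printed
threshold (0.0547), which is hard to reconcile with the reported claim that
only the lowest dose stayed below threshold; the package implements the
literal rule and leaves the discrepancy visible rather than guessing a
rescaling.

## Population model and estimation

Between-subject variability is exponential, `theta_i = theta * exp(eta_i)`
with `eta ~ N(0, omega^2)` and a diagonal `omega` matrix; CV% uses the
log-normal identity `100 * sqrt(exp(omega2) - 1)`. For the diuresis slope —
reported on a log10 scale — the log-normal deviate multiplies the
linear-scale factor `10^slope_log10` (a multiplicative deviate on a negative
log10 value would not preserve positivity or the CV% convention).

Residual error is proportional, additive or combined per channel:
`y = f * (1 + e1) + e2`. Defaults: plasma 18.4 % proportional; urinary drug
22.5 % proportional + 3.68 ug additive; diuresis 43.2 % proportional only
(no additive term is reported for this channel, and volumes are bounded away
from zero by the baseline); natriuresis 30.5 % proportional.

The marginal likelihood integrates each subject's random effects out with a
Laplace approximation around the subject's posterior mode (empirical Bayes
estimate), found by an inner quasi-Newton search with the Hessian taken by
central finite differences at the mode. This is the FOCE family of
approximations; bit-compatibility with any specific commercial estimator is
not a goal — correctness is established against closed forms (the Laplace
OFV equals the analytic marginal likelihood of a linear-Gaussian model to
1e−8 relative) and against 64-point adaptive Gauss–Hermite quadrature on a
nonlinear toy (within 0.5 OFV units).

The outer problem minimises OFV = −2 log L over log-transformed parameters
with an explicit central-difference gradient (step 1e−4 on the log scale).
The inner Laplace solves leave a numerical noise floor around 1e−5 OFV
units, so gradient steps much smaller than that would difference noise; this
is also why convergence is declared pragmatically — by the optimiser's own
relative-convergence criterion or by a restart from the incumbent failing to
improve the OFV further. Fits along genuinely flat ridges (see below) may
carry a stationarity flag while being perfectly usable local optima; the
fitted object reports the flag, the message and the restart gain.

Estimation is sequential, standard for this data pattern: the PK stage fits
plasma and urinary drug amounts jointly; the PD stages then condition on the
individual PK parameters (typicals modulated by the subject's empirical
Bayes etas) to compute each subject's daily urinary drive. Random effects
are estimated on `ka`, `CL`, `Fu` (PK), baseline/slope/α (diuresis) and
`kforNa`, `EmaxNa` (natriuresis), mirroring which parameters carry reported
variability.

Initial estimates default to the published population values — the standard
pharmacometric practice of anchoring a fit at literature estimates. For well
identified parameters the optimum is where the data put it regardless of the
start (the test suite refits from perturbed starts); for parameters the data
barely inform, the estimate stays near its literature anchor, which is the
honest behaviour and is flagged below.

### Identifiability limits

Three are worth naming:

* **`ka` typical.** With 126 % between-subject CV and 17 subjects, the
  population typical of `ka` is dominated by the sampling scatter of the
  individual etas (the published analysis reports ~50 % eta-shrinkage here
  too). Refits from different starts can land ~20 % apart in `ka` along an
  almost flat likelihood direction at essentially equal OFV.
* **Diuresis slope vs exponent.** `log10(slope)` and α trade off along a
  ridge (`Δlog10 slope ≈ −Δα · E[log10 Q]`); the fits agree on predictions
  to well under a percent while the raw coordinates can differ by a few
  percent. Tests therefore check the prediction agreement, and the joint
  recovery of both parameters is assessed only at the tolerance the ridge
  supports.
* **Resistance threshold, `kResON`, `kResOFF`.** With a piecewise-constant
  daily drive, the threshold is identified only up to the interval between
  attained stimulus levels (the likelihood is locally flat inside it), and
  the activation constants are informed mainly by the 2–3 day natriuresis
  decline and the washout days. These are fitted at the widest tolerance
  and with the literature anchor as the start.

## The synthetic trial generator

No raw data from the two source studies are available, so the package ships
a generator (`generate_trial()`, `generate_pooled_trial()`) that emulates
their designs and serves as the ground-truth harness for every estimation
claim:

* **Study 1**: 5 dogs, 5 crossover periods (placebo; 0.1/0.2/0.4/0.8
  mg/kg once daily for 14 days), rich plasma sampling on day 1 and after the
  last dose (to 72 h) with daily trough + 2 h samples between, 2-hourly
  urine collections on days 1 and 14, daily otherwise. The 0.8 mg/kg period
  is generated but flagged `excluded_from_fit` (the source analysis excluded
  it after renal histopathology findings at that dose).
* **Study 2**: 12 dogs (the study methods state 12; the abstract says 11 —
  the count is configurable), placebo plus 0.1/0.2/0.3/0.4 mg/kg dosed on
  day 1 and days 5–14, rich day-1 plasma, troughs on days 12–13, terminal
  sampling to 96 h, daily urine collections to day 16 (the exact urine
  schedule of this study is not published at sub-daily resolution; daily
  24 h collections are assumed). Twice-daily furosemide periods exist in
  the design only as placeholders — no furosemide model exists here.

Subjects draw log-normal individual parameters (`omega2 = log(1 +
(CV/100)^2)`) and uniform body weights, each from a deterministic
per-subject sub-seed, so datasets are reproducible and subjects independent;
the two studies use disjoint sub-seed streams under a shared seed. Residual
noise is applied per channel at the magnitudes above; negative noised values
are truncated at zero (counted in an attribute; the source is silent on
this); plasma below 5 ug/L and urinary drug below 20 ng/mL (against the
pro-rated collected volume) are flagged below quantification. Leading
below-limit plasma records are set to zero and retained, trailing and
interior ones removed (`apply_blq_rules()`); retained zeros are excluded
from the likelihood because a proportional-only residual model is degenerate
at `f = y = 0` and such records carry no information.

What the generator does *not* emulate — and hence what passing recovery
tests cannot show about real data: model misspecification (the fitted
structural models are exactly the generating ones), the late-course rise in
diuresis at doses ≥ 0.3 mg/kg (explicitly outside the fitted model, which
predicts no time-dependence at constant daily drive), post-treatment sodium
retention below baseline (the printed model cannot produce it, since the
stimulus is non-negative), collection-timing bias from spontaneous
urination, inter-occasion variability, and any covariate structure.

## Dose finding

At periodic steady state of a linear PK model the daily urinary amount is
exactly `F * Fu * dose` (mass balance), so the steady-state dose–response
curve and its inverse are closed-form. `solve_dose_for_target(460)` — the
severe-oedema decongestion target of 460 mL/day for a 10 kg dog — returns
0.244 mg/kg/day at the typical values. The corresponding published
recommendation is 0.26 mg/kg/day; the printed inputs do not reproduce that
figure exactly (the underlying body weight, rounding, or whether
variability-averaged rather than typical-value simulation was used is not
stated), and the package documents its own computation instead of tuning to
the printed dose; the mild-oedema target (284 mL/day) gives
0.127 mg/kg/day. Population uncertainty bands are Monte-Carlo over the
between-subject variabilities (seeded, 5th–95th percentiles), and
`abacus_report()` places model predictions next to the shipped observed
furosemide/torasemide day-9 equivalence table.

## Numerical choices and problem sizes

* Closed-form/piecewise-analytic integration everywhere in the production
  path; generic integrators (deSolve) and naive RK4 appear only as test
  oracles. Coinciding eigenvalues (`ka` equal to a hybrid rate constant;
  `kabsNa` equal to `kResOFF`) are handled by an eigenvalue nudge of one
  part in 1e8 and an exact resonance branch respectively.
* Inner Laplace: `nlminb` to 1e−12 relative tolerance, warm-started across
  outer iterations (the inner optimum is start-independent at that
  tolerance); indefinite finite-difference Hessians far from the optimum
  fall back to a ridged Cholesky.
* Outer search: log-scale parameters, explicit central-difference gradient
  (step 1e−4), relative tolerance 1e−7, one verification restart.
* Linear trapezoidal AUC (profiles are densely sampled in these designs);
  sample (n−1) standard deviations for CV summaries.
* Recovery analyses use the full pooled two-study design: 17 subjects,
  roughly 3,200 PK observations, 1,240 daily urine volumes and 1,480 sodium
  collections per replicate; three replicate trials (consecutive seeds) are
  fitted and the typical values averaged. One replicate fits in a few
  minutes on a single core.

## Limitations

The package reproduces the published analysis chain on data its own
generator creates; it does not establish the models' adequacy on new real
data. Covariate modelling, inter-occasion variability, omega covariances,
bootstrap/SIR uncertainty and a furosemide PK/PD model are out of scope.
Standard errors come from the finite-difference observed information at the
optimum (`se = TRUE`) and inherit the flat-ridge caveats above.
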