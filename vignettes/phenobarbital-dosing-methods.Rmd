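---
title: "Methods: population pharmacokinetics and dose optimization of phenobarbital in status epilepticus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population pharmacokinetics and dose optimization of phenobarbital}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

Phenobarbital disposition in critically ill adults with refractory or
superrefractory status epilepticus is described by a one-compartment model
with first-order absorption and first-order elimination. For patient $i$
with ideal body weight $\mathrm{IBW}_i$ (Brower formula from sex and
height), the typical values scale allometrically around the population
median ideal body weight $\mathrm{medIBW}$:

$$
V_i = \theta_V \left(\frac{\mathrm{IBW}_i}{\mathrm{medIBW}}\right)^{1}
e^{\eta_{V,i}}, \qquad
CL_{ik} = \theta_{CL}
\left(\frac{\mathrm{IBW}_i}{\mathrm{medIBW}}\right)^{0.75}
e^{\eta_{CL,i} + \kappa_{ik}},
$$

with lognormal interindividual variability (IIV)
$\eta_{V} \sim N(0, \omega_V^2)$, $\eta_{CL} \sim N(0, \omega_{CL}^2)$ and
lognormal interoccasion variability (IOV) $\kappa_{ik} \sim N(0,
\gamma_{CL}^2)$ on clearance, one independent deviate per occasion $k$.
Occasions are the intervals between consecutive trough samples; the first
occasion runs from the first dose to the first sample. Oral doses enter an
absorption depot scaled by the bioavailability fraction $F$; intravenous
doses are zero-order infusions (default duration 5 min) with
bioavailability 1. Residual variability is proportional,
$y = c\,(1 + \varepsilon)$, $\varepsilon \sim N(0, \sigma^2)$.

The packaged default parameters are the final population estimates for this
setting: $F = 0.96$, $k_a = 1.9\,\mathrm{h^{-1}}$ (fixed; trough-only
sampling carries no absorption-phase information), $\theta_V = 34.3$ L,
$\theta_{CL} = 0.38$ L/h at $\mathrm{medIBW} = 68.8$ kg,
$\omega_V = 0.71$, $\omega_{CL} = 0.40$, $\gamma_{CL} = 0.36$,
$\sigma = 0.082$. The implied elimination half-life is
$\ln 2 \cdot V/CL = 62.6$ h. No absorption lag is used in the default
model; `population_model(tlag = )` makes one available. All magnitudes of
the variance components are **standard deviations of log-scale effects**,
not variances — when transferring parameters to simulation tools whose
$\Omega$ blocks expect variances, they must be squared first; confusing the
two inflates the simulated spread substantially and shifts optimal doses
upward.

# The concentration engine

Between events the system
$\dot A_g = -k_a A_g$, $\dot A_c = k_a A_g + R(t) - (CL/V) A_c$
is linear with constant coefficients, so `concentration_profile()`
propagates the state exactly segment by segment, breaking at dose times,
infusion ends, occasion boundaries and requested output times. This makes
the solution exact for piecewise-constant clearance (no step-size error),
continuous across occasion boundaries, and linear in dose amounts. The
$k_a \to k_e$ degeneracy is handled by its analytic limit. A concentration
requested at a time where a dose is scheduled is evaluated immediately
*pre-dose*: all troughs in this package are pre-dose troughs. Doses sharing
a time and route are merged by summation. The engine is verified in the
test suite against adaptive ODE integration (`deSolve::lsoda`, tolerances
$10^{-11}$) over randomized mixed-route regimens with occasion-varying
clearance, to better than $10^{-6}$ mg/L.

# Estimation

The marginal likelihood integrates the conditional density
$N(y \mid c(\phi), (\sigma c(\phi))^2)$ over $(\eta_V, \eta_{CL},
\kappa_1, \dots)$ per patient; the objective function value (OFV) is
$-2\log L$. `ofv()` offers three integration routes:

* **Laplace** — a damped-Newton search for the posterior mode with a
  finite-difference Hessian; fast and deterministic.
* **Adaptive Gauss–Hermite** (`method = "agq"`) — exact in the limit of
  many nodes, available for up to two random effects per patient (i.e.
  $\gamma_{CL} = 0$); validated against dense brute-force quadrature to
  $10^{-3}$.
* **Importance sampling** (`method = "is"`) — antithetic common-random-
  number sampling from a Gaussian proposal at the mode. Deterministic
  given its seed and smooth in the parameters.

With one trough per occasion the per-patient posteriors are strongly
curved ("banana"-shaped over the prior scale), which biases a pure Laplace
maximization — it inflates $\sigma$ and deflates $\gamma_{CL}$ — and makes
fixed-node importance sampling converge slowly. `fit_population()`
therefore uses a **stochastic approximation EM (SAEM)** by default: the
E-step samples individual log-parameters $(\phi_V, \phi_{CL}, \kappa)$ by
adaptive componentwise random-walk Metropolis (per-patient random streams
keyed by patient ID, so fits are bit-reproducible and invariant to patient
ordering); the M-step is closed form for the covariate coefficients and
variance components because power/exponential covariate models are linear
in log space. $F$ has no random effect; it is updated each iteration by a
golden-section search that exploits the linearity of the profile in the
oral dose amounts ($c_j(F) = a_j + F b_j$), then smoothed by the usual
Robbins–Monro schedule (burn-in 600 iterations with step 1, then 400
iterations with step $k^{-0.7}$; 6 Metropolis sweeps per patient per
iteration). These defaults were chosen for reliable recovery on cohorts of
roughly 40–100 patients with a median of 6 troughs each; `saem_burn`,
`saem_iter` and `saem_mh` rescale them. The reported OFV at the solution
uses importance sampling (Laplace or AGQ on request via `ofv_method`); for
likelihood-ratio work near the $\chi^2$ thresholds the AGQ evaluation
should be preferred where it applies, since stochastic OFV estimates carry
finite-node bias that only partially cancels in differences.

$F$ is estimated on a logit scale and requires both routes in the data;
oral-only datasets are refused as non-identifiable. Missing height or
weight covariates are imputed by the population median. Continuous
covariates are centered at the dataset median; the power form is the
default functional form, matching the allometric structure of the final
model. Occasions are taken from the dataset's occasion column, never
re-derived.

**Covariate selection** follows stepwise forward inclusion (largest OFV
drop, at least 3.84, $p < .05$, $\chi^2_1$) and backward elimination
(retention requires a rise greater than 10.83, $p < .001$). The threshold
logic is unit-tested with stubbed fits. The calibration simulation for the
true-positive property deliberately uses a well-powered design — 80
patients, heights spanning 152–203 cm, IIV SDs 0.3/0.2 and no IOV — so
that the expected OFV drop for the allometric effect sits far above the
backward threshold; with the full default variability and the cohort's
actual IBW spread, an allometric effect of exponent 0.75–1 contributes an
expected drop of only a few points and cannot be reliably retained at
$p < .001$ from 37 patients.

**Uncertainty** comes from the nonparametric bootstrap — resampling
patients with replacement and refitting (`bootstrap_fit()`, or
`compute_rse = TRUE` inside `fit_population()`); non-convergent replicates
are dropped and counted. A numeric Hessian of the OFV is not used: the
stochastic objectives are reproducible but not smooth enough for reliable
second differences, and the deterministic Laplace surface has its optimum
elsewhere than the SAEM estimate.

**Diagnostics** (`diagnostics()`) report observed vs population and
individual predictions and a plain percentile visual predictive check:
observed 5/50/95th percentiles per time bin against the 5–95% band of the
same percentiles across datasets simulated from the fitted model on the
observed design. Prediction correction is not applied.

# The synthetic cohort

Because the underlying study deposited no data, `simulate_tdm_dataset()`
generates a cohort that emulates its design: 37 patients, 65% male,
heights from a truncated normal with median 173 cm and 5–95% range
161–187.5 cm, total body weight median 78.5 kg (51.7–93.3), mixed
oral/intravenous dosing with the route drawn per dose (oral probability
0.66), a loading dose of 10–20 mg/kg at $t = 0$, a per-patient maintenance
dose of 1–4 mg/kg every 12 h, doses rounded to 50 mg, treatment durations
lognormal with median 16 days (5–95% 2–61), and pre-dose trough sampling
at 08:00 on Mondays, Wednesdays and Fridays from a uniformly random
starting weekday — giving inter-sample gaps of 48 or 72 h and a median of
about 6 samples per patient. Observations outside the 0.6–150 mg/L
quantification range are flagged and excluded from estimation by default.
The truncated-normal/lognormal shapes are calibrated to the published
medians and 5–95% quantiles; only those summaries are emulated.
What passing recovery tests on this cohort shows is that the estimator is
consistent *under the assumed model and design*; real intensive-care data
add features the generator does not emulate (time-varying organ function,
comedication, dosing irregularities, assay batch effects), so external
evaluation remains necessary before any clinical use.

# Dose optimization

`simulate_pta()` draws virtual patients at a fixed ideal body weight with
IIV on $V$ and $CL$ and IOV on $CL$ redrawn in 48-h windows from $t = 0$
(the cohort's median monitoring interval; a 336-h horizon spans 7
occasions). Residual (assay) error is excluded: the probability of target
attainment (PTA) describes true concentrations. Parameter uncertainty is
not propagated. The target window is a trough of 18–40 mg/L; 70 mg/L marks
toxicity. Loading doses are evaluated at the $t = 12$ h trough after a
single dose; maintenance doses at the pre-dose $t = 336$ h trough (about
five half-lives, taken as steady state) under loading at $t = 0$ plus
maintenance every 12 h. `optimize_dose()` scans 100–2500 mg (step 100) for
loading and 50–500 mg (step 50) for maintenance, each grid cell with an
independent sub-seed, and ties break toward the lowest dose (safety).
`dosing_table()` assembles the per-IBW table for 55–80 kg, feeding the
route-matched optimal loading dose into the maintenance simulations, and
refuses ideal body weights outside 52.4–82.4 kg (the supported range;
allometric extrapolation beyond the observed sizes is not defensible).
The PTA surface near the optimum is flat — within about one percentage
point over ±200 mg — so at $10^4$ simulations per cell the selected dose
can scatter by one grid step between seeds; $10^5$ per cell stabilizes it.
Pooled attainment across the tabulated IBWs is computed with equal
simulation counts per IBW, so pooling and averaging coincide.

`recommend_individual_dose()` closes the precision-dosing loop: a MAP
estimate from `map_individual()` (population prior, the patient's dosing
history and troughs) yields the individual $V$ and $CL$; the recommended
maintenance dose is the grid dose whose closed-form steady-state trough
lies inside the window closest to its midpoint. Interoccasion deviates are
not projected forward — future occasions are unobserved, so the
interindividual level is used. With no monitoring data the recommendation
reduces to the population optimum for the patient's ideal body weight.

# Numerical choices and test problem sizes

Time is in hours, doses in mg, concentrations in mg/L throughout. The
engine treats times closer than $10^{-9}$ h as simultaneous. Degenerate
variance components (SD below $10^{-8}$) drop the corresponding random
effect exactly rather than sampling a near-singular dimension. The test
suite runs the dose-table reproduction at $10^4$ simulations per cell,
pooled-attainment checks at $10^4$ per IBW, engine-vs-ODE equivalence over
100 random regimens, parameter recovery on ten 100-patient cohorts, and
the covariate-selection calibration on ten 80-patient cohorts plus 100
stubbed likelihood-ratio draws; these sizes keep the full suite within a
few minutes on one core while leaving the Monte Carlo error well inside
the asserted tolerances.

# Known limitations

Two-compartment disposition, nonlinear (saturable) elimination, protein
binding and drug–drug interaction mechanisms are out of scope, as are
pharmacodynamic (seizure outcome) models and pediatric scaling. The VPC is
a plain percentile check without prediction correction. The SAEM and
importance-sampling OFV are stochastic (though exactly reproducible given
their seeds); analyses that hinge on OFV differences of a few points
should use the AGQ evaluation where the random-effect structure allows it.
Dosing recommendations inherit the flat PTA surface: neighbouring grid
doses are often practically equivalent, and the tabulated optimum should
be read with that granularity in mind.
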