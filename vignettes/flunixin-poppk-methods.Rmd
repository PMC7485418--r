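---
title: "Methods: population PK of flunixin in pre-wean piglets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population PK of flunixin in pre-wean piglets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, the estimation machinery, the
synthetic-study generator, and the numerical and design choices behind
`flunixinpk`. It is the package's methodological record: everything
here is implemented and exercised by the test suite; no empirical claim
is made that the tests or `scripts/acceptance.R` do not themselves
compute.

## Structural model

Flunixin disposition in piglets is described by a two-compartment
mammillary model with first-order elimination:

$$
\begin{aligned}
\dot A_{po} &= -k_{po} A_{po}\\
\dot A_{td} &= -k_{top} A_{td}\\
\dot A_c &= k_{po}A_{po} + k_{top}A_{td}
          - \Big(\tfrac{Cl}{V_c} + \tfrac{Q}{V_c}\Big) A_c
          + \tfrac{Q}{V_p} A_p\\
\dot A_p &= \tfrac{Q}{V_c}A_c - \tfrac{Q}{V_p}A_p
\end{aligned}
$$

with central concentration $C = A_c / V_c$. Routes differ only in how
dose mass enters: IV and IM are boluses into $A_c$; an oral dose places
$F_{po} \cdot D$ into the oral depot at the dose time; a transdermal
dose places $F_{top} \cdot D$ into the transdermal depot at the dose
time plus a lag. Internal units are minutes, milligrams, litres, and
mg/L; the I/O layer converts to µg/L (= ng/mL) and hours exactly once.

Parameters, with the reference (final-model) values shipped in
`flunixin_population_model()`:

| Parameter | Meaning | Unit | Typical value |
|---|---|---|---|
| `Cl` | systemic clearance (fast-metabolizer reference) | L/min | 0.012 |
| `beta_Cl_MET` | slow-metabolizer effect on log-Cl | – | −0.892 |
| `Vc`, `Vp` | central / peripheral volumes | L | 1.35 / 1.18 |
| `Q` | intercompartmental clearance | L/min | 0.003 |
| `F_top`, `k_top`, `Lag` | TD bioavailability, rate, lag | %, 1/min, min | 7.84, 3e-4, 26.4 |
| `F_po`, `k_po` | oral bioavailability, rate | %, 1/min | 100, 0.06 |
| `b` | proportional residual error | – | 0.294 |

Since $k_{top}$ is an order of magnitude smaller than the slow
disposition exponent, the transdermal terminal slope equals $k_{top}$
(flip-flop): $t_{1/2} = \ln 2 / k_{top} \approx 38.5$ h, versus the
disposition half-life of ≈ 8.9 h visible after IV dosing in slow
metabolizers.

**Solution method.** The system is linear, so profiles are computed in
closed form — a biexponential disposition kernel (exponents from the
quadratic in $Cl/V_c$, $Q/V_c$, $Q/V_p$) superposed per dose, with the
standard three-exponential expression for first-order input. A generic
eigen-decomposition path (`solve_states`) propagates the full
compartment state plus cumulative elimination for mass-balance audits,
and an adaptive ODE integration (deSolve) serves as the independent
oracle in the tests (agreement to 1e-8 relative). Closed form was
chosen because SAEM evaluates on the order of $10^5$ profiles per fit.
Repeated-exponent degeneracy (absorption rate colliding with a
disposition exponent) is handled by a 1e-8 relative nudge — far below
every other error scale.

**IM input.** The final parameterization lists no IM absorption
parameters and treats IM bioavailability as complete, so IM doses are
modeled as central boluses, exactly like IV. An optional first-order IM
depot (`im_depot` argument) exists for sensitivity analyses only.

**Crossover carry-over.** Phase-2 period 2 is *not* reset to zero: the
period-1 doses stay in the schedule and superposition handles the
residue. With the reference parameters the typical carry-over at the
end of TD sampling (216 h) is already below the LLOQ, which the tests
assert.

## Hierarchical model and SAEM

Individual parameters are log-normal,
$\phi_i = \mu\,e^{\eta_i}$, with two exceptions on the logit scale
($\mathrm{logit}\,F_i = \mathrm{logit}\,\xi + \eta_i$) so
bioavailabilities stay in (0, 1). The slow-metabolizer class enters as
$Cl_i = \mu_{Cl}\, e^{\beta \cdot MET_i + \eta_i}$ — the multiplicative
form; an additive covariate on the natural scale would not compose with
the log-normal link. Random effects of $Cl, Q, V_p, F_{top}$ carry free
correlations; all others are independent. Residual error is
proportional: $y = F(1 + b\,\varepsilon)$. Observations below the LLOQ
contribute $\Phi\!\big((\mathrm{LLOQ} - F)/(b\,\tilde F)\big)$ to the
likelihood (M3), with $\tilde F = \max(F, \mathrm{LLOQ}/2)$ — the SD
floor keeps the censored term finite where the structural prediction is
exactly zero (pre-lag samples). The floor binds only where predictions
are below 1 µg/L, i.e. where data are BLQ anyway.

`fit_saem()` implements SAEM:

* **E-step sampling.** Per subject, one independence proposal from the
  current population distribution plus two componentwise random-walk
  passes on the Gaussian scale. Random-walk scales are adapted per
  subject *and* per component toward 35% acceptance during the
  exploratory phase; posterior widths differ by orders of magnitude
  between a crossover pig with 41 observations and a phase-1 TD pig
  whose likelihood barely constrains most parameters, so shared scales
  freeze the well-informed chains (observed during development, hence
  the per-subject adaptation). Censored observations are imputed from
  their truncated-Gaussian conditionals for the residual-error
  statistic.
* **Schedule.** 300 exploratory iterations (step size 1) then 150
  smoothing iterations (step $1/(k-K_1)^{0.7}$), one chain. Simulated
  annealing during exploration prevents premature variance collapse
  (variances may shrink at most 5% per iteration).
* **M-step.** Exact: generalized least squares for the typical values
  and the covariate coefficient under the current random-effect
  precision; moment update for the structured covariance; closed-form
  update for $b$.
* **Numerical guards.** The free-correlation block is floored at
  eigenvalue 1e-2 *on the correlation scale*: maximum-likelihood
  correlation estimates of this block (true values up to 0.967) lock
  onto ±1, and a singular covariance makes the random-effect precision
  — which the M-step and the conditional samplers all use — explode.
  Logit-scale typical values are clamped to ±7 (bioavailability in
  [0.09%, 99.91%]), which is the numerical meaning of "estimated at
  >99%" for a boundary parameter.
* **Standard errors.** For the typical values and covariate effect, a
  GLS sandwich $A^{-1} B A^{-1}$ with $A = \sum X_i' W X_i$ and
  $B = \sum X_i' W (\Omega - V_i) W X_i$, where $V_i$ is the
  conditional covariance estimated from the post-convergence draws.
  Outer products of MCMC conditional scores — the textbook
  stochastic-approximation estimator — proved unusable here: the
  near-singular $\Omega^{-1}$ amplifies Monte-Carlo noise in the score
  estimates by orders of magnitude. The residual scale $b$ keeps the
  score route (scalar, stable), with split-half cross-products so
  sampling noise does not inflate the information.
* **Log-likelihood.** Importance sampling with a multivariate-t
  (5 df) proposal centred on a per-subject Laplace fit of the
  conditional posterior, defensively mixed 50:50 with the population
  prior. Moment-based proposals undercover the directions a subject's
  data do not constrain (where the conditional *is* the wide prior);
  the Laplace curvature inherits the prior's spread there
  automatically. BIC uses the subject count:
  $\mathrm{BIC} = -2\ell + k \ln N$.

**Oral bioavailability.** $F_{po}$ is logit-linked. Its IIV variance is
not identifiable from parallel-group data, so it is pinned (0.01 by
default, the final-model bookkeeping value) rather than estimated; left
free it absorbs the population-level signal and biases the typical
value. `fit_final_model()` implements the two-stage convention: a free
exploratory fit, then — only if the estimate exceeds 0.99 — a final fit
with $F_{po}$ fixed at 1. Because the generating truth sits on the
boundary $F_{po}=1$, the free estimator's sampling distribution
necessarily has a left tail: across replicate synthetic studies the
estimate is typically >99% but individual replicates can land a few
percent lower. Statements about "consistent" estimation near 100%
describe the typical replicate (the median), not a guarantee for every
draw.

**Initialization** follows the NCA-first convention: clearance and Vss
from the IV profiles (volume split evenly), $k_{top}$ from the TD
terminal slope (flip-flop makes the TD $\lambda_z$ *be* $k_{top}$),
$F_{top}$ from the TD/IV dose-normalized AUC ratio, $k_{po}$ from the
oral $t_{max}$; random-effect SDs start at 0.3, correlations at 0, $b$
at 0.3.

## Noncompartmental analysis

`estimate_lambda_z()` maximizes adjusted $R^2$ over contiguous terminal
windows of ≥3 points (candidates strictly after the peak for
extravascular routes), ties within 1e-4 broken toward more points —
the common "best fit" default. AUC/AUMC use linear-up/log-down
trapezoids by default (plain linear by config); extrapolation uses the
last positive observation. For IV profiles the initial concentration is
back-extrapolated log-linearly from the first two quantifiable points
and the time-zero segment enters the AUC. Censored observations are
excluded outright — no LLOQ/2 substitution — because the NLME stage
handles censoring properly and NCA here serves initialization and
summaries. Extravascular MRT is reported raw (absorption included); an
"absorption-corrected" MRT needs a mean absorption time no model-free
analysis of these profiles can supply, so none is invented. Vss (or
Vss/F) is Cl·MRT. The group summary reports mean/SD/median per route
with pairwise exclusion of missing metrics, and SD of a single profile
as 0 by convention.

## Synthetic-study generator

`generate_study()` reproduces the trial: 23 phase-1 piglets (IM 7 at
2.2 mg/kg; PO 8 and TD 8 at 3.3 mg/kg) sampled 0–72 h, and 16 phase-2
piglets in an IV (2.2 mg/kg, sampled to 60 h) / TD (3.3 mg/kg, sampled
to 216 h) crossover, washout 9 days after the end of period-1 sampling,
period 2 generated by superposition. Bodyweights come from the Box-Cox
sub-model (phase-appropriate), doses are mg/kg × weight, the
metabolizer class is Bernoulli(9/38), random effects are drawn from the
full reference covariance (verified positive definite; smallest
eigenvalue of the correlation block 0.027), proportional noise is
truncated at zero by resampling, and censoring applies strictly below
2 µg/L. Pre-dose (time-0) samples are generated as true zeros, stored
as BLQ, and flagged excluded — they carry no information under a model
with no endogenous baseline. Flags can emulate the real study's
exclusions (one regurgitated PO pig; 11 unverifiable IV points). The
default replicate yields ≈ 960 modelable observations with a BLQ
fraction of 13–18%, consistent with the study's order of magnitude
(≈ 16%).

What the generator does *not* emulate: assay batch effects, sampling
time deviations, dropout beyond the two exclusion flags, or any
misspecification of the structural model. Passing recovery tests
therefore demonstrates internal consistency of estimator and generator
— not robustness to the ways real data depart from the model.

**A finding worth recording:** at the published effect size
($\beta = -0.892$) and within-class variability ($\omega_{Cl} = 0.31$),
the two clearance classes overlap substantially at $n = 39$. Simulation
shows the Bayes-optimal classifier on *true* individual clearances
averages ≈ 2.3 misclassifications, and 1-D 2-means — which favours
balanced splits — averages ≈ 5 even on true values. The visually
"distinct" sub-populations reported for the real data must have been
separated more cleanly than the final parameters reproduce;
`classify_metabolizers()` is therefore tested for its proxy quality and
its behaviour on separable input, not for near-perfect recovery at the
study's own operating point.

## Dose–exposure simulation

`simulate_dose_panel()` draws, per dose (1, 2, 4, 8, 14, 20 mg/kg
transdermal by default), 500 individuals — random effects with the full
correlation structure, metabolizer mixture 9/38, phase-1 bodyweights —
and simulates noise-free courses on a 5-min grid out to 10 days (the
flip-flop half-life of ≈ 38.5 h makes a long horizon necessary; halving
the grid step moves results by <1%). Exposure against the four COX
thresholds (IC50/IC80 × COX-1/COX-2; equine values, as no porcine ones
exist) is summarized two ways:

* time the *population mean (and median) course* spends above the
  threshold, and
* the distribution of *per-individual* times above the threshold
  (mean, median, interquartile band), crossings linearly interpolated.

The distinction matters: the logit-normal bioavailability is heavy
tailed (CV ≈ 190%), so a minority of well-absorbing piglets spends many
hours above a threshold the mean course never reaches. At the reference
parameters and 20 mg/kg, the mean course peaks near 250 µg/L — below
the COX-1 IC80 of 390.52 µg/L — while the mean per-individual time
above that threshold is ≈ 8–9 h (and ≈ 0.3–0.6 h above the COX-2
IC80). Only the per-individual reading reproduces the published
conclusions ("more than 2 h" of COX-1 IC80 exposure, "less than 1 h"
above COX-2 IC80 at 20 mg/kg), so the dose-target claims are evaluated
on it; the mean-course numbers are reported alongside for completeness.

## Bodyweight sub-model

Weights follow
$(BW^\lambda - 1)/\lambda = BW_{pop} + IPV\cdot[\text{phase 2}] +
\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$, with reference values
$BW_{pop} = 1.31$, $IPV = 0.89$, $\sigma = 0.29$, $\lambda = 0.14$
(phase-1 typical weight $(1 + 0.14\cdot1.31)^{1/0.14} \approx 3.33$ kg).
The fit tries $\lambda$ from −2 to 2 in steps of 0.1 and minimizes a
spline interpolation of the SSE over the grid. One correction to the
naive reading of that recipe: the raw SSE of $(BW^\lambda-1)/\lambda$
is not comparable across $\lambda$ (its scale changes with $\lambda$;
the raw-SSE argmin sits at the grid edge). The implementation uses the
geometric-mean-normalized transform, which makes SSE proportional to
the Box-Cox profile likelihood and recovers $\lambda \approx 0.14$ from
data generated at the reference values. Sampling inverts the transform
and redraws the rare residuals with a non-positive inversion argument.

## Diagnostics and screening

Covariate screens (ANOVA for sex and MET, Pearson for bodyweight) and
pairwise random-effect correlation tests run on *one conditional
posterior draw per subject* rather than empirical-Bayes modes, the
standard shrinkage mitigation; thresholds are raw p < 0.05 with no
multiplicity correction — a documented limitation shared with common
practice in this field. `gof_diagnostics()` supplies
observation-vs-individual-prediction pairs, IWRES
$(y - F)/(b\,\tilde F)$ with lag-1 autocorrelation, and a prediction
distribution from simulated study replicates (quantiles 5–95% in steps
of 10 on a ≈ 50-min grid, residual noise included so the band is a
prediction band for observations). Axis scaling for plots
(ln(concentration + 1)) is left to the caller.

## Problem sizes and runtimes

Chosen so the full suite runs comfortably on one CPU: the default SAEM
schedule (300 + 150 iterations) fits the 39-piglet study in ≈ 40–60 s;
the parameter-recovery check uses 5 replicate studies; the generator's
self-closure test fits an enlarged 84-piglet design once with a
shortened schedule (150 + 80); the dose panel uses 500 individuals per
dose; bodyweight recovery uses 500 weights. Tolerances in the recovery
tests are set from the sampling variability implied by the design
(e.g. the fast-metabolizer clearance reference rests on ~9 piglets in
the study-sized design), not from algorithmic wishful thinking.

## Known limitations

* No between-occasion variability; the crossover is modeled with one
  parameter set per pig.
* No saturable elimination, enterohepatic recirculation, or
  transit-chain absorption; thresholds in the dose panel are static
  concentration cut-offs, not a PK/PD effect model.
* The importance-sampled log-likelihood carries Monte-Carlo noise of a
  few units; BIC comparisons across models fitted with the same
  settings are meaningful, digit-level log-likelihood values are not.
* The 2-means metabolizer classifier is honest about its operating
  point (see above); with real data one would inspect the clearance
  distribution before trusting any automatic split.
* Covariate and correlation screening use uncorrected p-values.
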