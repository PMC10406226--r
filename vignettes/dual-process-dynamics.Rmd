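---
title: "Modelling nightly drinking and desire: methods and design choices"
author: "cravedyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling nightly drinking and desire: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cravedyn)
```

## The model

`cravedyn` models two coupled nightly quantities for a person with
mild-to-moderate alcohol use disorder who is trying to moderate (not quit)
their drinking: the number of standard drinks consumed each evening, $A_n$,
and the desire (craving) to drink that evening, $D_n$, measured as a 0–12
composite of three Likert items. The two state variables evolve as a pair of
delayed difference equations:

$$D_n = d_1 A_{n-1} + d_2 D_{n-1} + d_3\,(A_{n-1} - A_{n-2})$$
$$A_n = a_1 (D_n - D_{n-1}) + a_2 A_{n-1} + a_3\,(A_{n-1} - A_{n-2})$$

Each term is a candidate mechanism of behavior change: carry-over of last
night's drinking into tonight's drinking ($a_2$) and desire ($d_1$),
persistence of desire ($d_2$), reactivity of drinking to the same-day change
in desire ($a_1$), and reaction — in either direction — to the recent
*trend* in drinking ($a_3$, $d_3$; a binge can either perpetuate itself or
trigger compensatory restraint, so these two coefficients are unrestricted
in sign while the other four are nonnegative rates).

Two conventions make the system well defined:

* **Update order.** The alcohol equation references the same-day desire
  $D_n$. We evaluate $D_n$ first (it depends only on yesterday's states) and
  then $A_n$; this is the only order that avoids a simultaneous system.
* **Initial conditions.** The two-night delay needs $A_0$, $A_1$, $D_1$.
  $A_0$ is the pre-study drinking level (average drinks/day over a 30-day
  Timeline Followback); $A_1$ and $D_1$ are the first diary day's reports.
  These are data, not estimated parameters.

The system is linear in its states, so its long-run behavior is governed by
the $3 \times 3$ companion matrix on $(A_n, A_{n-1}, D_n)$
(`companion_matrix()`): a dominant eigenvalue modulus below one gives damped
(possibly oscillatory) solutions. Three special steady states exist:
abstinence with no desire $E_0 = (0, 0)$ (always); a line of abstinent
states with constant positive desire when $d_2 = 1$ ($E_1$); and, when
$a_2 = 1$ and $d_2 \neq 1$, a line of *moderation* equilibria
$E_2 = (A^\*, d_1 A^\*/(1 - d_2))$ on which some constant level of drinking
is sustained with constant desire. Which $A^\*$ is reached depends on the
initial conditions, so `classify_equilibrium()` reports the constraint
rather than a single point. Equality with 1 is tested with a configurable
tolerance (default $10^{-9}$), since the special cases are exact conditions.

`classify_behavior()` labels a simulated alcohol path as constant, monotone,
damped-oscillatory, or growing. The thresholds are ours: differences smaller
than $10^{-8}$ of the trajectory scale count as zero, oscillation means at
least two sign changes of the successive differences, and the label is
assigned from day 2 onward because day 1 is a data-pinned value whose jump
into the dynamics is not a trend. The dominant eigenvalue modulus is
reported as a cross-check.

## Data and preprocessing

The expected input is a daily-diary (EMA) table — patient id, day 1–84,
drinks, and either a 0–12 desire composite or the three 0–4 items, of which
the first ("I really don't feel like drinking") is reverse-coded before
summing — plus a baseline table with the TLFB average. Preprocessing
follows the source study's rules:

* **Winsorization.** Pooled drink counts are capped at
  $\mathrm{round}(\bar{x} + 2s)$ (sample standard deviation); for the
  reference cohort this cap is the integer 17, which can be imposed
  directly via `fixed_cap`. Desire is never winsorized. Applying the same
  cap twice changes nothing.
* **Inclusion.** A patient enters the analysis with at least 30% of the 84
  possible days complete (both outcomes reported; the denominator is the
  full window, not days enrolled) and with data beyond day 42.
* **Lag tables.** `binned_lag_relationships()` reproduces the descriptive
  panels that motivated the linear terms: tonight's drinks or desire
  against each lagged predictor, pooled over patients, binned at integer
  predictor values, with bins supported by fewer than 10 tuples flagged. A
  tuple is used only when every field the panel needs is present on the
  consecutive calendar days involved; nothing is imputed, since imputation
  would inject exactly the serial structure the model is trying to infer.

## The synthetic cohort generator

No individual-level data are distributed with the source study, so the
package ships a generator (`generate_cohort()`) whose defaults emulate its
design: 37 patients, 84 days, population coefficients from the published
calibration, per-patient effective parameters
$\beta_i = \beta + b_i,\; b_i \sim N(0, \Psi)$ over the varying subset
$\{a_2, a_3, d_2, d_3\}$, initial conditions from truncated normals
matching the published cohort statistics, additive Gaussian noise with one
shared variance on both outcomes, and configurable missingness (default
25%, a typical daily-diary completion rate; day 1 is never masked because
it is collected at the in-person baseline visit and pins the initial
conditions). The published tables report only the diagonal of the
individual-level spread, so the default $\Psi$ is diagonal; $\sigma^2$
defaults to 1.0 on the observation scale and is likewise a fixture, not a
published value.

Three design choices deserve emphasis because they define what passing
tests do and do not show:

* **Day-1 observations are exact.** The calibration conditions on the
  day-1 values as known initial conditions. A generator that added noise to
  day 1 would therefore generate from a *different* model than the one
  being fitted, and for effective-parameter draws near the unit root the
  resulting initial-condition error amplifies geometrically — a half-drink
  day-1 error can dominate the entire likelihood. Noise is applied to days
  2 onward.
* **Latent trajectories are bounded.** With a diagonal $\Psi$ (the
  off-diagonal structure that stabilizes real patients is unpublished),
  independent draws put a nontrivial fraction of synthetic patients past
  the unit root, with latent diaries reaching $10^8$ or more drinks per
  night. Candidate patients whose noiseless trajectory exceeds 101 drinks
  (the largest raw count in the reference data) or 24 desire units in
  magnitude are redrawn. The effective-parameter distribution is therefore
  a truncated normal; `effective_population_mean()` computes its actual
  mean — the estimand a calibration on such a cohort should recover — by
  Monte Carlo from the same draw rule.
* **Rounding/clipping is off for calibration cohorts.** Rounding drinks to
  integers in 0–17 and desire to 0–12 (`round_and_clip = TRUE`) makes
  realistic-looking fixtures but steps outside the Gaussian likelihood;
  validation cohorts keep the observation model inside the assumed family.

Because the generator shares the trajectory code with the package (the
attached ground truth must be bit-for-bit reproducible), tests that compare
fitted against generating values validate the *inference machinery* — they
cannot detect a shared error in the trajectory recursion itself. That risk
is covered separately by plain-R two-line oracles and hand-evaluated
updates in the test suite. What passing recovery tests do **not** show is
robustness to features real EMA data have and the generator omits:
weekday/weekend periodicity, assessment reactivity, informative (non-MCAR)
missingness, and integer reporting.

## Identifiability screening

With all nine quantities (six coefficients, three initial conditions)
treated as mixed effects, a 37-patient calibration would have to determine
388 quantities; data-pinned initial conditions and a reduced varying subset
bring this to 163 (`count_parameters()`). The reduction is chosen by the
collinearity method: for each patient, the trajectory's local sensitivity
matrix is computed at that patient's own free six-parameter least-squares
fit (central differences, relative step 1%, absolute step $10^{-4}$ at
zero; each entry scaled by $\theta_k$ and a per-output scale — the mean
observed level of drinks or desire — a non-dimensionalization the final
index is invariant to up to its own column normalization). For every subset
of columns the index $1/\sqrt{\lambda_{\min}}$ of the unit-normalized Gram
matrix is compared with the conventional threshold of 20; indices in
[20, 30) carry a near-threshold annotation but still count as
non-identifiable. `select_common_subset()` then prefers subsets
identifiable in the most patients, larger subsets among ties, and smaller
maximum index after that; because singletons pass everywhere, this amounts
to the largest subset identifiable in *all* patients, and the full
per-subset tally is returned so the user can deliberately trade coverage
for size (as the source analysis did when it favored a four-coefficient
subset identifiable in 33 of 37 patients).

## Bayesian mixed-effects calibration

The observation model is $y_{ij} = f_{ij}(\beta_i) + \varepsilon_{ij}$,
$\varepsilon \sim N(0, \sigma^2)$, where $f$ is the *full trajectory*
simulated from the patient's initial conditions (not a one-step-ahead
prediction) and both outcomes share one error variance — matching the
published likelihood, whose kernel is
$\exp \sum_i [-\tfrac{1}{2\sigma^2} \sum_j (y_{ij} - f_{ij})^2]$ with the
random-effects prior kernel
$\exp \sum_i [-\tfrac12 (\beta_i - \beta)^T \Psi^{-1} (\beta_i - \beta)]$.
The sum over $i$ runs over patients (the source text calls the index "the
number of fixed effects", but only the patient reading makes the inner sum
over that patient's $n_i$ observations coherent). A per-outcome-variance
variant exists but is off by default.

Priors: flat (improper) on $\beta$; $\sigma^2 \sim$ Inv-Gamma with shape
$n_0/2$ and scale $n_0 s_0^2 / 2$ ($n_0 = 1$ keeps it nearly
noninformative); $\Psi \sim$ Inv-Wishart with $\rho_0 = 100$ degrees of
freedom. We parameterize the inverse-Wishart so that its *mean* is the
frequentist covariance seed $\Psi_0$, i.e. the scale matrix is
$(\rho_0 - p - 1)\Psi_0$: a large $\rho_0$ is meant to express confidence
in that seed, and with the raw covariance as the scale matrix it would
instead shrink the prior mean by a factor of about $\rho_0$, collapsing the
random effects. The seeds ($\beta_0$ as componentwise medians, $\Psi_0$ as
the sample covariance, $s_0^2$ as pooled residual variance) come from
per-patient *profile* fits with $a_1, d_1$ held at their fixed values —
free six-parameter fits can drift along the collinearity ridge, and their
varying components then pair badly with the fixed values the mixed-effects
model imposes.

Sampling is Metropolis-within-Gibbs. Per sweep: each patient's
four-dimensional block is updated by DRAM — an adaptive Metropolis proposal
whose covariance is re-estimated from that patient's chain history every
100 sweeps (scaled $2.38^2/d$), with one delayed-rejection stage that
retries a rejected move at one fifth of the proposal scale — followed by the
three conjugate draws: $\beta$ normal with mean $\bar{\beta}_i$ and
covariance $\Psi/N$ (the flat-prior conditional), $\Psi$ inverse-Wishart
with scale $S_0 + \sum_i (\beta_i - \beta)(\beta_i - \beta)^T$ and
$\rho_0 + N$ degrees of freedom, and $\sigma^2$ inverse-gamma with shape
$(n_0 + n_{\mathrm{obs}})/2$ and scale $(n_0 s_0^2 + \mathrm{SS})/2$. Two
numerical safeguards matter in practice: the *initial* proposal covariance
is the Gauss–Newton conditional covariance
$(J^T J / \sigma^2 + \Psi_0^{-1})^{-1}$ (per-patient conditionals are
orders of magnitude tighter than the population spread, and the prior term
bounds the proposal when $J^T J$ is near-singular along the ridge), and a
per-patient log-scale factor is nudged toward a 0.234 acceptance rate at
each adaptation (Roberts–Rosenthal), which keeps strongly curved patient
posteriors from stalling. Burn-in discards the first half; adaptation and
delayed rejection can each be disabled, reducing the block update to plain
Metropolis–Hastings for testing. Nonnegativity of $a_2, d_2$ is enforced by
rejecting proposals outside the support.

Diagnostics are standard Geweke $z$-scores (first 10% vs last 50%) and
effective sample sizes via `coda`, plus per-patient acceptance rates; the
exact convergence criteria of the source analysis are in an unavailable
supplement, so these conventional substitutes are used.

## Global sensitivity analysis

`default_ranges()` centers every input on its population value with a span
of ±2 individual-level standard deviations, floors the initial conditions
and $d_2$ at 0.001, and sets $a_1 \in [0.001, 1.0015]$,
$d_1 \in [0.001, 2.2742]$ — maxima chosen (in the source analysis) so that
solutions with all other inputs at baseline never exceed 17 drinks on any
day; the package verifies that property rather than assuming it. The
initial-condition ranges use the cohort's mean ±2 sd with the same floor;
the source states that the initial conditions entered the sampling but not
their ranges, so this symmetric rule is our documented assumption.

Designs are Latin hypercubes (`lhs`), one uniform draw per equal stratum
per input; outputs are total and maximum daily alcohol and desire over 84
days and one year, computed with non-negativity clipping on (solutions are
bounded to be biologically plausible during sweeps, with tonight's clipped
desire feeding the same-day alcohol update). PRCC is computed by rank
transformation (average ranks at ties), residualizing each input and the
output on all other inputs' ranks, and correlating the residuals; the
significance transform $\gamma\sqrt{(n - 2 - k)/(1 - \gamma^2)}$ is
referred to a $t$ distribution with $n - 2 - k$ degrees of freedom,
two-sided, unadjusted for multiplicity (36 PRCC values; the source states
no adjustment either). The default design size is 1000 (unpublished in the
source; configurable). Monotonicity sweeps vary one input over its range on
an even grid with the rest frozen at baseline, and call a response
non-monotone when its successive differences change sign beyond a
$10^{-9}$ relative tolerance; PRCC is a rank method, so these sweeps are
the check that monotonicity — its validity condition — roughly holds.

## Problem sizes and numerical choices

The packaged analyses and tests run at the study's own scale where that is
cheap (37 patients × 84 days for generation, preprocessing,
identifiability, and the five-replicate recovery experiment at 5000 sweeps
each) and at reduced scale where full length adds nothing to the property
being checked (300-sweep chains for reproducibility checks, LHS designs of
a few hundred points for distributional properties). Trajectory residual
sums are computed in compiled code; a residual sum exceeding $10^{12}$ is
treated as effectively infinite by the per-patient optimizer, whose
objective is minimized by Nelder–Mead from a one-step-ahead regression
start (with the fixed coefficients imposed as offsets in the profile case)
plus jittered restarts.

## Limitations

The model is linear by design — the source data supported linear terms —
and carries no treatment covariates, no weekday structure, and no
reactivity trend. The identifiability method is local: its verdict depends
on the evaluation point, and a patient flagged non-identifiable at one
local optimum may pass at another. The synthetic generator validates the
pipeline's statistical machinery, not its robustness to the reporting
artifacts of real diaries; conclusions about real-patient parameter values
should come from the published tables, which this package ships as
fixtures and does not attempt to re-derive.
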