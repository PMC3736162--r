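---
title: "Multistate Markov decision analysis of transplantation timing in MDS: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistate Markov decision analysis of transplantation timing in MDS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdshsct)
```

## The decision problem

Allogeneic hematopoietic stem cell transplantation (HSCT) is the only
curative treatment for myelodysplastic syndromes (MDS), but it carries
substantial transplant-related mortality. For a patient diagnosed at low
risk the question is not *whether* but *when*: transplanting early exposes
a patient with indolent disease to procedure-related death, while waiting
risks progression to stages where post-transplant outcomes are much worse.
`mdshsct` frames this as a continuous-time multistate Markov decision
analysis: fit the natural history of the disease and the effect of
transplantation from cohort data, then compare the life expectancy implied
by *delayed-transplantation policies* against never transplanting.

## The model

Disease states are the categories of a prognostic score — IPSS (Low,
Int-1, Int-2, High) or WPSS (Very-low … Very-high) — plus leukemic
evolution (AML) and death. The process is a time-homogeneous
continuous-time Markov chain with generator $Q$: from any risk state the
allowed moves are to the next risk state, to AML, and to death; AML can
only move to death; death is absorbing. MDS does not improve in this
model, so the chain is monotone in risk and $Q$ is upper triangular in the
state ordering.

Transplantation enters as a time-dependent binary covariate acting on
mortality. In state $k$, the post-HSCT death intensity is
$q_{kD} e^{\beta_k}$, a per-state hazard ratio $e^{\beta_k}$ relative to
untransplanted patients in the same state. Progression intensities are
left unchanged after HSCT. This is a deliberate reduction: in registry
data the disease state is not re-staged after transplantation, so a
separate post-transplant progression effect is not identifiable from the
available follow-up, and we do not expose one. The practical consequence —
worth keeping in mind when reading policy tables — is that the net benefit
of transplantation in state $k$ is carried entirely by where $e^{\beta_k}$
sits relative to 1, the *mortality-equalizing level*: an infinitesimal
delay in state $k$ changes expected survival with the sign of
$\beta_k$, because waiting and transplanting-on-progression lead to the
same post-transplant trajectory and differ only in the death intensity
experienced while waiting. Transplantation is not an option in the
very-low WPSS state, so no hazard ratio is modeled there.

## Likelihood

Cohort data are panel observed: the state is known exactly at visit times,
transitions between visits are interval censored, death times are exact
(with the state immediately before death unknown), and end of follow-up
alive is administrative censoring with unknown state. The contribution of
an interval of length $\Delta$ starting in state $i$ is

* panel, ending state $j$ observed: $P_{ij}(\Delta)$,
* exact death: $\sum_{m \ne D} P_{im}(\Delta)\, q^{\mathrm{eff}}_{mD}$,
* censor: $\sum_{m \ne D} P_{im}(\Delta)$,

with $P(\Delta) = e^{Q^{\mathrm{eff}} \Delta}$ and $Q^{\mathrm{eff}}$ the
transplant-modified generator on post-HSCT intervals. An interval
containing the transplantation time is split there, with the covariate
constant on each piece and the pieces chained by matrix multiplication.

Two cohorts inform different parts of the likelihood, mirroring the
two-sample design of supportive-care registries and transplant registries:
natural-history subjects contribute covariate-0 intervals from diagnosis;
transplanted subjects enter at transplantation, in a known state, with
covariate 1 thereafter, and contribute no pre-transplant intervals. A
single joint likelihood over both cohorts is maximized; the baseline
intensities are identified mainly by the first cohort and the hazard
ratios by the second. Pre-transplant treatment intervals (e.g. induction
chemotherapy before HSCT) are not modeled.

Estimation is by BFGS on the log scale (log intensities and log hazard
ratios, at most 20 parameters), with finite-difference gradients
(step `1e-5`), relative-tolerance stopping at `1e-8`, and the covariance
taken as the inverse numerical Hessian at the maximum. Fits are
deterministic given data and options. Because the generators are
triangular, transition probabilities inside the likelihood are computed
from an eigendecomposition (the eigenvalues are the diagonal), vectorized
over all observation intervals at once; if the decomposition is defective
or ill-conditioned (nearly equal total exit rates) the code falls back to
a dense scaling-and-squaring matrix exponential per interval. Identical
intervals are collapsed with multiplicities, which is what makes regular
visit grids cheap. Transitions with no directly observed events are
reported with a boundary warning rather than an error; their intensities
are not meaningfully estimated.

Goodness of fit is assessed the standard way for multistate models:
model-implied survival curves $S(t) = 1 - P_{i D}(t)$ are overlaid on
Kaplan–Meier estimates (`km_estimator()`, a thin wrapper over
`survival::survfit`), via `model_survival_curve()` and `plot_gof()`.

## Policies and their value

A policy is a threshold state $s^*$, a delay $t$ (months; converted to
years as $t/12$), an age at diagnosis $a_0$, and an eligibility cutoff
(65 years by default, strict): no transplant below $s^*$; on *first* entry
into $s^*$ a transplant is scheduled $t$ months later (the clock is not
restarted); leaving $s^*$ alive before the scheduled time — including
direct jumps from below $s^*$ into AML, which we treat as progression —
triggers immediate transplantation; any transplant, scheduled or
triggered, executes only while current age is under the cutoff, and a
missed schedule is never rescheduled. After transplantation the
transplant-modified intensities apply permanently.

Expected survival from diagnosis under a policy is computed algebraically.
The building block is the phase-type expectation: for transient states
with subgenerator $T$, entry distribution $\alpha$ and state weights $w$,
the expected weighted time to absorption is $\alpha^\top (-T)^{-1} w$.
The policy value decomposes into

1. weighted occupancy of the states below $s^*$ before the eligibility
   deadline ($\int_0^{T_E} e^{Q_B u}\,du = Q_B^{-1}(e^{Q_B T_E} - I)$,
   closed form),
2. natural continuation for patients still below $s^*$ when eligibility
   lapses (closed form),
3. immediate-transplant value for bypass jumps into AML (closed form),
4. the entry-time integral into $s^*$: the sojourn in $s^*$ is
   exponential, so conditioning on entry time $u$ gives a closed-form
   entry value that depends only on the nearer of the scheduled time and
   the eligibility deadline. Where the schedule governs ($u < T_E - t/12$)
   the entry value is constant and the integral is closed form; on the
   remaining window of length $\min(t/12, T_E)$ the integrand is smooth
   and is integrated by composite Simpson on a 0.01-year grid, with a
   half-step evaluation giving a Richardson error estimate that is
   reported as `numeric_tolerance` (typically far below the 1e-3-year
   target).

Delay-0 policies, NEVER policies, and patients at or past the eligibility
age reduce to fully closed-form values, which is the basis of the
null-equivalence tests.

Quality adjustment weights state occupancy by utilities: 1 for very-low
WPSS; 0.95 for low/intermediate WPSS and low/Int-1 IPSS; 0.90 for
high/very-high WPSS and Int-2/high IPSS; 0.85 for AML; and a constant 0.9
for all post-transplant survival (an average over chronic graft-versus-
host outcomes). Utilities enter as occupancy weights only; there is no
temporal discounting. QALY values therefore never exceed life expectancy,
with equality exactly at unit utilities.

## Validation by microsimulation and bootstrap

`microsim_value()` estimates the same policy value by exact-event Monte
Carlo: per state, a total-rate exponential sojourn plus a categorical
destination (the same law as per-transition exponential races, with fewer
draws), with deterministic interrupts at the scheduled transplant time and
eligibility checks at trigger events. The simulator and the algebraic
engine share one implementation of the policy semantics, so the
cross-check (agreement within 3 Monte-Carlo standard errors at
200,000 paths) tests the algebra, not a second copy of the rules. One
seeded sequential stream drives each run; `simulate_path()` reproduces a
single trajectory bitwise from its own seed. Paths are truncated at a
120-year horizon, beyond which occupancy is negligible for any plausible
generator; the estimator warns if more than 0.1% of paths are truncated.

Uncertainty in policy values is by nonparametric bootstrap
(`bootstrap_policy_ci()`): subjects are resampled with replacement
*within* each cohort — preserving the two-sample design and both cohort
sizes — the model is refitted (warm-started at the full-data estimate),
and the policy value recomputed; the interval is the 2.5–97.5 percentile
range over successful replicates. Percentile intervals were chosen over
BCa for simplicity; replicates that fail to converge are dropped and the
result is flagged if more than 20% fail.

## The synthetic-data generator

No individual-level MDS cohort is shipped or downloaded; the package
instead generates cohorts from known *fixture* parameters
(`default_fixture_parameters()`), so that every stage — likelihood,
policy algebra, microsimulation, bootstrap — can be tested against a
known truth. The fixture values are invented, not estimates from any real
cohort, and are chosen once to carry the qualitative structure the
analysis assumes:

* death intensities strictly increase along the risk ordering, AML worst;
* the post-HSCT mortality ratio is far above 1 in the lowest risk state
  (procedure-related mortality dwarfs a low baseline) and at or below the
  mortality-equalizing level from intermediate risk upward. Given the
  death-only covariate reduction described above, this is precisely the
  configuration that produces the expected clinical pattern: transplanting
  at diagnosis in the lowest state *loses* life expectancy, waiting for
  progression to intermediate risk and transplanting immediately
  *maximizes* the gain, and every further delay loses ground.

The natural-history generator emulates a supportive-care registry:
everyone enters in the lowest risk state at diagnosis, disease staging is
recorded at scheduled visits every 0.5 years (a plausible registry
cadence), death dates are exact, and administrative censoring is at
15 years. The transplant-cohort generator emulates a transplant registry:
entry at transplantation in a transplantable state drawn from a
registry-shaped mix (weighted to intermediate/high risk with a share of
AML evolved from MDS), survival-only follow-up for 10 years, covariate 1
throughout. Demo sizes default to 660 supportive-care and 477 transplanted
subjects.

Real registry data differ in ways the generator deliberately ignores:
visit schedules are irregular and can depend on disease state
(informative observation), patients are diagnosed across all risk states,
staging can be misclassified, intensities drift with calendar time and
age, and transplanted patients are re-staged occasionally. Passing the
recovery and cross-validation tests therefore demonstrates correctness of
the estimator and the policy algebra under the model's own assumptions —
not robustness to their violation.

## Problem sizes and tolerances used by the test suite

The suite exercises parameter recovery on one synthetic world of 5,000
natural-history plus 5,000 transplanted subjects (intensities with at
least 50 observed events recovered within ±15%, log hazard ratios within
±0.2), Wald-interval coverage for the low-risk hazard ratio over 50
worlds of 1,500 + 1,200 subjects (≥ 90% required), algebraic–microsim
agreement within 3 SE at 200,000 paths over six policy configurations
spanning thresholds, delays of 0–60 months and ages 40–65, and bootstrap
reproducibility at B = 200 on cohorts of 150 + 120 and 300 + 240
subjects. The recovery cohorts use a transplant entry-state mix tilted
toward the lower states so every hazard ratio is well informed. These
sizes keep the full suite in the tens of minutes on a single core while
leaving the stochastic assertions comfortable margins.

## Known limitations

Time homogeneity (no age- or duration-dependent intensities, hence no
long-term post-transplant survival plateau); death-only transplant
effects; no misclassification layer; no temporal discounting or costs;
no donor-type or conditioning stratification of policies. These follow
the scope of the underlying decision-analysis design; several would be
natural extensions of the likelihood module.
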