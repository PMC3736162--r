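# mdshsct

**When should a patient with myelodysplastic syndrome (MDS) receive an
allogeneic stem cell transplant?**

Allogeneic hematopoietic stem cell transplantation (HSCT) is the only
curative option in MDS, but it kills or harms some of the patients it is
meant to save. A patient diagnosed at low risk may live for years with
stable disease, so transplanting at diagnosis can *reduce* life
expectancy; waiting too long means transplanting at advanced stages,
where post-transplant survival is much worse. `mdshsct` is an R package
for resolving this timing question by decision analysis on a
continuous-time multistate Markov model. It is aimed at biostatisticians
and clinical researchers working with longitudinal MDS registry data
(or, more generally, panel-observed progressive diseases with an
irreversible intervention).

## The model

Disease states are the categories of a prognostic score — IPSS
(Low, Int-1, Int-2, High) or WPSS (Very-low … Very-high) — plus leukemic
evolution (AML) and absorbing death. Transitions go from each risk state
to the next one, to AML, and to death, with constant intensities
`q_ij` (per year) collected in a generator matrix `Q`, so interval
probabilities are `P(t) = exp(Qt)`. Transplantation is a time-dependent
binary covariate acting on mortality: in state `k` the post-HSCT death
intensity is `q_kD * exp(beta_k)`, a per-state hazard ratio (not modeled
in very-low WPSS, where transplantation is not an option).

The package provides:

* **Panel-data maximum likelihood** (`fit_model()`): states observed at
  visits, exact death times with unknown pre-death state, administrative
  censoring; a joint likelihood over a supportive-care cohort
  (covariate 0 from diagnosis) and a transplanted cohort (entry at
  transplantation, covariate 1).
* **Policy values in closed form** (`policy_expected_survival()`,
  `policy_table()`): expected survival from diagnosis — plain or
  QALY-weighted — under policies "transplant in state `s*` after a delay
  of `t` months, or immediately on progression, while younger than 65",
  computed by phase-type algebra with a small quadrature over the
  eligibility window.
* **Microsimulation validation** (`microsim_value()`, `simulate_path()`)
  and **bootstrap confidence intervals** (`bootstrap_policy_ci()`).
* A **synthetic-cohort generator** (`default_fixture_parameters()`,
  `generate_natural_history_cohort()`, `generate_transplant_cohort()`)
  with documented invented parameters, so the full pipeline runs and is
  tested without any external data.
* A one-call **pipeline** (`run_pipeline()`, or
  `Rscript scripts/run_pipeline.R`) writing fit, goodness-of-fit curves,
  policy tables and validation checks to CSV.

## Worked example

Fit the model to synthetic cohorts (660 supportive-care, 477 transplanted
subjects, generated from the package's documented fixture parameters) and
evaluate transplant timing policies:

```r
library(mdshsct)
true <- default_fixture_parameters("IPSS")   # invented, documented truth
ss   <- true$state_space
nat  <- generate_natural_history_cohort(true, 660, seed = 1)
tx   <- generate_transplant_cohort(true, 477, seed = 2)
fit  <- fit_model(list(nat, tx), ss)
fit
#> Multistate model fit (IPSS): 1137 subjects, 10155 intervals
#> log-likelihood -6127.498; converged
#> Transition intensities (/yr):
#>           Low   Int-1   Int-2    High     AML  Death
#> Low   -0.2559  0.2186  0.0000  0.0000  0.0139 0.0234
#> Int-1  0.0000 -0.3878  0.1990  0.0000  0.0878 0.1010
#> Int-2  0.0000  0.0000 -0.5919  0.2501  0.1164 0.2253
#> High   0.0000  0.0000  0.0000 -0.8102  0.3295 0.4806
#> AML    0.0000  0.0000  0.0000  0.0000 -1.0234 1.0234
#> Death  0.0000  0.0000  0.0000  0.0000  0.0000 0.0000
#> Post-HSCT mortality hazard ratios:
#>   Low Int-1 Int-2  High   AML
#> 6.151 1.233 0.905 0.320 0.374

hazard_ratios(fit)
#>   state        hr     lower      upper
#> 1   Low 6.1505657 2.3861505 15.8537605
#> 2 Int-1 1.2330134 0.7399359  2.0546670
#> 3 Int-2 0.9053105 0.5894147  1.3905102
#> 4  High 0.3201800 0.1704608  0.6014008
#> 5   AML 0.3738908 0.3026114  0.4619599
```

The fitted hazard ratios tell the clinical story: post-transplant
mortality is six times the (low) baseline in the Low state, but well
below baseline at high risk. The policy value of waiting:

```r
pol <- transplant_policy(ss, "Int-1", delay_months = 12, age_at_diagnosis = 40)
policy_expected_survival(fit, pol, default_utilities(ss))
#> Policy value (algebraic): life expectancy 8.325 yr, 7.723 QALY;
#> gain vs no transplant +0.707 (numeric tol 1e-12)
```

A patient diagnosed in Low at 40 who transplants 12 months after
progression to Int-1 gains 0.71 years over never transplanting (on these
fixture parameters). `policy_table()` sweeps policies, delays and ages
into the standard gain/loss table, and `microsim_value()` reproduces any
cell by simulating individual trajectories (agreement within Monte-Carlo
error is part of the test suite).

## Repository layout

```
R/                   implementation (state spaces, likelihood, policy
                     algebra, microsimulation, bootstrap, synthetic data,
                     pipeline)
tests/testthat/      unit, property and end-to-end acceptance tests
scripts/             acceptance.R, run_pipeline.R
vignettes/           methods vignette (model, assumptions, numerics,
                     design choices, limitations)
```
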