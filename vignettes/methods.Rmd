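---
title: "Methods: models, scenarios, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, scenarios, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`medicaidcap` simulates how capping federal Medicaid financing — through an
enhanced-match phase-out, a block grant, or a per-capita cap — would change
community health-center revenues and staffing capacity. This vignette is
the package's own account of the models, the synthetic data-generating
process they are tested against, and the design decisions taken where the
design was genuinely open.

## 1. Data model

The pipeline works on four tables (all CSV, UTF-8, comma separator, `.`
decimals, written with 17 significant digits so round trips are
bit-exact):

* **panel** — state-by-year health-center aggregates: patients and
  revenues by payer (Medicaid, Medicare, private, self-pay, other public),
  grant revenue, FTEs in eight staffing categories, and FTE cost totals in
  six service categories. Currency is nominal USD (units of \$1; we avoid
  the \$1,000 convention of published summary tables because implicit
  thousand-scaling is a classic source of silent errors).
* **population** — four age/sex bands (1–18, 19–49 female, 19–64, 65+)
  plus Medicaid eligibility thresholds for children, parents, and
  childless adults, stored as ratios of the federal poverty level
  (1.38 = 138% of FPL), matching their multiplicative use in the patient
  model.
* **policy** — FMAP and EFMAP schedules, expansion status and year, and a
  marketplace-expansion (QHP) flag.
* **cpi** — CPI-M and CPI-U annual growth fractions; projection years
  carry CPI-U only.

Years are calendar integers and must be contiguous within each state
because the revenue model is a lagged recursion. States whose ACA
expansion runs through subsidized marketplace plans are excluded from
quantitative runs (`exclude_qhp_states()`): their expansion revenues are
booked as private-plan revenue, which would distort Medicaid rollback
arithmetic.

## 2. Baseline model family

### Patients

Medicaid patient counts per state are fitted by least squares, without an
intercept, on five population-by-eligibility regressors: children times
the child threshold, women 19–49 times the parent threshold, adults 19–64
and 65+ times the childless-adult threshold, and the raw 19–64 band. The
no-intercept form is kept exactly as specified (an `intercept` flag exists
for robustness checks). Other payers use the four raw bands — removing the
eligibility terms collapses the two adult regressors into one — and the
private and self-pay equations add a level dummy for 2014 onward, when the
insurance marketplace opened. Regressors that are identically zero in a
fitting unit (the adult-eligibility terms in never-expanded states) are
dropped with a warning and reported as `NA`.

### Per-capita revenues

Per-capita revenue (payer revenue over payer patients) follows

$$R_t = \alpha_0 + \alpha_1 R_{t-1} + \alpha_2 t + \alpha_3 t\,\mathrm{ACA}_t + \alpha_4 t\,\mathrm{DRA}_t + \varepsilon_t,$$

with the trend centered at 2000 for conditioning. ACA switches on at each
state's *own* expansion year (not uniformly at 2014): the interaction is
meant to capture the expansion's effect on that state's revenue path, and
states that expanded in 2015 had no such exposure in 2014. DRA switches on
for years after 2005. Series are smoothed with a one-lead/one-lag moving
average (endpoints use the available two-term mean) before fitting *and*
for the projection seed — the smoother exists to absorb reimbursement-lag
artifacts, and seeding the forecast from an unsmoothed endpoint would
reintroduce exactly the artifact it removes. A fitted lag coefficient at
or above one raises an explosive-forecast flag. Forecasts iterate the
recursion dynamically and clamp at zero.

Smoothing interacts with parameter recovery: the moving average alters
series endpoints, so a smoothed fit cannot reproduce the coefficients of
an unsmoothed generating recursion exactly. Recovery tests therefore fit
with `smooth = FALSE`; applied runs keep the default `smooth = TRUE`.

### FTE costs

Service-category cost totals (compensation plus equipment depreciation)
follow an intercept plus a staff-mix linear predictor scaled by compound
labor-cost growth $(1+r)^{t-2000}$; the medical category uses three
staffing regressors (physicians, advanced-practice clinicians, other
medical personnel), other categories their own FTE count. The printed
growth term is typographically ambiguous in its source; we read it as
compound growth applied to the staff-mix predictor, the standard treatment
of labor-cost escalation. `r` is estimated by profiling a coarse grid
(steps of 0.005 across (-0.015, 0.095)) and refining with bounded
`nls(port)`; on exact (noiseless) fits the gradient cross-product is
singular, in which case the covariance is reported as `NA` and the
point estimates are kept.

### Fitting grain

Models are fitted separately by state when at least 12 usable years exist
per state, otherwise pooled across states (the choice is messaged). With
17 history years, per-state fits of 5-parameter models are feasible but
lag-coefficient estimates in short autoregressions carry O(1/n)
small-sample bias; the parameter-recovery checks therefore pool states,
which is also the configuration under which the generator's shared
coefficient vectors are the literally correct specification.

### Baseline projection

`predict()` projects patients and per-capita revenues for 2017–2024
(scenario arithmetic uses 2020–2024; 2019 values feed the per-capita-cap
deviance), holds grant revenue at its final history level, freezes service
allocation shares at their final-history-year cost proportions, grows unit
FTE costs with the fitted labor-cost model (final-history staff mix,
divided by the category FTE count), and derives baseline FTEs as allocated
revenue over unit cost. Negative projections clamp to zero with a logged
count. The Medicaid projection is split into traditional and expansion
groups by differencing against a counterfactual projection that freezes
the childless-adult eligibility threshold at its pre-expansion value —
the only attribution rule expressible with the patient model alone.

## 3. Scenario engine

Baseline Medicaid revenue is split into federal and state shares at the
state's FMAP (traditional group) or the year's EFMAP (expansion group).
The EFMAP schedule is 100% through 2016, stepping down to its statutory
90% in 2020.

* **S1 (EFMAP phase-out).** From 2020, federal funds fall by the 2016
  EFMAP−FMAP gap times projected per-capita expenditure times projected
  expansion enrollment. Nonexpansion states are untouched; state
  contributions are held at 2016 behavior throughout, in all scenarios.
* **S2 (block grant).** Federal contribution = 2016 federal contribution
  for the *traditional* population, grown by the inflation path. The
  expansion phase-out applies first, so the expansion group's baseline
  federal contribution is lost entirely. The grant is invariant to
  enrollment — the defining property of a block grant.
* **S3 (per-capita cap).** The 2020 cap is the state's mean 2015–2016
  per-capita federal contribution for the traditional population, grown by
  the inflation path and adjusted by $(1+\text{deviance}_{2019})$, where
  deviance is the state's projected per-capita expenditure relative to the
  national average in the prior year. Later years compound:
  $\text{cap}_t = \text{cap}_{t-1}(1+\pi_t)(1+\text{deviance}_{t-1})$.
  Scenario federal = cap × projected enrollment, hence homogeneous of
  degree one in enrollment.

Design decisions taken where the procedure was open:

* The default inflation factor is the fixed 2.3%/yr common to the 2017
  federal proposals; an estimated medical-CPI path (OLS of CPI-M growth on
  CPI-U growth over ≥10 overlapping years, applied to projected CPI-U) is
  available via `inflation = "cpim"`. The explicit number is the default
  because it is the one parameter all proposals stated.
* "2015–2016 levels" is implemented as the plain two-year mean.
* The deviance adjustment composes annually ("forecasted dynamically"); a
  one-time 2020 rebase is available via `compose_annually = FALSE`.
* The national average in the deviance is **unweighted** across states.
  An enrollment-weighted average would make each state's cap depend on
  every state's enrollment, destroying the cap's exact linearity in
  enrollment; the unweighted mean preserves it and is a plain reading of
  "national average per-capita expenditure".
* Shortfalls are floored at zero by default (block grants can produce
  short-term surpluses in slow-growing states, which are reported as
  negative values when `floor = FALSE`).
* Grants and non-Medicaid payer revenues pass through unchanged in every
  scenario.

Shortfall percentages divide by the group's attributed baseline Medicaid
revenue for group rows and by total baseline revenue (all payers plus
grants) for the all-group rows; zero baselines are flagged rather than
divided.

## 4. Capacity impact

Clinical cost is the budget share of the five clinical service categories
(medical, dental, mental health, substance-use treatment, other
professional services); nonclinical covers enabling and administrative
staff. The nonclinical cut fraction needed to absorb a shortfall while
preserving clinical FTEs is `shortfall / nonclinical_cost`; values above 1
are reported as-is with `feasible = FALSE` — a state that would have to
cut more than all of its nonclinical staff cannot preserve clinical
capacity budget-neutrally, and capping the number would hide how far out
of reach neutrality is.

Two enrollment assumptions bound the impact: *no cuts* (all shortfall
absorbed internally; upper bound) and *proportional cuts* (enrollment
falls by the revenue-shortfall percentage — not the federal-contribution
percentage, a configurable choice — with disenrolled patients recovering
the projected self-pay per-capita revenue on the sliding-fee scale; lower
bound). The sensitivity sweep recomputes impacts at fixed disenrollment
levels 5%–30% in 5-point steps, the range observed in state waiver
documents. Losing enabling staff plausibly lowers clinician productivity;
that feedback is deliberately not modelled, so clinical "preservation"
here is a budget statement, not a service-volume statement.

## 5. Synthetic data generator

The generator emulates the structure of the real reporting system with
known ground truth. Defaults — chosen once as the package's study
conditions — are: 8 states, 17 history years (2000–2016), projections to
2024; five expansion states (expanding in 2014 or 2015), two of them
QHP-flagged to exercise the exclusion rule, three nonexpansion. Population
bands follow exponential growth (state mean 1.5%/yr, SD 0.4pp, band
offsets SD 0.4pp) times a smooth cohort wave (amplitude 5%, band-specific
period and phase). The wave is what keeps the four bands linearly
distinguishable within a state — four clean exponentials with nearby
rates are numerically collinear, and real populations have cohort
structure. FMAPs are drawn in [0.50, 0.76]; eligibility thresholds are
child 1.6–2.5, parents 0.4–1.0, childless adults 0 jumping to 1.38 at
expansion.

Generating coefficients sit at magnitudes that reproduce realistic shares:
Medicaid per-capita revenue starting near \$400/patient and trending up,
patient populations in the tens of thousands per state, per-FTE costs on
the order of \$100k/yr with labor growth 1.5–3.5%/yr. Residual noise is
Gaussian, additive, truncated at zero (the simplest model consistent with
least-squares estimation; the truncation rate is logged and is well below
1% at defaults). Residuals are homoskedastic; state-clustered noise, which
real administrative panels plausibly exhibit, is not emulated. FTE staffing-mix
jitter (lognormal, SD 0.08) is part of the *design*, not residual noise,
so it persists in noiseless runs — without it the three medical staffing
regressors would be exactly proportional and the cost model unidentified.
The expansion effect enters only through the eligibility channel (patient
model) and the trend interaction (revenue model), never as a separate
level shift, mirroring the fitted models' structure.

Seeding: one master seed; per-channel child seeds (states, population,
patients, revenue, FTE, cost, CPI) are derived deterministically, so
partial config changes leave unrelated channels bit-identical.

What passing tests on this generator do **not** show: real UDS panels have
health-center-level heterogeneity, state-clustered and heteroskedastic
residuals, policy events beyond the two modelled indicators, and
population projections with structured (non-exponential) demographic
change. Parameter recovery and invariance results here validate the
*machinery*, not the empirical magnitudes of any published analysis —
whose headline figures depend on the full restricted panel and proprietary
projections.

## 6. Numerical choices

* Least squares uses a column-scaled QR decomposition (rank tolerance
  1e-10); coefficients and covariances are unscaled afterwards. This keeps
  near-collinear band regressors solvable without silently dropping terms.
* Identically zero columns are dropped before rank checking; genuinely
  collinear designs error, naming the aliased regressors.
* Negative projected counts/revenues clamp to zero with a logged count.
* Allocation shares renormalize to sum to one, with a message when an
  actual renormalization occurred.
* CSV doubles are written with `%.17g`, making write-read round trips
  exact.
* Problem sizes: tests and the acceptance script run 8-state panels; the
  replicate study for CI coverage uses 200 seeds with pooled fits, the
  size at which the coverage estimate's Monte-Carlo error is ~0.5pp.

## 7. Known limitations

* Non-Medicaid payer specifications reuse the Medicaid functional forms
  with eligibility regressors removed; the original payer-specific
  appendix forms were not available and are approximated as documented.
* Section 330 grant dynamics, marketplace-subsidy interactions,
  macroeconomic shocks, and provider behavioral responses are out of
  scope; grants and non-Medicaid revenues are held fixed across scenarios.
* The expansion/traditional attribution is model-based differencing, not
  administrative enrollment data.
* Per-state lag-coefficient estimates at 16 effective observations carry
  small-sample bias; pooled fits are preferred when coefficients can be
  assumed shared.
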