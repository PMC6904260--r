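# medicaidcap

Simulation toolkit for projecting how converting federal Medicaid financing
to a **block grant** or a **per-capita cap** would change community
health-center revenues and staffing capacity, state by state.

Community health centers draw the largest share of their operating revenue
from Medicaid, so proposals that cap federal Medicaid contributions fall
disproportionately on them. `medicaidcap` implements the full quantitative
pipeline needed to study such proposals on state-by-year panels shaped like
the Uniform Data System (UDS): baseline forecasting models, a financing
scenario engine, and a budget-neutral staffing-impact calculator — plus a
synthetic-data generator with known ground-truth parameters so every stage
is testable without access to restricted source data.

## The model

**Patients.** For each state *s*, year *t*, Medicaid patient counts are a
no-intercept linear combination of population-by-eligibility regressors,

```
Patients_{s,t} = b1 P_{1-18} E_child + b2 P_{19-49,F} E_parents
               + b3 P_{19-64} E_adults + b4 P_{65+} E_adults + b5 P_{19-64},
```

where `P` are census population bands and `E` are Medicaid eligibility
thresholds as ratios of the federal poverty level (the childless-adult
threshold jumps to 1.38 at the state's ACA expansion year). Other payers
use the raw population bands; private and self-pay add a level dummy from
2014 on, when the insurance marketplace opened.

**Per-capita revenues** follow a lagged recursion with policy-interaction
trends,

```
R_t = a0 + a1 R_{t-1} + a2 t + a3 t*ACA + a4 t*DRA,
```

with `ACA` the expansion-state/post-expansion indicator and `DRA` an
indicator for years after the Deficit Reduction Act of 2005. Series are
smoothed with a one-lead/one-lag moving average to absorb reimbursement
lags, and forecasts iterate the recursion dynamically from the last
observed value.

**FTE costs** per service category follow a staff-mix model with compound
labor-cost growth, `C_t = c0 + (c1 x1 + c2 x2 + c3 x3)(1+r)^(t-2000)`,
where the medical category's regressors are physician, advanced-practice
clinician, and other medical FTEs.

**Scenarios** (2020–2024, relative to baseline S0):

- **S1** — enhanced-match (EFMAP) phase-out: federal funds fall by the 2016
  EFMAP−FMAP gap times projected expansion enrollment.
- **S2** — block grant: federal contribution frozen at the 2016 traditional
  base, grown 2.3%/yr (or an estimated medical-CPI path), independent of
  enrollment.
- **S3** — per-capita cap: a capped per-enrollee amount grown by inflation
  and each state's deviance from the national-average per-capita
  expenditure, times actual projected enrollment.

Shortfalls are translated into the nonclinical (enabling + administrative)
FTE reductions needed to keep clinical FTEs at baseline budget-neutrally,
under upper-bound (no disenrollment) and lower-bound (proportional
disenrollment with sliding-fee self-pay recovery) assumptions, with a
5%–30% disenrollment sensitivity sweep.

## Worked example

```r
library(medicaidcap)

dat   <- synth_dataset(synth_config(seed = 42))   # 8 synthetic states
panel <- exclude_qhp_states(dat$panel, dat$policy)
#> excluding QHP-expansion state(s): AA, AB

fit <- hc_model(panel, dat$population, dat$policy)
#> fitting grain: state (min 17 usable years per state)
fit
#> Health-center revenue and capacity model
#>   states: 6, history: 2000-2016, grain: state
#>   payers modelled: medicaid, medicare, private, self_pay, other_public
#>   services modelled: medical, dental, mental_health, substance_use, ...

baseline <- predict(fit, dat$population, dat$policy)
scen <- run_scenarios(fit, baseline, dat$population, dat$policy, dat$cpi)
summarize_by_expansion_status(scen, dat$policy)$by_group
#>       expansion scenario       group shortfall_pct
#> 2     expansion       S1   expansion      4.23e-01
#> 3     expansion       S2   expansion      9.00e-01
#> 4     expansion       S3   expansion      1.96e-01
#> 9     expansion       S2 traditional      7.23e-02
#> 11    expansion       S3 traditional      1.37e-05
#> ...
```

The shortfall percentages are fractions of the group's baseline revenue: in
these synthetic expansion states a block grant wipes out 90% of
expansion-group Medicaid revenue (the enhanced 90% federal match
disappears) but only ~7% of traditional-group revenue, while a per-capita
cap — which still tracks enrollment — costs the expansion group ~20% and
the traditional group almost nothing. Nonexpansion states are untouched by
the EFMAP phase-out. The staffing translation shows when cuts stop being
absorbable:

```r
head(subset(fte_impact(scen, baseline, "no_cuts"), scenario == "S2"), 3)
#>   state scenario enrollment_assumption ... nonclinical_cut_pct feasible
#> 3    AC       S2               no_cuts ...                2.16    FALSE
#> 7    AD       S2               no_cuts ...                1.99    FALSE
```

A cut fraction above 1 means the state's health centers could not preserve
clinical staffing even by eliminating every nonclinical FTE.

`run_pipeline()` wraps all stages (synthesize or load CSVs, exclude, fit,
project, simulate scenarios, staffing impacts, sensitivity sweep) and
writes `baseline.csv`, `scenarios.csv`, `impact.csv`, `sensitivity.csv`,
`models.json`, and a run log; identical config and seed give byte-identical
artifacts.

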