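## Capacity impact: translate revenue shortfalls into the nonclinical
## (enabling + administrative) FTE reductions needed to preserve clinical
## FTEs budget-neutrally. Clinical staff: medical, dental, mental health,
## substance use treatment, and other professional services.

#' Nonclinical cost structure implied by a baseline projection
#'
#' Splits each state-year's projected budget into the clinical cost (the
#' five clinical service categories) and the nonclinical cost, with the
#' projected nonclinical FTE count.
#'
#' @param baseline A baseline projection from [predict.hc_model()].
#' @return A `data.frame` with `state`, `year`, `clinical_cost`,
#'   `nonclinical_cost`, `nonclinical_fte`.
#' @export
cost_structure <- function(baseline) {
  clin <- mc_clinical_services()
  clin_cost <- rowSums(
    baseline[paste0("share_", clin)]) * baseline$revenue_total
  data.frame(state = baseline$state, year = baseline$year,
             clinical_cost = clin_cost,
             nonclinical_cost = baseline$share_nonclinical *
               baseline$revenue_total,
             nonclinical_fte = baseline$fte_nonclinical,
             stringsAsFactors = FALSE)
}

#' Nonclinical FTE cut required to absorb a shortfall budget-neutrally
#'
#' The cut fraction is `shortfall / nonclinical_cost`. Values above 1 are
#' reported as-is (a state can need to "cut" more than all of its
#' nonclinical staff, signalling infeasibility) and flagged via `feasible`.
#' A zero nonclinical cost with a positive shortfall yields an infinite
#' sentinel and `feasible = FALSE`.
#'
#' @param shortfall_abs Non-negative shortfall in USD (vectorized).
#' @param nonclinical_cost Nonclinical budget in USD.
#' @return A `data.frame` with `nonclinical_cut_pct` (fraction) and
#'   `feasible`.
#' @export
compute_fte_cut <- function(shortfall_abs, nonclinical_cost) {
  if (any(shortfall_abs < 0)) stop_mc("shortfall must be floored at 0 upstream")
  cut <- ifelse(nonclinical_cost > 0, shortfall_abs / nonclinical_cost,
                ifelse(shortfall_abs > 0, Inf, 0))
  data.frame(nonclinical_cut_pct = cut, feasible = cut <= 1)
}

#' Offset a shortfall by revenue recovered from disenrolled patients
#'
#' Disenrolled Medicaid patients (`disenrollment_fraction` of projected
#' Medicaid enrollment) partially return as self-paying patients on the
#' sliding-fee scale, recovering the projected self-pay per-capita revenue
#' each. The net shortfall is floored at zero.
#'
#' @param shortfall_abs Gross shortfall in USD (vectorized).
#' @param medicaid_patients Projected Medicaid patients.
#' @param selfpay_pc Projected self-pay per-capita revenue (USD/person).
#' @param disenrollment_fraction Fraction in `[0, 1]`.
#' @return A `data.frame` with `disenrolled`, `recovered_revenue`,
#'   `net_shortfall`.
#' @export
apply_enrollment_offset <- function(shortfall_abs, medicaid_patients,
                                    selfpay_pc, disenrollment_fraction) {
  if (any(disenrollment_fraction < 0 | disenrollment_fraction > 1)) {
    stop_mc("disenrollment fraction must lie in [0, 1]")
  }
  disenrolled <- disenrollment_fraction * medicaid_patients
  recovered <- disenrolled * selfpay_pc
  data.frame(disenrolled = disenrolled, recovered_revenue = recovered,
             net_shortfall = pmax(0, shortfall_abs - recovered))
}

## Aggregate scenario shortfalls and baseline quantities per state x
## scenario over the scenario years (sums across 2020-2024).
impact_inputs <- function(scenario_results, baseline) {
  all_rows <- scenario_results[scenario_results$group == "all", ]
  cost <- cost_structure(baseline)
  agg <- stats::aggregate(all_rows["shortfall_abs"],
                          by = list(state = all_rows$state,
                                    scenario = all_rows$scenario), FUN = sum)
  yrs <- sort(unique(all_rows$year))
  bsub <- baseline[baseline$year %in% yrs, ]
  csub <- cost[cost$year %in% yrs, ]
  bagg <- stats::aggregate(
    data.frame(medicaid_patients = bsub$patients_medicaid,
               medicaid_revenue = bsub$revenue_medicaid,
               selfpay_revenue = bsub$revenue_self_pay,
               selfpay_patients = bsub$patients_self_pay,
               nonclinical_cost = csub$nonclinical_cost[
                 match(paste(bsub$state, bsub$year),
                       paste(csub$state, csub$year))]),
    by = list(state = bsub$state), FUN = sum)
  merge(agg, bagg, by = "state")
}

#' Nonclinical FTE impact per state and scenario
#'
#' Computes, for each state and scenario, the nonclinical FTE cut needed
#' to preserve clinical FTEs over the scenario years, under either
#' enrollment assumption: `"no_cuts"` (enrollment unchanged; the upper
#' bound on cuts) or `"proportional_cuts"` (enrollment falls in proportion
#' to the revenue shortfall and part of the loss is recovered from
#' sliding-fee self-pay revenue; the lower bound).
#'
#' @param scenario_results Output of [run_scenarios()].
#' @param baseline The baseline projection.
#' @param enrollment_assumption `"no_cuts"` or `"proportional_cuts"`.
#' @return An `FteImpact`-style `data.frame`: one row per state x scenario
#'   with `disenrollment_level`, `net_shortfall`, `nonclinical_cut_pct`,
#'   `feasible`.
#' @export
fte_impact <- function(scenario_results, baseline,
                       enrollment_assumption = c("no_cuts",
                                                 "proportional_cuts")) {
  enrollment_assumption <- match.arg(enrollment_assumption)
  inp <- impact_inputs(scenario_results, baseline)
  if (enrollment_assumption == "no_cuts") {
    level <- rep(0, nrow(inp))
    net <- inp$shortfall_abs
    recovered <- rep(0, nrow(inp))
  } else {
    ## enrollment falls by the revenue-shortfall percentage
    level <- pmin(1, ifelse(inp$medicaid_revenue > 0,
                            inp$shortfall_abs / inp$medicaid_revenue, 0))
    selfpay_pc <- ifelse(inp$selfpay_patients > 0,
                         inp$selfpay_revenue / inp$selfpay_patients, 0)
    off <- apply_enrollment_offset(inp$shortfall_abs, inp$medicaid_patients,
                                   selfpay_pc, level)
    net <- off$net_shortfall
    recovered <- off$recovered_revenue
  }
  cut <- compute_fte_cut(net, inp$nonclinical_cost)
  data.frame(state = inp$state, scenario = inp$scenario,
             enrollment_assumption = enrollment_assumption,
             disenrollment_level = level, gross_shortfall = inp$shortfall_abs,
             recovered_revenue = recovered, net_shortfall = net,
             nonclinical_cut_pct = cut$nonclinical_cut_pct,
             feasible = cut$feasible, stringsAsFactors = FALSE)
}

#' Disenrollment sensitivity sweep
#'
#' Recomputes the net shortfall and nonclinical cut at each fixed
#' disenrollment level (default 5% to 30% in 5-point steps, the range
#' observed in state waiver documents), producing one row per state,
#' scenario, and level. Net shortfalls are nonincreasing in the level
#' whenever self-pay recovery is positive.
#'
#' @param scenario_results Output of [run_scenarios()].
#' @param baseline The baseline projection.
#' @param levels Disenrollment fractions within `[0, 1]`.
#' @return A `data.frame` with one row per state x scenario x level.
#' @export
sensitivity_sweep <- function(scenario_results, baseline,
                              levels = seq(0.05, 0.30, by = 0.05)) {
  if (!length(levels)) stop_mc("levels must be non-empty")
  if (any(levels < 0 | levels > 1)) stop_mc("levels must lie in [0, 1]")
  inp <- impact_inputs(scenario_results, baseline)
  selfpay_pc <- ifelse(inp$selfpay_patients > 0,
                       inp$selfpay_revenue / inp$selfpay_patients, 0)
  out <- lapply(levels, function(lv) {
    off <- apply_enrollment_offset(inp$shortfall_abs, inp$medicaid_patients,
                                   selfpay_pc, lv)
    cut <- compute_fte_cut(off$net_shortfall, inp$nonclinical_cost)
    data.frame(state = inp$state, scenario = inp$scenario,
               disenrollment_level = lv,
               gross_shortfall = inp$shortfall_abs,
               recovered_revenue = off$recovered_revenue,
               net_shortfall = off$net_shortfall,
               nonclinical_cut_pct = cut$nonclinical_cut_pct,
               feasible = cut$feasible, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$state, res$scenario, res$disenrollment_level), ]
}
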