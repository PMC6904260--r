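## Scenario engine: federal/state split of Medicaid revenue and the three
## financing counterfactuals relative to baseline:
##   S1 - phase-out of the enhanced match (EFMAP) for the expansion group;
##   S2 - block grant: federal contribution frozen at the 2016 traditional
##        base and grown by an inflation factor, independent of enrollment;
##   S3 - per-capita cap: a capped per-enrollee federal amount grown by
##        inflation and each state's deviance from the national average,
##        times actual projected enrollment.

#' Split Medicaid revenue into federal and state shares
#'
#' The federal share is `fmap * revenue`; the state share is the remainder.
#' The statutory floor of 50% gives a dollar-to-dollar match; higher match
#' rates give `fmap/(1-fmap)` federal dollars per state dollar.
#'
#' @param revenue Non-negative revenue (vectorized).
#' @param fmap Federal match rate, strictly inside (0, 1).
#' @return A `data.frame` with columns `federal` and `state_share`.
#' @examples
#' split_federal_state(100, 0.5)
#' @export
split_federal_state <- function(revenue, fmap) {
  if (any(fmap <= 0 | fmap >= 1)) stop_mc("fmap must lie strictly in (0, 1)")
  if (any(revenue < 0)) stop_mc("revenue must be >= 0")
  data.frame(federal = fmap * revenue, state_share = (1 - fmap) * revenue)
}

#' Fixed-rate inflation path
#'
#' Cumulative multipliers `(1+rate)^(year-base_year)` from the base year,
#' defaulting to the 2.3% annual factor common to the 2017 federal
#' proposals.
#'
#' @param years Years to cover.
#' @param rate Annual inflation fraction.
#' @param base_year Multiplier is 1 here.
#' @return A `data.frame` of class `"inflation_path"` with `year`,
#'   `multiplier`, and a `source` attribute.
#' @export
inflation_path_fixed <- function(years, rate = 0.023, base_year = 2016L) {
  out <- data.frame(year = as.integer(years),
                    multiplier = (1 + rate)^(years - base_year))
  attr(out, "source") <- "fixed_2.3pct"
  class(out) <- c("inflation_path", "data.frame")
  out
}

#' Medical-inflation path estimated from CPI-U
#'
#' Regresses historical CPI-M growth on CPI-U growth (ordinary least
#' squares), predicts CPI-M growth for projection years from the projected
#' CPI-U path, and accumulates multipliers from the base year.
#'
#' @param cpi CPI table (schema `"cpi"`): historical rows have both series,
#'   projection rows have `cpi_u` only.
#' @param years Projection years needing multipliers.
#' @param base_year Multiplier is 1 here.
#' @param min_overlap Minimum overlapping historical years.
#' @return An `"inflation_path"` with attributes `source = "cpim_estimated"`
#'   and the fitted intercept/slope.
#' @export
estimate_cpim_path <- function(cpi, years, base_year = 2016L,
                               min_overlap = 10L) {
  hist <- cpi[!is.na(cpi$cpi_m) & !is.na(cpi$cpi_u), ]
  if (nrow(hist) < min_overlap) {
    stop_mc("need >= %d overlapping CPI-M/CPI-U years (have %d)",
            min_overlap, nrow(hist))
  }
  fit <- stats::lm(cpi_m ~ cpi_u, data = hist)
  need <- sort(setdiff(as.integer(years), NULL))
  path_years <- seq(base_year + 1L, max(need))
  u <- cpi$cpi_u[match(path_years, cpi$year)]
  if (anyNA(u)) {
    stop_mc("CPI-U missing for year(s): %s",
            paste(path_years[is.na(u)], collapse = ", "))
  }
  m_hat <- as.numeric(stats::predict(fit, data.frame(cpi_u = u)))
  mult <- cumprod(1 + m_hat)
  out <- data.frame(year = c(base_year, path_years),
                    multiplier = c(1, mult))
  out <- out[out$year %in% c(base_year, need), ]
  rownames(out) <- NULL
  attr(out, "source") <- "cpim_estimated"
  attr(out, "coefficients") <- stats::coef(fit)
  class(out) <- c("inflation_path", "data.frame")
  out
}

path_multiplier <- function(path, year) {
  m <- path$multiplier[match(year, path$year)]
  if (anyNA(m)) {
    stop_mc("inflation path lacks year(s): %s",
            paste(year[is.na(m)], collapse = ", "))
  }
  m
}

#' Baseline federal/state contribution table by coverage group
#'
#' Disaggregates baseline Medicaid revenue into traditional and expansion
#' groups (using the projection's enrollee attribution) and splits each
#' into federal and state contributions: the traditional group at the
#' state's FMAP, the expansion group at the year's EFMAP.
#'
#' @param baseline A [predict.hc_model()] baseline projection.
#' @param policy Policy table covering the projection years.
#' @return A `data.frame` with one row per state, year, and group
#'   (`traditional`/`expansion`): `enrollees`, `medicaid_revenue`,
#'   `per_capita_expenditure`, `federal`, `state_share`, `match_rate`.
#' @export
federal_share_table <- function(baseline, policy) {
  rows <- list()
  pol_key <- paste(policy$state, policy$year)
  for (grp in c("traditional", "expansion")) {
    enr <- baseline[[paste0("patients_", grp)]]
    revg <- enr * baseline$pc_revenue_medicaid
    m <- match(paste(baseline$state, baseline$year), pol_key)
    if (anyNA(m)) stop_mc("policy table does not cover all projection cells")
    rate <- if (grp == "traditional") policy$fmap[m] else policy$efmap[m]
    sp <- split_federal_state(revg, rate)
    rows[[grp]] <- data.frame(
      state = baseline$state, year = baseline$year, group = grp,
      enrollees = enr, medicaid_revenue = revg,
      per_capita_expenditure = baseline$pc_revenue_medicaid,
      federal = sp$federal, state_share = sp$state_share, match_rate = rate,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$state, out$year, out$group), ]
  rownames(out) <- NULL
  out
}

## Federal shares for observed history years, using the fitted patient
## model to attribute the expansion group within observed totals.
history_share_table <- function(model, panel, population, policy, years) {
  sub <- panel[panel$year %in% years, ]
  pop <- population[population$year %in% years &
                      population$state %in% unique(sub$state), ]
  pr <- project_patients(model$patients[["medicaid"]], pop, years)
  pr_cf <- project_patients(model$patients[["medicaid"]],
                            counterfactual_population(pop, policy), years)
  key <- paste(sub$state, sub$year)
  exp_hat <- pmax(0, pr$patients - pr_cf$patients)[
    match(key, paste(pr$state, pr$year))]
  tot_hat <- pr$patients[match(key, paste(pr$state, pr$year))]
  frac <- ifelse(tot_hat > 0, exp_hat / tot_hat, 0)
  pol_key <- paste(policy$state, policy$year)
  m <- match(key, pol_key)
  pc_obs <- sub$revenue_medicaid / pmax(sub$patients_medicaid, 1e-9)
  rows <- list()
  for (grp in c("traditional", "expansion")) {
    share <- if (grp == "expansion") frac else 1 - frac
    enr <- sub$patients_medicaid * share
    revg <- sub$revenue_medicaid * share
    rate <- if (grp == "traditional") policy$fmap[m] else policy$efmap[m]
    rows[[grp]] <- data.frame(
      state = sub$state, year = sub$year, group = grp, enrollees = enr,
      medicaid_revenue = revg, per_capita_expenditure = pc_obs,
      federal = rate * revg, state_share = (1 - rate) * revg,
      match_rate = rate, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$state, out$year, out$group), ]
}

scenario_frame <- function(shares, scenario, years) {
  sub <- shares[shares$year %in% years, ]
  data.frame(state = sub$state, year = sub$year, scenario = scenario,
             group = sub$group, baseline_federal = sub$federal,
             scenario_federal = sub$federal, shortfall_abs = 0,
             stringsAsFactors = FALSE)
}

#' Scenario S1: phase-out of the enhanced expansion match
#'
#' From 2020 on, the federal contribution for each expansion state is
#' reduced by the 2016 gap between the enhanced match (EFMAP) and the
#' state's traditional FMAP, multiplied by the projected per-capita
#' expenditure and the projected number of expansion enrollees. States that
#' never expanded are unaffected; state contributions are held at their
#' 2016 behavior throughout.
#'
#' @param shares Baseline [federal_share_table()].
#' @param policy Policy table (supplies 2016 FMAP/EFMAP).
#' @param years Scenario years (default 2020-2024).
#' @param base_year Year whose EFMAP-FMAP gap defines the reduction.
#' @return A scenario result `data.frame` (state, year, group,
#'   baseline/scenario federal, `shortfall_abs`).
#' @export
scenario_s1_efmap_phaseout <- function(shares, policy, years = 2020:2024,
                                       base_year = 2016L) {
  out <- scenario_frame(shares, "S1", years)
  pol16 <- policy[policy$year == base_year, ]
  m <- match(out$state, pol16$state)
  if (anyNA(m)) stop_mc("policy table lacks base-year rows for some states")
  gap <- pol16$efmap[m] - pol16$fmap[m]
  exp_idx <- out$group == "expansion" & pol16$expansion_state[m]
  sub <- shares[shares$year %in% years, ]
  if (any(exp_idx & (is.na(sub$enrollees) | is.na(sub$per_capita_expenditure)))) {
    stop_mc("expansion state missing enrollee or expenditure projections")
  }
  red <- ifelse(exp_idx, gap * sub$per_capita_expenditure * sub$enrollees, 0)
  out$scenario_federal <- out$baseline_federal - red
  out$shortfall_abs <- red
  out
}

#' Scenario S2: Medicaid block grant
#'
#' The federal contribution becomes a lump sum equal to each state's 2016
#' federal contribution for the traditional population, grown by the
#' inflation path, independent of projected enrollment. The enhanced-match
#' phase-out is applied first (the expansion group's federal contribution
#' is not part of the grant base), so the expansion group's baseline
#' federal contribution is lost entirely and the traditional group bears
#' the difference between its baseline federal contribution and the grant.
#'
#' @param shares Baseline [federal_share_table()].
#' @param shares_2016 History share table for the 2016 base
#'   (see [federal_share_table()] layout).
#' @param inflation An `"inflation_path"` with base year 2016.
#' @param years Scenario years.
#' @param apply_phaseout Apply the expansion phase-out first (default). If
#'   `FALSE` the expansion group keeps its baseline federal contribution
#'   (used for nesting checks).
#' @param floor Floor group shortfalls at zero (surpluses reported as
#'   negative when `FALSE`).
#' @return A scenario result `data.frame`.
#' @export
scenario_s2_block_grant <- function(shares, shares_2016, inflation,
                                    years = 2020:2024, apply_phaseout = TRUE,
                                    floor = TRUE) {
  out <- scenario_frame(shares, "S2", years)
  base16 <- shares_2016[shares_2016$group == "traditional" &
                          shares_2016$year == 2016L, ]
  m <- match(out$state, base16$state)
  if (anyNA(m)) stop_mc("missing 2016 traditional federal base for some states")
  mult <- path_multiplier(inflation, out$year)
  grant <- base16$federal[m] * mult
  trad <- out$group == "traditional"
  out$scenario_federal[trad] <- grant[trad]
  if (apply_phaseout) {
    out$scenario_federal[!trad] <- 0
  }
  out$shortfall_abs <- out$baseline_federal - out$scenario_federal
  if (floor) out$shortfall_abs <- pmax(0, out$shortfall_abs)
  out
}

#' Scenario S3: Medicaid per-capita cap
#'
#' The 2020 per-enrollee federal cap starts from the state's mean 2015-2016
#' per-capita federal contribution for the traditional population, grown by
#' the inflation path to 2020 and adjusted by the state's percent deviance
#' of projected per-capita expenditures from the (unweighted) national
#' average in the previous year. Later years compound annually:
#' `cap_t = cap_{t-1} * (1 + inflation_t) * (1 + deviance_{t-1})`. The
#' scenario federal contribution is the cap times projected enrollment, so
#' it scales one-for-one with enrollment (unlike the block grant).
#'
#' @param shares Baseline [federal_share_table()] covering 2019 onward (the
#'   2019 projection feeds the first deviance).
#' @param shares_2015_16 History share table for 2015-2016.
#' @param inflation An `"inflation_path"` with base year 2016 covering the
#'   scenario years.
#' @param years Scenario years.
#' @param compose_annually Compound the deviance adjustment each year
#'   (default); `FALSE` rebases once in the first scenario year.
#' @param floor Floor group shortfalls at zero.
#' @return A scenario result `data.frame`.
#' @export
scenario_s3_per_capita_cap <- function(shares, shares_2015_16, inflation,
                                       years = 2020:2024,
                                       compose_annually = TRUE, floor = TRUE) {
  out <- scenario_frame(shares, "S3", years)
  states <- unique(out$state)
  base <- shares_2015_16[shares_2015_16$group == "traditional" &
                           shares_2015_16$year %in% c(2015L, 2016L), ]
  pc_base <- tapply(base$federal / pmax(base$enrollees, 1e-9), base$state, mean)
  if (!all(states %in% names(pc_base))) {
    stop_mc("missing 2015-2016 per-capita federal base for some states")
  }

  ## unweighted national average of projected per-capita expenditures
  trad <- shares[shares$group == "traditional", ]
  dev_years <- seq(min(years) - 1L, max(years) - 1L)
  pc_proj <- tapply(trad$per_capita_expenditure,
                    list(trad$state, trad$year), mean)
  if (!all(as.character(dev_years) %in% colnames(pc_proj))) {
    stop_mc("baseline shares must cover year(s): %s",
            paste(setdiff(dev_years, colnames(pc_proj)), collapse = ", "))
  }
  nat <- colMeans(pc_proj[, as.character(dev_years), drop = FALSE])
  if (any(nat == 0)) stop_mc("national average per-capita expenditure is zero")
  deviance <- sweep(pc_proj[, as.character(dev_years), drop = FALSE],
                    2, nat, "/") - 1

  caps <- matrix(NA_real_, length(states), length(years),
                 dimnames = list(states, years))
  for (st in states) {
    for (k in seq_along(years)) {
      y <- years[k]
      infl_step <- path_multiplier(inflation, y) /
        path_multiplier(inflation, y - 1L)
      dev_prev <- deviance[st, as.character(y - 1L)]
      if (k == 1L) {
        caps[st, k] <- pc_base[[st]] * path_multiplier(inflation, y) *
          (1 + dev_prev)
      } else if (compose_annually) {
        caps[st, k] <- caps[st, k - 1L] * infl_step * (1 + dev_prev)
      } else {
        caps[st, k] <- caps[st, 1L] *
          path_multiplier(inflation, y) / path_multiplier(inflation, years[1L])
      }
    }
  }
  sub <- shares[shares$year %in% years, ]
  cap_t <- caps[cbind(match(out$state, states),
                      match(out$year, years))]
  out$scenario_federal <- cap_t * sub$enrollees
  out$shortfall_abs <- out$baseline_federal - out$scenario_federal
  if (floor) out$shortfall_abs <- pmax(0, out$shortfall_abs)
  out
}

#' Attach shortfall percentages and group totals to scenario results
#'
#' Adds rows for `group = "all"` (the sum over coverage groups) and
#' expresses each shortfall as a fraction of baseline revenue: group rows
#' relative to the group's attributed baseline Medicaid revenue, `"all"`
#' rows relative to total baseline revenue (all payers plus grants).
#'
#' @param scenario_result Output of one of the `scenario_*` functions.
#' @param baseline The baseline projection.
#' @param shares Baseline [federal_share_table()].
#' @return The scenario result with `"all"` rows appended and columns
#'   `baseline_revenue_group` and `shortfall_pct` added. Cells with a zero
#'   baseline get `NA` and an `undefined_pct` flag.
#' @export
compute_shortfall <- function(scenario_result, baseline, shares) {
  res <- scenario_result
  key <- function(d) paste(d$state, d$year, d$group)
  skey <- paste(shares$state, shares$year, shares$group)
  res$baseline_revenue_group <-
    shares$medicaid_revenue[match(key(res), skey)]
  agg <- stats::aggregate(
    res[c("baseline_federal", "scenario_federal", "shortfall_abs")],
    by = list(state = res$state, year = res$year, scenario = res$scenario),
    FUN = sum)
  agg$group <- "all"
  bkey <- paste(baseline$state, baseline$year)
  agg$baseline_revenue_group <-
    baseline$revenue_total[match(paste(agg$state, agg$year), bkey)]
  agg <- agg[names(res)]
  out <- rbind(res, agg)
  out$undefined_pct <- out$baseline_revenue_group <= 0
  out$shortfall_pct <- ifelse(out$undefined_pct, NA_real_,
                              out$shortfall_abs / out$baseline_revenue_group)
  out <- out[order(out$state, out$year, out$group), ]
  rownames(out) <- NULL
  out
}

#' Run the financing scenarios against a fitted model
#'
#' Convenience wrapper: builds the baseline and history share tables,
#' the inflation path, and runs the requested scenarios (S0 rows are
#' included with zero shortfall).
#'
#' @param model A fitted [hc_model()].
#' @param baseline A [predict.hc_model()] projection covering 2019 onward.
#' @param population,policy,cpi Input tables.
#' @param scenarios Subset of `c("S1", "S2", "S3")`.
#' @param inflation `"fixed"` (2.3%/yr) or `"cpim"` (estimated medical CPI).
#' @param years Scenario years.
#' @param floor Floor shortfalls at zero.
#' @return A scenario result table with shortfall percentages.
#' @export
run_scenarios <- function(model, baseline, population, policy, cpi,
                          scenarios = c("S1", "S2", "S3"),
                          inflation = c("fixed", "cpim"),
                          years = 2020:2024, floor = TRUE) {
  inflation <- match.arg(inflation)
  shares <- federal_share_table(baseline, policy)
  hist_shares <- history_share_table(model, model$panel, population, policy,
                                     2015:2016)
  path <- if (inflation == "fixed") {
    inflation_path_fixed(seq(2016L, max(years)))
  } else {
    estimate_cpim_path(cpi, seq(2017L, max(years)))
  }
  res <- list()
  s0 <- scenario_frame(shares, "S0", years)
  res$S0 <- compute_shortfall(s0, baseline, shares)
  if ("S1" %in% scenarios) {
    res$S1 <- compute_shortfall(
      scenario_s1_efmap_phaseout(shares, policy, years), baseline, shares)
  }
  if ("S2" %in% scenarios) {
    res$S2 <- compute_shortfall(
      scenario_s2_block_grant(shares, hist_shares, path, years, floor = floor),
      baseline, shares)
  }
  if ("S3" %in% scenarios) {
    res$S3 <- compute_shortfall(
      scenario_s3_per_capita_cap(shares, hist_shares, path, years,
                                 floor = floor), baseline, shares)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "inflation") <- attr(path, "source")
  out
}
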