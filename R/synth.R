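#' Configuration for the synthetic UDS-like data generator
#'
#' Builds and validates the ground-truth parameter set from which
#' [synth_dataset()] generates state-by-year panels, population tables, and
#' policy tables. Defaults emulate the structure of the real reporting
#' system: 17 history years (2000-2016), projections through 2024, eight
#' states of which five expand Medicaid and two of the expanders run their
#' expansion through subsidized marketplace plans (exercising the exclusion
#' rule).
#'
#' All currency is nominal USD; per-capita revenue coefficients follow the
#' lagged recursion `R_t = a0 + a1*R_{t-1} + a2*t + a3*t*ACA + a4*t*DRA`
#' with `t = year - 2000`, so `|a1| < 1` is required for stationarity.
#' Labor-cost growth `r` must lie in (-0.02, 0.10).
#'
#' @param n_states Number of synthetic states.
#' @param n_qhp Number of expansion states flagged as marketplace (QHP)
#'   expanders; these are excluded from quantitative runs.
#' @param expansion_share Fraction of states that expand Medicaid
#'   (QHP states count as expanders).
#' @param history_years,projection_years Integer year ranges.
#' @param true_patient_coeffs Named list per payer: for `medicaid`, the five
#'   coefficients on the population-by-eligibility regressors; for other
#'   payers, four coefficients on the raw population bands.
#' @param marketplace_dummy Named vector of level shifts applied to private
#'   and self-pay patient counts from 2014 onward.
#' @param true_revenue_coeffs Named list per payer of `c(a0, a1, a2, a3, a4)`.
#' @param true_fte_cost_coeffs Named list per cost service category:
#'   `medical` has an intercept and three slopes (physician, advanced
#'   practice clinician, other medical); other categories an intercept and
#'   one slope on the category FTE count.
#' @param labor_growth_range Per-state labor-cost growth `r` is drawn
#'   uniformly from this range.
#' @param pop_growth_mean,pop_growth_sd Mean and SD of per-state annual
#'   population growth.
#' @param band_growth_sd SD of band-specific growth offsets around the
#'   state rate (gives the four age bands distinct growth paths).
#' @param band_wave_amplitude Amplitude of the smooth cohort wave each band
#'   carries on top of its exponential path (distinct period and phase per
#'   band); keeps the four bands linearly distinguishable within a state,
#'   as cohort structure does in real populations. Set to 0 together with
#'   zero growth for exactly constant bands.
#' @param fte_jitter_sd SD of the lognormal year-to-year staffing-mix
#'   variation; part of the design (not residual noise), so it is applied
#'   even in noiseless runs.
#' @param noise_sd Named list of residual SDs for the stochastic channels:
#'   `patients` (persons), `revenue_pc` (USD/person), `fte_cost` (USD), and
#'   `cpi` (index-growth fraction).
#' @param cpi_intercept,cpi_slope CPI-M = intercept + slope * CPI-U (+ noise).
#' @param cpi_u_projected Projected CPI-U growth used for projection years.
#' @param seed Master seed; per-channel child seeds are derived from it.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_states = 8L,
                         n_qhp = 2L,
                         expansion_share = 0.625,
                         history_years = 2000:2016,
                         projection_years = 2017:2024,
                         true_patient_coeffs = list(
                           medicaid = c(0.02, 0.01, 0.015, 0.002, 0.005),
                           medicare = c(0.0005, 0.0005, 0.001, 0.02),
                           private = c(0.004, 0.002, 0.006, 0.002),
                           self_pay = c(0.003, 0.002, 0.008, 0.001),
                           other_public = c(0.001, 0.0005, 0.001, 0.001)),
                         marketplace_dummy = c(private = 3000, self_pay = -4000),
                         true_revenue_coeffs = list(
                           medicaid = c(200, 0.5, 6, 4, 2),
                           medicare = c(150, 0.5, 5, 0, 0),
                           private = c(115, 0.5, 4, 2, 0),
                           self_pay = c(30, 0.5, 1, 0, 0),
                           other_public = c(175, 0.5, 4, 0, 1)),
                         true_fte_cost_coeffs = list(
                           medical = c(200000, 220000, 120000, 70000),
                           dental = c(50000, 130000),
                           mental_health = c(30000, 110000),
                           substance_use = c(10000, 100000),
                           other_professional = c(50000, 90000),
                           nonclinical = c(80000, 75000)),
                         labor_growth_range = c(0.015, 0.035),
                         pop_growth_mean = 0.015,
                         pop_growth_sd = 0.004,
                         band_growth_sd = 0.004,
                         band_wave_amplitude = 0.05,
                         fte_jitter_sd = 0.08,
                         noise_sd = list(patients = 500, revenue_pc = 8,
                                         fte_cost = 20000, cpi = 0.002),
                         cpi_intercept = 0.015,
                         cpi_slope = 1.0,
                         cpi_u_projected = 0.023,
                         seed = 1L) {
  cfg <- list(n_states = as.integer(n_states), n_qhp = as.integer(n_qhp),
              expansion_share = expansion_share,
              history_years = as.integer(history_years),
              projection_years = as.integer(projection_years),
              true_patient_coeffs = true_patient_coeffs,
              marketplace_dummy = marketplace_dummy,
              true_revenue_coeffs = true_revenue_coeffs,
              true_fte_cost_coeffs = true_fte_cost_coeffs,
              labor_growth_range = labor_growth_range,
              pop_growth_mean = pop_growth_mean,
              pop_growth_sd = pop_growth_sd,
              band_growth_sd = band_growth_sd,
              band_wave_amplitude = band_wave_amplitude,
              fte_jitter_sd = fte_jitter_sd,
              noise_sd = noise_sd,
              cpi_intercept = cpi_intercept, cpi_slope = cpi_slope,
              cpi_u_projected = cpi_u_projected,
              seed = as.integer(seed))
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_states < 1L) stop_mc("n_states must be >= 1")
  if (cfg$n_qhp > ceiling(cfg$n_states * cfg$expansion_share)) {
    stop_mc("n_qhp cannot exceed the number of expansion states")
  }
  if (any(unlist(cfg$noise_sd) < 0)) stop_mc("noise SDs must be >= 0")
  a1 <- vapply(cfg$true_revenue_coeffs, `[`, numeric(1), 2L)
  if (any(abs(a1) >= 1)) {
    stop_mc("revenue lag coefficient |a1| must be < 1 for stationarity")
  }
  if (cfg$labor_growth_range[1] <= -0.02 || cfg$labor_growth_range[2] >= 0.10) {
    stop_mc("labor growth range must lie within (-0.02, 0.10)")
  }
  invisible(cfg)
}

## Per-state ground-truth profile (expansion status/year, FMAP, growth
## rates, eligibility thresholds). Drawn from its own child seed so that
## population, policy, and panel generation all see the same states.
synth_states <- function(config) {
  set.seed(channel_seed(config$seed, "states"))
  n <- config$n_states
  code <- paste0("A", LETTERS[seq_len(n)])
  n_exp <- min(n, ceiling(n * config$expansion_share))
  expansion <- rep(FALSE, n); expansion[seq_len(n_exp)] <- TRUE
  qhp <- rep(FALSE, n); qhp[seq_len(min(config$n_qhp, n_exp))] <- TRUE
  data.frame(
    state = code,
    expansion_state = expansion,
    expansion_year = ifelse(expansion,
                            2014L + stats::rbinom(n, 1L, 0.3), NA_integer_),
    qhp_expansion = qhp,
    fmap = stats::runif(n, 0.50, 0.76),
    pop_growth = stats::rnorm(n, config$pop_growth_mean, config$pop_growth_sd),
    r_labor = stats::runif(n, config$labor_growth_range[1],
                           config$labor_growth_range[2]),
    elig_child = stats::runif(n, 1.6, 2.5),
    elig_parents = stats::runif(n, 0.4, 1.0),
    base_age1_18 = stats::runif(n, 3e5, 9e5),
    base_age19_64 = stats::runif(n, 8e5, 2.5e6),
    base_age65_plus = stats::runif(n, 1.5e5, 6e5),
    female_ratio = stats::runif(n, 0.32, 0.38),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic population and eligibility table
#'
#' Each state's four age bands follow smooth exponential growth paths with
#' band-specific rates around the state rate. Eligibility thresholds
#' (ratios of the federal poverty level) are piecewise constant; the
#' childless-adult threshold jumps from 0 to 1.38 at the state's expansion
#' year in expansion states, emulating the ACA expansion (coverage for
#' adults under 138% of FPL).
#'
#' @param config A [synth_config()].
#' @return A population table covering history and projection years.
#' @export
generate_population <- function(config) {
  states <- synth_states(config)
  set.seed(channel_seed(config$seed, "population"))
  years <- c(config$history_years, config$projection_years)
  t0 <- min(config$history_years)
  out <- vector("list", nrow(states))
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    g <- st$pop_growth + stats::rnorm(4, 0, config$band_growth_sd)
    ## each band also carries a smooth cohort wave with its own period and
    ## phase, so the four bands are distinguishable within a state rather
    ## than four proportional exponentials
    phase <- stats::runif(4, 0, 2 * pi)
    period <- stats::runif(4, 8, 14)
    tt <- years - t0
    wave <- function(k) {
      1 + config$band_wave_amplitude * sin(2 * pi * tt / period[k] + phase[k])
    }
    p1 <- st$base_age1_18 * (1 + g[1])^tt * wave(1)
    p19_64 <- st$base_age19_64 * (1 + g[2])^tt * wave(2)
    p19_49f <- st$female_ratio * st$base_age19_64 * (1 + g[3])^tt * wave(3)
    p65 <- st$base_age65_plus * (1 + g[4])^tt * wave(4)
    ## keep the female 19-49 band inside the 19-64 band
    p19_49f <- pmin(p19_49f, p19_64)
    elig_adults <- if (isTRUE(st$expansion_state)) {
      ifelse(years >= st$expansion_year, 1.38, 0)
    } else rep(0, length(years))
    out[[i]] <- data.frame(
      state = st$state, year = as.integer(years),
      pop_age1_18 = p1, pop_age19_49_female = p19_49f,
      pop_age19_64 = p19_64, pop_age65_plus = p65,
      elig_child = st$elig_child, elig_parents = st$elig_parents,
      elig_adults = elig_adults, stringsAsFactors = FALSE)
  }
  pop <- do.call(rbind, out)
  attr(pop, "mc_schema") <- "population"
  pop
}

#' Generate the synthetic policy table (FMAP, EFMAP, expansion flags)
#'
#' FMAP is drawn per state within the statutory band (floor 50%, and here
#' at most 76%) and held constant over years. The enhanced match for the
#' expansion population is 100% through 2016, then steps down 95%, 94%,
#' 93%, reaching its statutory 90% in 2020.
#'
#' @param config A [synth_config()].
#' @return A policy table (schema `"policy"`) over history and projection years.
#' @export
generate_policy <- function(config) {
  states <- synth_states(config)
  years <- c(config$history_years, config$projection_years)
  efmap_for <- function(y) {
    ifelse(y <= 2016, 1.00,
      ifelse(y == 2017, 0.95,
        ifelse(y == 2018, 0.94,
          ifelse(y == 2019, 0.93, 0.90))))
  }
  pol <- merge(states[c("state", "expansion_state", "expansion_year",
                        "qhp_expansion", "fmap")],
               data.frame(year = as.integer(years)))
  pol$efmap <- efmap_for(pol$year)
  pol <- pol[order(pol$state, pol$year),
             c("state", "year", "fmap", "efmap", "expansion_state",
               "expansion_year", "qhp_expansion")]
  rownames(pol) <- NULL
  attr(pol, "mc_schema") <- "policy"
  pol
}

#' Generate synthetic CPI-U and CPI-M growth series
#'
#' Historical CPI-U growth follows a slow deterministic cycle around 2.1%
#' plus noise; CPI-M growth is an affine function of CPI-U
#' (`intercept + slope * CPI-U`) plus noise, mimicking medical inflation
#' running above general inflation. Projection years carry the configured
#' CPI-U growth and no CPI-M (to be predicted downstream).
#'
#' @param config A [synth_config()].
#' @return A CPI table (schema `"cpi"`) with columns `year`, `cpi_m`, `cpi_u`.
#' @export
generate_cpi_series <- function(config) {
  set.seed(channel_seed(config$seed, "cpi"))
  hy <- config$history_years
  py <- config$projection_years
  tt <- hy - min(hy)
  cpi_u_h <- 0.021 + 0.004 * sin(2 * pi * tt / 8) +
    stats::rnorm(length(hy), 0, config$noise_sd$cpi)
  cpi_m_h <- config$cpi_intercept + config$cpi_slope * cpi_u_h +
    stats::rnorm(length(hy), 0, config$noise_sd$cpi)
  cpi <- data.frame(
    year = as.integer(c(hy, py)),
    cpi_m = c(cpi_m_h, rep(NA_real_, length(py))),
    cpi_u = c(cpi_u_h, rep(config$cpi_u_projected, length(py))))
  attr(cpi, "mc_schema") <- "cpi"
  cpi
}

## Design matrix for the patient model of one payer. Medicaid uses the five
## population-by-eligibility regressors; other payers the four raw bands.
## Private and self-pay add the 2014+ marketplace dummy.
patient_design <- function(pop, payer, marketplace_year = 2014L) {
  X <- if (payer == "medicaid") {
    cbind(p1_18_child = pop$pop_age1_18 * pop$elig_child,
          p19_49f_parents = pop$pop_age19_49_female * pop$elig_parents,
          p19_64_adults = pop$pop_age19_64 * pop$elig_adults,
          p65_adults = pop$pop_age65_plus * pop$elig_adults,
          p19_64 = pop$pop_age19_64)
  } else {
    cbind(p1_18 = pop$pop_age1_18,
          p19_49f = pop$pop_age19_49_female,
          p19_64 = pop$pop_age19_64,
          p65 = pop$pop_age65_plus)
  }
  if (payer %in% c("private", "self_pay")) {
    X <- cbind(X, marketplace = as.numeric(pop$year >= marketplace_year))
  }
  X
}

true_patient_beta <- function(config, payer) {
  b <- config$true_patient_coeffs[[payer]]
  if (payer %in% c("private", "self_pay")) {
    b <- c(b, config$marketplace_dummy[[payer]])
  }
  b
}

## Latent per-capita revenue recursion for one state x payer.
revenue_recursion <- function(alpha, years, aca_on, dra_on, r_start,
                              eps = NULL, t_center = 2000L) {
  tt <- years - t_center
  r <- numeric(length(years))
  prev <- r_start
  for (k in seq_along(years)) {
    val <- alpha[1] + alpha[2] * prev + alpha[3] * tt[k] +
      alpha[4] * tt[k] * aca_on[k] + alpha[5] * tt[k] * dra_on[k]
    if (!is.null(eps)) val <- val + eps[k]
    r[k] <- val
    prev <- val
  }
  r
}

#' Generate a synthetic state-by-year health-center panel
#'
#' Patients per payer are linear combinations of population-by-eligibility
#' regressors plus Gaussian noise truncated at zero; per-capita revenues
#' follow the lagged recursion with expansion (ACA) and Deficit Reduction
#' Act (DRA, years after 2005) trend interactions; payer revenue is
#' patients times per-capita revenue; FTE cost totals follow the staff-mix
#' model with compound labor-cost growth `(1+r)^(t-2000)`. The returned
#' ground truth holds the generating coefficients, the per-state profile,
#' and the noiseless latent series.
#'
#' @param config A [synth_config()].
#' @param population Output of [generate_population()] (may be omitted).
#' @param policy Output of [generate_policy()] (may be omitted).
#' @return A list with elements `panel` (history-years StatePanel) and
#'   `truth` (ground-truth list). The truncation rate of negative draws is
#'   recorded in `truth$truncation_rate`.
#' @export
generate_panel <- function(config,
                           population = generate_population(config),
                           policy = generate_policy(config)) {
  validate_synth_config(config)
  states <- synth_states(config)
  hy <- config$history_years
  pop_h <- population[population$year %in% hy, ]
  payers <- mc_payers()
  t_center <- min(hy)

  ## --- patients ---------------------------------------------------------
  set.seed(channel_seed(config$seed, "patients"))
  n_trunc <- 0L; n_draw <- 0L
  patients <- list(); patients_latent <- list()
  for (payer in payers) {
    X <- patient_design(pop_h, payer)
    beta <- true_patient_beta(config, payer)
    latent <- as.numeric(X %*% beta)
    noisy <- latent + stats::rnorm(length(latent), 0, config$noise_sd$patients)
    n_trunc <- n_trunc + sum(noisy < 0); n_draw <- n_draw + length(noisy)
    patients[[payer]] <- pmax(0, noisy)
    patients_latent[[payer]] <- pmax(0, latent)
  }

  ## --- per-capita revenues ---------------------------------------------
  set.seed(channel_seed(config$seed, "revenue"))
  pc <- list(); pc_latent <- list()
  dra_on <- as.numeric(pop_h$year > 2005)
  for (payer in payers) {
    alpha <- config$true_revenue_coeffs[[payer]]
    pc[[payer]] <- numeric(nrow(pop_h))
    pc_latent[[payer]] <- numeric(nrow(pop_h))
    for (st in states$state) {
      idx <- which(pop_h$state == st)
      yrs <- pop_h$year[idx]
      srow <- states[states$state == st, ]
      aca_on <- if (isTRUE(srow$expansion_state)) {
        as.numeric(yrs >= srow$expansion_year)
      } else rep(0, length(yrs))
      r_start <- alpha[1] / (1 - alpha[2])
      eps <- stats::rnorm(length(yrs), 0, config$noise_sd$revenue_pc)
      pc[[payer]][idx] <- revenue_recursion(alpha, yrs, aca_on,
                                            dra_on[idx], r_start, eps,
                                            t_center)
      pc_latent[[payer]][idx] <- revenue_recursion(alpha, yrs, aca_on,
                                                   dra_on[idx], r_start,
                                                   NULL, t_center)
    }
    neg <- pc[[payer]] < 0
    n_trunc <- n_trunc + sum(neg); n_draw <- n_draw + length(neg)
    pc[[payer]] <- pmax(0, pc[[payer]])
  }

  ## --- FTEs (design variation, always applied) --------------------------
  set.seed(channel_seed(config$seed, "fte"))
  ratios <- c(medical_physician = 1 / 2500, medical_apc = 1 / 4000,
              medical_other = 1 / 1500, dental = 1 / 6000,
              mental_health = 1 / 8000, substance_use = 1 / 30000,
              other_professional = 1 / 2000, nonclinical = 1 / 1800)
  patients_total_latent <- Reduce(`+`, patients_latent)
  fte <- list()
  for (svc in mc_fte_services()) {
    jit <- exp(stats::rnorm(nrow(pop_h), 0, config$fte_jitter_sd))
    fte[[svc]] <- ratios[[svc]] * patients_total_latent * jit
  }

  ## --- FTE cost totals --------------------------------------------------
  set.seed(channel_seed(config$seed, "fte_cost"))
  growth <- (1 + states$r_labor[match(pop_h$state, states$state)])^
    (pop_h$year - t_center)
  cost <- list(); cost_latent <- list()
  for (svc in mc_cost_services()) {
    b <- config$true_fte_cost_coeffs[[svc]]
    mix <- if (svc == "medical") {
      b[2] * fte$medical_physician + b[3] * fte$medical_apc +
        b[4] * fte$medical_other
    } else {
      b[2] * fte[[svc]]
    }
    latent <- b[1] + mix * growth
    noisy <- latent + stats::rnorm(length(latent), 0, config$noise_sd$fte_cost)
    n_trunc <- n_trunc + sum(noisy < 0); n_draw <- n_draw + length(noisy)
    cost[[svc]] <- pmax(0, noisy)
    cost_latent[[svc]] <- pmax(0, latent)
  }

  ## --- assemble ---------------------------------------------------------
  panel <- data.frame(state = pop_h$state, year = pop_h$year,
                      stringsAsFactors = FALSE)
  patients_total <- Reduce(`+`, patients)
  panel$n_health_centers <- round(patients_total_latent / 2e4) + 3L
  for (payer in payers) panel[[paste0("patients_", payer)]] <- patients[[payer]]
  panel$patients_total <- patients_total
  for (payer in payers) {
    panel[[paste0("revenue_", payer)]] <- patients[[payer]] * pc[[payer]]
  }
  panel$revenue_total_patient <-
    rowSums(panel[paste0("revenue_", payers)])
  base_rev <- stats::ave(panel$revenue_total_patient, panel$state,
                         FUN = function(v) v[1])
  panel$grant_revenue <- 0.6 * base_rev * 1.02^(panel$year - t_center)
  for (svc in mc_fte_services()) panel[[paste0("fte_", svc)]] <- fte[[svc]]
  for (svc in mc_cost_services()) {
    panel[[paste0("fte_cost_", svc)]] <- cost[[svc]]
  }
  panel <- panel[order(panel$state, panel$year), panel_columns()]
  rownames(panel) <- NULL
  attr(panel, "mc_schema") <- "panel"

  trunc_rate <- n_trunc / n_draw
  if (trunc_rate > 0) {
    message(sprintf("truncated %d of %d draws (%.3f%%) at zero",
                    n_trunc, n_draw, 100 * trunc_rate))
  }
  truth <- list(
    config = config,
    states = states,
    patient_coeffs = lapply(payers, function(p) true_patient_beta(config, p)),
    revenue_coeffs = config$true_revenue_coeffs,
    fte_cost_coeffs = config$true_fte_cost_coeffs,
    latent = list(patients = patients_latent, per_capita_revenue = pc_latent,
                  fte_cost = cost_latent),
    truncation_rate = trunc_rate)
  names(truth$patient_coeffs) <- payers
  list(panel = panel, truth = truth)
}

#' Generate a complete synthetic dataset
#'
#' Convenience wrapper producing all four tables plus the ground truth from
#' one configuration. Identical `(config, seed)` give bit-identical output.
#'
#' @param config A [synth_config()].
#' @return A list with `panel`, `population`, `policy`, `cpi`, `truth`.
#' @export
synth_dataset <- function(config = synth_config()) {
  population <- generate_population(config)
  policy <- generate_policy(config)
  cpi <- generate_cpi_series(config)
  gen <- generate_panel(config, population, policy)
  list(panel = gen$panel, population = population, policy = policy,
       cpi = cpi, truth = gen$truth)
}
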