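#' Fit the full health-center forecasting model
#'
#' Fits, on a historical state-by-year panel, the three model families the
#' projection pipeline is built on: patient counts per payer, per-capita
#' revenues per payer, and FTE cost totals per service category. The
#' returned object drives baseline projections ([predict.hc_model()]),
#' financing scenarios ([run_scenarios()]), and capacity impacts.
#'
#' By default each family is fitted separately by state when at least 12
#' usable history years exist per state; otherwise states are pooled (one
#' shared coefficient vector), and the choice is messaged.
#'
#' @param panel History panel (after any QHP-state exclusion).
#' @param population Population/eligibility table covering the panel years
#'   and the projection horizon.
#' @param policy Policy table.
#' @param payers Payers to model (default all five).
#' @param services Cost service categories to model (default all six).
#' @param grain `"auto"`, `"state"`, or `"pooled"`.
#' @param smooth Smooth per-capita revenue series before fitting and for
#'   the projection seed.
#' @param t_center Trend centering year for the revenue model.
#' @return An object of class `"hc_model"`.
#' @examples
#' dat <- synth_dataset(synth_config(seed = 7))
#' panel <- exclude_qhp_states(dat$panel, dat$policy)
#' fit <- hc_model(panel, dat$population, dat$policy)
#' print(fit)
#' @export
hc_model <- function(panel, population, policy,
                     payers = mc_payers(), services = mc_cost_services(),
                     grain = c("auto", "state", "pooled"),
                     smooth = TRUE, t_center = 2000L) {
  grain <- match.arg(grain)
  years_per_state <- tapply(panel$year, panel$state,
                            function(y) length(unique(y)))
  if (grain == "auto") {
    grain <- if (min(years_per_state) >= 12L) "state" else "pooled"
    message("fitting grain: ", grain,
            sprintf(" (min %d usable years per state)", min(years_per_state)))
  }
  patient_fits <- lapply(payers, function(p) {
    fit_patient_model(panel, population, p, grain = grain)
  })
  names(patient_fits) <- payers
  revenue_fits <- lapply(payers, function(p) {
    fit_revenue_model(panel, policy, p, grain = grain, smooth = smooth,
                      t_center = t_center)
  })
  names(revenue_fits) <- payers
  cost_fits <- lapply(services, function(s) {
    fit_fte_cost_model(panel, s, grain = grain, t_center = min(panel$year))
  })
  names(cost_fits) <- services
  structure(list(patients = patient_fits, revenues = revenue_fits,
                 fte_costs = cost_fits, payers = payers, services = services,
                 grain = grain, smooth = smooth, t_center = t_center,
                 panel = panel, policy = policy,
                 history_years = sort(unique(panel$year))),
            class = "hc_model")
}

#' @export
print.hc_model <- function(x, ...) {
  cat("Health-center revenue and capacity model\n")
  cat(sprintf("  states: %d, history: %d-%d, grain: %s\n",
              length(unique(x$panel$state)), min(x$history_years),
              max(x$history_years), x$grain))
  cat(sprintf("  payers modelled: %s\n", paste(x$payers, collapse = ", ")))
  cat(sprintf("  services modelled: %s\n", paste(x$services, collapse = ", ")))
  expl <- unlist(lapply(x$revenues, function(f) {
    vapply(f$fits, function(g) isTRUE(g$explosive), logical(1))
  }))
  if (any(expl)) cat("  warning: explosive revenue forecasts flagged\n")
  invisible(x)
}

#' @export
coef.hc_model <- function(object, ...) {
  stack <- function(fits, family, key) {
    do.call(rbind, lapply(names(fits), function(nm) {
      f <- fits[[nm]]
      if (is.null(f)) return(NULL)
      do.call(rbind, lapply(names(f$fits), function(u) {
        cf <- f$fits[[u]]$coefficients_full %||% f$fits[[u]]$coefficients
        data.frame(family = family, unit = u, component = nm,
                   term = names(cf), estimate = unname(cf),
                   stringsAsFactors = FALSE)
      }))
    }))
  }
  rbind(stack(object$patients, "patients"),
        stack(object$revenues, "per_capita_revenue"),
        stack(object$fte_costs, "fte_cost"))
}

#' @export
summary.hc_model <- function(object, ...) {
  cf <- stats::coef(object)
  out <- list(coefficients = cf,
              n_states = length(unique(object$panel$state)),
              grain = object$grain,
              sigma = list(
                patients = vapply(object$patients, function(f)
                  mean(vapply(f$fits, `[[`, numeric(1), "sigma")), numeric(1)),
                revenues = vapply(object$revenues, function(f)
                  mean(vapply(f$fits, `[[`, numeric(1), "sigma")), numeric(1))))
  class(out) <- "summary.hc_model"
  out
}

#' @export
print.summary.hc_model <- function(x, ...) {
  cat(sprintf("hc_model summary: %d states, grain %s\n", x$n_states, x$grain))
  cat("residual SDs (patients):\n")
  print(round(x$sigma$patients, 2))
  cat("residual SDs (per-capita revenue):\n")
  print(round(x$sigma$revenues, 3))
  cat(sprintf("%d coefficients fitted\n", nrow(x$coefficients)))
  invisible(x)
}

#' @export
residuals.hc_model <- function(object, family = c("patients", "revenues"),
                               ...) {
  family <- match.arg(family)
  fits <- object[[family]]
  do.call(rbind, lapply(names(fits), function(nm) {
    do.call(rbind, lapply(names(fits[[nm]]$fits), function(u) {
      data.frame(component = nm, unit = u,
                 residual = fits[[nm]]$fits[[u]]$residuals,
                 stringsAsFactors = FALSE)
    }))
  }))
}

## Counterfactual population: freeze the childless-adult eligibility
## threshold at its pre-expansion value (used to attribute the expansion
## enrollee group).
counterfactual_population <- function(population, policy) {
  info <- unique(policy[c("state", "expansion_state", "expansion_year")])
  pop <- population
  for (i in seq_len(nrow(info))) {
    if (!isTRUE(info$expansion_state[i])) next
    st <- info$state[i]; ey <- info$expansion_year[i]
    idx <- pop$state == st
    pre <- pop$elig_adults[idx & pop$year < ey]
    pre_val <- if (length(pre)) pre[1] else 0
    pop$elig_adults[idx] <- pre_val
  }
  pop
}

#' Project the baseline (status quo) scenario
#'
#' Produces the baseline projection: patient counts per payer (clamped at
#' zero), per-capita revenues per payer (dynamic recursion seeded from the
#' final smoothed history value), payer revenues (patients times per-capita
#' revenue), grant revenue held at its final history-year level, service
#' allocation shares frozen at their final history-year proportions, unit
#' FTE costs grown by the fitted labor-cost model, and the implied baseline
#' FTEs per service (revenue allocated to the category divided by its unit
#' cost). Medicaid enrollment is split into traditional and expansion
#' groups by differencing the projection against a counterfactual that
#' freezes adult eligibility at its pre-expansion level.
#'
#' @param object A fitted [hc_model()].
#' @param population Population table covering `years`.
#' @param policy Policy table.
#' @param years Projection years (default 2017-2024; scenario arithmetic
#'   uses 2020-2024 but needs the 2019 projections for the per-capita-cap
#'   deviance).
#' @param ... Unused.
#' @return A `data.frame` of class `"baseline_projection"`.
#' @export
predict.hc_model <- function(object, population = NULL, policy = NULL,
                             years = 2017:2024, ...) {
  if (is.null(policy)) policy <- object$policy
  if (is.null(population)) stop_mc("a population table is required")
  states <- sort(unique(object$panel$state))
  pop <- population[population$state %in% states &
                      population$year %in% years, ]
  if (!nrow(pop)) stop_mc("population table does not cover projection years")
  base <- expand.grid(state = states, year = sort(unique(pop$year)),
                      stringsAsFactors = FALSE)
  base <- base[order(base$state, base$year), ]
  rownames(base) <- NULL

  ## patients per payer + expansion attribution
  for (payer in object$payers) {
    pr <- project_patients(object$patients[[payer]], pop, years)
    base[[paste0("patients_", payer)]] <-
      pr$patients[match(paste(base$state, base$year),
                        paste(pr$state, pr$year))]
  }
  cf_pop <- counterfactual_population(pop, policy)
  pr_cf <- project_patients(object$patients[["medicaid"]], cf_pop, years)
  cf <- pr_cf$patients[match(paste(base$state, base$year),
                             paste(pr_cf$state, pr_cf$year))]
  base$patients_expansion <- pmax(0, base$patients_medicaid - cf)
  base$patients_traditional <- base$patients_medicaid - base$patients_expansion

  ## per-capita revenues by dynamic recursion
  for (payer in object$payers) {
    rf <- object$revenues[[payer]]
    col <- paste0("pc_revenue_", payer)
    base[[col]] <- NA_real_
    for (st in states) {
      u <- if (rf$grain == "state") st else "(pooled)"
      alpha <- rf$fits[[u]]$coefficients_full
      yrs <- base$year[base$state == st]
      seed <- rf$seeds[[st]]
      if (min(yrs) != as.integer(names(seed)) + 1L) {
        stop_mc("projection years must start right after the history (state %s)",
                st)
      }
      aca <- aca_indicator(st, yrs, policy)
      dra <- dra_indicator(yrs)
      base[[col]][base$state == st] <- project_per_capita_revenue(
        alpha, unname(seed), yrs, aca, dra, rf$t_center)
    }
  }

  for (payer in object$payers) {
    base[[paste0("revenue_", payer)]] <-
      base[[paste0("patients_", payer)]] * base[[paste0("pc_revenue_", payer)]]
  }

  ## grants held at final history level; totals
  last_hist <- max(object$history_years)
  g <- object$panel[object$panel$year == last_hist, c("state", "grant_revenue")]
  base$grant_revenue <- g$grant_revenue[match(base$state, g$state)]
  base$revenue_total <- rowSums(
    base[paste0("revenue_", object$payers)]) + base$grant_revenue

  ## allocation shares frozen at final history-year cost proportions
  costs <- object$panel[object$panel$year == last_hist,
                        c("state", paste0("fte_cost_", object$services))]
  share_mat <- normalize_shares(as.matrix(costs[, -1, drop = FALSE]),
                                quiet = TRUE)
  for (j in seq_along(object$services)) {
    base[[paste0("share_", object$services[j])]] <-
      share_mat[match(base$state, costs$state), j]
  }

  ## unit FTE costs: fitted cost at final-history staff mix grown to year t,
  ## divided by the category FTE count at the final history year
  hist_fte <- object$panel[object$panel$year == last_hist, ]
  for (svc in object$services) {
    cfit <- object$fte_costs[[svc]]
    col <- paste0("unit_cost_", svc)
    base[[col]] <- NA_real_
    for (st in states) {
      u <- if (cfit$grain == "state") st else "(pooled)"
      cc <- cfit$fits[[u]]$coefficients
      hrow <- hist_fte[hist_fte$state == st, ]
      xmix <- as.numeric(as.matrix(hrow[, cfit$xcols, drop = FALSE]))
      n_fte <- sum(xmix)
      if (n_fte <= 0) stop_mc("state %s service %s: zero FTE base", st, svc)
      slopes <- cc[seq(2, 1 + length(xmix))]
      tt <- base$year[base$state == st] - cfit$t_center
      pred_cost <- cc[["b0"]] + sum(slopes * xmix) * (1 + cc[["r"]])^tt
      if (any(pred_cost <= 0)) {
        stop_mc("state %s service %s: nonpositive projected FTE cost", st, svc)
      }
      base[[col]][base$state == st] <- pred_cost / n_fte
    }
  }

  ## baseline FTEs: allocated revenue / unit cost
  for (svc in object$services) {
    base[[paste0("fte_", svc)]] <-
      base$revenue_total * base[[paste0("share_", svc)]] /
      base[[paste0("unit_cost_", svc)]]
  }
  class(base) <- c("baseline_projection", "data.frame")
  attr(base, "services") <- object$services
  attr(base, "payers") <- object$payers
  attr(base, "last_history_year") <- last_hist
  base
}

#' Simulate new panels from a fitted model
#'
#' Draws `nsim` replicate history panels from the fitted model families:
#' patient counts from the fitted linear predictors plus Gaussian residual
#' noise at the estimated residual SD (truncated at zero), per-capita
#' revenues from the fitted recursions, and FTE costs from the fitted
#' staff-mix model, holding the observed FTE design fixed. Useful for
#' parametric-bootstrap checks.
#'
#' @param object A fitted [hc_model()].
#' @param nsim Number of replicate panels.
#' @param seed Optional seed.
#' @param population Population table covering the history years (the
#'   model object does not retain it, so it must be supplied).
#' @param ... Unused.
#' @return A list of `nsim` panels.
#' @export
simulate.hc_model <- function(object, nsim = 1, seed = NULL,
                              population = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(population)) stop_mc("a population table is required")
  panel <- object$panel
  pop_h <- population[population$year %in% object$history_years &
                        population$state %in% unique(panel$state), ]
  pop_h <- pop_h[order(pop_h$state, pop_h$year), ]
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    sim <- panel
    for (payer in object$payers) {
      pf <- object$patients[[payer]]
      pr <- project_patients(pf, pop_h, object$history_years)
      sig <- mean(vapply(pf$fits, `[[`, numeric(1), "sigma"))
      sim[[paste0("patients_", payer)]] <-
        pmax(0, pr$patients + stats::rnorm(nrow(sim), 0, sig))
    }
    sim$patients_total <- rowSums(sim[paste0("patients_", object$payers)])
    for (payer in object$payers) {
      rf <- object$revenues[[payer]]
      pc <- numeric(nrow(sim))
      for (st in unique(sim$state)) {
        u <- if (rf$grain == "state") st else "(pooled)"
        f <- rf$fits[[u]]
        idx <- which(sim$state == st)
        yrs <- sim$year[idx]
        alpha <- f$coefficients_full
        alpha[is.na(alpha)] <- 0
        aca <- aca_indicator(st, yrs, object$policy)
        dra <- dra_indicator(yrs)
        prev <- object$panel[[paste0("revenue_", payer)]][idx][1] /
          object$panel[[paste0("patients_", payer)]][idx][1]
        for (k in seq_along(idx)) {
          tt <- yrs[k] - rf$t_center
          val <- alpha[1] + alpha[2] * prev + alpha[3] * tt +
            alpha[4] * tt * aca[k] + alpha[5] * tt * dra[k] +
            stats::rnorm(1, 0, f$sigma)
          val <- max(0, val)
          pc[idx[k]] <- val; prev <- val
        }
      }
      sim[[paste0("revenue_", payer)]] <-
        sim[[paste0("patients_", payer)]] * pc
    }
    sim$revenue_total_patient <- rowSums(sim[paste0("revenue_", object$payers)])
    out[[s]] <- sim
  }
  out
}

#' @export
plot.hc_model <- function(x, population = NULL, payer = "medicaid", ...) {
  panel <- x$panel
  pc <- panel[[paste0("revenue_", payer)]] / panel[[paste0("patients_", payer)]]
  states <- unique(panel$state)
  graphics::matplot(
    x = sort(unique(panel$year)),
    y = vapply(states, function(st) pc[panel$state == st],
               numeric(length(unique(panel$year)))),
    type = "l", lty = 1, xlab = "year",
    ylab = sprintf("per-capita %s revenue (USD)", payer),
    main = "Observed per-capita revenue by state", ...)
  invisible(x)
}
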