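## Model family: patient counts, per-capita revenues, FTE costs.
##
## Patients (per payer): no-intercept least squares of counts on
## population-by-eligibility regressors; private/self-pay add a level dummy
## for 2014+ (marketplace rollout). Per-capita revenue (per payer): lagged
## recursion with linear trend and trend-by-policy interactions (state
## expansion, Deficit Reduction Act). FTE cost (per service category):
## staff-mix linear predictor scaled by compound labor-cost growth.

drop_null_columns <- function(X, tol = 1e-12) {
  keep <- colSums(abs(X)) > tol
  list(X = X[, keep, drop = FALSE], dropped = colnames(X)[!keep])
}

fit_ls <- function(X, y, intercept = FALSE) {
  if (intercept) X <- cbind(`(Intercept)` = 1, X)
  ## column-scale for conditioning; coefficients are unscaled afterwards
  norms <- sqrt(colSums(X^2))
  norms[norms == 0] <- 1
  Xs <- sweep(X, 2, norms, "/")
  qrX <- qr(Xs, tol = 1e-10)
  if (qrX$rank < ncol(Xs)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_mc("rank-deficient design; collinear regressor(s): %s",
            paste(aliased, collapse = ", "))
  }
  beta_s <- qr.coef(qrX, y)
  res <- as.numeric(y - Xs %*% beta_s)
  dfres <- length(y) - ncol(X)
  sigma2 <- if (dfres > 0) sum(res^2) / dfres else NA_real_
  ip <- order(qrX$pivot)
  XtXinv_s <- chol2inv(qr.R(qrX))[ip, ip, drop = FALSE]
  ## undo the scaling: beta = beta_s / norms, V = D^-1 Vs D^-1
  vc <- sigma2 * XtXinv_s / tcrossprod(norms)
  dimnames(vc) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(as.numeric(beta_s) / norms,
                                      colnames(X)),
       vcov = vc, sigma = sqrt(sigma2), n = length(y),
       df_residual = dfres, residuals = res, fitted = y - res)
}

#' Fit the patient-count model for one payer
#'
#' For Medicaid the regressors are the five population-by-eligibility
#' products (children, parent-eligible women 19-49, expansion-eligible
#' adults 19-64 and 65+, and the raw 19-64 band), with no intercept. Other
#' payers use the four raw population bands; private and self-pay add a
#' dummy for 2014 and later, when the insurance marketplace opened.
#' Regressor columns that are identically zero (for example the
#' adult-eligibility terms in a state that never expanded) are dropped with
#' a warning and reported as `NA` coefficients.
#'
#' @param panel State-by-year panel (history years).
#' @param population Population/eligibility table covering the panel years.
#' @param payer One of [mc_payers()].
#' @param grain `"state"` for separate per-state regressions (requires at
#'   least `min_years` usable years per state) or `"pooled"` for one
#'   stacked regression sharing coefficients across states.
#' @param min_years Minimum history years required per fitting unit.
#' @param intercept Add an intercept to the printed no-intercept
#'   specification (robustness option; default `FALSE`).
#' @param marketplace_year First year of the marketplace dummy.
#' @return An object of class `"mc_patient_fit"`.
#' @export
fit_patient_model <- function(panel, population, payer,
                              grain = c("state", "pooled"),
                              min_years = 7L, intercept = FALSE,
                              marketplace_year = 2014L) {
  grain <- match.arg(grain)
  dat <- merge(panel[c("state", "year", paste0("patients_", payer))],
               population, by = c("state", "year"))
  dat <- dat[order(dat$state, dat$year), ]
  y_all <- dat[[paste0("patients_", payer)]]
  X_all <- patient_design(dat, payer, marketplace_year)
  units <- if (grain == "state") unique(dat$state) else "(pooled)"
  fits <- list()
  for (u in units) {
    idx <- if (grain == "state") which(dat$state == u) else seq_len(nrow(dat))
    need <- ncol(X_all) + 2L
    if (length(unique(dat$year[idx])) < max(min_years, need)) {
      stop_mc("payer '%s', unit '%s': %d year(s) of data; need >= %d",
              payer, u, length(unique(dat$year[idx])), max(min_years, need))
    }
    dn <- drop_null_columns(X_all[idx, , drop = FALSE])
    if (length(dn$dropped)) {
      warn_mc("payer '%s', unit '%s': dropping all-zero regressor(s): %s",
              payer, u, paste(dn$dropped, collapse = ", "))
    }
    fit <- fit_ls(dn$X, y_all[idx], intercept = intercept)
    full <- stats::setNames(rep(NA_real_, ncol(X_all)), colnames(X_all))
    full[names(fit$coefficients)] <- fit$coefficients
    fit$coefficients_full <- full
    fits[[u]] <- fit
  }
  structure(list(payer = payer, grain = grain, fits = fits,
                 terms = colnames(X_all), intercept = intercept,
                 marketplace_year = marketplace_year),
            class = "mc_patient_fit")
}

#' Project patient counts from a fitted patient model
#'
#' Evaluates the fitted linear predictor on the population table for the
#' requested years and clamps negative predictions at zero (clamps are
#' messaged).
#'
#' @param fit An `"mc_patient_fit"`.
#' @param population Population table covering `years`.
#' @param years Years to project.
#' @return A `data.frame` with `state`, `year`, `patients`.
#' @export
project_patients <- function(fit, population, years) {
  missing_years <- setdiff(years, unique(population$year))
  if (length(missing_years)) {
    stop_mc("population table lacks year(s): %s",
            paste(missing_years, collapse = ", "))
  }
  pop <- population[population$year %in% years, ]
  if (fit$grain == "state") {
    ## project only the states the model was fitted on
    pop <- pop[pop$state %in% names(fit$fits), ]
  }
  pop <- pop[order(pop$state, pop$year), ]
  X <- patient_design(pop, fit$payer, fit$marketplace_year)
  pred <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    u <- if (fit$grain == "state") pop$state[i] else "(pooled)"
    f <- fit$fits[[u]]
    if (is.null(f)) stop_mc("no fit available for state '%s'", pop$state[i])
    beta <- f$coefficients_full
    x <- X[i, ]
    nz_dropped <- is.na(beta) & abs(x) > 1e-12
    if (any(nz_dropped)) {
      warn_mc("state '%s' year %d: nonzero value in dropped regressor(s) %s",
              pop$state[i], pop$year[i],
              paste(names(beta)[nz_dropped], collapse = ", "))
    }
    beta[is.na(beta)] <- 0
    val <- sum(beta * x)
    if (fit$intercept) val <- val + f$coefficients[["(Intercept)"]]
    pred[i] <- val
  }
  pred <- clamp_nonneg(pred, "projected patient counts")
  data.frame(state = pop$state, year = pop$year, patients = pred,
             stringsAsFactors = FALSE)
}

## Scenario indicators for the revenue model.
aca_indicator <- function(state, year, policy) {
  info <- unique(policy[c("state", "expansion_state", "expansion_year")])
  m <- match(state, info$state)
  as.numeric(info$expansion_state[m] & !is.na(info$expansion_year[m]) &
               year >= info$expansion_year[m])
}

dra_indicator <- function(year, dra_year = 2005L) as.numeric(year > dra_year)

#' Fit the per-capita revenue model for one payer
#'
#' Per-capita revenue (payer revenue divided by payer patients) is
#' optionally smoothed with [smooth_per_capita_revenue()] and regressed on
#' its one-year lag, a linear time trend (centered at 2000), and trend
#' interactions with the state-expansion indicator (on from the state's own
#' expansion year) and the Deficit Reduction Act indicator (on after 2005).
#' The first year of each state's series is lost to the lag. A fitted lag
#' coefficient with absolute value at or above one raises an
#' explosive-forecast warning and sets the `explosive` flag. If the
#' expansion interaction column is identically zero (no expansion states in
#' the fitting unit) the term is dropped with a warning.
#'
#' @param panel History panel.
#' @param policy Policy table with expansion status/years.
#' @param payer One of [mc_payers()].
#' @param grain `"state"` or `"pooled"` (lags are always taken within state).
#' @param smooth Apply the one-lead/one-lag moving average before fitting
#'   (and to the projection seed).
#' @param t_center Year subtracted from calendar year for the trend.
#' @return An object of class `"mc_revenue_fit"` holding, per fitting unit,
#'   the coefficients `a0` (intercept), `a1` (lag), `a2` (trend),
#'   `a3` (trend x expansion), `a4` (trend x DRA), and the smoothed series'
#'   final value per state for seeding projections.
#' @export
fit_revenue_model <- function(panel, policy, payer,
                              grain = c("state", "pooled"),
                              smooth = TRUE, t_center = 2000L) {
  grain <- match.arg(grain)
  dat <- panel[order(panel$state, panel$year), ]
  rev <- dat[[paste0("revenue_", payer)]]
  pat <- dat[[paste0("patients_", payer)]]
  if (any(pat <= 0)) {
    stop_mc("payer '%s': nonpositive patient count; per-capita revenue undefined",
            payer)
  }
  pc <- rev / pat
  rows <- list(); seeds <- list()
  for (st in unique(dat$state)) {
    idx <- which(dat$state == st)
    yrs <- dat$year[idx]
    series <- pc[idx]
    if (smooth) series <- smooth_per_capita_revenue(series)
    seeds[[st]] <- stats::setNames(series[length(series)], max(yrs))
    k <- seq_along(idx)[-1]
    rows[[st]] <- data.frame(
      state = st, year = yrs[k], y = series[k], lag = series[k - 1L],
      t = yrs[k] - t_center,
      t_aca = (yrs[k] - t_center) * aca_indicator(st, yrs[k], policy),
      t_dra = (yrs[k] - t_center) * dra_indicator(yrs[k]),
      stringsAsFactors = FALSE)
  }
  dd <- do.call(rbind, rows)
  units <- if (grain == "state") unique(dd$state) else "(pooled)"
  fits <- list()
  for (u in units) {
    sub <- if (grain == "state") dd[dd$state == u, ] else dd
    X <- as.matrix(sub[c("lag", "t", "t_aca", "t_dra")])
    dn <- drop_null_columns(X)
    if ("t_aca" %in% dn$dropped) {
      warn_mc("payer '%s', unit '%s': no expansion exposure; dropping the expansion interaction",
              payer, u)
    }
    fit <- fit_ls(dn$X, sub$y, intercept = TRUE)
    full <- stats::setNames(rep(NA_real_, 5L),
                            c("(Intercept)", "lag", "t", "t_aca", "t_dra"))
    full[names(fit$coefficients)] <- fit$coefficients
    fit$coefficients_full <- full
    fit$explosive <- is.finite(full[["lag"]]) && abs(full[["lag"]]) >= 1
    if (fit$explosive) {
      warn_mc("payer '%s', unit '%s': lag coefficient %.3f >= 1; forecasts are explosive",
              payer, u, full[["lag"]])
    }
    fits[[u]] <- fit
  }
  structure(list(payer = payer, grain = grain, fits = fits, smooth = smooth,
                 t_center = t_center, seeds = seeds),
            class = "mc_revenue_fit")
}

#' Project a per-capita revenue series by dynamic recursion
#'
#' Iterates `R_t = a0 + a1*R_{t-1} + a2*t + a3*t*ACA_t + a4*t*DRA_t`
#' forward from the last observed value, clamping at zero. `alpha` entries
#' that are `NA` (dropped terms) contribute zero.
#'
#' @param alpha Numeric vector `c(a0, a1, a2, a3, a4)`.
#' @param last_observed Seed value for the year preceding `years[1]`.
#' @param years Projection years (contiguous, increasing).
#' @param aca_on,dra_on 0/1 indicator vectors along `years` (defaults: off /
#'   on, matching projection years after 2005).
#' @param t_center Trend centering year.
#' @return Numeric vector of projected values along `years`.
#' @export
project_per_capita_revenue <- function(alpha, last_observed, years,
                                       aca_on = rep(0, length(years)),
                                       dra_on = rep(1, length(years)),
                                       t_center = 2000L) {
  alpha[is.na(alpha)] <- 0
  tt <- years - t_center
  out <- numeric(length(years))
  prev <- last_observed
  for (k in seq_along(years)) {
    val <- alpha[1] + alpha[2] * prev + alpha[3] * tt[k] +
      alpha[4] * tt[k] * aca_on[k] + alpha[5] * tt[k] * dra_on[k]
    val <- max(0, val)
    out[k] <- val
    prev <- val
  }
  out
}

#' Fit the FTE cost model for one service category
#'
#' Cost totals (compensation plus equipment depreciation) are modelled as
#' an intercept plus a staff-mix linear predictor scaled by compound
#' labor-cost growth `(1+r)^(t - t0)`, with `t0` the first panel year. The
#' medical category uses three staffing regressors (physicians, advanced
#' practice clinicians, other medical personnel); every other category uses
#' its own FTE count. The growth rate `r` is estimated per fitting unit by
#' profiling a coarse grid (least-squares fit at each candidate) and then
#' refining with [stats::nls()], or fixed via `r`.
#'
#' @param panel History panel.
#' @param service One of [mc_cost_services()].
#' @param grain `"state"` or `"pooled"` (pooled shares slopes and `r`).
#' @param r Optional fixed labor growth rate (skips estimation).
#' @param r_grid Candidate grid for the profile search.
#' @param t_center First panel year `t0`.
#' @return An object of class `"mc_ftecost_fit"` with per-unit coefficients
#'   `(b0, slopes..., r)` and their covariance.
#' @export
fit_fte_cost_model <- function(panel, service,
                               grain = c("state", "pooled"), r = NULL,
                               r_grid = seq(-0.015, 0.095, by = 0.005),
                               t_center = 2000L) {
  grain <- match.arg(grain)
  dat <- panel[order(panel$state, panel$year), ]
  xcols <- if (service == "medical") {
    c("fte_medical_physician", "fte_medical_apc", "fte_medical_other")
  } else paste0("fte_", service)
  y <- dat[[paste0("fte_cost_", service)]]
  if (all(rowSums(abs(as.matrix(dat[, xcols, drop = FALSE]))) == 0)) {
    warn_mc("service '%s': FTE counts are zero in all years; skipping", service)
    return(NULL)
  }
  units <- if (grain == "state") unique(dat$state) else "(pooled)"
  fits <- list()
  for (u in units) {
    idx <- if (grain == "state") which(dat$state == u) else seq_len(nrow(dat))
    X <- as.matrix(dat[idx, xcols, drop = FALSE])
    tt <- dat$year[idx] - t_center
    yy <- y[idx]
    ssr_at <- function(rr) {
      Xg <- X * (1 + rr)^tt
      sum(fit_ls(Xg, yy, intercept = TRUE)$residuals^2)
    }
    if (is.null(r)) {
      ssr <- vapply(r_grid, ssr_at, numeric(1))
      r0 <- r_grid[which.min(ssr)]
      dfnl <- data.frame(yy = yy, tt = tt)
      for (j in seq_along(xcols)) dfnl[[paste0("x", j)]] <- X[, j]
      mixterm <- paste(sprintf("b%d * x%d", seq_along(xcols),
                               seq_along(xcols)), collapse = " + ")
      form <- stats::as.formula(
        sprintf("yy ~ b0 + (%s) * (1 + r)^tt", mixterm))
      start0 <- fit_ls(X * (1 + r0)^tt, yy, intercept = TRUE)$coefficients
      start <- as.list(stats::setNames(
        c(start0, r0), c("b0", paste0("b", seq_along(xcols)), "r")))
      nl <- try(stats::nls(form, data = dfnl, start = start,
                           algorithm = "port",
                           lower = c(rep(-Inf, length(xcols) + 1L), -0.0199),
                           upper = c(rep(Inf, length(xcols) + 1L), 0.0999),
                           control = stats::nls.control(maxiter = 200,
                                                        warnOnly = TRUE)),
                silent = TRUE)
      if (inherits(nl, "try-error")) {
        coefv <- c(start0, r = r0)
        vc <- matrix(NA_real_, length(coefv), length(coefv))
        sigma <- sqrt(min(ssr) / (length(yy) - length(coefv)))
        resid <- yy - (coefv[1] +
                         as.numeric(X %*% coefv[2:(1 + length(xcols))]) *
                         (1 + r0)^tt)
      } else {
        coefv <- stats::coef(nl)
        vc <- try(stats::vcov(nl), silent = TRUE)
        if (inherits(vc, "try-error")) {
          ## exact fits leave a singular gradient cross-product
          vc <- matrix(NA_real_, length(coefv), length(coefv))
        }
        resid <- stats::resid(nl)
        sigma <- sqrt(sum(resid^2) / max(1, length(yy) - length(coefv)))
      }
    } else {
      lsf <- fit_ls(X * (1 + r)^tt, yy, intercept = TRUE)
      coefv <- c(lsf$coefficients, r = r)
      vc <- rbind(cbind(lsf$vcov, 0), 0)
      sigma <- lsf$sigma
      resid <- lsf$residuals
    }
    names(coefv) <- c("b0", paste0("b", seq_along(xcols)), "r")
    fits[[u]] <- list(coefficients = coefv, vcov = vc, sigma = sigma,
                      n = length(yy), residuals = resid)
  }
  structure(list(service = service, grain = grain, fits = fits,
                 xcols = xcols, t_center = t_center),
            class = "mc_ftecost_fit")
}
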