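test_that("lead/lag smoothing matches hand-computed window means", {
  expect_equal(smooth_per_capita_revenue(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  expect_equal(smooth_per_capita_revenue(c(1, 2, 3, 4)), c(1.5, 2, 3, 3.5))
  expect_equal(smooth_per_capita_revenue(c(0, 0, 3, 0, 0)), c(0, 1, 1, 1, 0))
  expect_error(smooth_per_capita_revenue(c(1, 2)), "length >= 3")
})

test_that("noiseless fits recover the generating coefficients", {
  w <- noiseless_world()
  truth <- w$dat$truth
  exp_analyzed <- intersect(
    truth$states$state[truth$states$expansion_state &
                         !truth$states$qhp_expansion],
    unique(w$panel$state))

  for (payer in mc_payers()) {
    pf <- suppressWarnings(
      fit_patient_model(w$panel, w$dat$population, payer))
    tr <- truth$patient_coeffs[[payer]]
    for (st in exp_analyzed) {
      est <- pf$fits[[st]]$coefficients_full
      est[is.na(est)] <- 0
      relerr <- abs(est - tr) / pmax(abs(tr), 1e-12)
      expect_lt(max(relerr[tr != 0]), 1e-6)
    }
    rf <- suppressWarnings(
      fit_revenue_model(w$panel, w$dat$policy, payer, smooth = FALSE))
    atr <- truth$revenue_coeffs[[payer]]
    for (st in exp_analyzed) {
      est <- rf$fits[[st]]$coefficients_full
      est[is.na(est)] <- 0
      relerr <- abs(est - atr) / pmax(abs(atr), 1e-12)
      expect_lt(max(relerr[atr != 0]), 1e-6)
    }
  }
  for (svc in mc_cost_services()) {
    cf <- fit_fte_cost_model(w$panel, svc)
    for (st in exp_analyzed) {
      est <- cf$fits[[st]]$coefficients
      tr <- c(truth$fte_cost_coeffs[[svc]],
              truth$states$r_labor[truth$states$state == st])
      expect_lt(max(abs(est - tr) / pmax(abs(tr), 1e-12)), 1e-4)
    }
  }
})

test_that("all-zero eligibility reduces the Medicaid fit to the raw-band term", {
  w <- noiseless_world()
  pop0 <- w$dat$population
  pop0$elig_child <- 0; pop0$elig_parents <- 0; pop0$elig_adults <- 0
  st <- unique(w$panel$state)[1]
  ## construct counts that only load on the unconditional 19-64 band
  panel <- w$panel[w$panel$state == st, ]
  popst <- pop0[pop0$state == st & pop0$year %in% panel$year, ]
  panel$patients_medicaid <- 0.005 * popst$pop_age19_64
  fit <- suppressWarnings(
    fit_patient_model(panel, pop0, "medicaid"))
  cf <- fit$fits[[st]]$coefficients_full
  expect_true(all(is.na(cf[c("p1_18_child", "p19_49f_parents",
                             "p19_64_adults", "p65_adults")])))
  expect_equal(unname(cf["p19_64"]), 0.005, tolerance = 1e-10)
})

test_that("too few history years raises an insufficient-data error", {
  w <- noiseless_world()
  short <- w$panel[w$panel$year <= 2002, ]
  expect_error(
    suppressWarnings(fit_patient_model(short, w$dat$population, "medicaid")),
    "need >=")
})

test_that("projection is the in-sample identity on noiseless data and scales linearly", {
  w <- noiseless_world()
  pf <- suppressWarnings(
    fit_patient_model(w$panel, w$dat$population, "medicaid"))
  pr <- suppressWarnings(
    project_patients(pf, w$dat$population, 2000:2016))
  key <- paste(w$panel$state, w$panel$year)
  got <- pr$patients[match(key, paste(pr$state, pr$year))]
  expect_equal(got, w$panel$patients_medicaid, tolerance = 1e-8)

  ## doubling every population band doubles the no-intercept prediction
  pop2 <- w$dat$population
  for (cn in grep("^pop_", names(pop2), value = TRUE)) {
    pop2[[cn]] <- 2 * pop2[[cn]]
  }
  pr2 <- suppressWarnings(project_patients(pf, pop2, 2020:2024))
  pr1 <- suppressWarnings(project_patients(pf, w$dat$population, 2020:2024))
  expect_equal(pr2$patients, 2 * pr1$patients, tolerance = 1e-10)

  ## missing population year errors
  expect_error(project_patients(pf, w$dat$population, 2030), "2030")
})

test_that("negative raw predictions clamp to zero with a message", {
  fit <- structure(list(
    payer = "medicare", grain = "state", intercept = FALSE,
    marketplace_year = 2014L,
    fits = list(AA = list(coefficients_full = c(
      p1_18 = -1, p19_49f = 0, p19_64 = 0, p65 = 0)))),
    class = "mc_patient_fit")
  pop <- generate_population(synth_config(seed = 3))
  expect_message(pr <- project_patients(fit, pop[pop$state == "AA", ], 2020),
                 "clamped")
  expect_equal(pr$patients, 0)
})

test_that("the per-capita revenue recursion reproduces hand-computed paths", {
  ## a0=10, a1=0.5 from seed 100: 60, 40, 30
  got <- project_per_capita_revenue(c(10, 0.5, 0, 0, 0), 100, 2020:2022)
  expect_equal(got, c(60, 40, 30))
  ## pure random walk holds the seed constant
  expect_equal(project_per_capita_revenue(c(0, 1, 0, 0, 0), 77, 2020:2024),
               rep(77, 5))
  ## pure intercept jumps to the constant immediately
  expect_equal(project_per_capita_revenue(c(42, 0, 0, 0, 0), 7, 2020:2023),
               rep(42, 4))
  ## clamping at zero
  expect_equal(project_per_capita_revenue(c(-5, 0.5, 0, 0, 0), 4, 2020:2021),
               c(0, 0))
})

test_that("revenue fits flag explosive series and drop dead interactions", {
  w <- noiseless_world()
  st <- unique(w$panel$state)[1]
  panel <- w$panel[w$panel$state == st, ]
  panel$patients_medicaid <- 1
  panel$revenue_medicaid <- 1.05^(panel$year - 2000)
  pol <- w$dat$policy[w$dat$policy$state == st, ]
  pol$expansion_state <- FALSE; pol$expansion_year <- NA_integer_
  warns <- capture_warnings(
    rf <- fit_revenue_model(panel, pol, "medicaid", smooth = FALSE))
  expect_true(any(grepl("expansion interaction", warns)))
  expect_true(any(grepl("explosive", warns)))
  expect_true(rf$fits[[st]]$explosive)
  expect_equal(unname(rf$fits[[st]]$coefficients_full["lag"]), 1.05,
               tolerance = 1e-6)
  expect_true(is.na(rf$fits[[st]]$coefficients_full["t_aca"]))
})

test_that("FTE cost fitting handles the no-growth limit and scales in the mix", {
  cfg <- noiseless_config(seed = 6, labor_growth_range = c(0, 0))
  dat <- synth_dataset(cfg)
  panel <- suppressMessages(exclude_qhp_states(dat$panel, dat$policy))
  cf <- fit_fte_cost_model(panel, "dental")
  for (st in names(cf$fits)) {
    expect_lt(abs(cf$fits[[st]]$coefficients[["r"]]), 1e-6)
  }
  ## doubling the staffing columns doubles predicted cost net of intercept
  w <- noiseless_world()
  cm <- fit_fte_cost_model(w$panel, "medical")
  st <- names(cm$fits)[1]
  cc <- cm$fits[[st]]$coefficients
  x <- c(10, 5, 20); tt <- 10
  pred <- function(xv) {
    cc[["b0"]] + sum(cc[c("b1", "b2", "b3")] * xv) * (1 + cc[["r"]])^tt
  }
  expect_equal(pred(2 * x) - cc[["b0"]], 2 * (pred(x) - cc[["b0"]]),
               tolerance = 1e-10)
})

test_that("baseline projection allocates revenue by frozen shares over unit costs", {
  run <- default_run()
  base <- run$baseline
  svc <- mc_cost_services()
  ## identity: fte = revenue_total * share / unit_cost
  for (s in svc) {
    expect_equal(base[[paste0("fte_", s)]],
                 base$revenue_total * base[[paste0("share_", s)]] /
                   base[[paste0("unit_cost_", s)]],
                 tolerance = 1e-12)
  }
  shares <- as.matrix(base[paste0("share_", svc)])
  expect_equal(unname(rowSums(shares)), rep(1, nrow(base)), tolerance = 1e-12)
  expect_true(all(as.matrix(base[paste0("fte_", svc)]) >= 0))
  ## revenue identity per payer
  for (p in mc_payers()) {
    expect_equal(base[[paste0("revenue_", p)]],
                 base[[paste0("patients_", p)]] *
                   base[[paste0("pc_revenue_", p)]], tolerance = 1e-12)
  }
  ## worked arithmetic: shares (.5, .5), revenue 100, unit costs (10, 20)
  sh <- medicaidcap:::normalize_shares(c(a = 0.5, b = 0.5))
  expect_equal(unname(100 * sh / c(10, 20)), c(5, 2.5))
  ## renormalization is applied and logged when shares do not sum to one
  expect_message(sh2 <- medicaidcap:::normalize_shares(c(a = 1, b = 3)),
                 "renormalized")
  expect_equal(unname(sh2), c(0.25, 0.75))
})

test_that("noiseless baseline projection extends the generating process", {
  cfg <- noiseless_config(seed = 12)
  dat <- synth_dataset(cfg)
  panel <- suppressMessages(exclude_qhp_states(dat$panel, dat$policy))
  fit <- suppressWarnings(suppressMessages(
    hc_model(panel, dat$population, dat$policy, smooth = FALSE)))
  base <- suppressWarnings(suppressMessages(
    predict(fit, dat$population, dat$policy, years = 2017:2024)))
  ## per-capita medicaid path continues the true recursion from 2016
  truth <- dat$truth
  for (st in unique(base$state)) {
    alpha <- cfg$true_revenue_coeffs$medicaid
    lat16 <- truth$latent$per_capita_revenue$medicaid[
      dat$panel$state == st & dat$panel$year == 2016]
    srow <- truth$states[truth$states$state == st, ]
    yrs <- 2017:2024
    aca <- if (srow$expansion_state) as.numeric(yrs >= srow$expansion_year)
           else rep(0, length(yrs))
    expected <- oracle_pc_recursion(alpha, lat16, yrs, aca, rep(1, length(yrs)))
    got <- base$pc_revenue_medicaid[base$state == st]
    expect_equal(got, expected, tolerance = 1e-6)
  }
})

test_that("projected Medicaid patients rise weakly in population when fits are positive", {
  run <- default_run()
  fit <- run$fit$patients$medicaid
  pop <- run$inputs$population
  pop_up <- pop
  for (cn in grep("^pop_", names(pop_up), value = TRUE)) {
    pop_up[[cn]] <- pop_up[[cn]] * 1.10
  }
  pr <- suppressWarnings(project_patients(fit, pop, 2020:2024))
  pr_up <- suppressWarnings(project_patients(fit, pop_up, 2020:2024))
  for (st in unique(pr$state)) {
    cf <- fit$fits[[st]]$coefficients_full
    if (all(is.na(cf) | cf >= 0)) {
      expect_true(all(pr_up$patients[pr_up$state == st] >=
                        pr$patients[pr$state == st] - 1e-9))
    }
  }
})

test_that("the fitted model object supports the standard methods", {
  run <- default_run()
  fit <- run$fit
  expect_s3_class(fit, "hc_model")
  expect_output(print(fit), "Health-center")
  cf <- coef(fit)
  expect_true(all(c("family", "unit", "component", "term",
                    "estimate") %in% names(cf)))
  expect_true(nrow(cf) > 50)
  sm <- summary(fit)
  expect_output(print(sm), "coefficients fitted")
  res <- residuals(fit, "revenues")
  expect_true(is.numeric(res$residual))
  sims <- suppressWarnings(suppressMessages(
    simulate(fit, nsim = 2, seed = 99, population = run$inputs$population)))
  expect_length(sims, 2)
  expect_true(all(sims[[1]]$patients_medicaid >= 0))
  expect_false(identical(sims[[1]]$patients_medicaid,
                         sims[[2]]$patients_medicaid))
  pdf(NULL)
  expect_silent(plot(fit))
  dev.off()
})
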