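test_that("identical config and seed give bit-identical outputs", {
  a <- synth_dataset(synth_config(seed = 17))
  b <- synth_dataset(synth_config(seed = 17))
  for (nm in c("panel", "population", "policy", "cpi")) {
    expect_identical(a[[nm]], b[[nm]])
  }
  expect_identical(a$truth$latent, b$truth$latent)
  c <- synth_dataset(synth_config(seed = 18))
  expect_false(identical(a$panel, c$panel))
})

test_that("population growth paths follow the configured rates", {
  ## zero growth and zero cohort wave: constant bands
  cfg0 <- synth_config(seed = 3, pop_growth_mean = 0, pop_growth_sd = 0,
                       band_growth_sd = 0, band_wave_amplitude = 0)
  pop0 <- generate_population(cfg0)
  for (cn in grep("^pop_", names(pop0), value = TRUE)) {
    spread <- tapply(pop0[[cn]], pop0$state, function(v) diff(range(v)))
    expect_true(all(spread == 0))
  }

  ## 1%/yr for 10 years: ratio (1.01)^10 against year 0
  cfg1 <- synth_config(seed = 3, pop_growth_mean = 0.01, pop_growth_sd = 0,
                       band_growth_sd = 0, band_wave_amplitude = 0)
  pop1 <- generate_population(cfg1)
  st <- pop1[pop1$state == "AA", ]
  expect_equal(st$pop_age1_18[st$year == 2010] / st$pop_age1_18[st$year == 2000],
               1.01^10, tolerance = 1e-12)

  ## invariants: non-negative, female band inside the 19-64 band,
  ## projections reach 2024, adult threshold jumps at the expansion year
  pop <- generate_population(synth_config(seed = 3))
  expect_true(all(pop$pop_age19_49_female <= pop$pop_age19_64))
  expect_gte(max(pop$year), 2024)
  pol <- generate_policy(synth_config(seed = 3))
  exp_states <- unique(pol$state[pol$expansion_state])
  for (st in exp_states) {
    ey <- unique(pol$expansion_year[pol$state == st])
    sub <- pop[pop$state == st, ]
    expect_true(all(sub$elig_adults[sub$year < ey] == 0))
    expect_true(all(sub$elig_adults[sub$year >= ey] >= 1.33))
  }
  non_exp <- setdiff(unique(pol$state), exp_states)
  expect_true(all(pop$elig_adults[pop$state %in% non_exp] == 0))
})

test_that("a noiseless panel equals its latent series", {
  w <- noiseless_world()
  full <- generate_panel(w$cfg)
  for (p in mc_payers()) {
    expect_equal(full$panel[[paste0("patients_", p)]],
                 full$truth$latent$patients[[p]], tolerance = 1e-12)
    expect_equal(full$panel[[paste0("revenue_", p)]],
                 full$truth$latent$patients[[p]] *
                   full$truth$latent$per_capita_revenue[[p]],
                 tolerance = 1e-12)
  }
  for (svc in mc_cost_services()) {
    expect_equal(full$panel[[paste0("fte_cost_", svc)]],
                 full$truth$latent$fte_cost[[svc]], tolerance = 1e-12)
  }
})

test_that("nonexpansion states see no expansion contribution in any year", {
  w <- noiseless_world()
  truth <- w$dat$truth
  non_exp <- truth$states$state[!truth$states$expansion_state]
  expect_gt(length(non_exp), 0)
  panel <- w$dat$panel
  alpha <- w$cfg$true_revenue_coeffs$medicaid
  for (st in non_exp) {
    idx <- panel$state == st
    yrs <- panel$year[idx]
    ## recursion with the expansion interaction removed must match exactly
    expected <- oracle_pc_recursion(
      c(alpha[1], alpha[2], alpha[3], 0, alpha[5]),
      alpha[1] / (1 - alpha[2]), yrs, rep(0, length(yrs)),
      as.numeric(yrs > 2005))
    got <- truth$latent$per_capita_revenue$medicaid[panel$state == st]
    expect_equal(got, expected, tolerance = 1e-12)
  }
})

test_that("the trendless revenue recursion sits at its closed-form fixed point", {
  cfg <- noiseless_config(
    seed = 2,
    true_revenue_coeffs = list(medicaid = c(200, 0.5, 0, 0, 0),
                               medicare = c(150, 0.5, 0, 0, 0),
                               private = c(115, 0.5, 0, 0, 0),
                               self_pay = c(30, 0.5, 0, 0, 0),
                               other_public = c(175, 0.5, 0, 0, 0)))
  gen <- generate_panel(cfg)
  for (p in mc_payers()) {
    a <- cfg$true_revenue_coeffs[[p]]
    expect_equal(unique(round(gen$truth$latent$per_capita_revenue[[p]], 9)),
                 a[1] / (1 - a[2]), tolerance = 1e-9)
  }
})

test_that("CPI generator honors its affine construction and is recoverable", {
  ## noiseless identity: intercept 0, slope 1 makes CPI-M track CPI-U
  cfg <- noiseless_config(seed = 4, cpi_intercept = 0, cpi_slope = 1)
  cpi <- generate_cpi_series(cfg)
  hist <- cpi[!is.na(cpi$cpi_m), ]
  expect_equal(hist$cpi_m, hist$cpi_u, tolerance = 1e-12)

  ## constant offset construction
  cfg2 <- noiseless_config(seed = 4, cpi_intercept = 0.005, cpi_slope = 1)
  cpi2 <- generate_cpi_series(cfg2)
  hist2 <- cpi2[!is.na(cpi2$cpi_m), ]
  expect_equal(hist2$cpi_m - hist2$cpi_u, rep(0.005, nrow(hist2)),
               tolerance = 1e-12)

  ## OLS on a default (noisy) series recovers (a, b) within 2 SE at n = 17
  cfg3 <- synth_config(seed = 4)
  cpi3 <- generate_cpi_series(cfg3)
  hist3 <- cpi3[!is.na(cpi3$cpi_m), ]
  expect_equal(nrow(hist3), 17L)
  fit <- lm(cpi_m ~ cpi_u, data = hist3)
  est <- coef(summary(fit))
  expect_lt(abs(est["(Intercept)", "Estimate"] - cfg3$cpi_intercept),
            2 * est["(Intercept)", "Std. Error"])
  expect_lt(abs(est["cpi_u", "Estimate"] - cfg3$cpi_slope),
            2 * est["cpi_u", "Std. Error"])
})

test_that("generated quantities are non-negative with rare truncation", {
  dat <- synth_dataset(synth_config(seed = 23))
  num <- setdiff(panel_cols <- names(dat$panel), c("state", "year"))
  expect_true(all(as.matrix(dat$panel[num]) >= 0))
  expect_lt(dat$truth$truncation_rate, 0.01)
})
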