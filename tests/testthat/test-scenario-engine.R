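test_that("the federal/state split follows the match-rate arithmetic", {
  expect_equal(split_federal_state(100, 0.5),
               data.frame(federal = 50, state_share = 50))
  expect_equal(split_federal_state(0, 0.6),
               data.frame(federal = 0, state_share = 0))
  ## Mississippi-style match: just under 76% gives $3.11 per state dollar
  sp <- split_federal_state(1, 0.7565)
  expect_equal(round(sp$federal / sp$state_share, 2), 3.11)
  expect_error(split_federal_state(10, 1), "fmap")
  expect_error(split_federal_state(10, 0), "fmap")
  expect_error(split_federal_state(-1, 0.5), "revenue")
})

test_that("the estimated medical-inflation path honors its affine structure", {
  yrs_h <- 2000:2016
  ## identical series: projected CPI-M equals projected CPI-U
  cpi <- data.frame(year = c(yrs_h, 2017:2024),
                    cpi_m = c(0.02 + 0.005 * sin(yrs_h - 2000),
                              rep(NA, 8)),
                    cpi_u = c(0.02 + 0.005 * sin(yrs_h - 2000),
                              rep(0.023, 8)))
  path <- estimate_cpim_path(cpi, 2017:2024)
  expect_equal(path$multiplier[path$year == 2024], 1.023^8, tolerance = 1e-9)

  ## constant offset: projected CPI-M = CPI-U + 0.5pp
  cpi2 <- cpi
  cpi2$cpi_m[1:17] <- cpi2$cpi_u[1:17] + 0.005
  path2 <- estimate_cpim_path(cpi2, 2017:2024)
  expect_equal(path2$multiplier[path2$year == 2024], 1.028^8, tolerance = 1e-9)

  ## insufficient overlap errors
  cpi3 <- cpi
  cpi3$cpi_m[1:9] <- NA
  expect_error(estimate_cpim_path(cpi3, 2017:2024), "overlapping")
  ## missing projected CPI-U errors
  cpi4 <- cpi
  cpi4$cpi_u[cpi4$year == 2022] <- NA
  expect_error(estimate_cpim_path(cpi4, 2017:2024), "2022")
})

test_that("S1 reduces expansion federal funds by the 2016 match gap", {
  sh <- mini_shares()
  pol <- mini_policy()
  res <- scenario_s1_efmap_phaseout(sh, pol, years = 2020:2024)
  ## nonexpansion state: zero shortfall in every year and group
  expect_true(all(res$shortfall_abs[res$state == "NX"] == 0))
  ## traditional rows unaffected everywhere
  expect_true(all(res$shortfall_abs[res$group == "traditional"] == 0))
  ## arithmetic oracle: gap 0.4 x pc x enrollees
  r20 <- res[res$state == "EX" & res$year == 2020 & res$group == "expansion", ]
  pcv <- sh$per_capita_expenditure[sh$state == "EX" & sh$year == 2020][1]
  expect_equal(r20$shortfall_abs, (1.0 - 0.6) * pcv * 500, tolerance = 1e-12)
  ## EFMAP equal to FMAP nulls the reduction
  pol2 <- mini_policy(); pol2$efmap <- 0.6
  res2 <- scenario_s1_efmap_phaseout(sh, pol2, years = 2020:2024)
  expect_true(all(res2$shortfall_abs == 0))
  ## worked numbers: EFMAP .9, FMAP .5, $5,000 pc, 1,000 enrollees -> $2.0M
  expect_equal((0.9 - 0.5) * 5000 * 1000, 2e6)
})

test_that("S2 block grants are enrollment-invariant and growth-matched limits vanish", {
  sh <- mini_shares(fed_growth = 0.023, exp_enroll = 0)
  hist <- mini_hist()
  path <- inflation_path_fixed(2016:2024)
  res <- scenario_s2_block_grant(sh, hist, path, years = 2020:2024)
  ## baseline trad federal grows at exactly 2.3% from the 2016 base
  expect_true(all(abs(res$shortfall_abs[res$group == "traditional"]) < 1e-6))

  ## direct exponentiation: base $100M, 2024 multiplier 1.023^8
  hist2 <- mini_hist()
  hist2$federal[hist2$state == "EX" & hist2$year == 2016 &
                  hist2$group == "traditional"] <- 100e6
  res2 <- scenario_s2_block_grant(sh, hist2, path, years = 2020:2024)
  expect_equal(res2$scenario_federal[res2$state == "EX" & res2$year == 2024 &
                                       res2$group == "traditional"],
               100e6 * 1.023^8, tolerance = 1e-12)

  ## doubling projected enrollment changes baseline but not the grant
  sh_dbl <- mini_shares(fed_growth = 0.023, exp_enroll = 0,
                        enroll = c(EX = 2000, NX = 1600))
  res3 <- scenario_s2_block_grant(sh_dbl, hist, path, years = 2020:2024,
                                  floor = FALSE)
  res0 <- scenario_s2_block_grant(sh, hist, path, years = 2020:2024,
                                  floor = FALSE)
  expect_equal(res3$scenario_federal, res0$scenario_federal, tolerance = 1e-12)
  expect_equal(res3$shortfall_abs - res0$shortfall_abs,
               res3$baseline_federal - res0$baseline_federal,
               tolerance = 1e-8)
})

test_that("S2 with phase-out disabled and growth-matched inflation nests S0", {
  sh <- mini_shares(fed_growth = 0.031)
  hist <- mini_hist()
  path <- inflation_path_fixed(2016:2024, rate = 0.031)
  res <- scenario_s2_block_grant(sh, hist, path, years = 2020:2024,
                                 apply_phaseout = FALSE, floor = FALSE)
  expect_equal(res$scenario_federal[res$group == "traditional"],
               res$baseline_federal[res$group == "traditional"],
               tolerance = 1e-8)
  expect_true(all(abs(res$shortfall_abs) < 1e-6))
})

test_that("S3 caps scale with enrollment and vanish in the matched limit", {
  ## every state at the national average with 2.3% growth: zero shortfall
  ## (history held flat at the 2016 level so the 2015-2016 mean is the base)
  sh <- mini_shares(fed_growth = 0.023, exp_enroll = 0)
  hist <- mini_shares(years = 2015:2016, fed_growth = 0)
  path <- inflation_path_fixed(2016:2024)
  res <- scenario_s3_per_capita_cap(sh, hist, path, years = 2020:2024)
  expect_true(all(abs(res$shortfall_abs[res$group == "traditional"]) < 1e-6))

  ## homogeneity of degree 1: halving enrollment halves the cap payment
  sh_half <- sh
  sh_half$enrollees <- sh$enrollees / 2
  sh_half$medicaid_revenue <- sh$medicaid_revenue / 2
  sh_half$federal <- sh$federal / 2
  sh_half$state_share <- sh$state_share / 2
  res_half <- scenario_s3_per_capita_cap(sh_half, hist, path,
                                         years = 2020:2024)
  expect_equal(res_half$scenario_federal, res$scenario_federal / 2,
               tolerance = 1e-12)

  ## worked arithmetic: pc base 4000, one year of 2.3% inflation, +10%
  ## deviance -> 2020 cap 4501.20; engineer state A at +10% deviance
  pcs <- c(EX = 1100, NX = 900)  # unweighted mean 1000, dev_EX = +0.1
  sh2 <- mini_shares(years = 2019:2020, fed_growth = 0, pc = pcs)
  hist2 <- mini_shares(years = 2015:2016, fed_growth = 0, pc = pcs)
  hist2$federal[hist2$state == "EX" & hist2$group == "traditional"] <-
    4000 * hist2$enrollees[hist2$state == "EX" &
                             hist2$group == "traditional"]
  path1 <- inflation_path_fixed(2019:2020, rate = 0.023, base_year = 2019L)
  res2 <- scenario_s3_per_capita_cap(sh2, hist2, path1, years = 2020)
  cap <- res2$scenario_federal[res2$state == "EX" &
                                 res2$group == "traditional"] /
    sh2$enrollees[sh2$state == "EX" & sh2$year == 2020 &
                    sh2$group == "traditional"]
  expect_equal(cap, 4000 * 1.023 * 1.10, tolerance = 1e-9)
  expect_equal(4000 * 1.023 * 1.10, 4501.2, tolerance = 1e-12)
})

test_that("shortfall percentages are consistent and additive across groups", {
  run <- default_run()
  scen <- run$scenarios
  ## S0 shortfall is identically zero
  expect_true(all(scen$shortfall_abs[scen$scenario == "S0"] == 0))
  expect_true(all(scen$shortfall_pct[scen$scenario == "S0"] == 0,
                  na.rm = TRUE))
  ## group additivity: traditional + expansion = all
  for (sc in c("S1", "S2", "S3")) {
    d <- scen[scen$scenario == sc, ]
    grp_sum <- tapply(d$shortfall_abs[d$group != "all"],
                      paste(d$state, d$year)[d$group != "all"], sum)
    all_val <- tapply(d$shortfall_abs[d$group == "all"],
                      paste(d$state, d$year)[d$group == "all"], sum)
    expect_equal(grp_sum[names(all_val)], all_val, tolerance = 1e-8)
  }
  ## pct = abs / group baseline where defined
  ok <- !is.na(scen$shortfall_pct)
  expect_equal(scen$shortfall_pct[ok],
               scen$shortfall_abs[ok] / scen$baseline_revenue_group[ok],
               tolerance = 1e-12)
  ## worked example: $10M on $100M is 10%
  expect_equal(10e6 / 100e6, 0.10)
})

test_that("nonexpansion states are untouched by S1 on full synthetic runs", {
  run <- default_run()
  pol <- unique(run$inputs$policy[c("state", "expansion_state")])
  non_exp <- pol$state[!pol$expansion_state]
  s1 <- run$scenarios[run$scenarios$scenario == "S1", ]
  expect_true(all(s1$shortfall_abs[s1$state %in% non_exp] == 0))
})
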