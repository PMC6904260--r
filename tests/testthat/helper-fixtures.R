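## Shared fixtures and independent oracles. Helpers are loaded once per
## test run; expensive fixtures are cached across files in `.fixture_cache`.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

## Default synthetic study conditions, fitted model, baseline, scenarios.
default_run <- function() {
  cached("default_run", suppressWarnings(suppressMessages(
    run_pipeline(list(seed = 1))
  )))
}

## A small noiseless world for exact-identity checks.
noiseless_config <- function(seed = 5, ...) {
  synth_config(seed = seed,
               noise_sd = list(patients = 0, revenue_pc = 0,
                               fte_cost = 0, cpi = 0), ...)
}

noiseless_world <- function() {
  cached("noiseless_world", {
    cfg <- noiseless_config()
    dat <- synth_dataset(cfg)
    panel <- suppressMessages(exclude_qhp_states(dat$panel, dat$policy))
    list(cfg = cfg, dat = dat, panel = panel)
  })
}

## 5-analyzed-state fixture for oracle-equivalence checks.
five_state_run <- function() {
  cached("five_state_run", suppressWarnings(suppressMessages(
    run_pipeline(list(seed = 20,
                      synth = list(n_states = 6, n_qhp = 1,
                                   expansion_share = 0.5)))
  )))
}

## ---- independent scalar oracles (naive year-by-year loops) -------------

## Patient projection: explicit per-row sum of coefficient * regressor.
oracle_project_patients <- function(fit, population, years) {
  pop <- population[population$year %in% years, ]
  pop <- pop[order(pop$state, pop$year), ]
  out <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    r <- pop[i, ]
    u <- if (fit$grain == "state") r$state else "(pooled)"
    b <- fit$fits[[u]]$coefficients_full
    b[is.na(b)] <- 0
    if (fit$payer == "medicaid") {
      x <- c(r$pop_age1_18 * r$elig_child,
             r$pop_age19_49_female * r$elig_parents,
             r$pop_age19_64 * r$elig_adults,
             r$pop_age65_plus * r$elig_adults,
             r$pop_age19_64)
    } else {
      x <- c(r$pop_age1_18, r$pop_age19_49_female, r$pop_age19_64,
             r$pop_age65_plus)
      if (fit$payer %in% c("private", "self_pay")) {
        x <- c(x, as.numeric(r$year >= fit$marketplace_year))
      }
    }
    out[i] <- max(0, sum(b * x))
  }
  data.frame(state = pop$state, year = pop$year, patients = out)
}

## Per-capita revenue recursion, one value at a time.
oracle_pc_recursion <- function(alpha, seed_value, years, aca, dra,
                                t_center = 2000) {
  alpha[is.na(alpha)] <- 0
  prev <- seed_value
  out <- numeric(length(years))
  for (k in seq_along(years)) {
    tt <- years[k] - t_center
    v <- alpha[1] + alpha[2] * prev + alpha[3] * tt +
      alpha[4] * tt * aca[k] + alpha[5] * tt * dra[k]
    v <- max(0, v)
    out[k] <- v
    prev <- v
  }
  out
}

## Scenario federal contributions recomputed state by state, year by year.
oracle_scenarios <- function(shares, hist_shares, policy, years,
                             rate = 0.023) {
  states <- sort(unique(shares$state))
  rows <- list()
  pol16 <- policy[policy$year == 2016, ]
  base16 <- hist_shares[hist_shares$group == "traditional" &
                          hist_shares$year == 2016, ]
  base1516 <- hist_shares[hist_shares$group == "traditional" &
                            hist_shares$year %in% c(2015, 2016), ]
  ## national unweighted average of traditional per-capita expenditures
  nat <- sapply(sort(unique(shares$year)), function(y) {
    mean(shares$per_capita_expenditure[shares$group == "traditional" &
                                         shares$year == y])
  })
  names(nat) <- sort(unique(shares$year))
  for (st in states) {
    gap <- pol16$efmap[pol16$state == st] - pol16$fmap[pol16$state == st]
    is_exp <- pol16$expansion_state[pol16$state == st]
    b16 <- base16$federal[base16$state == st]
    b <- base1516[base1516$state == st, ]
    pc_base <- mean(b$federal / b$enrollees)
    cap_prev <- NA
    for (y in years) {
      sh_t <- shares[shares$state == st & shares$year == y &
                       shares$group == "traditional", ]
      sh_e <- shares[shares$state == st & shares$year == y &
                       shares$group == "expansion", ]
      ## S1
      red <- if (is_exp) gap * sh_e$per_capita_expenditure * sh_e$enrollees else 0
      ## S2
      grant <- b16 * (1 + rate)^(y - 2016)
      ## S3 (annual composition of the deviance)
      pc_prev <- shares$per_capita_expenditure[
        shares$state == st & shares$year == y - 1 &
          shares$group == "traditional"]
      dev <- pc_prev / nat[[as.character(y - 1)]] - 1
      cap <- if (y == min(years)) {
        pc_base * (1 + rate)^(y - 2016) * (1 + dev)
      } else {
        cap_prev * (1 + rate) * (1 + dev)
      }
      cap_prev <- cap
      rows[[length(rows) + 1L]] <- data.frame(
        state = st, year = y,
        s1_federal_exp = sh_e$federal - red,
        s2_federal_trad = grant,
        s3_federal_trad = cap * sh_t$enrollees,
        s3_federal_exp = cap * sh_e$enrollees)
    }
  }
  do.call(rbind, rows)
}

## Hand-built two-state share fixture: one expansion ("EX", 0.6 FMAP,
## 500 expansion enrollees) and one nonexpansion ("NX") state, with
## baseline per-capita expenditure growing at `fed_growth` from 2016.
mini_shares <- function(years = 2019:2024, fed_growth = 0.023,
                        pc = c(EX = 5000, NX = 5000),
                        enroll = c(EX = 1000, NX = 800),
                        exp_enroll = 500) {
  rows <- list()
  for (st in c("EX", "NX")) {
    for (grp in c("traditional", "expansion")) {
      enr <- if (grp == "traditional") enroll[[st]] else {
        if (st == "EX") exp_enroll else 0
      }
      rate <- if (grp == "traditional") 0.6 else 0.9
      for (y in years) {
        g <- (1 + fed_growth)^(y - 2016)
        rev <- pc[[st]] * enr * g
        rows[[length(rows) + 1L]] <- data.frame(
          state = st, year = y, group = grp, enrollees = enr,
          medicaid_revenue = rev, per_capita_expenditure = pc[[st]] * g,
          federal = rate * rev, state_share = (1 - rate) * rev,
          match_rate = rate)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$state, out$year, out$group), ]
}

mini_policy <- function() {
  d <- expand.grid(state = c("EX", "NX"), year = 2000:2024,
                   stringsAsFactors = FALSE)
  transform(d, fmap = 0.6, efmap = 1.0,
            expansion_state = state == "EX",
            expansion_year = ifelse(state == "EX", 2014L, NA_integer_),
            qhp_expansion = FALSE)
}

mini_hist <- function(pc = c(EX = 5000, NX = 5000),
                      enroll = c(EX = 1000, NX = 800)) {
  mini_shares(years = 2015:2016, pc = pc, enroll = enroll)
}
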