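## One-call reproducible pipeline: synthesize (or load) inputs, exclude
## marketplace-expansion states, fit, project, run scenarios, compute
## staffing impacts, write artifacts.

#' Run the full simulation pipeline
#'
#' Orchestrates the whole analysis from a run configuration: load the four
#' input CSVs (or generate them synthetically), exclude marketplace (QHP)
#' expansion states, fit the model, project the baseline, run the
#' financing scenarios, compute staffing impacts and the disenrollment
#' sensitivity sweep, and write `baseline.csv`, `scenarios.csv`,
#' `impact.csv`, `sensitivity.csv`, `models.json`, and `run_log.txt` to the
#' output directory. Identical configuration and seed give byte-identical
#' outputs.
#'
#' @param config A named list or path to a YAML file with (optionally)
#'   `panel`, `population`, `policy`, `cpi` (CSV paths; omitted means
#'   synthesize), `synth` (list of [synth_config()] overrides), `years`
#'   (scenario years), `scenarios`, `inflation` (`"fixed"`/`"cpim"`),
#'   `levels` (sensitivity levels), `seed`, and `out_dir`.
#' @return Invisibly, a list with all in-memory stage outputs.
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config)) stop_mc("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  years <- as.integer(config$years %||% 2020:2024)
  scen_list <- config$scenarios %||% c("S1", "S2", "S3")
  inflation <- config$inflation %||% "fixed"
  levels <- config$levels %||% seq(0.05, 0.30, by = 0.05)
  out_dir <- config$out_dir %||% NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_mc("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  truth <- NULL
  if (!is.null(config$panel)) {
    inputs <- stage("load", {
      for (f in c("panel", "population", "policy", "cpi")) {
        if (is.null(config[[f]])) stop_mc("config missing input path '%s'", f)
        if (!file.exists(config[[f]])) {
          stop_mc("input file for '%s' not found: %s", f, config[[f]])
        }
      }
      list(panel = read_panel(config$panel, "panel"),
           population = read_panel(config$population, "population"),
           policy = read_panel(config$policy, "policy"),
           cpi = read_panel(config$cpi, "cpi"))
    })
  } else {
    inputs <- stage("synth", {
      scfg <- do.call(synth_config, c(config$synth %||% list(),
                                      list(seed = seed)))
      dat <- synth_dataset(scfg)
      truth <<- dat$truth
      dat[c("panel", "population", "policy", "cpi")]
    })
  }

  panel <- stage("exclude", exclude_qhp_states(inputs$panel, inputs$policy))
  fit <- stage("fit", hc_model(panel, inputs$population, inputs$policy))
  baseline <- stage("baseline", {
    predict(fit, inputs$population, inputs$policy,
            years = seq(max(fit$history_years) + 1L, max(years)))
  })
  scen <- stage("scenarios", {
    run_scenarios(fit, baseline, inputs$population, inputs$policy,
                  inputs$cpi, scenarios = scen_list, inflation = inflation,
                  years = years)
  })
  impact_upper <- stage("impact", fte_impact(scen, baseline, "no_cuts"))
  impact_lower <- stage("impact", fte_impact(scen, baseline,
                                             "proportional_cuts"))
  impact <- rbind(impact_upper, impact_lower)
  sweep <- stage("sensitivity", sensitivity_sweep(scen, baseline, levels))
  summary_tbl <- stage("summary",
                       summarize_by_expansion_status(scen, inputs$policy))

  result <- list(inputs = inputs, truth = truth, fit = fit,
                 baseline = baseline, scenarios = scen, impact = impact,
                 sensitivity = sweep, summary = summary_tbl,
                 seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_table(as.data.frame(baseline), file.path(out_dir, "baseline.csv"))
    write_table(scen, file.path(out_dir, "scenarios.csv"))
    write_table(impact, file.path(out_dir, "impact.csv"))
    write_table(sweep, file.path(out_dir, "sensitivity.csv"))
    jsonlite::write_json(stats::coef(fit), file.path(out_dir, "models.json"),
                         dataframe = "rows", digits = NA)
    cfg_flat <- config[!vapply(config, is.list, logical(1))]
    log_lines <- c(
      sprintf("seed: %d", seed),
      sprintf("scenario years: %s", paste(range(years), collapse = "-")),
      sprintf("inflation: %s", inflation),
      sprintf("states analyzed: %s",
              paste(sort(unique(panel$state)), collapse = ",")),
      sprintf("config: %s",
              paste(names(cfg_flat), vapply(cfg_flat, function(v)
                paste(v, collapse = ","), character(1)),
                sep = "=", collapse = "; ")))
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(result)
}

#' Summarize scenario results by expansion status
#'
#' Aggregates shortfall percentages by expansion status, scenario, and
#' coverage group (enrollee-weighted by default), and ranks states from
#' most to least affected by their final-year total shortfall percentage.
#'
#' @param scenario_results Output of [run_scenarios()].
#' @param policy Policy table (expansion flags).
#' @param weights `"enrollees"` (weight states by baseline Medicaid
#'   enrollment) or `"equal"`.
#' @return A list with `by_group` (mean shortfall percentages) and
#'   `rankings` (states ordered most- to least-affected per scenario).
#' @export
summarize_by_expansion_status <- function(scenario_results, policy,
                                          weights = c("enrollees", "equal")) {
  weights <- match.arg(weights)
  info <- unique(policy[c("state", "expansion_state")])
  res <- scenario_results
  res$expansion <- ifelse(info$expansion_state[match(res$state, info$state)],
                          "expansion", "nonexpansion")
  grp <- res[res$group != "all" & !is.na(res$shortfall_pct), ]
  w <- if (weights == "enrollees") {
    pmax(grp$baseline_revenue_group, 0)
  } else rep(1, nrow(grp))
  by_group <- stats::aggregate(
    list(shortfall_pct = grp$shortfall_pct * w, w = w),
    by = list(expansion = grp$expansion, scenario = grp$scenario,
              group = grp$group), FUN = sum)
  by_group$shortfall_pct <- ifelse(by_group$w > 0,
                                   by_group$shortfall_pct / by_group$w,
                                   NA_real_)
  by_group$w <- NULL

  final_year <- max(res$year)
  allg <- res[res$group == "all" & res$year == final_year, ]
  rankings <- do.call(rbind, lapply(split(allg, allg$scenario), function(d) {
    d <- d[order(-d$shortfall_pct, d$state), ]
    data.frame(scenario = d$scenario, rank = seq_len(nrow(d)),
               state = d$state, shortfall_pct = d$shortfall_pct,
               stringsAsFactors = FALSE)
  }))
  rownames(rankings) <- NULL
  list(by_group = by_group, rankings = rankings)
}
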