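## Data model: column sets shared across the package.

#' Payer and service category constants
#'
#' `mc_payers()` returns the five payer categories tracked in UDS-style
#' panels; `mc_fte_services()` the eight staffing categories; and
#' `mc_cost_services()` the six service categories at which FTE costs are
#' modelled (the three medical staffing columns share one cost category).
#'
#' @return Character vector of category names.
#' @export
mc_payers <- function() {
  c("medicaid", "medicare", "private", "self_pay", "other_public")
}

#' @rdname mc_payers
#' @export
mc_fte_services <- function() {
  c("medical_physician", "medical_apc", "medical_other", "dental",
    "mental_health", "substance_use", "other_professional", "nonclinical")
}

#' @rdname mc_payers
#' @export
mc_cost_services <- function() {
  c("medical", "dental", "mental_health", "substance_use",
    "other_professional", "nonclinical")
}

## Clinical vs nonclinical split: clinical covers medical, dental, mental
## health, substance use treatment, and other professional services; the
## nonclinical category covers enabling and administrative staff.
mc_clinical_services <- function() setdiff(mc_cost_services(), "nonclinical")

panel_columns <- function() {
  c("state", "year", "n_health_centers",
    paste0("patients_", mc_payers()), "patients_total",
    paste0("revenue_", mc_payers()), "revenue_total_patient",
    "grant_revenue",
    paste0("fte_", mc_fte_services()),
    paste0("fte_cost_", mc_cost_services()))
}

population_columns <- function() {
  c("state", "year",
    "pop_age1_18", "pop_age19_49_female", "pop_age19_64", "pop_age65_plus",
    "elig_child", "elig_parents", "elig_adults")
}

policy_columns <- function() {
  c("state", "year", "fmap", "efmap",
    "expansion_state", "expansion_year", "qhp_expansion")
}

cpi_columns <- function() c("year", "cpi_m", "cpi_u")

schema_columns <- function(schema) {
  switch(schema,
    panel = panel_columns(),
    population = population_columns(),
    policy = policy_columns(),
    cpi = cpi_columns(),
    stop_mc("unknown schema '%s'", schema))
}

#' Read and validate a pipeline input table
#'
#' Reads one of the four CSV table kinds (`"panel"`, `"population"`,
#' `"policy"`, `"cpi"`), checks that every required column is present,
#' ignores unknown columns with a warning, and enforces the schema's
#' invariants (non-negativity, adding-up identities, per-state year
#' contiguity). CSVs are UTF-8, comma-separated, with a header row and `.`
#' decimals.
#'
#' @param path Path to a CSV file.
#' @param schema One of `"panel"`, `"population"`, `"policy"`, `"cpi"`.
#' @return A validated `data.frame` carrying a `"mc_schema"` attribute.
#' @seealso [validate_panel()], [write_table()]
#' @export
read_panel <- function(path, schema = c("panel", "population", "policy", "cpi")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop_mc("input file not found: %s", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  req <- schema_columns(schema)
  missing <- setdiff(req, names(raw))
  if (length(missing)) {
    stop_mc("schema '%s': missing required column(s): %s",
            schema, paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(raw), req)
  if (length(extra)) {
    warn_mc("schema '%s': ignoring unknown column(s): %s",
            schema, paste(extra, collapse = ", "))
  }
  tbl <- raw[req]
  tbl <- coerce_schema(tbl, schema)
  rep <- validate_table(tbl, schema)
  if (nrow(rep)) {
    stop_mc("schema '%s': %d invariant violation(s); first: %s",
            schema, nrow(rep), format_violation(rep[1L, ]))
  }
  attr(tbl, "mc_schema") <- schema
  tbl
}

coerce_schema <- function(tbl, schema) {
  if ("state" %in% names(tbl)) tbl$state <- as.character(tbl$state)
  if ("year" %in% names(tbl)) tbl$year <- as.integer(tbl$year)
  if (schema == "policy") {
    tbl$expansion_state <- as.logical(tbl$expansion_state)
    tbl$qhp_expansion <- as.logical(tbl$qhp_expansion)
    tbl$expansion_year <- suppressWarnings(as.integer(tbl$expansion_year))
  }
  num <- setdiff(names(tbl), c("state", "year", "expansion_state",
                               "expansion_year", "qhp_expansion"))
  for (cn in num) tbl[[cn]] <- as.numeric(tbl[[cn]])
  tbl
}

#' Write a pipeline table to CSV
#'
#' Numeric columns are written with 17 significant digits so that a
#' write-then-read round trip reproduces every double bit-for-bit.
#'
#' @param tbl A table as returned by [read_panel()] or the generators.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(tbl, path) {
  out <- as.data.frame(tbl)
  for (cn in names(out)) {
    if (is.double(out[[cn]])) {
      out[[cn]] <- vapply(out[[cn]], function(v) {
        if (is.na(v)) "" else sprintf("%.17g", v)
      }, character(1))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

format_violation <- function(row) {
  sprintf("state=%s year=%s field=%s: %s",
          row$state, row$year, row$field, row$message)
}

violation <- function(state, year, field, message) {
  data.frame(state = as.character(state), year = as.integer(year),
             field = field, message = message, stringsAsFactors = FALSE)
}

empty_report <- function() {
  data.frame(state = character(), year = integer(), field = character(),
             message = character(), stringsAsFactors = FALSE)
}

#' Validate a state-by-year health-center panel
#'
#' Checks every panel invariant and returns a report with one row per
#' violation: all counts, revenues and FTEs non-negative; total patients and
#' total patient revenue equal to the payer sums; years contiguous within
#' each state. An empty report means the panel is valid. This is a
#' reporting operation and never throws.
#'
#' @param panel A panel `data.frame` with the columns of
#'   `read_panel(schema = "panel")`.
#' @param tol Relative tolerance for the adding-up identities.
#' @return A `data.frame` with columns `state`, `year`, `field`, `message`.
#' @export
validate_panel <- function(panel, tol = 1e-8) {
  rep <- empty_report()
  numcols <- setdiff(panel_columns(), c("state", "year"))
  for (cn in numcols) {
    bad <- which(!is.na(panel[[cn]]) & panel[[cn]] < 0)
    for (i in bad) {
      rep <- rbind(rep, violation(panel$state[i], panel$year[i], cn,
                                  sprintf("negative value %g at row %d",
                                          panel[[cn]][i], i)))
    }
  }
  pat_sum <- rowSums(panel[paste0("patients_", mc_payers())])
  rev_sum <- rowSums(panel[paste0("revenue_", mc_payers())])
  bad_pat <- which(abs(pat_sum - panel$patients_total) >
                     tol * pmax(1, abs(panel$patients_total)))
  for (i in bad_pat) {
    rep <- rbind(rep, violation(panel$state[i], panel$year[i], "patients_total",
                                "payer patients do not sum to total"))
  }
  bad_rev <- which(abs(rev_sum - panel$revenue_total_patient) >
                     tol * pmax(1, abs(panel$revenue_total_patient)))
  for (i in bad_rev) {
    rep <- rbind(rep, violation(panel$state[i], panel$year[i],
                                "revenue_total_patient",
                                "payer revenues do not sum to total"))
  }
  for (st in unique(panel$state)) {
    yrs <- sort(panel$year[panel$state == st])
    if (length(yrs) > 1L && !identical(as.integer(yrs),
                                       seq(min(yrs), max(yrs)))) {
      rep <- rbind(rep, violation(st, min(yrs), "year",
                                  "years are not a contiguous range"))
    }
  }
  rep
}

validate_table <- function(tbl, schema) {
  switch(schema,
    panel = validate_panel(tbl),
    population = validate_population(tbl),
    policy = validate_policy(tbl),
    cpi = validate_cpi(tbl))
}

validate_population <- function(pop) {
  rep <- empty_report()
  for (cn in grep("^pop_|^elig_", names(pop), value = TRUE)) {
    bad <- which(!is.na(pop[[cn]]) & pop[[cn]] < 0)
    for (i in bad) {
      rep <- rbind(rep, violation(pop$state[i], pop$year[i], cn,
                                  sprintf("negative value at row %d", i)))
    }
  }
  bad <- which(pop$pop_age19_49_female > pop$pop_age19_64 + 1e-9)
  for (i in bad) {
    rep <- rbind(rep, violation(pop$state[i], pop$year[i],
                                "pop_age19_49_female",
                                "female 19-49 band exceeds the 19-64 band"))
  }
  rep
}

validate_policy <- function(pol) {
  rep <- empty_report()
  bad <- which(!(pol$fmap > 0 & pol$fmap < 1))
  for (i in bad) {
    rep <- rbind(rep, violation(pol$state[i], pol$year[i], "fmap",
                                "FMAP outside (0, 1)"))
  }
  bad <- which(pol$expansion_state & !is.na(pol$efmap) & pol$efmap < pol$fmap)
  for (i in bad) {
    rep <- rbind(rep, violation(pol$state[i], pol$year[i], "efmap",
                                "EFMAP below FMAP for an expansion state"))
  }
  rep
}

validate_cpi <- function(cpi) {
  rep <- empty_report()
  for (cn in c("cpi_m", "cpi_u")) {
    bad <- which(!is.na(cpi[[cn]]) & (cpi[[cn]] <= -0.05 | cpi[[cn]] >= 0.20))
    for (i in bad) {
      rep <- rbind(rep, violation("", cpi$year[i], cn,
                                  "inflation fraction outside (-0.05, 0.20)"))
    }
  }
  rep
}

#' Drop states whose Medicaid expansion runs through marketplace plans
#'
#' States that expanded coverage by subsidizing qualified health plans on
#' the marketplace (historically New Hampshire and Iowa) book expansion
#' revenues as private-plan revenues, which would distort Medicaid rollback
#' simulations; they are excluded from the quantitative pipeline.
#'
#' @param panel A state-by-year panel.
#' @param policy A policy table (schema `"policy"`) with a `qhp_expansion`
#'   flag defined for every panel state.
#' @return The panel without the flagged states; removals are messaged.
#' @export
exclude_qhp_states <- function(panel, policy) {
  flags <- unique(policy[c("state", "qhp_expansion")])
  unknown <- setdiff(unique(panel$state), flags$state)
  if (length(unknown)) {
    stop_mc("qhp_expansion flag undefined for state(s): %s",
            paste(unknown, collapse = ", "))
  }
  drop <- flags$state[flags$qhp_expansion]
  drop <- intersect(drop, unique(panel$state))
  if (length(drop)) {
    message("excluding QHP-expansion state(s): ", paste(drop, collapse = ", "))
  }
  out <- panel[!panel$state %in% drop, , drop = FALSE]
  if (nrow(out) == 0L) warn_mc("all states excluded; panel is empty")
  rownames(out) <- NULL
  out
}
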