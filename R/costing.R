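#' Equivalent annual cost of a capital outlay
#'
#' Converts a capital purchase into a constant annual charge over its useful
#' life using an annuity-due factor (payments at the start of each period):
#' `AF = (1 - (1+r)^-n) / r * (1+r)`, and `EAC = outlay / AF`. At `r = 0`
#' this reduces to straight-line depreciation `outlay / n`. The annuity-due
#' convention is the one that reproduces the programme's capital ledger rows
#' (an ordinary annuity does not).
#'
#' @param capital_outlay purchase cost (Int$), non-negative.
#' @param lifetime useful life in years (default 5).
#' @param rate annual discount rate (default 0.05).
#' @return annual charge in Int$/year.
#' @examples
#' equivalent_annual_cost(2901.14, 5, 0.05)  # 638.18
#' equivalent_annual_cost(1000, 5, 0)        # 200
#' @export
equivalent_annual_cost <- function(capital_outlay, lifetime = 5, rate = 0.05) {
  if (any(capital_outlay < 0))
    stop("capital_outlay must be non-negative", call. = FALSE)
  if (any(lifetime < 1)) stop("lifetime must be >= 1 year", call. = FALSE)
  if (any(rate < 0)) stop("rate must be non-negative", call. = FALSE)
  af <- ifelse(rate == 0, lifetime,
               (1 - (1 + rate)^(-lifetime)) / rate * (1 + rate))
  capital_outlay / af
}

.ledger_categories <- c("labour", "capital", "land", "resource",
                        "overhead", "visit", "consumption")
# institution-level categories are annual totals for the whole programme and
# are divided by the covered population; the remaining categories are already
# expressed per patient-year in the ledger
.institution_categories <- c("labour", "capital", "land", "resource")

#' Read a micro-costing ledger CSV
#'
#' Expected columns: `item`, `category` (one of labour, capital, land,
#' resource, overhead, visit, consumption), `unit_cost`, `quantity`, and for
#' capital rows `capital_lifetime` (years) and `capital_rate`. Land rows are
#' priced per m2-month, so their quantity is in m2-months per year.
#'
#' @param path CSV file path.
#' @return a data.frame of ledger items.
#' @export
read_ledger <- function(path) {
  if (!file.exists(path)) stop("ledger file not found: ", path, call. = FALSE)
  led <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("item", "category", "unit_cost", "quantity")
  missing <- setdiff(required, names(led))
  if (length(missing))
    stop("ledger is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (is.null(led$capital_lifetime)) led$capital_lifetime <- NA_real_
  if (is.null(led$capital_rate)) led$capital_rate <- NA_real_
  led
}

#' Micro-costing: annual and per-patient cost breakdown
#'
#' Reproduces the programme's accounting arithmetic: each non-capital item
#' costs `unit_cost * quantity` per year; capital items are annuitised with
#' [equivalent_annual_cost()] over their lifetime at their rate. Institution
#' -level categories (labour, capital, land, resource) are summed to an
#' annual programme total and divided by `population_size` for the
#' per-patient figure; overhead, visit and consumption rows are already per
#' patient-year.
#'
#' @param items data.frame of ledger items (see [read_ledger()]).
#' @param population_size patients covered (default 30,000).
#' @return an object of class `cost_breakdown`: a list with `by_category`
#'   (data.frame of category, annual_cost, per_patient), `programme_total`,
#'   `programme_per_patient` (institution-level categories only) and
#'   `annual_total_per_patient` (programme per patient + per-patient
#'   categories).
#' @export
compute_ledger <- function(items, population_size = 30000L) {
  if (population_size <= 0) stop("population_size must be > 0", call. = FALSE)
  if (is.null(items$capital_lifetime))
    items$capital_lifetime <- rep(NA_real_, nrow(items))
  if (is.null(items$capital_rate))
    items$capital_rate <- rep(NA_real_, nrow(items))
  bad <- setdiff(unique(items$category), .ledger_categories)
  if (length(bad))
    stop("unknown ledger category: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (any(items$unit_cost < 0) || any(items$quantity < 0))
    stop("unit_cost and quantity must be non-negative", call. = FALSE)

  outlay <- items$unit_cost * items$quantity
  is_cap <- items$category == "capital"
  annual <- outlay
  if (any(is_cap)) {
    lt <- ifelse(is.na(items$capital_lifetime[is_cap]), 5,
                 items$capital_lifetime[is_cap])
    rt <- ifelse(is.na(items$capital_rate[is_cap]), 0.05,
                 items$capital_rate[is_cap])
    annual[is_cap] <- equivalent_annual_cost(outlay[is_cap], lt, rt)
  }

  cats <- intersect(.ledger_categories, unique(items$category))
  by_cat <- data.frame(
    category = cats,
    annual_cost = vapply(cats, function(cc) sum(annual[items$category == cc]),
                         numeric(1)),
    stringsAsFactors = FALSE)
  inst <- by_cat$category %in% .institution_categories
  by_cat$per_patient <- ifelse(inst, by_cat$annual_cost / population_size,
                               by_cat$annual_cost)
  programme_total <- sum(by_cat$annual_cost[inst])
  structure(list(
    by_category = by_cat,
    items = data.frame(item = items$item, category = items$category,
                       annual_cost = annual, stringsAsFactors = FALSE),
    programme_total = programme_total,
    programme_per_patient = programme_total / population_size,
    annual_total_per_patient = programme_total / population_size +
      sum(by_cat$per_patient[!inst]),
    population_size = population_size), class = "cost_breakdown")
}

#' @export
print.cost_breakdown <- function(x, ...) {
  cat("<cost_breakdown>\n")
  print(x$by_category, row.names = FALSE)
  cat(sprintf("programme total %.2f | per patient %.4f | annual total/pt %.2f\n",
              x$programme_total, x$programme_per_patient,
              x$annual_total_per_patient))
  invisible(x)
}

#' Bundled micro-costing ledgers
#'
#' Paths to the ledgers shipped with the package: the hypertension programme
#' ledger (institution-level labour/capital/land/resource items plus
#' per-patient overhead, visit and consumption rows) and the usual-care
#' ledger (per-patient rows only).
#'
#' @param strategy `"programme"` or `"usual"`.
#' @return file path to the ledger CSV.
#' @export
ledger_path <- function(strategy = c("programme", "usual")) {
  strategy <- match.arg(strategy)
  system.file("extdata", paste0("ledger_", strategy, ".csv"),
              package = "htncea", mustWork = TRUE)
}

#' Annual treatment cost per patient for a strategy
#'
#' The per-cycle cost charged by the cohort model to every patient alive at
#' cycle start: covered drugs (`drug_cost_year * drug_coverage`), diagnostic
#' and follow-up tests, the programme fee (zero under usual care), medical
#' visits at `n_visits_year * (visit_cost + overhead_per_visit)`, the annual
#' ambulance service, and in the first cycle only the diagnostic work-up at
#' entry.
#'
#' @param components named list or vector of cost components:
#'   `drug_cost_year`, `drug_coverage`, `test_cost_year`,
#'   `programme_fee_year`, `n_visits_year`, `visit_cost`,
#'   `overhead_per_visit`, `ambulance_cost_year`, `first_year_test_cost`.
#' @param first_cycle add the entry diagnostic work-up? (default `FALSE`)
#' @return Int$ per patient-year.
#' @export
annual_treatment_cost <- function(components, first_cycle = FALSE) {
  cmp <- as.list(components)
  cmp$drug_cost_year * cmp$drug_coverage + cmp$test_cost_year +
    cmp$programme_fee_year +
    cmp$n_visits_year * (cmp$visit_cost + cmp$overhead_per_visit) +
    cmp$ambulance_cost_year +
    if (isTRUE(first_cycle)) cmp$first_year_test_cost else 0
}

#' Hospital cost of one acute cardiovascular event episode
#'
#' Hospital expenditure is charged only when the event receives hospital
#' attention; unassisted events (including sudden deaths) cost nothing to
#' the payer.
#'
#' @param assisted logical: did the event receive hospital care?
#' @param event_hospital_cost cost of an assisted episode (Int$).
#' @return Int$.
#' @export
event_episode_cost <- function(assisted, event_hospital_cost) {
  ifelse(assisted, event_hospital_cost, 0)
}

#' Fit a lognormal law to positive cost samples
#'
#' Returns the mean and standard deviation of the log-transformed samples,
#' the parameterisation used for the skewed hospital-episode costs.
#'
#' @param samples positive numeric vector, length >= 2.
#' @return named numeric `c(mu, sigma)`.
#' @export
fit_lognormal <- function(samples) {
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop("all samples must be positive and finite", call. = FALSE)
  lx <- log(samples)
  c(mu = mean(lx), sigma = stats::sd(lx))
}

#' Cost components of a strategy, at base-case values
#'
#' Merges the strategy-specific block of a parameter set with the shared cost
#' block into the flat component list consumed by
#' [annual_treatment_cost()] and the cohort engine.
#'
#' @param params a `parameter_set`.
#' @param strategy `"usual"` or `"programme"`.
#' @return named list of scalars.
#' @export
strategy_components <- function(params, strategy = c("usual", "programme")) {
  strategy <- match.arg(strategy)
  bases <- function(block) lapply(block, function(s) s$base)
  st <- bases(params[[strategy]])
  cm <- bases(params$common)
  c(st[c("drug_cost_year", "test_cost_year", "n_visits_year",
         "programme_fee_year")],
    cm[c("drug_coverage", "visit_cost", "overhead_per_visit",
         "ambulance_cost_year", "first_year_test_cost",
         "event_hospital_cost")])
}
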