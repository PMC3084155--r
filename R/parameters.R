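#' Base-case parameter set of the hypertension programme model
#'
#' Returns the full set of model inputs for the two treatment strategies
#' ("usual care" and the comprehensive hypertension programme), each scalar
#' carrying its base-case value and its sampling distribution for the
#' probabilistic sensitivity analysis. Costs are per patient in 2010
#' International Dollars; event risks are annual probabilities.
#'
#' The set is organised in three blocks:
#' \describe{
#'   \item{`usual`, `programme`}{strategy-specific costs (drugs, diagnostic
#'     tests, programme fee, number of medical visits) and the strategy's
#'     hazard ratio on the reference cardiovascular event risk. The programme
#'     block also carries `hr_scenario`, a uniform law used only when the
#'     hazard-ratio scenario mode replaces the normal draw.}
#'   \item{`common`}{costs shared by both strategies (per-visit cost and
#'     overhead, ambulance, drug coverage fraction, hospital cost of an
#'     assisted acute event, first-year diagnostic work-up), the reference
#'     event risks by age band (65-74 / 75+) and risk stratum
#'     (intermediate / high), the acute-event pathway (sudden death,
#'     unrecognized events, case fatality by assistance and age band), and
#'     the cohort entry conditions (starting age, proportion starting at
#'     intermediate risk).}
#' }
#'
#' @return an object of class `parameter_set`.
#' @seealso [econ_settings()], [sample_parameter_set()], [run_cohort()]
#' @export
base_case <- function() {
  ps <- list(
    schema = 1L,
    usual = list(
      drug_cost_year    = dist_spec("lognormal", 4.36, 1.39, base = 206.43),
      test_cost_year    = dist_spec("uniform", 20.37, 37.83, base = 29.10),
      n_visits_year     = dist_spec("lognormal", 1.68, 0.89, base = 7.68),
      programme_fee_year = dist_spec("fixed", base = 0),
      hr                = dist_spec("normal", 0.6150, 0.0089)
    ),
    programme = list(
      drug_cost_year    = dist_spec("lognormal", 4.59, 1.26, base = 216.55),
      test_cost_year    = dist_spec("uniform", 25.33, 47.04, base = 36.19),
      n_visits_year     = dist_spec("lognormal", 1.16, 0.85, base = 4.72),
      programme_fee_year = dist_spec("uniform", 10.26, 19.06, base = 14.66),
      hr                = dist_spec("normal", 0.5124, 0.0131),
      hr_scenario       = dist_spec("uniform", 0.4500, 0.5700, base = 0.5100)
    ),
    common = list(
      overhead_per_visit   = dist_spec("uniform", 1.39, 2.57, base = 1.98),
      visit_cost           = dist_spec("uniform", 6.74, 12.52, base = 9.63),
      ambulance_cost_year  = dist_spec("uniform", 12.21, 22.67, base = 17.44),
      drug_coverage        = dist_spec("uniform", 0.40, 1.00, base = 0.70),
      event_hospital_cost  = dist_spec("lognormal", 8.24, 1.39, base = 10041.65),
      first_year_test_cost = dist_spec("uniform", 82.44, 153.11, base = 117.78),
      p_ref_intermediate_65_74 = dist_spec("uniform", 0.0223, 0.0285, base = 0.0255),
      p_ref_intermediate_75    = dist_spec("uniform", 0.0300, 0.0500, base = 0.0400),
      p_ref_high_65_74         = dist_spec("uniform", 0.0300, 0.0350, base = 0.0325),
      p_ref_high_75            = dist_spec("uniform", 0.1500, 0.2500, base = 0.2000),
      p_start_intermediate = dist_spec("uniform", 0.0, 1.0, base = 0.70),
      start_age            = dist_spec("uniform", 65, 80, base = 65),
      p_unrecognized       = dist_spec("uniform", 0.2500, 0.4000, base = 0.3670),
      p_sudden_death       = dist_spec("uniform", 0.0600, 0.1400, base = 0.1000),
      cfr_assisted_65_74   = dist_spec("uniform", 0.1000, 0.2000, base = 0.1500),
      cfr_assisted_75      = dist_spec("uniform", 0.2500, 0.3500, base = 0.3000),
      cfr_unassisted_65_74 = dist_spec("uniform", 0.2000, 0.4000, base = 0.3000),
      cfr_unassisted_75    = dist_spec("uniform", 0.5500, 0.6500, base = 0.6000)
    )
  )
  structure(ps, class = "parameter_set")
}

# parameters drawn as Normal that must be truncated, with their support
.normal_supports <- list(hr = c(0, 1.5))
# parameters that are probabilities (truncate normal draws to [0,1]; uniform
# laws in the printed tables already respect this)
.probability_params <- c("drug_coverage",
                         "p_ref_intermediate_65_74", "p_ref_intermediate_75",
                         "p_ref_high_65_74", "p_ref_high_75",
                         "p_start_intermediate", "p_unrecognized",
                         "p_sudden_death",
                         "cfr_assisted_65_74", "cfr_assisted_75",
                         "cfr_unassisted_65_74", "cfr_unassisted_75")

#' @export
print.parameter_set <- function(x, ...) {
  cat("<parameter_set> schema", x$schema, "\n")
  for (blk in c("usual", "programme", "common")) {
    cat(" $", blk, ": ", paste(names(x[[blk]]), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

validate_parameter_set <- function(params) {
  if (!inherits(params, "parameter_set"))
    stop("not a parameter_set", call. = FALSE)
  template <- base_case()
  for (blk in c("usual", "programme", "common")) {
    missing <- setdiff(names(template[[blk]]), names(params[[blk]]))
    if (length(missing))
      stop("parameter_set is missing required key(s): ",
           paste0(blk, "$", missing, collapse = ", "), call. = FALSE)
    for (nm in names(params[[blk]])) {
      spec <- params[[blk]][[nm]]
      validate_dist_spec(spec)
      if (nm %in% .probability_params && (spec$base < 0 || spec$base > 1))
        stop(blk, "$", nm, " base ", spec$base, " outside [0, 1]",
             call. = FALSE)
      if (nm == "hr" && spec$base <= 0)
        stop(blk, "$hr must be positive", call. = FALSE)
      if (grepl("cost|fee", nm) && spec$base < 0)
        stop(blk, "$", nm, " must be non-negative", call. = FALSE)
    }
  }
  cm <- params$common
  for (band in c("65_74", "75")) {
    if (cm[[paste0("cfr_unassisted_", band)]]$base <
        cm[[paste0("cfr_assisted_", band)]]$base)
      stop("case fatality without hospital assistance must be >= assisted (",
           band, ")", call. = FALSE)
  }
  invisible(params)
}

#' Write / read a parameter set as a YAML file
#'
#' The file is a plain YAML document with a `schema: 1` marker and one
#' mapping per parameter `{kind, p1, p2, base}`, so edited scenarios can be
#' version-controlled. `load_parameters()` validates on read: missing keys
#' raise a schema error naming the key, out-of-range values a validation
#' error. Round-trip is exact (`load_parameters(save_parameters(p)) == p`).
#'
#' @param params a `parameter_set`.
#' @param path file path.
#' @return `load_parameters()` returns a validated `parameter_set`;
#'   `save_parameters()` returns `path` invisibly.
#' @export
save_parameters <- function(params, path) {
  validate_parameter_set(params)
  to_plain <- function(spec) {
    out <- list(kind = spec$kind, base = spec$base)
    if (spec$kind != "fixed") { out$p1 <- spec$p1; out$p2 <- spec$p2 }
    out
  }
  doc <- list(schema = params$schema,
              usual = lapply(params$usual, to_plain),
              programme = lapply(params$programme, to_plain),
              common = lapply(params$common, to_plain))
  yaml::write_yaml(doc, path, precision = 15L)
  invisible(path)
}

#' @rdname save_parameters
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema)) stop("parameter file missing `schema` key", call. = FALSE)
  if (doc$schema != 1L) stop("unsupported parameter schema: ", doc$schema, call. = FALSE)
  from_plain <- function(x, where) {
    for (k in c("kind", "base")) {
      if (is.null(x[[k]]))
        stop("parameter file missing `", k, "` for ", where, call. = FALSE)
    }
    dist_spec(x$kind, p1 = x$p1 %||% NA_real_, p2 = x$p2 %||% NA_real_,
              base = x$base)
  }
  ps <- list(schema = 1L)
  for (blk in c("usual", "programme", "common")) {
    if (is.null(doc[[blk]]))
      stop("parameter file missing `", blk, "` block", call. = FALSE)
    ps[[blk]] <- mapply(from_plain, doc[[blk]],
                        paste0(blk, "$", names(doc[[blk]])),
                        SIMPLIFY = FALSE)
  }
  validate_parameter_set(structure(ps, class = "parameter_set"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Consistency report of base cases against their distributions
#'
#' For each uniform parameter reports the absolute deviation of the base case
#' from the interval midpoint; for each lognormal parameter the relative
#' deviation of the base case from the implied mean `exp(p1 + p2^2/2)`.
#' Deviations above 5% are flagged. Normal and fixed parameters are reported
#' with zero deviation (their base is the location parameter by
#' construction).
#'
#' @param params a `parameter_set`.
#' @return a data.frame with columns `block`, `parameter`, `kind`, `base`,
#'   `implied`, `deviation` (absolute for uniform, relative for lognormal)
#'   and `flag`.
#' @export
validate_distributions <- function(params) {
  validate_parameter_set(params)
  rows <- list()
  for (blk in c("usual", "programme", "common")) {
    for (nm in names(params[[blk]])) {
      spec <- params[[blk]][[nm]]
      implied <- dist_mean(spec)
      dev <- switch(spec$kind,
        uniform   = abs(spec$base - implied),
        lognormal = abs(spec$base - implied) / abs(spec$base),
        0)
      flag <- switch(spec$kind,
        uniform   = dev > 0.05 * max(1, abs(spec$base)),
        lognormal = dev > 0.05,
        FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        block = blk, parameter = nm, kind = spec$kind, base = spec$base,
        implied = implied, deviation = dev, flag = flag,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Analysis settings of the cost-effectiveness model
#'
#' Structural settings that are never sampled by the probabilistic
#' sensitivity analysis.
#'
#' @param discount_rate annual discount rate for both costs and life-years
#'   (base case 0.05; scenario sweeps use 0 to 0.12).
#' @param wtp_threshold willingness-to-pay threshold in Int$ per life-year
#'   gained (45,000, three times 2010 GDP per capita).
#' @param wtp_grid ordered WTP values for the acceptability curve.
#' @param start_age,p_start_intermediate cohort entry conditions; `NULL`
#'   (default) takes the base values from the parameter set, so that the
#'   probabilistic analysis can redraw them.
#' @param max_age model horizon: the cohort is followed to its last cycle
#'   starting at `max_age - 1` (default 100).
#' @param psa_iterations default number of probabilistic iterations.
#' @param population_size patients covered, for population-impact scaling.
#' @param half_cycle credit half a life-year to within-cycle decedents
#'   (default `FALSE`: only patients completing a cycle alive earn the year).
#' @param scenario_hr use the uniform hazard-ratio scenario law for the
#'   programme instead of its normal law when sampling (default `FALSE`).
#' @return an object of class `econ_settings`.
#' @export
econ_settings <- function(discount_rate = 0.05,
                          wtp_threshold = 45000,
                          wtp_grid = seq(0, 100000, by = 2500),
                          start_age = NULL,
                          p_start_intermediate = NULL,
                          max_age = 100L,
                          psa_iterations = 100000L,
                          population_size = 30000L,
                          half_cycle = FALSE,
                          scenario_hr = FALSE) {
  if (discount_rate < 0 || discount_rate > 0.2)
    stop("discount_rate must be in [0, 0.2]", call. = FALSE)
  if (!is.null(start_age) && (start_age < 65 || start_age >= max_age))
    stop("start_age must satisfy 65 <= start_age < max_age", call. = FALSE)
  if (!is.null(p_start_intermediate) &&
      (p_start_intermediate < 0 || p_start_intermediate > 1))
    stop("p_start_intermediate must be in [0, 1]", call. = FALSE)
  structure(list(discount_rate = discount_rate,
                 wtp_threshold = wtp_threshold,
                 wtp_grid = wtp_grid,
                 start_age = start_age,
                 p_start_intermediate = p_start_intermediate,
                 max_age = as.integer(max_age),
                 psa_iterations = as.integer(psa_iterations),
                 population_size = as.integer(population_size),
                 half_cycle = isTRUE(half_cycle),
                 scenario_hr = isTRUE(scenario_hr)),
            class = "econ_settings")
}

#' @export
print.econ_settings <- function(x, ...) {
  cat("<econ_settings> discount", x$discount_rate,
      "| WTP", x$wtp_threshold, "Int$/LYG | horizon age", x$max_age, "\n")
  invisible(x)
}
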