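# deterministic paired evaluation, optionally with parameter overrides
deterministic_increment <- function(params, settings, lt, overrides = NULL) {
  mi_u <- compile_model_inputs(params, "usual", settings, lt, overrides)
  mi_p <- compile_model_inputs(params, "programme", settings, lt, overrides)
  res_u <- cohort_engine(mi_u, settings$discount_rate)
  res_p <- cohort_engine(mi_p, settings$discount_rate)
  list(delta_cost = res_p$disc_cost - res_u$disc_cost,
       delta_effect = res_p$disc_lyg - res_u$disc_lyg,
       cost_usual = res_u$disc_cost, cost_programme = res_p$disc_cost,
       effect_usual = res_u$disc_lyg, effect_programme = res_p$disc_lyg)
}

#' Deterministic base-case comparison of the two strategies
#'
#' Runs the paired cohort models at base-case values and returns costs,
#' effects, increments and the ICER (with dominance status).
#'
#' @param params a `parameter_set`.
#' @param settings an [econ_settings()].
#' @param lt a `life_table`.
#' @return a list with per-strategy `disc_cost`/`disc_lyg`, `delta_cost`,
#'   `delta_effect`, and `icer` (see [icer()]).
#' @export
base_case_analysis <- function(params = base_case(),
                               settings = econ_settings(), lt) {
  inc <- deterministic_increment(params, settings, lt)
  c(inc, list(icer = icer(inc$delta_cost, inc$delta_effect)))
}

#' One-way sensitivity analysis for a single parameter
#'
#' Evaluates the deterministic model at the lower and upper bound of one
#' parameter, all others held at base case. The reported output is the
#' incremental net monetary benefit at the willingness-to-pay threshold
#' (`wtp * dE - dC`), which is defined for every input; the deterministic
#' ICER at each bound is attached where the increments admit one.
#'
#' @param params a `parameter_set`.
#' @param param_name qualified name `block.parameter`, e.g.
#'   `"common.drug_coverage"` or `"programme.hr"`.
#' @param low,high bounds to evaluate (`low <= high`).
#' @param settings an [econ_settings()].
#' @param lt a `life_table`.
#' @return a one-row data.frame (a tornado entry): `parameter`, `low`,
#'   `high`, `nmb_low`, `nmb_high`, `spread`, `icer_low`, `icer_high`.
#' @export
one_way <- function(params, param_name, low, high,
                    settings = econ_settings(), lt) {
  if (low > high) stop("low must be <= high", call. = FALSE)
  parts <- strsplit(param_name, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || is.null(params[[parts[1]]][[parts[2]]]))
    stop("unknown parameter: ", param_name, call. = FALSE)
  wtp <- settings$wtp_threshold
  eval_at <- function(value) {
    ov <- stats::setNames(list(value), param_name)
    inc <- deterministic_increment(params, settings, lt, overrides = ov)
    ic <- icer(inc$delta_cost, inc$delta_effect)
    c(nmb = wtp * inc$delta_effect - inc$delta_cost,
      icer = if (ic$status == "ratio") ic$icer else NA_real_,
      delta_cost = inc$delta_cost, delta_effect = inc$delta_effect)
  }
  at_low <- eval_at(low); at_high <- eval_at(high)
  data.frame(parameter = param_name, low = low, high = high,
             nmb_low = at_low[["nmb"]], nmb_high = at_high[["nmb"]],
             spread = abs(at_high[["nmb"]] - at_low[["nmb"]]),
             icer_low = at_low[["icer"]], icer_high = at_high[["icer"]],
             delta_effect_low = at_low[["delta_effect"]],
             delta_effect_high = at_high[["delta_effect"]],
             stringsAsFactors = FALSE)
}

#' Tornado analysis over all sampled parameters
#'
#' Runs [one_way()] for every parameter with a non-fixed distribution
#' (uniform parameters at their endpoints, normal and lognormal parameters
#' at their central 95% quantiles) and for the structural discount rate
#' swept over its scenario set, and ranks entries by descending spread of
#' incremental net monetary benefit at the threshold.
#'
#' @param params a `parameter_set`.
#' @param settings an [econ_settings()].
#' @param lt a `life_table`.
#' @param discount_rates structural sweep for the discount rate entry
#'   (default `c(0, 0.03, 0.05, 0.07, 0.12)`; `NULL` to omit).
#' @return data.frame of tornado entries sorted by descending `spread`.
#' @export
tornado <- function(params, settings = econ_settings(), lt,
                    discount_rates = c(0, 0.03, 0.05, 0.07, 0.12)) {
  entries <- list()
  for (blk in c("usual", "programme", "common")) {
    for (nm in names(params[[blk]])) {
      if (blk == "programme" && nm == "hr_scenario") next
      spec <- params[[blk]][[nm]]
      if (spec$kind == "fixed") next
      b <- dist_bounds(spec)
      if (nm %in% .probability_params) b <- pmin(pmax(b, 0), 1)
      if (nm == "hr") b <- pmin(pmax(b, 1e-6), 1.5)
      entries[[paste0(blk, ".", nm)]] <-
        one_way(params, paste0(blk, ".", nm), b[1], b[2], settings, lt)
    }
  }
  if (!is.null(discount_rates) && length(discount_rates)) {
    wtp <- settings$wtp_threshold
    nmb_at <- vapply(discount_rates, function(r) {
      s <- settings; s$discount_rate <- r
      inc <- deterministic_increment(params, s, lt)
      wtp * inc$delta_effect - inc$delta_cost
    }, numeric(1))
    entries[["structural.discount_rate"]] <- data.frame(
      parameter = "structural.discount_rate",
      low = min(discount_rates), high = max(discount_rates),
      nmb_low = nmb_at[which.min(discount_rates)],
      nmb_high = nmb_at[which.max(discount_rates)],
      spread = max(nmb_at) - min(nmb_at),
      icer_low = NA_real_, icer_high = NA_real_,
      delta_effect_low = NA_real_, delta_effect_high = NA_real_,
      stringsAsFactors = FALSE)
  }
  if (!length(entries))
    return(one_way(params, "common.visit_cost", 0, 0, settings, lt)[0, ])
  out <- do.call(rbind, entries)
  rownames(out) <- NULL
  out[order(-out$spread), , drop = FALSE]
}

#' Discount-rate scenario sweep
#'
#' Re-evaluates the deterministic base case and (optionally) the
#' probabilistic analysis at each structural discount rate. All rates share
#' the same parameter draws (common random numbers), so differences between
#' rates are purely structural.
#'
#' @param params a `parameter_set`.
#' @param rates discount rates, each in `[0, 0.2]`.
#' @param settings an [econ_settings()].
#' @param lt a `life_table`.
#' @param psa_n PSA iterations per rate (0 skips the probabilistic part).
#' @param seed RNG seed for the shared draws.
#' @return list with `deterministic` (data.frame: rate, increments, ICER),
#'   `psa` (data.frame: rate, dominance/cost-effective/above-threshold
#'   fractions) or `NULL`, and `psa_result` (the underlying multi-rate
#'   `psa_result`) or `NULL`.
#' @export
discount_scenarios <- function(params, rates = c(0, 0.03, 0.05, 0.07, 0.12),
                               settings = econ_settings(), lt,
                               psa_n = 0L, seed = 1L) {
  if (any(rates < 0 | rates > 0.2))
    stop("rates must lie in [0, 0.2]", call. = FALSE)
  det <- do.call(rbind, lapply(rates, function(r) {
    s <- settings; s$discount_rate <- r
    inc <- deterministic_increment(params, s, lt)
    ic <- icer(inc$delta_cost, inc$delta_effect)
    data.frame(rate = r, delta_cost = inc$delta_cost,
               delta_effect = inc$delta_effect,
               icer = if (ic$status == "ratio") ic$icer else NA_real_,
               status = ic$status, stringsAsFactors = FALSE)
  }))
  psa_df <- NULL; psa_res <- NULL
  if (psa_n > 0) {
    psa_res <- run_psa(params, settings, lt, n = psa_n, seed = seed,
                       rates = rates)
    psa_df <- do.call(rbind, lapply(rates, function(r) {
      sm <- summarize_psa(psa_res, rate = r)
      data.frame(rate = r, frac_dominant = sm$frac_dominant,
                 frac_cost_effective = sm$frac_cost_effective,
                 frac_above_threshold = sm$frac_above_threshold,
                 frac_dominated = sm$frac_dominated,
                 p_cost_effective_total = sm$frac_dominant +
                   sm$frac_cost_effective)
    }))
  }
  list(deterministic = det, psa = psa_df, psa_result = psa_res)
}

#' Population-level life-years gained
#'
#' Scales the per-patient incremental effectiveness to the covered
#' hypertensive population.
#'
#' @param delta_effect_per_patient incremental LYG per patient.
#' @param population_size patients covered.
#' @return life-years.
#' @examples
#' population_impact(0.18, 30000)  # 5400
#' @export
population_impact <- function(delta_effect_per_patient, population_size) {
  if (any(population_size < 0))
    stop("population_size must be >= 0", call. = FALSE)
  delta_effect_per_patient * population_size
}
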