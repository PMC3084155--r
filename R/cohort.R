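#' Discount a value to present terms
#'
#' Cycle 0 is undiscounted (standard decision-tree convention): the factor is
#' `(1 + rate)^-t` for a reward accrued in cycle `t`.
#'
#' @param value numeric.
#' @param rate annual discount rate, >= 0.
#' @param t cycle index (0, 1, ...).
#' @return discounted value.
#' @export
discount <- function(value, rate, t) {
  if (any(rate < 0)) stop("rate must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  value / (1 + rate)^t
}

#' Annual event probability under a treatment strategy
#'
#' The strategy's hazard ratio multiplies the reference population's annual
#' event probability directly on the probability scale, capped at 1. At the
#' magnitudes involved (annual risks below 0.25) the difference from a
#' rate-scale transformation is negligible.
#'
#' @param p_ref reference annual probability of a cardiovascular event.
#' @param hr strategy hazard ratio, > 0.
#' @return probability.
#' @examples
#' event_probability(0.0255, 0.6150)  # 0.0156825
#' @export
event_probability <- function(p_ref, hr) {
  if (any(p_ref < 0 | p_ref > 1)) stop("p_ref must be in [0, 1]", call. = FALSE)
  if (any(hr <= 0)) stop("hr must be > 0", call. = FALSE)
  pmin(1, p_ref * hr)
}

#' Outcome distribution of an acute cardiovascular event
#'
#' Resolves the event sub-tree. A fraction `p_sudden_death` of events is
#' immediately fatal with no possibility of care (counted as unassisted
#' deaths). Of the remaining events, a fraction `p_unrecognized` never
#' reaches hospital attention (asymptomatic, atypical or unattended
#' presentations) and faces the unassisted case fatality; the rest are
#' hospitalised and face the (lower) assisted case fatality. Case fatality
#' depends on the age band.
#'
#' @param age_band `"65-74"` or `"75+"`.
#' @param aem named list with `p_sudden_death`, `p_unrecognized`,
#'   `cfr_assisted_65_74`, `cfr_assisted_75`, `cfr_unassisted_65_74`,
#'   `cfr_unassisted_75` (e.g. the `common` base values of a parameter set).
#' @return named numeric summing to 1: `assisted_survive`, `assisted_die`,
#'   `unassisted_survive`, `unassisted_die`.
#' @examples
#' aem <- lapply(base_case()$common, function(s) s$base)
#' acute_event_outcome("65-74", aem)
#' @export
acute_event_outcome <- function(age_band = c("65-74", "75+"), aem) {
  age_band <- match.arg(age_band)
  sfx <- if (age_band == "65-74") "65_74" else "75"
  ps <- aem$p_sudden_death
  pu <- aem$p_unrecognized
  cfr_yes <- aem[[paste0("cfr_assisted_", sfx)]]
  cfr_no <- aem[[paste0("cfr_unassisted_", sfx)]]
  for (p in c(ps, pu, cfr_yes, cfr_no))
    if (p < 0 || p > 1) stop("acute-event probabilities must be in [0, 1]",
                             call. = FALSE)
  if (cfr_no < cfr_yes)
    stop("unassisted case fatality must be >= assisted", call. = FALSE)
  c(assisted_survive   = (1 - ps) * (1 - pu) * (1 - cfr_yes),
    assisted_die       = (1 - ps) * (1 - pu) * cfr_yes,
    unassisted_survive = (1 - ps) * pu * (1 - cfr_no),
    unassisted_die     = ps + (1 - ps) * pu * cfr_no)
}

# Flatten a parameter set + settings + life table into the numeric inputs the
# cycle loop needs. `overrides` replaces base values (used by the PSA and the
# one-way sensitivity analysis with sampled/bounded draws).
compile_model_inputs <- function(params, strategy, settings, lt,
                                 overrides = NULL) {
  bases <- c(
    stats::setNames(lapply(params[[strategy]], function(s) s$base),
                    paste0(strategy, ".", names(params[[strategy]]))),
    stats::setNames(lapply(params$common, function(s) s$base),
                    paste0("common.", names(params$common))))
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), c(names(bases)))
    # overrides addressed to the other strategy are silently irrelevant here
    unknown <- unknown[!grepl("^(usual|programme)\\.", unknown)]
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    keep <- intersect(names(overrides), names(bases))
    bases[keep] <- overrides[keep]
  }
  g <- function(nm) bases[[paste0("common.", nm)]]
  s <- function(nm) bases[[paste0(strategy, ".", nm)]]

  start_age <- settings$start_age %||% g("start_age")
  p_start_int <- settings$p_start_intermediate %||% g("p_start_intermediate")
  start_age <- as.integer(floor(start_age))
  if (start_age < 65 || start_age >= settings$max_age)
    stop("start_age must satisfy 65 <= start_age < max_age", call. = FALSE)

  comp <- list(drug_cost_year = s("drug_cost_year"),
               test_cost_year = s("test_cost_year"),
               n_visits_year = s("n_visits_year"),
               programme_fee_year = s("programme_fee_year"),
               drug_coverage = g("drug_coverage"),
               visit_cost = g("visit_cost"),
               overhead_per_visit = g("overhead_per_visit"),
               ambulance_cost_year = g("ambulance_cost_year"),
               first_year_test_cost = g("first_year_test_cost"))

  hr <- if (strategy == "programme" && isTRUE(settings$scenario_hr))
    bases[["programme.hr_scenario"]] else s("hr")

  aem <- list(p_sudden_death = g("p_sudden_death"),
              p_unrecognized = g("p_unrecognized"),
              cfr_assisted_65_74 = g("cfr_assisted_65_74"),
              cfr_assisted_75 = g("cfr_assisted_75"),
              cfr_unassisted_65_74 = g("cfr_unassisted_65_74"),
              cfr_unassisted_75 = g("cfr_unassisted_75"))
  out_young <- acute_event_outcome("65-74", aem)
  out_old <- acute_event_outcome("75+", aem)

  ages <- start_age:(settings$max_age - 1L)
  list(
    start_age = start_age,
    max_age = settings$max_age,
    p_start_intermediate = p_start_int,
    treat_cost = annual_treatment_cost(comp, first_cycle = FALSE),
    first_year_extra = comp$first_year_test_cost,
    event_cost_assisted = g("event_hospital_cost"),
    frac_assisted = (1 - aem$p_sudden_death) * (1 - aem$p_unrecognized),
    # p_ev[band, stratum]: band 1 = 65-74, 2 = 75+; stratum 1 = intermediate
    p_ev = matrix(event_probability(
      c(g("p_ref_intermediate_65_74"), g("p_ref_intermediate_75"),
        g("p_ref_high_65_74"), g("p_ref_high_75")), hr), nrow = 2),
    p_die_event = c(out_young[["assisted_die"]] + out_young[["unassisted_die"]],
                    out_old[["assisted_die"]] + out_old[["unassisted_die"]]),
    outcome = cbind(out_young, out_old),
    qx = q_noncv(lt, ages),
    ages = ages,
    half_cycle = isTRUE(settings$half_cycle))
}

# Deterministic cycle loop. `rates` may be a vector: discounted totals are
# accumulated for each rate in one pass. Returns totals and (optionally) the
# per-cycle trace.
cohort_engine <- function(mi, rates, trace = FALSE) {
  n_cycles <- length(mi$ages)
  occ <- c(intermediate = mi$p_start_intermediate,
           high = 1 - mi$p_start_intermediate,
           dead_cv = 0, dead_other = 0)
  nr <- length(rates)
  disc_cost <- numeric(nr); disc_lyg <- numeric(nr)
  df <- 1 + rates
  tr <- if (trace) vector("list", n_cycles)
  events_total <- 0
  for (t in seq_len(n_cycles) - 1L) {
    age <- mi$ages[t + 1L]
    band <- if (age < 75) 1L else 2L
    pe_i <- mi$p_ev[band, 1L]; pe_h <- mi$p_ev[band, 2L]
    q <- mi$qx[t + 1L]
    int <- occ[[1L]]; high <- occ[[2L]]
    alive <- int + high
    if (alive < 1e-9) break
    ev <- int * pe_i + high * pe_h
    die_ev <- ev * mi$p_die_event[band]
    ev_surv <- ev - die_ev
    die_other <- (int * (1 - pe_i) + high * (1 - pe_h)) * q
    new_int <- int * (1 - pe_i) * (1 - q)
    new_high <- high * (1 - pe_h) * (1 - q) + ev_surv
    cost <- alive * mi$treat_cost +
      (if (t == 0L) alive * mi$first_year_extra else 0) +
      ev * mi$frac_assisted * mi$event_cost_assisted
    survivors <- new_int + new_high
    lyg <- if (mi$half_cycle) survivors + 0.5 * (alive - survivors)
           else survivors
    w <- df^(-t)
    disc_cost <- disc_cost + cost * w
    disc_lyg <- disc_lyg + lyg * w
    events_total <- events_total + ev
    if (trace) tr[[t + 1L]] <- c(cycle = t, age = age,
      intermediate = new_int, high = new_high,
      dead_cv = occ[[3L]] + die_ev, dead_other = occ[[4L]] + die_other,
      events = ev, cv_deaths = die_ev, other_deaths = die_other,
      cost = cost, lyg = lyg)
    occ <- c(new_int, new_high, occ[[3L]] + die_ev, occ[[4L]] + die_other)
  }
  list(disc_cost = disc_cost, disc_lyg = disc_lyg, events = events_total,
       occupancy = occ,
       trace = if (trace) as.data.frame(do.call(rbind, tr)))
}

#' One annual cycle of the Markov cohort model
#'
#' Advances a cohort state by one cycle: each live stratum faces its
#' strategy-specific event probability; events are resolved through the
#' acute sub-tree ([acute_event_outcome()]); patients without an event die
#' of non-cardiovascular causes with the life-table probability at their
#' age; event survivors are promoted to (or stay in) the high-risk stratum.
#' Treatment cost is charged to everyone alive at cycle start and hospital
#' cost to assisted events (fatal or not); one undiscounted life-year is
#' credited per end-of-cycle survivor.
#'
#' @param state list with `occupancy` (named numeric over `intermediate`,
#'   `high`, `dead_cv`, `dead_other`, summing to 1) and `age`.
#' @param params a `parameter_set`.
#' @param strategy `"usual"` or `"programme"`.
#' @param settings an [econ_settings()].
#' @param lt a `life_table`.
#' @param first_cycle charge the entry diagnostic work-up?
#' @return list with `state` (advanced one year), `cycle_cost`, `cycle_lyg`,
#'   `events` (expected events this cycle).
#' @export
cycle_transition <- function(state, params, strategy, settings, lt,
                             first_cycle = FALSE) {
  occ <- state$occupancy
  stopifnot(abs(sum(occ) - 1) < 1e-9, all(occ >= 0))
  if (state$age >= settings$max_age)
    stop("cohort has reached the model horizon", call. = FALSE)
  settings$start_age <- state$age
  mi <- compile_model_inputs(params, strategy, settings, lt)
  mi$p_start_intermediate <- NA  # occupancy supplied, not rebuilt
  if (!first_cycle) mi$first_year_extra <- 0
  age <- state$age
  band <- if (age < 75) 1L else 2L
  pe <- mi$p_ev[band, ]
  q <- q_noncv(lt, age)
  ev <- occ[["intermediate"]] * pe[1L] + occ[["high"]] * pe[2L]
  die_ev <- ev * mi$p_die_event[band]
  new_int <- occ[["intermediate"]] * (1 - pe[1L]) * (1 - q)
  new_high <- occ[["high"]] * (1 - pe[2L]) * (1 - q) + (ev - die_ev)
  die_other <- (occ[["intermediate"]] * (1 - pe[1L]) +
                occ[["high"]] * (1 - pe[2L])) * q
  alive <- occ[["intermediate"]] + occ[["high"]]
  cost <- alive * mi$treat_cost + alive * mi$first_year_extra +
    ev * mi$frac_assisted * mi$event_cost_assisted
  survivors <- new_int + new_high
  lyg <- if (mi$half_cycle) survivors + 0.5 * (alive - survivors) else survivors
  list(state = list(occupancy = c(intermediate = unname(new_int),
                                  high = unname(new_high),
                                  dead_cv = unname(occ[["dead_cv"]] + die_ev),
                                  dead_other = unname(occ[["dead_other"]] +
                                                      die_other)),
                    age = age + 1L),
       cycle_cost = unname(cost), cycle_lyg = unname(lyg),
       events = unname(ev))
}

#' Run the Markov cohort model for one strategy
#'
#' Propagates the cohort from its starting age to the model horizon in
#' annual cycles, accumulating discounted per-patient cost and life-years
#' gained. The cohort enters with `p_start_intermediate` of patients at
#' intermediate risk and the rest at high risk; the first cycle additionally
#' charges the entry diagnostic work-up.
#'
#' @param params a `parameter_set`.
#' @param strategy `"usual"` or `"programme"`.
#' @param settings an [econ_settings()].
#' @param lt a `life_table`.
#' @param trace keep the per-cycle trace? (default `TRUE`)
#' @return an object of class `cohort_result`: list with `disc_cost`,
#'   `disc_lyg` (per patient), `events` (expected lifetime events per
#'   patient), `strategy`, `discount_rate`, and `trace` (data.frame with one
#'   row per cycle: occupancy by state, events, deaths, cost, LYG).
#' @examples
#' lt <- synthetic_life_table()
#' res <- run_cohort(base_case(), "programme", econ_settings(), lt)
#' res$disc_lyg
#' @export
run_cohort <- function(params, strategy = c("usual", "programme"),
                       settings = econ_settings(), lt, trace = TRUE) {
  strategy <- match.arg(strategy)
  validate_parameter_set(params)
  validate_life_table(lt)
  mi <- compile_model_inputs(params, strategy, settings, lt)
  eng <- cohort_engine(mi, settings$discount_rate, trace = trace)
  structure(list(disc_cost = eng$disc_cost, disc_lyg = eng$disc_lyg,
                 events = eng$events, occupancy = eng$occupancy,
                 strategy = strategy,
                 discount_rate = settings$discount_rate,
                 start_age = mi$start_age, trace = eng$trace),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf(
    "<cohort_result> %s: cost %.1f Int$/patient | %.3f LYG/patient (r = %g)\n",
    x$strategy, x$disc_cost, x$disc_lyg, x$discount_rate))
  invisible(x)
}

#' Individual-level microsimulation of the same decision tree
#'
#' Simulates independent patient trajectories through the identical annual
#' event/assistance/death structure and returns Monte-Carlo means and
#' standard errors of discounted cost and life-years. The cohort model is
#' the expectation of this process, so the two must agree within sampling
#' error; the microsimulation serves as a brute-force validation oracle for
#' [run_cohort()].
#'
#' @param params,strategy,settings,lt as in [run_cohort()].
#' @param n_individuals number of simulated patients.
#' @param seed RNG seed for reproducibility.
#' @return list with `disc_cost`, `disc_lyg` (means), `se_cost`, `se_lyg`,
#'   and `n`.
#' @export
run_microsim <- function(params, strategy = c("usual", "programme"),
                         settings = econ_settings(), lt,
                         n_individuals = 10000L, seed = 1L) {
  strategy <- match.arg(strategy)
  if (n_individuals < 1) stop("n_individuals must be >= 1", call. = FALSE)
  validate_parameter_set(params)
  validate_life_table(lt)
  mi <- compile_model_inputs(params, strategy, settings, lt)
  r <- settings$discount_rate
  set.seed(seed)
  n <- as.integer(n_individuals)
  # state per patient: 1 intermediate, 2 high, 0 dead
  state <- ifelse(stats::runif(n) < mi$p_start_intermediate, 1L, 2L)
  cost <- numeric(n); lyg <- numeric(n)
  for (t in seq_along(mi$ages) - 1L) {
    alive <- state > 0L
    if (!any(alive)) break
    age <- mi$ages[t + 1L]
    band <- if (age < 75) 1L else 2L
    w <- (1 + r)^(-t)
    idx <- which(alive)
    cost[idx] <- cost[idx] +
      (mi$treat_cost + if (t == 0L) mi$first_year_extra else 0) * w
    pe <- mi$p_ev[band, state[idx]]
    has_event <- stats::runif(length(idx)) < pe
    ev_idx <- idx[has_event]
    if (length(ev_idx)) {
      # joint resolution of the sub-tree: outcome rows are
      # assisted_survive, assisted_die, unassisted_survive, unassisted_die
      cum <- cumsum(mi$outcome[, band])
      u <- stats::runif(length(ev_idx))
      branch <- findInterval(u, cum) + 1L
      assisted <- branch <= 2L
      cost[ev_idx[assisted]] <- cost[ev_idx[assisted]] +
        mi$event_cost_assisted * w
      dies <- branch %in% c(2L, 4L)
      state[ev_idx[dies]] <- 0L
      state[ev_idx[!dies]] <- 2L   # survivors promoted to high risk
    }
    ne_idx <- idx[!has_event]
    if (length(ne_idx)) {
      dies_bg <- stats::runif(length(ne_idx)) < mi$qx[t + 1L]
      state[ne_idx[dies_bg]] <- 0L
    }
    survivors <- state > 0L
    lyg[survivors] <- lyg[survivors] + w
    if (mi$half_cycle) {
      died_now <- alive & !survivors
      lyg[died_now] <- lyg[died_now] + 0.5 * w
    }
  }
  list(disc_cost = mean(cost), disc_lyg = mean(lyg),
       se_cost = stats::sd(cost) / sqrt(n), se_lyg = stats::sd(lyg) / sqrt(n),
       n = n)
}
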