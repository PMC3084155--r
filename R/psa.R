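#' Draw one parameter set for the probabilistic sensitivity analysis
#'
#' Redraws every parameter with a non-fixed distribution. Common variables
#' (shared costs, reference risks, acute-event pathway, cohort entry
#' conditions) are drawn once and shared by both strategies; the
#' strategy-specific blocks are drawn independently. Normal draws are
#' truncated by resampling to the valid support (hazard ratios to
#' `(0, 1.5]`, probabilities to `[0, 1]`); the sampled starting age is
#' floored to whole years by the engine. The discount rate is structural and
#' never sampled. The programme's `hr_scenario` law is an alternative draw
#' for the scenario mode, not an additional one, and is left fixed here.
#'
#' @param base a `parameter_set` providing the distributions.
#' @return a `parameter_set` in which every sampled parameter's `base` is
#'   replaced by its draw (distributions are retained).
#' @export
sample_parameter_set <- function(base) {
  drawn <- base
  for (blk in c("usual", "programme", "common")) {
    for (nm in names(base[[blk]])) {
      spec <- base[[blk]][[nm]]
      if (spec$kind == "fixed") next
      support <- if (nm == "hr") c(0, 1.5)
                 else if (nm %in% .probability_params) c(0, 1)
      drawn[[blk]][[nm]]$base <- draw_dist(spec, 1L, support = support)
    }
  }
  drawn
}

#' Run the probabilistic sensitivity analysis
#'
#' Repeatedly samples a parameter set ([sample_parameter_set()]) and
#' evaluates the paired cohort models (usual care and programme) under the
#' shared common draws, yielding per-iteration incremental cost and
#' incremental effectiveness. Several discount rates can be evaluated in one
#' pass over the same draws (common random numbers), which is how the
#' discount-rate scenario analyses keep their parameter uncertainty
#' identical across rates.
#'
#' @param params a `parameter_set`.
#' @param settings an [econ_settings()]; `settings$start_age` and
#'   `settings$p_start_intermediate` are left `NULL` so that each iteration
#'   uses its own draw of the entry conditions.
#' @param lt a `life_table`.
#' @param n iterations (default `settings$psa_iterations`).
#' @param seed RNG seed; the full run is reproducible given the seed.
#' @param rates discount rates to evaluate (default the settings rate).
#' @return an object of class `psa_result`: list with `iterations` (a
#'   data.frame with columns `rate`, `draw`, `cost_usual`, `cost_programme`,
#'   `effect_usual`, `effect_programme`, `delta_cost`, `delta_effect`),
#'   `n`, `seed`, `rates`, `wtp_threshold`.
#' @export
run_psa <- function(params, settings = econ_settings(), lt,
                    n = settings$psa_iterations, seed = 1L,
                    rates = settings$discount_rate) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  validate_parameter_set(params)
  validate_life_table(lt)
  set.seed(seed)
  nr <- length(rates)
  cu <- ce <- eu <- ee <- matrix(NA_real_, nrow = n, ncol = nr)
  for (i in seq_len(n)) {
    drawn <- sample_parameter_set(params)
    mi_u <- compile_model_inputs(drawn, "usual", settings, lt)
    mi_p <- compile_model_inputs(drawn, "programme", settings, lt)
    res_u <- cohort_engine(mi_u, rates)
    res_p <- cohort_engine(mi_p, rates)
    cu[i, ] <- res_u$disc_cost; eu[i, ] <- res_u$disc_lyg
    ce[i, ] <- res_p$disc_cost; ee[i, ] <- res_p$disc_lyg
  }
  iterations <- data.frame(
    rate = rep(rates, each = n),
    draw = rep(seq_len(n), times = nr),
    cost_usual = as.vector(cu), cost_programme = as.vector(ce),
    effect_usual = as.vector(eu), effect_programme = as.vector(ee))
  iterations$delta_cost <- iterations$cost_programme - iterations$cost_usual
  iterations$delta_effect <- iterations$effect_programme -
    iterations$effect_usual
  structure(list(iterations = iterations, n = n, seed = seed, rates = rates,
                 wtp_threshold = settings$wtp_threshold),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  cat("<psa_result>", x$n, "iterations | seed", x$seed,
      "| discount rate(s):", paste(x$rates, collapse = ", "), "\n")
  invisible(x)
}

# iterations of a psa_result at one discount rate
psa_at_rate <- function(psa, rate = psa$rates[1]) {
  it <- psa$iterations[psa$iterations$rate == rate, , drop = FALSE]
  if (!nrow(it)) stop("no PSA iterations at rate ", rate, call. = FALSE)
  it
}

#' Incremental cost-effectiveness ratio with dominance handling
#'
#' @param delta_cost incremental cost (programme minus comparator).
#' @param delta_effect incremental effectiveness in LYG.
#' @return a list with `status` (`"ratio"`, `"dominant"`, `"dominated"` or
#'   `"undefined"`) and `icer` (the ratio when status is `"ratio"`, `NA`
#'   otherwise). Dominant: more effective and less costly. Dominated: less
#'   effective and more costly. Undefined: zero incremental effect.
#' @examples
#' icer(195.3, 0.18)  # ratio ~1085 (rounded increments of a published table)
#' @export
icer <- function(delta_cost, delta_effect) {
  if (delta_effect == 0) return(list(status = "undefined", icer = NA_real_))
  if (delta_cost < 0 && delta_effect > 0)
    return(list(status = "dominant", icer = NA_real_))
  if (delta_cost > 0 && delta_effect < 0)
    return(list(status = "dominated", icer = NA_real_))
  list(status = "ratio", icer = delta_cost / delta_effect)
}

#' Classify one PSA iteration on the cost-effectiveness plane
#'
#' @param delta_cost,delta_effect incremental cost and effect.
#' @param wtp willingness-to-pay threshold (Int$/LYG).
#' @return one of `"dominant"` (cheaper and more effective), `"dominated"`
#'   (costlier and less effective), `"cost_effective"` (positive net
#'   monetary benefit `wtp * dE - dC` without dominance) or
#'   `"above_threshold"`.
#' @export
classify_iteration <- function(delta_cost, delta_effect, wtp) {
  if (wtp < 0) stop("wtp must be >= 0", call. = FALSE)
  if (delta_cost < 0 && delta_effect > 0) return("dominant")
  if (delta_cost > 0 && delta_effect < 0) return("dominated")
  if (wtp * delta_effect - delta_cost > 0) "cost_effective" else "above_threshold"
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that each strategy is
#' the optimal one, i.e. the fraction of PSA iterations in which it has the
#' higher net monetary benefit (ties split evenly). The two probabilities
#' sum to 1 at every threshold.
#'
#' @param psa a `psa_result` (or its `iterations` data.frame).
#' @param wtp_grid ordered WTP values.
#' @param rate discount rate to use when `psa` holds several.
#' @return data.frame with columns `wtp`, `p_usual`, `p_programme`.
#' @export
ceac <- function(psa, wtp_grid, rate = NULL) {
  it <- if (inherits(psa, "psa_result"))
    psa_at_rate(psa, rate %||% psa$rates[1]) else psa
  if (!nrow(it) || !length(wtp_grid))
    stop("need non-empty iterations and wtp grid", call. = FALSE)
  p_prog <- vapply(wtp_grid, function(w) {
    nmb_inc <- w * it$delta_effect - it$delta_cost
    mean((nmb_inc > 0) + 0.5 * (nmb_inc == 0))
  }, numeric(1))
  data.frame(wtp = wtp_grid, p_usual = 1 - p_prog, p_programme = p_prog)
}

#' Summarise a probabilistic sensitivity analysis
#'
#' Means and 95% percentile intervals of per-strategy discounted cost and
#' effectiveness and of the increments, plus the fractions of iterations in
#' which the programme is dominant, cost-effective below the threshold
#' (positive net monetary benefit without dominance), above the threshold,
#' or dominated. The four fractions sum to 1.
#'
#' @param psa a `psa_result`.
#' @param wtp willingness-to-pay threshold (default the one in the result).
#' @param rate discount rate to summarise when several were evaluated.
#' @return an object of class `psa_summary`.
#' @export
summarize_psa <- function(psa, wtp = psa$wtp_threshold, rate = NULL) {
  it <- psa_at_rate(psa, rate %||% psa$rates[1])
  if (nrow(it) < 2) stop("need at least 2 iterations", call. = FALSE)
  qs <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  stat <- function(x) c(mean = mean(x), lo = qs(x)[1], hi = qs(x)[2])
  cls <- mapply(classify_iteration, it$delta_cost, it$delta_effect,
                MoreArgs = list(wtp = wtp))
  frac <- function(k) mean(cls == k)
  structure(list(
    n = nrow(it), wtp = wtp,
    rate = it$rate[1],
    cost_usual = stat(it$cost_usual),
    cost_programme = stat(it$cost_programme),
    effect_usual = stat(it$effect_usual),
    effect_programme = stat(it$effect_programme),
    delta_cost = stat(it$delta_cost),
    delta_effect = stat(it$delta_effect),
    icer_of_means = mean(it$delta_cost) / mean(it$delta_effect),
    p_negative_effect = mean(it$delta_effect < 0),
    frac_dominant = frac("dominant"),
    frac_cost_effective = frac("cost_effective"),
    frac_above_threshold = frac("above_threshold"),
    frac_dominated = frac("dominated")), class = "psa_summary")
}

#' @export
print.psa_summary <- function(x, ...) {
  f <- function(v) sprintf("%.2f (%.2f - %.2f)", v[1], v[2], v[3])
  cat("<psa_summary>", x$n, "iterations at discount rate", x$rate, "\n")
  cat("  cost usual     ", f(x$cost_usual), "\n")
  cat("  cost programme ", f(x$cost_programme), "\n")
  cat("  LYG usual      ", f(x$effect_usual), "\n")
  cat("  LYG programme  ", f(x$effect_programme), "\n")
  cat("  delta cost     ", f(x$delta_cost), "\n")
  cat("  delta LYG      ", f(x$delta_effect), "\n")
  cat(sprintf("  dominant %.1f%% | cost-effective %.1f%% | above threshold %.1f%% | dominated %.1f%% (WTP %g)\n",
              100 * x$frac_dominant, 100 * x$frac_cost_effective,
              100 * x$frac_above_threshold, 100 * x$frac_dominated, x$wtp))
  invisible(x)
}
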