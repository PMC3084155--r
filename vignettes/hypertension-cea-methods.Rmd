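---
title: "Methods: a Markov cost-effectiveness model of comprehensive hypertension management in the elderly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cost-effectiveness model of comprehensive hypertension management in the elderly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(htncea)
```

## The decision problem

`htncea` compares two strategies for treating hypertensive patients aged 65
and over from a third-party payer's perspective: *usual care* (primary-care
visits, drugs, tests) and a *comprehensive hypertension programme* (usual
care plus telephone monitoring by medical students, lifestyle support,
education and an electronic record, billed as an annual per-patient fee).
Effectiveness is measured in life-years gained (LYG), not QALYs — the model
deliberately carries no health-state valuations — and costs in 2010
International Dollars. The decision output is the incremental
cost-effectiveness ratio (ICER, \(\Delta C / \Delta E\)), dominance
classification and cost-effectiveness acceptability curves (CEAC) against a
willingness-to-pay (WTP) threshold of 45,000 Int\$/LYG (three times GDP per
capita).

## Model structure

Each strategy is evaluated with the same Markov cohort model in annual
cycles over a lifetime horizon. Live states are two cardiovascular risk
strata — *intermediate* (hypertension and age as only risk factors) and
*high* (prior events, diabetes or other factors) — plus two absorbing death
states (cardiovascular, other). In each cycle a live patient either

1. has an acute cardiovascular event (composite of AMI, unstable angina,
   stroke, TIA, heart failure, peripheral artery disease), with annual
   probability `p_ref(age band, stratum) × HR(strategy)` capped at 1;
2. dies of non-cardiovascular causes with the life-table probability
   `q_noncv(age)`; or
3. continues unchanged.

The two branches compete as a tree, event first: background mortality
applies only to the event-free branch, mirroring the three mutually
exclusive annual paths of the model diagram. Event survivors start the next
cycle in the high-risk stratum regardless of origin; age bands (65–74, 75+)
are assigned by age at cycle start.

An acute event is resolved by a sub-tree: with probability `p_sudden_death`
(0.10) it is immediately fatal with no possibility of care; otherwise it
goes unrecognized — asymptomatic, atypical or unattended — with probability
`p_unrecognized` (0.367). Assisted events incur the hospital episode cost
(10,041.65 Int\$, fatal or not) and face the assisted case fatality (0.15 /
0.30 by age band); unassisted events cost the payer nothing and face the
higher unassisted fatality (0.30 / 0.60). Sudden deaths are counted as
unassisted deaths, and the unrecognized fraction applies to non-sudden
events only; the composition rule is a modelling choice, as only the two
marginal probabilities are available.

Rewards per cycle: every patient alive at cycle start is charged the annual
treatment cost (covered drugs, tests, programme fee, visits with per-visit
overhead, ambulance; plus a one-off diagnostic work-up in the first cycle),
on the grounds that care is consumed before death; one life-year is
credited to each patient alive at cycle *end*, so within-cycle decedents
earn nothing. No half-cycle correction is applied by default — a
`half_cycle` switch exists for sensitivity. Cycle-0 rewards are
undiscounted; cycle *t* rewards are discounted by \((1+r)^{-t}\) with
\(r = 5\%\) for both costs and effects in the base case.

The cohort enters at age 65 with 70% at intermediate risk, and is followed
to age 100. Extending the horizon to 110 changes discounted results by well
under 0.5% (tested), because the synthetic life table leaves essentially no
survivors past 100.

## Parameters

All parameters live in a `parameter_set` (see `base_case()`), each as a
`dist_spec` carrying a base-case value and a sampling law. Strategy blocks
hold the arm-specific costs and the hazard ratio on the reference event
risk (usual care Normal(0.6150, 0.0089); programme Normal(0.5124, 0.0131),
reflecting the larger blood-pressure reduction achieved by the programme);
the common block holds shared costs, reference risks, the acute-event
pathway and the cohort entry conditions. Lognormal laws are parameterised
by the mean and SD of the natural log — `exp(4.36 + 1.39²/2) ≈ 205.6`
against a printed base of 206.43 confirms that reading — and uniform laws
by their bounds, with bases at the midpoint. Three printed uniforms are
deliberately *not* midpoint-centred and are kept as printed: starting age
(65 in U(65, 80)), the intermediate-risk entry share (0.70 in U(0, 1)) and
the unrecognized-event risk (0.367 in U(0.25, 0.40)). The reference risk
table is also kept exactly as printed even though its high-risk 65–74 rate
(0.0325) is below the intermediate-risk 75+ rate (0.0400): the rates come
from an external risk equation and are inputs, not quantities to repair.

Parameter files are YAML with a `schema: 1` marker
(`save_parameters()`/`load_parameters()`, validating round trip); the
micro-costing ledgers are CSV.

## Micro-costing

`compute_ledger()` reproduces the programme's accounting: item cost = unit
cost × quantity; capital items are converted to equivalent annual costs
over 5 years at 5% with an **annuity-due** factor
\(AF = \frac{1-(1+r)^{-n}}{r}(1+r) = 4.546\) — the convention that
reproduces the published capital rows (an ordinary annuity gives 670.1
rather than 638.2 for the first item). Institution-level categories are
divided by the 30,000 covered patients; overhead, visit and consumption
rows are already per patient-year. Printed unit costs are rounded to 2
decimals, so recomputed figures agree with print to ~0.2%, not exactly.

Two cost readings coexist in the source material: the accounting ledger
(programme drugs 198.99, visits 7.40 + 0.74/yr) and the sensitivity-analysis
variable table (drugs 216.55 lognormal, visits 4.72 lognormal). The Markov
model consumes the variable table, whose rows carry the distributions the
PSA needs; the ledger is reproduced by the costing module only. This choice
has a visible consequence, discussed under Limitations.

Drug coverage (0.70) multiplies the drug cost only — it is a payer coverage
proportion, not a utilization factor for tests or visits. Overhead is
charged per visit, using each arm's sampled visit count.

## Background mortality

The model needs annual probabilities of death from causes *other than*
cardiovascular disease (cardiovascular deaths arise inside the event tree).
Cause-deleted national life tables for the study population are not
redistributable, so `synthetic_life_table()` generates one from a Gompertz
hazard \(h(x) = a e^{b(x-65)}\) with a constant cardiovascular fraction
removed: \(q_x = (1-e^{-h(x)})(1-f_{cv})\). Defaults \(a = 0.013\),
\(b = 0.095\), \(f_{cv} = 0.30\) give a remaining all-cause life expectancy
at 65 of about 18.5 years and ~30% of deaths cardiovascular, typical of an
urban middle-class elderly population; they were fixed once, from
demographic reasoning, and are deliberately *not* calibrated to reproduce
published absolute life-year outputs — that would be circular. The constant
cardiovascular fraction across ages trades realism (the CV share of deaths
actually declines in extreme old age) for transparency. A two-parameter
Gompertz law cannot reproduce the plateauing of observed oldest-old
mortality; at this horizon the effect on discounted outputs is negligible.
`load_life_table()` accepts an external `age,qx` CSV whenever a real
cause-deleted table is available, which is the recommended route for any
substantive application.

## Probabilistic sensitivity analysis

`run_psa()` redraws every non-fixed parameter per iteration: common
variables once per iteration and shared by both arms (so that, e.g., the
hospital episode cost cancels from \(\Delta C\) except through the event
count), strategy blocks independently. Normal draws are truncated by
resampling — hazard ratios to (0, 1.5], probabilities to [0, 1] — which at
the printed SDs essentially never triggers but keeps the sampler total.
The starting age draw is floored to whole years. The discount rate is
structural and never sampled; instead `run_psa()` accepts a vector of rates
and accumulates discounted totals for all of them in a single pass over the
same draws, which is also how the discount-rate scenario analysis achieves
common random numbers exactly. Each iteration evaluates the *cohort
expectation* per draw (not one simulated individual per draw, which would
add first-order Monte-Carlo noise to the scatter).

The default iteration count is 100,000; the analyses shipped in the
acceptance script and test suite use 10,000, at which binomial error on a
fraction near 0.5 is ±0.5 percentage points — far below the differences
that matter here. Iterations classify as dominant (\(\Delta C<0,
\Delta E>0\)), cost-effective (positive incremental net monetary benefit
\(\lambda\Delta E-\Delta C\) without dominance), above-threshold, or
dominated; the four fractions sum to 1. CEAC probabilities are NMB-argmax
frequencies with ties split evenly.

## One-way and tornado analysis

`one_way()` evaluates the deterministic model at a parameter's bounds
(uniform: endpoints; normal/lognormal: central 95% quantiles). Because the
base case sits near the dominance boundary, the ICER is numerically
unstable as \(\Delta C\) crosses zero, so entries are ranked by the spread
of incremental **net monetary benefit at the 45,000 threshold** — a single
comparable unit for every parameter — with per-bound ICERs attached where
the increments admit one. The discount rate enters the tornado as a
structural sweep over {0, 0.03, 0.05, 0.07, 0.12}; as in the original
analysis it carries by far the largest spread, because treatment costs are
paid from year one while survival benefits accrue late.

## Validation oracles

Three independent routes check the engine:

- **Microsimulation**: `run_microsim()` pushes individual patients through
  the identical tree; cohort expectations agree within 3 Monte-Carlo SE on
  five structurally different scenarios (tested).
- **Closed-form survival**: with all cardiovascular risk removed, the
  cohort's undiscounted LYG equals the life table's curtate life expectancy
  by direct summation to machine precision; with background mortality also
  removed, LYG equals the 35-year horizon exactly.
- **Structural properties**: occupancy conservation every cycle;
  monotonicity of discounted LYG in the discount rate, event risks, case
  fatalities and background mortality; strategy ordering under
  lower-hazard-ratio draws; CEAC monotone in WTP; bit-reproducibility under
  a fixed seed.

## Design choices that were genuinely open

- *Interface*: the package's users are analysts working in R, so the
  surface is functions plus this vignette and the acceptance script; no
  shell wrapper is shipped.
- *Hazard ratios on the probability scale*, capped at 1: consistent with
  the published derived-risk layout; at these magnitudes a rate-scale
  transform differs by < 0.1%.
- *Treatment cost charged to cycle-start occupancy*, including within-year
  decedents, matching how event costs attach to fatal assisted events.
- *Scenario hazard-ratio law* (Uniform 0.45–0.57) replaces the programme's
  normal law when `scenario_hr = TRUE`; it is never drawn *in addition to*
  it, which would double-sample one quantity.
- *Percentile intervals* (2.5/97.5) summarise PSA distributions; the
  published intervals state no method and skewed cost draws make normal
  approximations poor.

## Limitations, and what passing tests do not show

The synthetic life table emulates plausible old-age background mortality;
it is not the national cause-deleted table the original analysis used.
Absolute per-strategy costs and life-years therefore carry structural
uncertainty of a few percent, and the package's tests of absolute levels
use tolerances, not exact targets. Incremental quantities are more robust
but not immune.

More consequentially, the two published cost readings disagree on the
programme's visit intensity (4.72/yr in the PSA-variable table vs 8.14/yr
in the accounting ledger). With the PSA-table reading the programme's
annual treatment cost (274.7 Int\$) falls slightly *below* usual care's
(280.2 Int\$), and with fewer acute events the programme is **dominant** in
the deterministic base case (\(\Delta C \approx -354\) Int\$,
\(\Delta E \approx 0.20\) LYG) rather than carrying a small positive ICER
near 1,100 Int\$/LYG. The ~40 Int\$/yr visit-cost gap times ~12 discounted
years accounts almost exactly for the difference. The package follows the
PSA-variable table throughout and reports what it computes; analysts who
prefer the ledger reading can override `programme$n_visits_year` and rerun.
Probabilistic fractions shift accordingly: dominance ~57% rather than ~43%,
with the overall probability of cost-effectiveness at the 45,000 threshold
(~98%) and the above-threshold fraction (~2%) barely affected.

Finally, sampling the entry conditions (starting age U(65, 80),
intermediate share U(0, 1)) widens the per-strategy effect distributions
substantially; analyses that intend parameter uncertainty only, not
population heterogeneity, should fix both via `econ_settings()`.

## Worked example

```{r, eval = FALSE}
lt <- synthetic_life_table()
bc <- base_case_analysis(base_case(), econ_settings(), lt)
bc$delta_cost; bc$delta_effect; bc$icer

psa <- run_psa(base_case(), econ_settings(), lt, n = 10000, seed = 1,
               rates = c(0.05, 0.12))
summarize_psa(psa, rate = 0.05)
plot_ceac(ceac(psa, seq(0, 100000, 2500)))
```
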