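---
title: "Markov cohort cost-effectiveness modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Markov cohort cost-effectiveness modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The decision problem

`markovcea` evaluates competing treatment strategies with a discrete-time
Markov cohort model. A cohort of identical patients is distributed over a
small set of mutually exclusive health states; each model cycle, the cohort
fractions are redistributed by a strategy-specific transition probability
matrix. Per-cycle costs and effectiveness rewards attached to the states are
accrued, discounted, and summed into expected totals per strategy, and the
strategies are compared on the incremental cost-effectiveness ratio (ICER):

$$\mathrm{ICER} = \frac{\Delta C}{\Delta E}
  = \frac{C_{\text{intervention}} - C_{\text{comparator}}}
         {E_{\text{intervention}} - E_{\text{comparator}}}.$$

The bundled worked example, `mcrc_base_case()`, is the published base case of
a four-state model of first-line treatment for metastatic colorectal cancer
from the perspective of a Brazilian public teaching hospital: XELOX
(capecitabine + oxaliplatin) versus XELOX plus bevacizumab, with FOLFIRI as
second-line therapy in both arms, a supportive-care state, and death as the
single absorbing state. The whole cohort starts in first-line therapy and
only moves forward (first line → second line → supportive care → death, with
skips allowed); backward transitions are structural zeros. The horizon is 60
months as 20 three-month cycles, costs are in 2013 BRL, effectiveness is in
months of life gained, and the annual discount rate is 5%.

## Costing

State costs are built bottom-up by micro-costing: itemized amounts are
aggregated over a closed set of six categories (medications, pharmacy
preparation, nursing administration, laboratory tests, imaging tests,
hospitalization) by `aggregate_cycle_cost()`, which also reports category
shares in percent. Unknown categories are errors, not a pooled "other" —
silent pooling is how costing tables drift from their sources. Supportive
care is costed as hospitalization (3 days/month at 529.67 BRL/day over a
3-month cycle, `hospitalization_cycle_cost()`) plus laboratory tests.
`inflation_adjust()` provides the compound adjustment used to bring
retrospective drug costs to the reference year. Currency is kept as doubles
end to end; rounding to 2 decimals happens only in report columns, so
display rounding never contaminates downstream arithmetic. The 230 BRL
central venous catheter implanted for FOLFIRI can be charged as a one-time
cost on first entry into second-line therapy
(`mcrc_base_case(include_catheter = TRUE)`); the default leaves it off
because the published FOLFIRI cycle total is reproduced without it.

## Accrual and discounting conventions

Published cohort models frequently leave three choices unstated: *where*
within a cycle rewards accrue (start, end, or the half-cycle correction),
whether the first cycle is discounted, and how discrete cycles map onto
discount time. Rather than hard-coding one guess, every choice is an
explicit field of `convention_flags()`:

* `reward_source` — `"months_alive"` (3 months per cycle alive; standard
  life-month accounting) or `"state_os_per_cycle"` (the per-state
  effectiveness reward each cycle). The bundled model's published
  effectiveness totals (97.07 and 99.32 months over a 60-month horizon)
  exceed the horizon, so they cannot be months alive; they are reproduced by
  the per-state overall-survival rewards.
* `accrual_timing` / `cost_timing` — `cycle_start`, `cycle_end`, or
  `half_cycle` occupancy for the effect and cost streams respectively.
* `discount_first_cycle` — whether discount time starts at one cycle
  instead of zero.
* `discount_basis` — `"annual"` compounds the quoted rate over calendar
  years (`t = k \cdot \ell / 12` years for cycle `k` of length `\ell`
  months); `"per_cycle"` applies the quoted rate once per model cycle, the
  behaviour a model effectively has when its discount time index is the
  stage counter rather than elapsed years.

The discount point of each stream follows its accrual point: start-of-cycle
accrual is discounted at `k` cycles, half-cycle at `k + 1/2`, end-of-cycle
at `k + 1`. The engine defaults are start-of-cycle accrual with an
undiscounted first cycle on the annual basis — the common default of
decision-tree tools — with all alternatives reachable through the flags.

### Calibrating the convention against published totals

`calibrate_conventions()` evaluates the model in every cell of the 72-cell
convention grid and scores each by the maximum relative deviation from the
target per-strategy (cost, effectiveness) totals — a scale-free score across
cost and effectiveness units. Ties keep the deterministic enumeration order.
For the bundled model the search is decisive:

```{r calibrate}
fx <- mcrc_base_case()
cal <- calibrate_conventions(fx$model, fx$reference_results)
head(as.data.frame(cal), 3)
compare_strategies(fx$model, best_conventions(cal))
```

A single cell — per-state overall-survival rewards, half-cycle correction
for both streams, mid-cycle discounting with the 5% rate compounded per
3-month cycle — reproduces all four published totals within 0.5%, while the
runner-up sits above 5%. The published increments and ICER follow within 1%
from that one cell, so the calibration is treated as having identified the
generating convention rather than as a fit. No other cell comes close, and
no cell of the purely annual-basis subgrid is within 5%; the per-cycle
discount basis is what the published numbers imply.

Published tables also round: the published ICER (21,231.43) is not the
quotient of the published rounded increments (47,833.57 / 2.25 =
21,259.36). The pipeline therefore treats unrounded values as canonical and
rounds only for display.

## Sensitivity analysis

**One-way (tornado).** `tornado()` is a deterministic one-factor-at-a-time
analysis: each parameter is set to its lower and upper bound with the rest
at base, the ICER is recomputed, and parameters are ranked by the induced
ICER interval width. When a probability is moved, the remaining positive
entries of its row are rescaled proportionally so the row stays stochastic;
structural zeros never receive mass. ICER endpoints are reported signed with
dominance labels: in the bundled model, pushing the comparator's
supportive-care effectiveness to its upper bound makes the incremental
effectiveness negative — the intervention becomes dominated — which the
signed ratio shows as a sign flip.

**Probabilistic (PSA).** `run_psa()` draws joint parameter sets and fully
re-evaluates both strategies per draw. Cost parameters are gamma-distributed
with moments matched to the published mean ± SD ranges
(`gamma_from_mean_sd()`; `range_to_sd()` recovers the SD as the half-range,
which the cost rows' exact symmetry about their base values supports);
effectiveness and transition probabilities are uniform over their ranges,
with each sampled transition row renormalized draw-by-draw. Parameters are
sampled independently — no correlation structure is published — and the
discount rate is varied one-way only, not sampled. Draw classification on
the cost-effectiveness plane uses the half-open rule Q1 (`ΔE>0, ΔC>0`), Q2
(`ΔE≤0, ΔC>0`), Q3 (`ΔE≤0, ΔC≤0`), Q4 (`ΔE>0, ΔC≤0`), so fractions always
sum to 1. `ceac()` computes acceptability curves from the net monetary
benefit `λE − C`; exact NMB ties are awarded to the comparator (a
measure-zero event, fixed for reproducibility), making the two curves
complementary by construction. The default λ grid spans 0 to three times
GDP per capita (27,229 BRL, 2014), the WHO-style willingness-to-pay
threshold of 81,687 BRL.

At 100,000 simulations the bundled model places roughly 63% of draws in
quadrant 1 and gives the intervention a probability near 0.6 of being
cost-effective at the 3×-GDP threshold — in the vicinity of the published
63.22% / 63.5%, which is as close as one can claim: the published sampling
distributions are under-parameterized, so these are qualitative reference
points, not reproduction targets.

## Verification strategy

Three independent routes check the deterministic engine:

* a closed form: for any 2-state model, undiscounted expected alive-cycles
  equal the geometric partial sum `(1 − p^T)/(1 − p)` to 1e-10;
* an individual-level microsimulation oracle (`microsimulate()`) sampling
  patient trajectories under identical conventions, whose means must agree
  with cohort expectations within 4 standard errors at large n;
* structural properties on randomly generated models: every occupancy row
  sums to 1 within 1e-12, absorbing-state occupancy is non-decreasing, and
  months-alive effectiveness never exceeds the horizon.

The synthetic generator (`generate_model()`) produces valid random model
specifications — forward-only row-stochastic matrices with positive death
probability from every transient state, positive category-decomposed costs,
positive rewards, mean-centred ranges clipped to `[0, 1]` for probabilities
— and `generate_microcosting()` produces itemized ledgers that aggregate
back to specified category totals exactly (the largest item absorbs rounding
residue). The generator emulates the *structure* real parameter tables have,
not clinical realism: costs are log-normal around a scale, transitions are
Dirichlet-like draws. Passing property tests therefore demonstrates engine
correctness on the whole class of valid inputs, not calibration of any
particular disease model. The test suite exercises 10,000 generated models,
a 200,000-patient microsimulation, 10^6-draw gamma moment recovery and a
100,000-draw PSA; these sizes keep Monte-Carlo error well below the asserted
tolerances.

## Numerical choices and degenerate inputs

* Transition rows must sum to 1 within 1e-9 at load; occupancy conservation
  is then maintained to 1e-12 through the horizon.
* Degenerate sensitivity ranges (`low == base == high`) reproduce the base
  case exactly, draw for draw.
* An empty micro-costing ledger aggregates to total 0 with shares flagged
  undefined rather than NaN percentages.
* Zero discount gives factor exactly 1; the engine never exponentiates a
  negative base.
* `icer()` covers the degenerate increments with labels (dominant,
  dominated, equivalent) instead of returning infinities; the tornado keeps
  signed ratios so a dominance flip is visible as a sign change.

## Known limitations

* Two-strategy comparisons only; no extended-dominance frontier over three
  or more strategies.
* No quality-of-life weighting (the bundled model has no utility data; its
  effectiveness unit is months of life, not QALYs).
* No correlated PSA and no expected-value-of-perfect-information analysis.
* No tunnel states or time-varying transition probabilities; the transition
  matrix is constant over cycles.
* The convention grid covers accrual timing, first-cycle discounting and
  discount basis; it cannot represent more exotic accounting (e.g. rewards
  credited only on state entry), which would show up as a calibration
  residual no grid cell can close.
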