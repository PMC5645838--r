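#' Accrual and discounting conventions for the cohort engine
#'
#' Cohort models in different tools differ silently in where within a cycle
#' rewards and costs accrue and how discrete cycles map onto discount time.
#' These flags make every such choice explicit so that a published result can
#' be reproduced (or shown irreproducible) by an exhaustive grid search over
#' conventions rather than by guessing.
#'
#' \describe{
#'   \item{reward_source}{`"months_alive"` credits `cycle_length_months` per
#'     cycle spent in any non-absorbing state (standard life-month
#'     accounting); `"state_os_per_cycle"` credits the per-state effectiveness
#'     reward (here: the overall-survival months attached to the occupied
#'     state) each cycle.}
#'   \item{accrual_timing}{occupancy used for the effectiveness accrual of
#'     cycle k: `"cycle_start"` (pre-transition), `"cycle_end"`
#'     (post-transition) or `"half_cycle"` (their mean, the half-cycle
#'     correction).}
#'   \item{cost_timing}{same choice, for the cost stream.}
#'   \item{discount_first_cycle}{if `TRUE`, shift discount time by one full
#'     cycle so that even the first accrual is discounted.}
#'   \item{discount_basis}{`"annual"` compounds the annual rate over
#'     `t_years = t_cycles * cycle_length_months / 12`; `"per_cycle"` applies
#'     the quoted rate once per model cycle (a convention some
#'     decision-modelling setups effectively use when discounting on the
#'     stage counter).}
#' }
#'
#' The discount time of each stream follows its accrual point: start-of-cycle
#' accrual is discounted at t = k cycles, half-cycle at k + 1/2, end-of-cycle
#' at k + 1.
#'
#' @param reward_source,accrual_timing,cost_timing,discount_first_cycle,discount_basis
#'   See description.
#' @return A `convention_flags` object.
#' @export
convention_flags <- function(reward_source = c("state_os_per_cycle",
                                               "months_alive"),
                             accrual_timing = c("cycle_start", "cycle_end",
                                                "half_cycle"),
                             cost_timing = c("cycle_start", "cycle_end",
                                             "half_cycle"),
                             discount_first_cycle = FALSE,
                             discount_basis = c("annual", "per_cycle")) {
  structure(list(
    reward_source = match.arg(reward_source),
    accrual_timing = match.arg(accrual_timing),
    cost_timing = match.arg(cost_timing),
    discount_first_cycle = isTRUE(discount_first_cycle),
    discount_basis = match.arg(discount_basis)
  ), class = "convention_flags")
}

#' @export
print.convention_flags <- function(x, ...) {
  cat(sprintf(paste0("conventions: rewards=%s, accrual=%s, costs=%s, ",
                     "discount_first_cycle=%s, discount_basis=%s\n"),
              x$reward_source, x$accrual_timing, x$cost_timing,
              x$discount_first_cycle, x$discount_basis))
  invisible(x)
}

#' The full enumeration of convention-flag combinations
#'
#' @return Data frame, one row per cell of the convention grid, in a fixed
#'   deterministic order (used for tie-breaking in calibration).
#' @export
convention_grid <- function() {
  g <- expand.grid(
    reward_source = c("months_alive", "state_os_per_cycle"),
    accrual_timing = c("cycle_start", "cycle_end", "half_cycle"),
    cost_timing = c("cycle_start", "cycle_end", "half_cycle"),
    discount_first_cycle = c(FALSE, TRUE),
    discount_basis = c("annual", "per_cycle"),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  g
}

timing_shift <- function(timing) {
  switch(timing, cycle_start = 0, half_cycle = 0.5, cycle_end = 1,
         stop("unknown accrual timing: ", timing, call. = FALSE))
}

#' Discount factor for one model cycle
#'
#' @param annual_rate Annual discount rate (fraction, >= 0).
#' @param cycle_index Zero-based cycle index.
#' @param cycle_length_months Cycle length in months.
#' @param discount_first_cycle If `TRUE`, shift discount time by one cycle.
#' @param timing_shift Within-cycle offset in cycles (0 start, 0.5 half,
#'   1 end); default 0.
#' @param basis `"annual"` (default: compound over calendar years) or
#'   `"per_cycle"` (compound the quoted rate once per cycle).
#' @return Factor in (0, 1]; exactly 1 when the rate is 0 or discount time is
#'   0.
#' @export
discount_factor <- function(annual_rate, cycle_index, cycle_length_months,
                            discount_first_cycle = FALSE, timing_shift = 0,
                            basis = c("annual", "per_cycle")) {
  stopifnot(annual_rate >= 0, all(cycle_index >= 0))
  basis <- match.arg(basis)
  t_cycles <- cycle_index + timing_shift +
    if (isTRUE(discount_first_cycle)) 1 else 0
  t_units <- if (basis == "annual") t_cycles * cycle_length_months / 12 else
    t_cycles
  (1 + annual_rate)^(-t_units)
}

#' One Markov transition step
#'
#' Left-multiplies a cohort occupancy vector by a transition matrix.
#'
#' @param occupancy Numeric vector over states, summing to 1.
#' @param matrix Validated transition matrix.
#' @return The next occupancy vector.
#' @export
markov_step <- function(occupancy, matrix) {
  if (length(occupancy) != nrow(matrix))
    stop("occupancy length does not match the transition matrix", call. = FALSE)
  drop(occupancy %*% matrix)
}

state_cost_totals <- function(strategy) {
  vapply(strategy$state_costs, total_cost, numeric(1))
}

reward_vector <- function(strategy, model, conventions) {
  if (conventions$reward_source == "months_alive") {
    ifelse(model$states$absorbing, 0, model$cycle_length_months)
  } else {
    unname(strategy$state_rewards)
  }
}

#' Run the cohort model for one strategy
#'
#' Propagates the cohort through `horizon_cycles` transitions and accrues
#' discounted costs and effectiveness under the given conventions. The trace
#' keeps `horizon_cycles + 1` occupancy snapshots (cycles 0..T, so that
#' end-of-cycle and half-cycle accrual are well defined) and exactly
#' `horizon_cycles` per-cycle accrual entries.
#'
#' @param strategy A [strategy_spec()] from `model`, or its name.
#' @param model A [model_spec()].
#' @param conventions A [convention_flags()].
#' @return A `cohort_trace`: list with `occupancy` (matrix, cycles x states),
#'   `cycle_costs`, `cycle_effects` (discounted, length `horizon_cycles`) and
#'   `totals` (named: `cost`, `effect`).
#' @export
run_cohort <- function(strategy, model, conventions = convention_flags()) {
  if (is.character(strategy)) strategy <- model$strategies[[strategy]]
  stopifnot(inherits(strategy, "strategy_spec"), inherits(model, "model_spec"))
  nm <- model$states$name
  T_ <- model$horizon_cycles
  P <- strategy$transition
  occ <- matrix(0, T_ + 1L, length(nm), dimnames = list(0:T_, nm))
  occ[1L, ] <- model$initial_occupancy
  for (k in seq_len(T_)) occ[k + 1L, ] <- occ[k, ] %*% P

  costs <- state_cost_totals(strategy)
  rewards <- reward_vector(strategy, model, conventions)
  r <- model$annual_discount_rate
  clm <- model$cycle_length_months

  pick <- function(timing, k) {
    switch(timing,
           cycle_start = occ[k + 1L, ],
           cycle_end = occ[k + 2L, ],
           half_cycle = (occ[k + 1L, ] + occ[k + 2L, ]) / 2)
  }
  ks <- 0:(T_ - 1L)
  df_cost <- discount_factor(r, ks, clm, conventions$discount_first_cycle,
                             timing_shift(conventions$cost_timing),
                             conventions$discount_basis)
  df_eff <- discount_factor(r, ks, clm, conventions$discount_first_cycle,
                            timing_shift(conventions$accrual_timing),
                            conventions$discount_basis)
  cycle_costs <- numeric(T_)
  cycle_effects <- numeric(T_)
  for (k in ks) {
    cycle_costs[k + 1L] <- df_cost[k + 1L] *
      sum(pick(conventions$cost_timing, k) * costs)
    cycle_effects[k + 1L] <- df_eff[k + 1L] *
      sum(pick(conventions$accrual_timing, k) * rewards)
  }

  # one-time entry costs: charged at the cycle boundary where the cohort
  # fraction first enters the state (initial occupancy counts as entry at
  # time 0); discounted at the boundary time, no within-cycle shift
  if (any(strategy$entry_costs != 0)) {
    ec <- strategy$entry_costs
    df0 <- discount_factor(r, 0:T_, clm, conventions$discount_first_cycle,
                           0, conventions$discount_basis)
    cycle_costs[1L] <- cycle_costs[1L] + df0[1L] * sum(occ[1L, ] * ec)
    for (k in seq_len(T_)) {
      inflow <- pmax(occ[k + 1L, ] - occ[k, ] * diag(P), 0)
      cycle_costs[min(k, T_)] <- cycle_costs[min(k, T_)] +
        df0[k + 1L] * sum(inflow * ec)
    }
  }

  structure(list(strategy = strategy$name, occupancy = occ,
                 cycle_costs = cycle_costs, cycle_effects = cycle_effects,
                 totals = c(cost = sum(cycle_costs),
                            effect = sum(cycle_effects)),
                 conventions = conventions),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat(sprintf("cohort trace '%s': %d cycles, expected cost %.2f, expected effect %.4f\n",
              x$strategy, length(x$cycle_costs), x$totals[["cost"]],
              x$totals[["effect"]]))
  invisible(x)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  T_ <- length(x$cycle_costs)
  data.frame(cycle = 0:T_, x$occupancy,
             discounted_cost = c(x$cycle_costs, NA),
             discounted_effect = c(x$cycle_effects, NA),
             row.names = NULL, check.names = FALSE)
}

#' Export a cohort trace as a delimited table
#'
#' @param trace A `cohort_trace`.
#' @param file Path of the CSV file to write.
#' @return The file path, invisibly.
#' @export
write_trace <- function(trace, file) {
  utils::write.csv(as.data.frame(trace), file, row.names = FALSE)
  invisible(file)
}

#' Expected discounted totals for one strategy
#'
#' @inheritParams run_cohort
#' @return Named numeric vector `c(cost = , effect = )`.
#' @export
expected_outcomes <- function(strategy, model,
                              conventions = convention_flags()) {
  run_cohort(strategy, model, conventions)$totals
}
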