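#' Fixed micro-costing category set
#'
#' The closed set of cost categories a per-cycle state cost is broken into:
#' medications, pharmacy preparation of the infusion, nursing administration,
#' laboratory tests, imaging tests and hospitalization. Unknown categories are
#' rejected rather than pooled.
#'
#' @return Character vector of the six category names, in report order.
#' @export
cost_categories <- function() {
  c("medications", "preparation_pharmacy", "administration_nursing",
    "laboratory_tests", "imaging_tests", "hospitalization")
}

#' Define a health state
#'
#' @param name State label, unique within a model.
#' @param absorbing Logical; `TRUE` for the single absorbing (death) state.
#' @param order_index Integer position of the state in the transition matrix.
#' @return A `health_state` object.
#' @export
health_state <- function(name, absorbing = FALSE, order_index = NA_integer_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.logical(absorbing), length(absorbing) == 1L)
  structure(list(name = name, absorbing = absorbing,
                 order_index = as.integer(order_index)),
            class = "health_state")
}

#' Per-cycle cost breakdown over the fixed category set
#'
#' Missing categories are filled with zero; amounts must be non-negative and
#' categories must come from [cost_categories()].
#'
#' @param ... Named amounts, e.g. `medications = 6428`.
#' @param amounts Alternatively, a named numeric vector.
#' @return Named numeric vector of class `cost_breakdown` covering all six
#'   categories, with a `total` attribute.
#' @export
cost_breakdown <- function(..., amounts = NULL) {
  x <- if (is.null(amounts)) unlist(list(...)) else amounts
  if (length(x) == 0L) x <- numeric(0)
  cats <- cost_categories()
  if (length(x) > 0L) {
    if (is.null(names(x)) || any(!nzchar(names(x))))
      stop("cost_breakdown amounts must be named by category", call. = FALSE)
    unknown <- setdiff(names(x), cats)
    if (length(unknown) > 0L)
      stop("unknown cost category: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    if (any(x < 0))
      stop("cost amounts must be non-negative", call. = FALSE)
  }
  out <- stats::setNames(numeric(length(cats)), cats)
  out[names(x)] <- as.numeric(x)
  structure(out, total = sum(out), class = "cost_breakdown")
}

#' Total of a cost breakdown
#' @param x A `cost_breakdown`.
#' @return The sum over categories.
#' @export
total_cost <- function(x) {
  if (!is.null(attr(x, "total"))) attr(x, "total") else sum(unclass(x))
}

#' Validate a transition probability matrix
#'
#' Checks that the matrix is square, entries lie in `[0, 1]`, every row sums
#' to 1 within `tol`, and each absorbing state maps onto itself with
#' probability 1.
#'
#' @param mat Square numeric matrix, rows = origin states.
#' @param state_names Character vector of state names (row/column order).
#' @param absorbing Logical vector marking absorbing states.
#' @param tol Row-sum tolerance (default `1e-9`).
#' @return The matrix, with dimnames set, invisibly usable as a validated
#'   transition matrix.
#' @export
transition_matrix <- function(mat, state_names, absorbing, tol = 1e-9) {
  mat <- as.matrix(mat)
  n <- length(state_names)
  if (nrow(mat) != n || ncol(mat) != n)
    stop("transition matrix must be ", n, "x", n, " to match the state list",
         call. = FALSE)
  dimnames(mat) <- list(state_names, state_names)
  if (any(mat < 0 | mat > 1))
    stop("transition probabilities must lie in [0, 1]", call. = FALSE)
  rs <- rowSums(mat)
  bad <- which(abs(rs - 1) > tol)
  if (length(bad) > 0L)
    stop(sprintf("transition row '%s' sums to %.10g, not 1",
                 state_names[bad[1L]], rs[bad[1L]]), call. = FALSE)
  for (i in which(absorbing)) {
    if (abs(mat[i, i] - 1) > tol)
      stop(sprintf("absorbing state '%s' must map to itself with probability 1",
                   state_names[i]), call. = FALSE)
  }
  mat
}

#' Define a treatment strategy
#'
#' A strategy bundles a transition matrix, per-state per-cycle cost breakdowns,
#' per-state effectiveness rewards (months) and optional one-time costs charged
#' on first entry into a state.
#'
#' @param name Strategy label.
#' @param transition Square transition probability matrix (validated against
#'   the model's state list by [model_spec()]).
#' @param state_costs Named list of [cost_breakdown()] objects, one per state
#'   (states omitted get zero cost).
#' @param state_rewards Named numeric vector of per-cycle effectiveness rewards
#'   in months, one per state (omitted states get zero).
#' @param entry_costs Optional named numeric vector of one-time costs charged
#'   when the cohort first enters a state (e.g. a central venous catheter on
#'   entry into second-line therapy). Default: none.
#' @return A `strategy_spec` object.
#' @export
strategy_spec <- function(name, transition, state_costs, state_rewards,
                          entry_costs = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name, transition = as.matrix(transition),
                 state_costs = state_costs,
                 state_rewards = state_rewards,
                 entry_costs = entry_costs),
            class = "strategy_spec")
}

#' Assemble and validate a complete decision model
#'
#' @param states List of [health_state()] objects; exactly one must be
#'   absorbing.
#' @param strategies List of [strategy_spec()] objects.
#' @param horizon_cycles Number of model cycles (default 20).
#' @param cycle_length_months Cycle length in months (default 3).
#' @param annual_discount_rate Annual discount rate as a fraction (default
#'   0.05).
#' @param initial_occupancy Named numeric vector over states summing to 1;
#'   default puts the whole cohort in the first state.
#' @return A validated `model_spec` object. Transition matrices are checked
#'   row by row; the absorbing state must carry zero cost and zero reward in
#'   every strategy.
#' @export
model_spec <- function(states, strategies, horizon_cycles = 20L,
                       cycle_length_months = 3, annual_discount_rate = 0.05,
                       initial_occupancy = NULL) {
  stopifnot(length(states) >= 2L, length(strategies) >= 1L)
  nm <- vapply(states, function(s) s$name, character(1))
  if (anyDuplicated(nm))
    stop("state names must be unique", call. = FALSE)
  abs_flag <- vapply(states, function(s) isTRUE(s$absorbing), logical(1))
  if (sum(abs_flag) != 1L)
    stop("exactly one absorbing state is required", call. = FALSE)
  horizon_cycles <- as.integer(horizon_cycles)
  if (horizon_cycles < 1L) stop("horizon_cycles must be >= 1", call. = FALSE)
  if (annual_discount_rate < 0)
    stop("discount rate must be >= 0", call. = FALSE)
  if (cycle_length_months <= 0)
    stop("cycle length must be positive", call. = FALSE)

  if (is.null(initial_occupancy)) {
    initial_occupancy <- stats::setNames(numeric(length(nm)), nm)
    initial_occupancy[1L] <- 1
  } else {
    initial_occupancy <- initial_occupancy[nm]
    if (anyNA(initial_occupancy))
      stop("initial occupancy must cover every state", call. = FALSE)
  }
  if (abs(sum(initial_occupancy) - 1) > 1e-9)
    stop("initial occupancy must sum to 1", call. = FALSE)

  strategies <- lapply(strategies, function(st) {
    st$transition <- transition_matrix(st$transition, nm, abs_flag)
    cb <- stats::setNames(
      lapply(nm, function(s) {
        if (!is.null(st$state_costs[[s]])) {
          b <- st$state_costs[[s]]
          if (!inherits(b, "cost_breakdown")) b <- cost_breakdown(amounts = b)
          b
        } else cost_breakdown()
      }), nm)
    st$state_costs <- cb
    rw <- stats::setNames(numeric(length(nm)), nm)
    if (!is.null(st$state_rewards)) {
      unknown <- setdiff(names(st$state_rewards), nm)
      if (length(unknown) > 0L)
        stop("reward for unknown state: ", paste(unknown, collapse = ", "),
             call. = FALSE)
      rw[names(st$state_rewards)] <- st$state_rewards
    }
    st$state_rewards <- rw
    ec <- stats::setNames(numeric(length(nm)), nm)
    if (!is.null(st$entry_costs)) ec[names(st$entry_costs)] <- st$entry_costs
    st$entry_costs <- ec
    dead <- nm[abs_flag]
    if (total_cost(st$state_costs[[dead]]) != 0 || st$state_rewards[[dead]] != 0)
      stop(sprintf("absorbing state '%s' must have zero cost and zero reward (strategy '%s')",
                   dead, st$name), call. = FALSE)
    st
  })
  names(strategies) <- vapply(strategies, function(s) s$name, character(1))
  if (anyDuplicated(names(strategies)))
    stop("strategy names must be unique", call. = FALSE)

  structure(list(
    states = data.frame(name = nm, absorbing = abs_flag,
                        order_index = seq_along(nm), stringsAsFactors = FALSE),
    strategies = strategies,
    horizon_cycles = horizon_cycles,
    cycle_length_months = cycle_length_months,
    annual_discount_rate = annual_discount_rate,
    initial_occupancy = initial_occupancy
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("Markov cohort model: %d states, %d strategies\n",
              nrow(x$states), length(x$strategies)))
  cat(sprintf("  states: %s (absorbing: %s)\n",
              paste(x$states$name, collapse = ", "),
              x$states$name[x$states$absorbing]))
  cat(sprintf("  horizon: %d cycles x %g months, discount %.1f%%/year\n",
              x$horizon_cycles, x$cycle_length_months,
              100 * x$annual_discount_rate))
  invisible(x)
}

#' One sensitivity range for a model parameter
#'
#' Encodes one row of a sensitivity-range table: the base-case value plus the
#' (low, high) interval explored in one-way and probabilistic sensitivity
#' analysis. The parameter is addressed structurally by kind, strategy and
#' state (plus destination state for transition probabilities).
#'
#' @param kind One of `"cost"`, `"effectiveness"`, `"probability"`,
#'   `"discount"`.
#' @param base,low,high Base-case value and sensitivity bounds,
#'   `low <= base <= high`.
#' @param strategy Strategy name the parameter belongs to (`NA` for the
#'   discount rate).
#' @param state State the parameter attaches to (`NA` for the discount rate).
#' @param to_state Destination state, for `kind = "probability"` only.
#' @param source Free-text provenance note.
#' @return One-row data frame with a derived `parameter_id`.
#' @export
parameter_range <- function(kind, base, low, high, strategy = NA_character_,
                            state = NA_character_, to_state = NA_character_,
                            source = "") {
  kind <- match.arg(kind, c("cost", "effectiveness", "probability", "discount"))
  if (!(low <= base && base <= high))
    stop("parameter range must satisfy low <= base <= high", call. = FALSE)
  if (kind == "probability" && (low < 0 || high > 1))
    stop("probability ranges must stay within [0, 1]", call. = FALSE)
  id <- paste(stats::na.omit(c(kind, strategy, state, to_state)), collapse = ".")
  data.frame(parameter_id = id, kind = kind, strategy = strategy,
             state = state, to_state = to_state, base = base, low = low,
             high = high, source = source, stringsAsFactors = FALSE)
}
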