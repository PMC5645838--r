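#' Half-range standard deviation of a sensitivity interval
#'
#' Cost sensitivity intervals are published as mean plus/minus one standard
#' deviation; the SD is therefore recovered as half the interval width.
#'
#' @param low,high Interval bounds, `high >= low`.
#' @return `(high - low) / 2`.
#' @export
range_to_sd <- function(low, high) {
  if (any(high < low)) stop("high must be >= low", call. = FALSE)
  (high - low) / 2
}

#' Gamma distribution matched to a mean and standard deviation
#'
#' Moment-matching parameterization used for cost parameters in the
#' probabilistic sensitivity analysis: `shape = (mean/sd)^2`,
#' `scale = sd^2/mean`, so the gamma has exactly the requested first two
#' moments.
#'
#' @param mean,sd Positive target moments.
#' @return List with `shape` and `scale`.
#' @export
gamma_from_mean_sd <- function(mean, sd) {
  if (any(mean <= 0) || any(sd <= 0))
    stop("mean and sd must be positive", call. = FALSE)
  list(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Sample a transition row from per-entry uniform ranges
#'
#' Each entry is drawn uniformly on its `[low, high]` interval (degenerate
#' intervals reproduce the base entry exactly) and the row is renormalized to
#' sum to 1, preserving structural zeros. Uses the current RNG state.
#'
#' @param base_row Stochastic base row.
#' @param lows,highs Per-entry bounds; defaults equal to `base_row`
#'   (degenerate).
#' @return A row summing to 1 within 1e-12.
#' @export
sample_transition_row <- function(base_row, lows = base_row,
                                  highs = base_row) {
  stopifnot(length(lows) == length(base_row),
            length(highs) == length(base_row))
  if (any(lows < 0) || any(highs > 1) || any(highs < lows))
    stop("transition ranges must satisfy 0 <= low <= high <= 1",
         call. = FALSE)
  if (abs(sum(base_row) - 1) > 1e-9)
    stop("base row must be stochastic", call. = FALSE)
  width <- highs - lows
  draw <- lows + width * stats::runif(length(base_row))
  draw[width == 0] <- base_row[width == 0]
  draw / sum(draw)
}

## --- applying a single parameter value to a model (one-way analysis) -----

apply_range_value <- function(model, row, value) {
  if (row$kind != "discount") {
    if (!(row$strategy %in% names(model$strategies)))
      stop("range '", row$parameter_id, "' references unknown strategy",
           call. = FALSE)
    if (!(row$state %in% model$states$name))
      stop("range '", row$parameter_id, "' references unknown state",
           call. = FALSE)
  }
  if (row$kind == "probability" && !(row$to_state %in% model$states$name))
    stop("range '", row$parameter_id, "' references unknown destination state",
         call. = FALSE)
  switch(row$kind,
    cost = {
      st <- model$strategies[[row$strategy]]
      b <- st$state_costs[[row$state]]
      tot <- total_cost(b)
      amounts <- if (tot > 0) unclass(b) * (value / tot) else
        stats::setNames(c(value, numeric(length(b) - 1L)), names(b))
      model$strategies[[row$strategy]]$state_costs[[row$state]] <-
        cost_breakdown(amounts = amounts)
      model
    },
    effectiveness = {
      model$strategies[[row$strategy]]$state_rewards[[row$state]] <- value
      model
    },
    probability = {
      P <- model$strategies[[row$strategy]]$transition
      i <- row$state
      j <- row$to_state
      others <- setdiff(colnames(P)[P[i, ] > 0 | colnames(P) == j], j)
      rest <- sum(P[i, others])
      if (rest <= 0 && abs(value - 1) > 1e-12)
        stop("cannot rebalance row '", i, "': no other positive entries",
             call. = FALSE)
      P[i, others] <- if (rest > 0) P[i, others] * (1 - value) / rest else 0
      P[i, j] <- value
      model$strategies[[row$strategy]]$transition <-
        transition_matrix(P, model$states$name, model$states$absorbing)
      model
    },
    discount = {
      model$annual_discount_rate <- value
      model
    },
    stop("unknown parameter kind: ", row$kind, call. = FALSE))
}

icer_value <- function(res) {
  if (res$delta_effect != 0) res$delta_cost / res$delta_effect
  else if (res$delta_cost == 0) 0 else sign(res$delta_cost) * Inf
}

#' One-way (tornado) sensitivity analysis of the ICER
#'
#' One-factor-at-a-time analysis: each parameter is set to its lower and then
#' its upper sensitivity bound with all other parameters at base case, and the
#' two-strategy ICER is recomputed. Entries are ranked by the width of the
#' induced ICER interval, the ordering a tornado diagram displays.
#'
#' The reported ICER endpoints are signed ratios `dC/dE`; a sign flip relative
#' to the base case means the intervention becomes dominated (or dominant)
#' within the explored range, and the accompanying label says which.
#'
#' @inheritParams run_cohort
#' @param ranges Data frame of [parameter_range()] rows.
#' @return Data frame of class `tornado_result`: `parameter_id`,
#'   `icer_at_low`, `icer_at_high`, `label_at_low`, `label_at_high`, `width`,
#'   sorted by descending width. Attribute `base_icer` holds the base-case
#'   ratio.
#' @export
tornado <- function(model, conventions, ranges) {
  stopifnot(nrow(ranges) >= 1L)
  base <- compare_strategies(model, conventions)
  one <- function(row, value) {
    m <- apply_range_value(model, row, value)
    res <- compare_strategies(m, conventions)
    list(value = icer_value(res), label = res$label)
  }
  ent <- lapply(seq_len(nrow(ranges)), function(i) {
    row <- ranges[i, ]
    if (row$kind != "discount" &&
        !(row$strategy %in% names(model$strategies)))
      stop("range references unknown strategy: ", row$strategy,
           call. = FALSE)
    lo <- one(row, row$low)
    hi <- one(row, row$high)
    data.frame(parameter_id = row$parameter_id,
               icer_at_low = lo$value, icer_at_high = hi$value,
               label_at_low = lo$label, label_at_high = hi$label,
               width = abs(hi$value - lo$value), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, ent)
  out <- out[order(-out$width), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, base_icer = icer_value(base),
            class = c("tornado_result", "data.frame"))
}

## --- probabilistic sensitivity analysis ----------------------------------

sample_psa_parameters <- function(ranges, n) {
  draws <- lapply(seq_len(nrow(ranges)), function(i) {
    row <- ranges[i, ]
    if (row$high == row$low) return(rep(row$base, n))
    switch(row$kind,
      cost = {
        g <- gamma_from_mean_sd(row$base, range_to_sd(row$low, row$high))
        stats::rgamma(n, shape = g$shape, scale = g$scale)
      },
      effectiveness = stats::runif(n, row$low, row$high),
      probability = stats::runif(n, row$low, row$high),
      discount = rep(row$base, n))   # varied one-way, held at base in PSA
  })
  names(draws) <- ranges$parameter_id
  draws
}

# per-strategy draw arrays: state cost matrix (n x S), reward matrix,
# transition rows as a list over origin states of (n x S) matrices
build_strategy_draws <- function(strategy, model, ranges, draws, n) {
  nm <- model$states$name
  S <- length(nm)
  costs <- matrix(rep(state_cost_totals(strategy), each = n), n, S,
                  dimnames = list(NULL, nm))
  rewards <- matrix(rep(unname(strategy$state_rewards), each = n), n, S,
                    dimnames = list(NULL, nm))
  P <- strategy$transition
  P_rows <- lapply(seq_len(S), function(i)
    matrix(rep(P[i, ], each = n), n, S, dimnames = list(NULL, nm)))
  for (i in seq_len(nrow(ranges))) {
    row <- ranges[i, ]
    if (is.na(row$strategy) || row$strategy != strategy$name) next
    d <- draws[[row$parameter_id]]
    if (row$kind == "cost") costs[, row$state] <- d
    if (row$kind == "effectiveness") rewards[, row$state] <- d
    if (row$kind == "probability")
      P_rows[[match(row$state, nm)]][, row$to_state] <- d
  }
  # renormalize every sampled transition row draw-by-draw (structural zeros
  # are preserved); absorbing rows were never touched
  for (i in seq_len(S)) {
    rs <- rowSums(P_rows[[i]])
    P_rows[[i]] <- P_rows[[i]] / rs
  }
  list(costs = costs, rewards = rewards, P_rows = P_rows)
}

# vectorized cohort evaluation over n simultaneous parameter draws
evaluate_draws <- function(sd_, model, conventions, n) {
  nm <- model$states$name
  S <- length(nm)
  T_ <- model$horizon_cycles
  r <- model$annual_discount_rate
  clm <- model$cycle_length_months
  ks <- 0:(T_ - 1L)
  df_cost <- discount_factor(r, ks, clm, conventions$discount_first_cycle,
                             timing_shift(conventions$cost_timing),
                             conventions$discount_basis)
  df_eff <- discount_factor(r, ks, clm, conventions$discount_first_cycle,
                            timing_shift(conventions$accrual_timing),
                            conventions$discount_basis)
  rewards <- if (conventions$reward_source == "months_alive")
    matrix(rep(ifelse(model$states$absorbing, 0, clm), each = n), n, S)
  else sd_$rewards

  occ <- matrix(rep(model$initial_occupancy, each = n), n, S)
  tot_cost <- numeric(n)
  tot_eff <- numeric(n)
  point <- function(timing, a, b) {
    switch(timing, cycle_start = a, cycle_end = b, half_cycle = (a + b) / 2)
  }
  for (k in ks) {
    occ_next <- matrix(0, n, S)
    for (i in seq_len(S)) occ_next <- occ_next + occ[, i] * sd_$P_rows[[i]]
    tot_cost <- tot_cost + df_cost[k + 1L] *
      rowSums(point(conventions$cost_timing, occ, occ_next) * sd_$costs)
    tot_eff <- tot_eff + df_eff[k + 1L] *
      rowSums(point(conventions$accrual_timing, occ, occ_next) * rewards)
    occ <- occ_next
  }
  list(cost = tot_cost, effect = tot_eff)
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' Draws `n` joint parameter sets (costs from moment-matched gamma
#' distributions, effectiveness and transition probabilities from uniform
#' distributions over their sensitivity ranges, transition rows renormalized
#' draw-by-draw; the discount rate is held at base), fully re-evaluates both
#' strategies for every draw, and returns the per-draw outcome pairs and
#' increments. Parameters are sampled independently; no correlation structure
#' is imposed.
#'
#' @inheritParams tornado
#' @param n Number of simulations (>= 1).
#' @param seed Integer seed; same seed, same draws.
#' @return A `psa_draws` object: list with `params` (data frame of sampled
#'   parameter values), `results` (data frame with per-strategy cost/effect
#'   and `delta_cost`, `delta_effect`), `n`, `seed`.
#' @export
run_psa <- function(model, conventions, ranges, n = 100000L, seed = NULL) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  if (length(model$strategies) != 2L)
    stop("run_psa expects exactly two strategies", call. = FALSE)
  n <- as.integer(n)
  if (!is.null(seed)) set.seed(seed)
  draws <- sample_psa_parameters(ranges, n)
  res <- lapply(model$strategies, function(st) {
    sd_ <- build_strategy_draws(st, model, ranges, draws, n)
    evaluate_draws(sd_, model, conventions, n)
  })
  s <- names(model$strategies)
  results <- data.frame(
    cost_1 = res[[1L]]$cost, effect_1 = res[[1L]]$effect,
    cost_2 = res[[2L]]$cost, effect_2 = res[[2L]]$effect)
  results$delta_cost <- results$cost_2 - results$cost_1
  results$delta_effect <- results$effect_2 - results$effect_1
  structure(list(params = as.data.frame(draws, check.names = FALSE),
                 results = results, strategies = s, n = n, seed = seed),
            class = "psa_draws")
}

#' @export
print.psa_draws <- function(x, ...) {
  cat(sprintf("PSA: %d draws, strategies %s vs %s\n", x$n,
              x$strategies[1L], x$strategies[2L]))
  cat(sprintf("  mean dC = %.2f, mean dE = %.4f\n",
              mean(x$results$delta_cost), mean(x$results$delta_effect)))
  invisible(x)
}

#' Cost-effectiveness plane quadrant shares
#'
#' Classifies each draw's increment pair: Q1 (`dE > 0, dC > 0`, more
#' effective and more costly), Q2 (`dE <= 0, dC > 0`), Q3
#' (`dE <= 0, dC <= 0`), Q4 (`dE > 0, dC <= 0`). Boundary points follow the
#' stated half-open rule (zero increments count as "not greater"), so the
#' four fractions always sum to 1.
#'
#' @param draws A `psa_draws` object or a data frame with `delta_effect` and
#'   `delta_cost` columns.
#' @return Named numeric vector of fractions `Q1`..`Q4`.
#' @export
ce_plane_quadrants <- function(draws) {
  d <- if (inherits(draws, "psa_draws")) draws$results else draws
  if (is.null(d) || nrow(d) == 0L)
    stop("no draws to classify", call. = FALSE)
  de <- d$delta_effect
  dc <- d$delta_cost
  c(Q1 = mean(de > 0 & dc > 0),
    Q2 = mean(de <= 0 & dc > 0),
    Q3 = mean(de <= 0 & dc <= 0),
    Q4 = mean(de > 0 & dc <= 0))
}

#' Cost-effectiveness acceptability curve
#'
#' For every willingness-to-pay value in `lambda_grid`, the probability that
#' each strategy is cost-effective is the fraction of draws in which it has
#' the strictly highest net monetary benefit; exact ties are awarded to the
#' comparator (first strategy), so the two curves sum to 1 everywhere.
#'
#' @param draws A `psa_draws` object.
#' @param lambda_grid Numeric vector of willingness-to-pay values per month.
#' @return Data frame of class `ceac_curve`: `lambda`, and one probability
#'   column per strategy.
#' @export
ceac <- function(draws, lambda_grid) {
  stopifnot(inherits(draws, "psa_draws"), length(lambda_grid) >= 1L)
  d <- draws$results
  p2 <- vapply(lambda_grid, function(l)
    mean(nmb(d$cost_2, d$effect_2, l) > nmb(d$cost_1, d$effect_1, l)),
    numeric(1))
  out <- data.frame(lambda = lambda_grid, p1 = 1 - p2, p2 = p2)
  names(out)[2:3] <- make.names(draws$strategies, unique = TRUE)
  structure(out, strategies = draws$strategies,
            class = c("ceac_curve", "data.frame"))
}

#' Default willingness-to-pay grid for an acceptability curve
#'
#' @param gdp_per_capita GDP per capita (default 27,229).
#' @param multiplier Upper end as a multiple of GDP per capita (default 3).
#' @param steps Number of grid points (default 200).
#' @return Numeric vector from 0 to `gdp_per_capita * multiplier`.
#' @export
lambda_grid <- function(gdp_per_capita = 27229, multiplier = 3,
                        steps = 200L) {
  seq(0, wtp_threshold(gdp_per_capita, multiplier), length.out = steps + 1L)
}
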