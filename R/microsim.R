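#' Individual-level microsimulation oracle
#'
#' Simulates `n_patients` independent patient trajectories through the same
#' transition structure, accruing discounted costs and effectiveness under
#' the same conventions as [run_cohort()]. Because the cohort model computes
#' the exact expectation of this stochastic process, the microsimulation mean
#' converges to the cohort totals and serves as an independent check of the
#' deterministic engine.
#'
#' @inheritParams run_cohort
#' @param n_patients Number of simulated patients (>= 1).
#' @param seed Integer seed for reproducibility (optional).
#' @return List with `mean_cost`, `mean_effect`, `se_cost`, `se_effect` and
#'   `n_patients`.
#' @export
microsimulate <- function(strategy, model, conventions = convention_flags(),
                          n_patients = 10000L, seed = NULL) {
  if (is.character(strategy)) strategy <- model$strategies[[strategy]]
  stopifnot(n_patients >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_patients)
  nm <- model$states$name
  S <- length(nm)
  T_ <- model$horizon_cycles
  P <- strategy$transition
  cum <- t(apply(P, 1L, cumsum))

  # states[, k] = 1-based state index of each patient at cycle k-1
  states <- matrix(0L, n, T_ + 1L)
  states[, 1L] <- sample.int(S, n, replace = TRUE,
                             prob = model$initial_occupancy)
  for (k in seq_len(T_)) {
    u <- stats::runif(n)
    cur <- states[, k]
    nxt <- integer(n)
    for (s in seq_len(S)) {
      idx <- cur == s
      if (any(idx))
        nxt[idx] <- findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L
    }
    states[, k + 1L] <- nxt
  }

  costs <- state_cost_totals(strategy)
  rewards <- reward_vector(strategy, model, conventions)
  r <- model$annual_discount_rate
  clm <- model$cycle_length_months
  ks <- 0:(T_ - 1L)
  df_cost <- discount_factor(r, ks, clm, conventions$discount_first_cycle,
                             timing_shift(conventions$cost_timing),
                             conventions$discount_basis)
  df_eff <- discount_factor(r, ks, clm, conventions$discount_first_cycle,
                            timing_shift(conventions$accrual_timing),
                            conventions$discount_basis)

  point_vals <- function(vals, timing, k) {
    v_start <- vals[states[, k + 1L]]
    if (timing == "cycle_start") return(v_start)
    v_end <- vals[states[, k + 2L]]
    if (timing == "cycle_end") v_end else (v_start + v_end) / 2
  }
  tot_cost <- numeric(n)
  tot_eff <- numeric(n)
  for (k in ks) {
    tot_cost <- tot_cost +
      df_cost[k + 1L] * point_vals(costs, conventions$cost_timing, k)
    tot_eff <- tot_eff +
      df_eff[k + 1L] * point_vals(rewards, conventions$accrual_timing, k)
  }
  if (any(strategy$entry_costs != 0)) {
    ec <- strategy$entry_costs
    df0 <- discount_factor(r, 0:T_, clm, conventions$discount_first_cycle,
                           0, conventions$discount_basis)
    tot_cost <- tot_cost + df0[1L] * ec[states[, 1L]]
    for (k in seq_len(T_)) {
      moved <- states[, k + 1L] != states[, k]
      tot_cost <- tot_cost + df0[k + 1L] * ec[states[, k + 1L]] * moved
    }
  }

  list(mean_cost = mean(tot_cost), mean_effect = mean(tot_eff),
       se_cost = stats::sd(tot_cost) / sqrt(n),
       se_effect = stats::sd(tot_eff) / sqrt(n),
       n_patients = n)
}
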