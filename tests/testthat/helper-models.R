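# Small models used across tests.

# 2-state alive/dead model: stay-alive probability p, per-cycle cost while
# alive, T cycles. Expected alive cycle-visits (start-of-cycle counting,
# no discount) is the geometric partial sum (1 - p^T) / (1 - p).
two_state_model <- function(p = 0.5, cost = 100, horizon = 3L,
                            discount = 0, reward_os = NULL) {
  states <- list(health_state("alive"),
                 health_state("dead", absorbing = TRUE))
  P <- rbind(c(p, 1 - p), c(0, 1))
  rewards <- c(alive = if (is.null(reward_os)) 3 else reward_os)
  s <- strategy_spec("only", P,
                     state_costs = list(alive = cost_breakdown(
                       medications = cost)),
                     state_rewards = rewards)
  model_spec(states, list(s), horizon_cycles = horizon,
             cycle_length_months = 3, annual_discount_rate = discount)
}

# conventions used by the closed-form checks: undiscounted start-of-cycle
# life-month accounting
months_alive_flags <- function() {
  convention_flags(reward_source = "months_alive",
                   accrual_timing = "cycle_start",
                   cost_timing = "cycle_start")
}

# two identical strategies except for the first-state cycle cost
paired_toy_model <- function(cost1 = 100, cost2 = 150, p = 0.5,
                             horizon = 3L, os2 = 4) {
  states <- list(health_state("alive"),
                 health_state("dead", absorbing = TRUE))
  P <- rbind(c(p, 1 - p), c(0, 1))
  mk <- function(name, cost, os) {
    strategy_spec(name, P,
                  state_costs = list(alive = cost_breakdown(
                    medications = cost)),
                  state_rewards = c(alive = os))
  }
  model_spec(states, list(mk("a", cost1, 3), mk("b", cost2, os2)),
             horizon_cycles = horizon, cycle_length_months = 3,
             annual_discount_rate = 0)
}

# minimal psa_draws-shaped object for CEAC / quadrant unit tests
fake_psa <- function(cost_1, effect_1, cost_2, effect_2,
                     strategies = c("a", "b")) {
  results <- data.frame(cost_1 = cost_1, effect_1 = effect_1,
                        cost_2 = cost_2, effect_2 = effect_2)
  results$delta_cost <- results$cost_2 - results$cost_1
  results$delta_effect <- results$effect_2 - results$effect_1
  structure(list(params = NULL, results = results, strategies = strategies,
                 n = nrow(results), seed = NULL),
            class = "psa_draws")
}
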