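test_that("discount factors follow the stated time conventions", {
  expect_equal(discount_factor(0, 7, 3), 1)
  expect_equal(discount_factor(0.05, 4, 3), 1 / 1.05)
  expect_equal(discount_factor(0.05, 0, 3), 1)
  # discounting the first cycle shifts time by one cycle
  expect_equal(discount_factor(0.05, 3, 3, discount_first_cycle = TRUE),
               1 / 1.05)
  # per-cycle basis compounds once per cycle regardless of cycle length
  expect_equal(discount_factor(0.05, 2, 3, basis = "per_cycle"),
               1 / 1.05^2)
  # mid-cycle shift
  expect_equal(discount_factor(0.05, 0, 3, timing_shift = 0.5,
                               basis = "per_cycle"), 1.05^-0.5)
})

test_that("a Markov step left-multiplies occupancy and conserves mass", {
  fx <- mcrc_base_case()
  P <- fx$model$strategies$XELOX$transition
  expect_equal(unname(markov_step(c(1, 0, 0, 0), P)),
               c(0.66, 0.20, 0.08, 0.06))
  two <- markov_step(markov_step(c(1, 0, 0, 0), P), P)
  expect_equal(unname(two[1]), 0.66^2)
  expect_equal(sum(two), 1, tolerance = 1e-12)
  expect_equal(markov_step(c(0.3, 0.3, 0.2, 0.2), diag(4)),
               c(0.3, 0.3, 0.2, 0.2))
  expect_error(markov_step(c(1, 0), P), "does not match")
})

test_that("2-state cohort matches the geometric closed form", {
  for (p in c(0.2, 0.5, 0.9, 0.99)) {
    for (T_ in c(1L, 3L, 20L)) {
      m <- two_state_model(p = p, cost = 100, horizon = T_)
      tr <- run_cohort("only", m, months_alive_flags())
      expect_equal(tr$totals[["effect"]], 3 * (1 - p^T_) / (1 - p),
                   tolerance = 1e-10)
      expect_equal(tr$totals[["cost"]], 100 * (1 - p^T_) / (1 - p),
                   tolerance = 1e-10)
    }
  }
  # the worked toy numbers: p = 0.5, T = 3
  m <- two_state_model()
  expect_equal(expected_outcomes("only", m, months_alive_flags()),
               c(cost = 175, effect = 5.25))
})

test_that("mean first-line sojourn approaches 1/(1-p) at long horizons", {
  fx <- mcrc_base_case()
  m <- fx$model
  m$horizon_cycles <- 200L
  m$annual_discount_rate <- 0
  tr <- run_cohort("XELOX", m, months_alive_flags())
  expect_equal(sum(tr$occupancy[1:200, "first_line"]), 1 / (1 - 0.66),
               tolerance = 1e-6)
})

test_that("cohort starting in the absorbing state accrues nothing", {
  fx <- mcrc_base_case()
  m <- fx$model
  m$initial_occupancy <- c(first_line = 0, second_line = 0,
                           supportive_care = 0, death = 1)
  tr <- run_cohort("XELOX", m, convention_flags())
  expect_equal(unname(tr$totals), c(0, 0))
})

test_that("occupancy conserves mass and absorption is monotone", {
  for (seed in 1:40) {
    gen <- generate_model(generator_config(seed = seed,
                                           n_states = 2L + seed %% 5L))
    for (st in names(gen$model$strategies)) {
      tr <- run_cohort(st, gen$model, convention_flags())
      expect_true(all(abs(rowSums(tr$occupancy) - 1) < 1e-12))
      dead <- tr$occupancy[, gen$model$states$absorbing]
      expect_true(all(diff(dead) >= -1e-15))
    }
  }
})

test_that("discounting and the horizon bound behave as expected", {
  fx <- mcrc_base_case()
  cf <- convention_flags(reward_source = "months_alive")
  m0 <- fx$model
  m0$annual_discount_rate <- 0
  undisc <- expected_outcomes("XELOX", m0, cf)
  disc <- expected_outcomes("XELOX", fx$model, cf)
  expect_lt(disc[["cost"]], undisc[["cost"]])
  expect_lt(disc[["effect"]], undisc[["effect"]])
  # months alive cannot exceed the horizon
  expect_lte(undisc[["effect"]],
             m0$horizon_cycles * m0$cycle_length_months)
})

test_that("trace export has one row per cycle snapshot", {
  fx <- mcrc_base_case()
  tr <- run_cohort("XELOX", fx$model, convention_flags())
  d <- as.data.frame(tr)
  expect_equal(nrow(d), fx$model$horizon_cycles + 1L)
  expect_equal(sum(d$discounted_cost, na.rm = TRUE), tr$totals[["cost"]])
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  expect_equal(nrow(utils::read.csv(f)), 21L)
})
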