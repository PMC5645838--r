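test_that("half-range SD reconstructs the published cost intervals", {
  expect_equal(range_to_sd(6636.06, 9876.58), 1620.26)
  expect_equal(range_to_sd(20664, 40946.96), 10141.48)
  expect_equal(range_to_sd(5, 5), 0)
  expect_error(range_to_sd(2, 1), ">= low")
})

test_that("gamma moment matching has the stated shape and recovers moments", {
  g <- gamma_from_mean_sd(3, 3)
  expect_equal(g$shape, 1)  # exponential case
  g2 <- gamma_from_mean_sd(8256.32, 1620.26)
  expect_equal(g2$shape, 25.9658, tolerance = 1e-4)
  expect_error(gamma_from_mean_sd(-1, 1), "positive")
  expect_error(gamma_from_mean_sd(1, 0), "positive")
  set.seed(5)
  x <- stats::rgamma(200000, shape = g2$shape, scale = g2$scale)
  expect_equal(mean(x), 8256.32, tolerance = 0.01)
  expect_equal(stats::sd(x), 1620.26, tolerance = 0.02)
})

test_that("sampled transition rows stay stochastic", {
  base <- c(0.66, 0.20, 0.08, 0.06)
  # degenerate ranges reproduce the base row
  expect_identical(sample_transition_row(base), base)
  set.seed(1)
  lows <- c(0.60, 0.18, 0.07, 0.04)
  highs <- c(0.72, 0.22, 0.09, 0.08)
  for (i in 1:50) {
    row <- sample_transition_row(base, lows, highs)
    expect_equal(sum(row), 1, tolerance = 1e-12)
    expect_true(all(row >= 0))
  }
  expect_error(sample_transition_row(base, lows, highs * 20),
               "0 <= low <= high <= 1")
  # law of large numbers: per-entry mean ~ midpoint / sum(midpoints)
  set.seed(2)
  draws <- t(replicate(20000, sample_transition_row(base, lows, highs)))
  mid <- (lows + highs) / 2
  expect_equal(colMeans(draws), mid / sum(mid), tolerance = 0.01)
})

test_that("tornado ranks parameters by induced ICER width", {
  fx <- mcrc_base_case()
  cf <- convention_flags()
  # zero-width range is ranked last with width 0
  ranges <- rbind(fx$ranges[fx$ranges$kind == "cost", ][1:3, ],
                  parameter_range("cost", 12984, 12984, 12984,
                                  "XELOX", "second_line"))
  tor <- tornado(fx$model, cf, ranges)
  expect_equal(tor$width[nrow(tor)], 0)
  expect_true(!is.unsorted(rev(tor$width)))
  # midpoint run reproduces the base-case ICER
  base_res <- compare_strategies(fx$model, cf)
  mid <- parameter_range("cost", 8256.32, 8256.32, 8256.32, "XELOX",
                         "first_line")
  tor_mid <- tornado(fx$model, cf, mid)
  expect_equal(tor_mid$icer_at_low, base_res$icer, tolerance = 1e-12)
  expect_equal(tor_mid$icer_at_high, base_res$icer, tolerance = 1e-12)
})

test_that("a single comparator cycle cost enters the ICER affinely", {
  fx <- mcrc_base_case()
  cf <- convention_flags()
  base <- compare_strategies(fx$model, cf)
  # discounted exposure of the first-line state = cost total per unit cost
  m_unit <- fx$model
  for (s in names(m_unit$strategies))
    m_unit$strategies[[s]]$state_costs <- list(
      first_line = cost_breakdown(medications = 1))
  m_unit <- model_spec(
    list(health_state("first_line"), health_state("second_line"),
         health_state("supportive_care"),
         health_state("death", absorbing = TRUE)),
    m_unit$strategies, 20L, 3, 0.05)
  exposure <- expected_outcomes("XELOX", m_unit, cf)[["cost"]]
  row <- fx$ranges[fx$ranges$kind == "cost" &
                   fx$ranges$strategy == "XELOX" &
                   fx$ranges$state == "first_line", ]
  tor <- tornado(fx$model, cf, row)
  # analytic: raising the comparator cost by d lowers dC by d * exposure
  pred_low <- (base$delta_cost - (row$low - row$base) * exposure) /
    base$delta_effect
  pred_high <- (base$delta_cost - (row$high - row$base) * exposure) /
    base$delta_effect
  expect_equal(tor$icer_at_low, pred_low, tolerance = 1e-9)
  expect_equal(tor$icer_at_high, pred_high, tolerance = 1e-9)
})

test_that("tornado rejects ranges that reference nothing in the model", {
  fx <- mcrc_base_case()
  bad <- parameter_range("cost", 1, 0, 2, "NOPE", "first_line")
  expect_error(tornado(fx$model, convention_flags(), bad),
               "unknown strategy")
})

test_that("PSA with degenerate ranges reproduces the base case exactly", {
  fx <- mcrc_base_case()
  cf <- convention_flags()
  degen <- fx$ranges
  degen$low <- degen$base
  degen$high <- degen$base
  psa <- run_psa(fx$model, cf, degen, n = 25, seed = 1)
  base <- compare_strategies(fx$model, cf)
  expect_equal(length(unique(psa$results$cost_1)), 1L)
  expect_equal(length(unique(psa$results$delta_effect)), 1L)
  expect_equal(psa$results$cost_1[1], base$strategies$cost[1],
               tolerance = 1e-9)
  expect_equal(psa$results$delta_cost[1], base$delta_cost,
               tolerance = 1e-9)
})

test_that("PSA draws are reproducible under a seed and positive-valued", {
  fx <- mcrc_base_case()
  cf <- convention_flags()
  a <- run_psa(fx$model, cf, fx$ranges, n = 200, seed = 42)
  b <- run_psa(fx$model, cf, fx$ranges, n = 200, seed = 42)
  expect_identical(a$results, b$results)
  c_ <- run_psa(fx$model, cf, fx$ranges, n = 200, seed = 43)
  expect_false(identical(a$results, c_$results))
  cost_cols <- fx$ranges$parameter_id[fx$ranges$kind == "cost"]
  expect_true(all(as.matrix(a$params[cost_cols]) > 0))
  expect_error(run_psa(fx$model, cf, fx$ranges, n = 0), ">= 1")
})

test_that("quadrant fractions sum to one and match an orthant oracle", {
  set.seed(31)
  n <- 200000
  d <- data.frame(delta_effect = stats::rnorm(n, 0.5, 1),
                  delta_cost = stats::rnorm(n, 1, 1))
  q <- ce_plane_quadrants(d)
  expect_equal(sum(q), 1)
  # independent normals: orthant probabilities factorize
  expect_equal(unname(q[["Q1"]]), stats::pnorm(0.5) * stats::pnorm(1),
               tolerance = 0.01)
  expect_equal(unname(q[["Q2"]]), stats::pnorm(-0.5) * stats::pnorm(1),
               tolerance = 0.01)
  all_q1 <- data.frame(delta_effect = c(1, 2), delta_cost = c(1, 2))
  expect_equal(unname(ce_plane_quadrants(all_q1)[["Q1"]]), 1)
  expect_error(ce_plane_quadrants(data.frame()), "no draws")
})

test_that("the acceptability curve is complementary with correct limits", {
  # 4 draws with known geometry
  psa <- fake_psa(cost_1 = c(100, 100, 100, 100),
                  effect_1 = c(10, 10, 10, 10),
                  cost_2 = c(90, 150, 150, 150),
                  effect_2 = c(11, 12, 9, 10.5))
  cv <- ceac(psa, c(0, 1e9))
  # lambda = 0: NMB reduces to -cost; strategy 2 wins only when cheaper
  expect_equal(cv[[3]][1], 0.25)
  expect_equal(cv[[2]][1] + cv[[3]][1], 1)
  # lambda -> Inf: strategy 2 wins exactly when delta_effect > 0
  expect_equal(cv[[3]][2], mean(psa$results$delta_effect > 0))
  # exact NMB ties go to the comparator
  tie <- fake_psa(100, 10, 110, 11)
  expect_equal(ceac(tie, 10)[[3]], 0)
})

test_that("the CEAC sits near one half at the base ICER of a symmetric model", {
  # symmetric increments around the base: dC ~ N(50, 5), dE ~ N(1, 0.1)
  set.seed(8)
  n <- 40000
  psa <- fake_psa(cost_1 = rep(0, n), effect_1 = rep(0, n),
                  cost_2 = stats::rnorm(n, 50, 5),
                  effect_2 = stats::rnorm(n, 1, 0.1))
  cv <- ceac(psa, 50)
  expect_equal(cv[[3]], 0.5, tolerance = 0.02)
})
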