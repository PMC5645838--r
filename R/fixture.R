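#' Published metastatic colorectal cancer base case (XELOX vs XELOX + bevacizumab)
#'
#' Base-case parameter set of a four-state Markov cohort model comparing XELOX
#' alone (strategy 1) with XELOX plus bevacizumab (strategy 2) as first-line
#' therapy for metastatic colorectal cancer, costed by micro-costing from the
#' perspective of a Brazilian public teaching hospital. States: first-line
#' therapy, second-line therapy (FOLFIRI in both strategies), supportive care,
#' and death (absorbing). Horizon 60 months as 20 three-month cycles, 5%
#' annual discount rate, whole cohort starting in first-line therapy.
#'
#' Per-cycle state costs (BRL) are broken down over the six micro-costing
#' categories; the supportive-care total is hospitalization at 529.67 BRL/day
#' for 3 days/month over a 3-month cycle plus laboratory tests. Effectiveness
#' rewards are the overall-survival months attached to each state.
#' Sensitivity ranges: cost ranges are mean +/- one standard deviation;
#' effectiveness and probability ranges are the published study-derived or
#' 10%-variation intervals.
#'
#' @param include_catheter If `TRUE`, add the 230 BRL long-term central venous
#'   catheter as a one-time cost on first entry into second-line therapy. The
#'   default `FALSE` treats it as already contained in the published FOLFIRI
#'   cycle total.
#' @return List with elements:
#'   \describe{
#'     \item{model}{a validated [model_spec()]}
#'     \item{ranges}{data frame of [parameter_range()] rows (one per
#'       sensitivity-table row, including the discount rate)}
#'     \item{reference_results}{data frame of the published per-strategy
#'       expected totals (cost in BRL, effectiveness in months of life
#'       gained), usable as a calibration target for
#'       [calibrate_conventions()]}
#'     \item{gdp_per_capita}{the 2014 Brazilian GDP per capita (27,229 BRL)
#'       used for the willingness-to-pay threshold}
#'   }
#' @export
mcrc_base_case <- function(include_catheter = FALSE) {
  st <- c("first_line", "second_line", "supportive_care", "death")
  states <- list(
    health_state("first_line", order_index = 1L),
    health_state("second_line", order_index = 2L),
    health_state("supportive_care", order_index = 3L),
    health_state("death", absorbing = TRUE, order_index = 4L))

  p1 <- rbind(c(0.66, 0.20, 0.08, 0.06),
              c(0.00, 0.49, 0.45, 0.06),
              c(0.00, 0.00, 0.75, 0.25),
              c(0.00, 0.00, 0.00, 1.00))
  p2 <- rbind(c(0.67, 0.12, 0.16, 0.05),
              c(0.00, 0.49, 0.45, 0.06),
              c(0.00, 0.00, 0.75, 0.25),
              c(0.00, 0.00, 0.00, 1.00))
  dimnames(p1) <- dimnames(p2) <- list(st, st)

  folfiri <- cost_breakdown(
    medications = 4327.80, preparation_pharmacy = 270.18,
    administration_nursing = 6700.74, laboratory_tests = 409.08,
    imaging_tests = 1276.20)
  supportive <- cost_breakdown(
    laboratory_tests = 265.48,
    hospitalization = hospitalization_cycle_cost(529.67, 3, 3))
  xelox <- cost_breakdown(
    medications = 6428.00, preparation_pharmacy = 81.24,
    administration_nursing = 580.80, laboratory_tests = 265.48,
    imaging_tests = 900.80)
  xelox_bev <- cost_breakdown(
    medications = 27592.00, preparation_pharmacy = 120.08,
    administration_nursing = 1006.40, laboratory_tests = 367.00,
    imaging_tests = 1720.00)

  entry <- if (include_catheter) c(second_line = 230) else NULL
  s1 <- strategy_spec(
    "XELOX", p1,
    state_costs = list(first_line = xelox, second_line = folfiri,
                       supportive_care = supportive),
    state_rewards = c(first_line = 17.6, second_line = 20.6,
                      supportive_care = 18),
    entry_costs = entry)
  s2 <- strategy_spec(
    "XELOX+bevacizumab", p2,
    state_costs = list(first_line = xelox_bev, second_line = folfiri,
                       supportive_care = supportive),
    state_rewards = c(first_line = 19.8, second_line = 20.6,
                      supportive_care = 18),
    entry_costs = entry)

  model <- model_spec(states, list(s1, s2), horizon_cycles = 20L,
                      cycle_length_months = 3, annual_discount_rate = 0.05)

  pr <- function(...) parameter_range(...)
  ranges <- rbind(
    # effectiveness (overall survival, months)
    pr("effectiveness", 17.6, 15.8, 19.3, "XELOX", "first_line",
       source = "systematic review"),
    pr("effectiveness", 20.6, 18.5, 22.6, "XELOX", "second_line",
       source = "FOLFIRI trial"),
    pr("effectiveness", 18.0, 16.2, 19.8, "XELOX", "supportive_care",
       source = "supportive-care trial"),
    pr("effectiveness", 19.8, 17.8, 21.8, "XELOX+bevacizumab", "first_line",
       source = "systematic review"),
    pr("effectiveness", 20.6, 18.5, 22.6, "XELOX+bevacizumab", "second_line",
       source = "FOLFIRI trial"),
    pr("effectiveness", 18.0, 16.2, 19.8, "XELOX+bevacizumab",
       "supportive_care", source = "supportive-care trial"),
    # per-cycle state costs (mean +/- SD)
    pr("cost", 8256.32, 6636.06, 9876.58, "XELOX", "first_line",
       source = "micro-costing"),
    pr("cost", 12984.00, 11600.70, 14367.30, "XELOX", "second_line",
       source = "micro-costing"),
    pr("cost", 5032.51, 4529.26, 5535.76, "XELOX", "supportive_care",
       source = "micro-costing"),
    pr("cost", 30805.48, 20664.00, 40946.96, "XELOX+bevacizumab",
       "first_line", source = "micro-costing"),
    pr("cost", 12984.00, 11600.70, 14367.30, "XELOX+bevacizumab",
       "second_line", source = "micro-costing"),
    pr("cost", 5032.51, 4529.26, 5535.76, "XELOX+bevacizumab",
       "supportive_care", source = "micro-costing"),
    # transition probabilities, strategy 1
    pr("probability", 0.66, 0.60, 0.72, "XELOX", "first_line", "first_line",
       source = "assumed 10%"),
    pr("probability", 0.20, 0.18, 0.22, "XELOX", "first_line", "second_line",
       source = "pooled trials"),
    pr("probability", 0.08, 0.07, 0.09, "XELOX", "first_line",
       "supportive_care", source = "first-line trial"),
    pr("probability", 0.06, 0.04, 0.08, "XELOX", "first_line", "death",
       source = "pooled trials"),
    pr("probability", 0.49, 0.45, 0.53, "XELOX", "second_line", "second_line",
       source = "FOLFIRI trial"),
    pr("probability", 0.45, 0.41, 0.49, "XELOX", "second_line",
       "supportive_care", source = "FOLFIRI trial"),
    pr("probability", 0.06, 0.04, 0.08, "XELOX", "second_line", "death",
       source = "FOLFIRI trial"),
    pr("probability", 0.75, 0.68, 0.82, "XELOX", "supportive_care",
       "supportive_care", source = "supportive-care trial"),
    pr("probability", 0.25, 0.23, 0.27, "XELOX", "supportive_care", "death",
       source = "supportive-care trial"),
    # transition probabilities, strategy 2
    pr("probability", 0.67, 0.61, 0.73, "XELOX+bevacizumab", "first_line",
       "first_line", source = "assumed 10%"),
    pr("probability", 0.12, 0.10, 0.14, "XELOX+bevacizumab", "first_line",
       "second_line", source = "pooled trials"),
    pr("probability", 0.16, 0.14, 0.18, "XELOX+bevacizumab", "first_line",
       "supportive_care", source = "first-line trial"),
    pr("probability", 0.05, 0.04, 0.06, "XELOX+bevacizumab", "first_line",
       "death", source = "pooled trials"),
    pr("probability", 0.49, 0.45, 0.53, "XELOX+bevacizumab", "second_line",
       "second_line", source = "FOLFIRI trial"),
    pr("probability", 0.45, 0.41, 0.49, "XELOX+bevacizumab", "second_line",
       "supportive_care", source = "FOLFIRI trial"),
    pr("probability", 0.06, 0.04, 0.08, "XELOX+bevacizumab", "second_line",
       "death", source = "FOLFIRI trial"),
    pr("probability", 0.75, 0.68, 0.82, "XELOX+bevacizumab",
       "supportive_care", "supportive_care", source = "supportive-care trial"),
    pr("probability", 0.25, 0.23, 0.27, "XELOX+bevacizumab",
       "supportive_care", "death", source = "supportive-care trial"),
    # discount rate
    pr("discount", 0.05, 0.00, 0.10, source = "national HTA guideline"))

  reference_results <- data.frame(
    strategy = c("XELOX", "XELOX+bevacizumab"),
    cost = c(41396.84, 89230.41),
    effect = c(97.07, 99.32),
    stringsAsFactors = FALSE)

  list(model = model, ranges = ranges,
       reference_results = reference_results,
       gdp_per_capita = 27229)
}
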