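#' Incremental cost-effectiveness ratio with dominance handling
#'
#' Computes `delta_cost / delta_effect` and classifies the degenerate cases:
#' an intervention that gains effectiveness at non-positive extra cost is
#' `dominant`; one that loses (or gains no) effectiveness at positive extra
#' cost is `dominated`; zero increments on both axes are `equivalent`;
#' anything else is `undominated` and carries a finite ratio.
#'
#' @param delta_cost Incremental cost (intervention minus comparator).
#' @param delta_effect Incremental effectiveness, in months.
#' @return A `cea_icer` object: list with `value` (the ratio, `NA` when a
#'   dominance label applies) and `label`. `as.numeric()` extracts the value.
#' @export
icer <- function(delta_cost, delta_effect) {
  label <- if (delta_cost == 0 && delta_effect == 0) {
    "equivalent"
  } else if (delta_effect > 0 && delta_cost <= 0) {
    "dominant"
  } else if (delta_effect <= 0 && delta_cost > 0) {
    "dominated"
  } else {
    "undominated"
  }
  value <- if (label == "undominated") delta_cost / delta_effect else NA_real_
  structure(list(value = value, label = label,
                 delta_cost = delta_cost, delta_effect = delta_effect),
            class = "cea_icer")
}

#' @export
as.double.cea_icer <- function(x, ...) x$value

#' @export
print.cea_icer <- function(x, ...) {
  if (x$label == "undominated")
    cat(sprintf("ICER: %.2f per month (dC = %.2f, dE = %.4f)\n",
                x$value, x$delta_cost, x$delta_effect))
  else
    cat(sprintf("ICER: %s (dC = %.2f, dE = %.4f)\n",
                x$label, x$delta_cost, x$delta_effect))
  invisible(x)
}

#' Convert an ICER per month of life gained to per life-year gained
#'
#' @param icer_per_month ICER in currency per month.
#' @return `icer_per_month * 12`.
#' @export
monthly_to_annual_icer <- function(icer_per_month) {
  stopifnot(is.finite(icer_per_month))
  icer_per_month * 12
}

#' Willingness-to-pay threshold as a multiple of GDP per capita
#'
#' @param gdp_per_capita GDP per capita in currency units.
#' @param multiplier Non-negative multiplier (the WHO-style rule of thumb
#'   uses 3).
#' @return `gdp_per_capita * multiplier`.
#' @export
wtp_threshold <- function(gdp_per_capita, multiplier = 3) {
  stopifnot(gdp_per_capita >= 0, multiplier >= 0)
  gdp_per_capita * multiplier
}

#' Net monetary benefit
#'
#' @param cost Expected cost.
#' @param effect Expected effectiveness in months.
#' @param lambda Willingness-to-pay per month (>= 0).
#' @return `lambda * effect - cost`.
#' @export
nmb <- function(cost, effect, lambda) {
  stopifnot(all(lambda >= 0))
  lambda * effect - cost
}

#' Compare two strategies on expected discounted outcomes
#'
#' Evaluates both strategies of a two-strategy model under the given
#' conventions; the first strategy is the comparator. Increments are
#' intervention minus comparator; the ICER and dominance label follow
#' [icer()].
#'
#' @inheritParams run_cohort
#' @return A `ce_result`: list with `strategies` (data frame of per-strategy
#'   expected cost and effectiveness), `delta_cost`, `delta_effect`, `icer`
#'   (numeric, `NA` under dominance/equivalence) and `label`.
#' @export
compare_strategies <- function(model, conventions = convention_flags()) {
  if (length(model$strategies) != 2L)
    stop("compare_strategies expects exactly two strategies", call. = FALSE)
  outs <- lapply(model$strategies, expected_outcomes, model = model,
                 conventions = conventions)
  tab <- data.frame(
    strategy = names(model$strategies),
    cost = vapply(outs, `[[`, numeric(1), "cost"),
    effect = vapply(outs, `[[`, numeric(1), "effect"),
    row.names = NULL, stringsAsFactors = FALSE)
  dc <- tab$cost[2L] - tab$cost[1L]
  de <- tab$effect[2L] - tab$effect[1L]
  ic <- icer(dc, de)
  structure(list(strategies = tab, delta_cost = dc, delta_effect = de,
                 icer = ic$value, label = ic$label,
                 conventions = conventions),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat("Cost-effectiveness comparison (comparator = first strategy)\n")
  tab <- x$strategies
  tab$cost <- sprintf("%.2f", tab$cost)
  tab$effect <- sprintf("%.2f", tab$effect)
  print(tab, row.names = FALSE)
  if (x$label == "undominated")
    cat(sprintf("  dC = %.2f, dE = %.2f, ICER = %.2f per month\n",
                x$delta_cost, x$delta_effect, x$icer))
  else
    cat(sprintf("  dC = %.2f, dE = %.2f, %s\n",
                x$delta_cost, x$delta_effect, x$label))
  invisible(x)
}

#' Export a comparison as a delimited report table
#'
#' Writes one row per strategy with unrounded values plus 2-decimal display
#' columns, mirroring the usual published layout (cost, incremental cost,
#' effectiveness, incremental effectiveness, ICER).
#'
#' @param result A `ce_result`.
#' @param file CSV path.
#' @return The file path, invisibly.
#' @export
write_ce_report <- function(result, file) {
  tab <- result$strategies
  tab$incremental_cost <- c(NA, result$delta_cost)
  tab$incremental_effect <- c(NA, result$delta_effect)
  tab$icer <- c(NA, result$icer)
  tab$label <- c(NA, result$label)
  for (col in c("cost", "effect", "incremental_cost", "incremental_effect",
                "icer"))
    tab[[paste0(col, "_display")]] <- round(tab[[col]], 2)
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' Search the convention grid for the cell closest to target totals
#'
#' When a published model's accrual and discounting conventions are not
#' stated, the honest alternative to guessing is an exhaustive search: every
#' cell of [convention_grid()] is evaluated on the model and scored by the
#' maximum relative deviation from the target per-strategy (cost,
#' effectiveness) totals. Ties keep the grid enumeration order (stable sort).
#'
#' @param model A two-strategy [model_spec()].
#' @param target Data frame with columns `strategy`, `cost`, `effect` (e.g.
#'   the `reference_results` element of [mcrc_base_case()]).
#' @return A `calibration_result`: the grid data frame with an added `score`
#'   column, sorted ascending by score, plus attribute `best` holding the
#'   best-scoring [convention_flags()].
#' @export
calibrate_conventions <- function(model, target) {
  stopifnot(all(c("strategy", "cost", "effect") %in% names(target)))
  target <- target[match(names(model$strategies), target$strategy), ]
  if (anyNA(target$cost))
    stop("target must cover every strategy in the model", call. = FALSE)
  grid <- convention_grid()
  tgt <- c(target$cost, target$effect)
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    cf <- convention_flags(grid$reward_source[i], grid$accrual_timing[i],
                           grid$cost_timing[i], grid$discount_first_cycle[i],
                           grid$discount_basis[i])
    outs <- lapply(model$strategies, expected_outcomes, model = model,
                   conventions = cf)
    got <- c(vapply(outs, `[[`, numeric(1), "cost"),
             vapply(outs, `[[`, numeric(1), "effect"))
    max(abs(got / tgt - 1))
  }, numeric(1))
  ord <- order(grid$score)            # stable: ties keep enumeration order
  out <- grid[ord, , drop = FALSE]
  rownames(out) <- NULL
  best <- convention_flags(out$reward_source[1L], out$accrual_timing[1L],
                           out$cost_timing[1L], out$discount_first_cycle[1L],
                           out$discount_basis[1L])
  structure(out, best = best, class = c("calibration_result", "data.frame"))
}

#' Best convention flags found by a calibration
#' @param calibration A `calibration_result`.
#' @return The top-ranked [convention_flags()].
#' @export
best_conventions <- function(calibration) attr(calibration, "best")
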