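#' Aggregate micro-costing line items into a per-cycle cost breakdown
#'
#' Bottom-up costing: itemized resource-use amounts (drug vials, infusion-bag
#' preparations, nursing time, tests, bed-days) are summed within the fixed
#' category set and expressed as a per-cycle breakdown with category shares.
#'
#' @param line_items Data frame with columns `category` and `amount`, or a
#'   list of `(category, amount)` pairs.
#' @return A [cost_breakdown()] with attributes `total` and `shares`
#'   (percentage per category, rounded to 2 decimals). An empty input yields
#'   total 0 with `NA` shares and attribute `undefined_shares = TRUE`.
#' @examples
#' aggregate_cycle_cost(data.frame(
#'   category = c("medications", "laboratory_tests"),
#'   amount = c(6428, 265.48)))
#' @export
aggregate_cycle_cost <- function(line_items) {
  if (is.list(line_items) && !is.data.frame(line_items))
    line_items <- do.call(rbind, lapply(line_items, function(it)
      data.frame(category = it[[1L]], amount = as.numeric(it[[2L]]),
                 stringsAsFactors = FALSE)))
  if (is.null(line_items) || nrow(line_items) == 0L) {
    out <- cost_breakdown()
    attr(out, "shares") <- stats::setNames(
      rep(NA_real_, length(cost_categories())), cost_categories())
    attr(out, "undefined_shares") <- TRUE
    return(out)
  }
  stopifnot(all(c("category", "amount") %in% names(line_items)))
  if (any(line_items$amount < 0))
    stop("line-item amounts must be non-negative", call. = FALSE)
  unknown <- setdiff(unique(line_items$category), cost_categories())
  if (length(unknown) > 0L)
    stop("unknown cost category: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sums <- tapply(line_items$amount, factor(line_items$category,
                                           levels = cost_categories()), sum)
  sums[is.na(sums)] <- 0
  out <- cost_breakdown(amounts = stats::setNames(as.numeric(sums),
                                                  cost_categories()))
  tot <- total_cost(out)
  shares <- if (tot > 0) round(100 * unclass(out) / tot, 2) else
    stats::setNames(rep(NA_real_, length(out)), names(out))
  attr(out, "shares") <- shares
  if (tot == 0) attr(out, "undefined_shares") <- TRUE
  out
}

#' Category shares of an aggregated cost breakdown
#' @param x A `cost_breakdown` produced by [aggregate_cycle_cost()].
#' @return Named numeric vector of percentages (2 decimals).
#' @export
cost_shares <- function(x) attr(x, "shares")

#' Compound inflationary adjustment
#'
#' Brings a retrospectively collected cost forward by `n_years` of compound
#' inflation at `annual_rate` (e.g. drug acquisition costs collected over
#' several years and expressed in a single reference year).
#'
#' @param amount Cost in currency units.
#' @param annual_rate Annual inflation rate as a fraction.
#' @param n_years Non-negative integer number of years.
#' @return `amount * (1 + annual_rate)^n_years`.
#' @export
inflation_adjust <- function(amount, annual_rate, n_years) {
  if (any(n_years < 0)) stop("n_years must be >= 0", call. = FALSE)
  amount * (1 + annual_rate)^n_years
}

#' Per-cycle hospitalization cost from a daily bed rate
#'
#' @param day_rate Cost per hospitalization day.
#' @param days_per_month Hospitalization days per month.
#' @param months_per_cycle Months per model cycle.
#' @return `day_rate * days_per_month * months_per_cycle`.
#' @export
hospitalization_cycle_cost <- function(day_rate, days_per_month,
                                       months_per_cycle) {
  stopifnot(day_rate >= 0, days_per_month >= 0, months_per_cycle >= 0)
  day_rate * days_per_month * months_per_cycle
}
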