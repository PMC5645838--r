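#' Configuration for the synthetic model generator
#'
#' @param seed Integer seed.
#' @param n_states Number of states including the single absorbing state
#'   (>= 2).
#' @param n_strategies Number of strategies (>= 1).
#' @param cost_scale Typical per-cycle state cost (currency, > 0).
#' @param reward_scale Typical per-state effectiveness reward (months, > 0).
#' @param range_width_fraction Half-width of generated sensitivity ranges as
#'   a fraction of the base value, in `[0, 1)`.
#' @param forward_only If `TRUE` (default) transitions are forward-only
#'   (upper-triangular plus absorption), mirroring a progressive disease
#'   pathway; `FALSE` generates a dense stochastic matrix for engine stress
#'   tests.
#' @return A `generator_config` object.
#' @export
generator_config <- function(seed = 1L, n_states = 4L, n_strategies = 2L,
                             cost_scale = 10000, reward_scale = 18,
                             range_width_fraction = 0.1,
                             forward_only = TRUE) {
  stopifnot(n_states >= 2L, n_strategies >= 1L, cost_scale > 0,
            reward_scale > 0,
            range_width_fraction >= 0, range_width_fraction < 1)
  structure(list(seed = as.integer(seed), n_states = as.integer(n_states),
                 n_strategies = as.integer(n_strategies),
                 cost_scale = cost_scale, reward_scale = reward_scale,
                 range_width_fraction = range_width_fraction,
                 forward_only = isTRUE(forward_only)),
            class = "generator_config")
}

#' Generate a random but valid model specification
#'
#' Produces a [model_spec()] with the structural properties the analysis
#' assumes: one absorbing death state, row-stochastic transition matrices
#' (forward-only by default, with every transient state carrying positive
#' death probability), positive per-cycle state costs broken down over the
#' six costing categories, positive effectiveness rewards, and mean-centred
#' sensitivity ranges (`base * (1 +/- width)`, probability ranges clipped to
#' `[0, 1]`). Reproducible under the config seed.
#'
#' @param config A [generator_config()].
#' @return List with `model` (a validated [model_spec()]) and `ranges`.
#' @export
generate_model <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  S <- config$n_states
  nm <- c(paste0("state_", seq_len(S - 1L)), "death")
  states <- c(lapply(seq_len(S - 1L), function(i)
    health_state(nm[i], order_index = i)),
    list(health_state("death", absorbing = TRUE, order_index = S)))
  cats <- cost_categories()
  w <- config$range_width_fraction

  make_strategy <- function(si) {
    P <- matrix(0, S, S, dimnames = list(nm, nm))
    for (i in seq_len(S - 1L)) {
      reach <- if (config$forward_only) i:S else seq_len(S)
      raw <- stats::rexp(length(reach)) + 0.05  # keep death prob positive
      P[i, reach] <- raw / sum(raw)
    }
    P[S, S] <- 1
    costs <- stats::setNames(lapply(seq_len(S - 1L), function(i) {
      tot <- config$cost_scale * stats::rlnorm(1L, 0, 0.4)
      split <- stats::rexp(length(cats))
      cost_breakdown(amounts = stats::setNames(tot * split / sum(split), cats))
    }), nm[-S])
    rewards <- stats::setNames(
      config$reward_scale * stats::runif(S - 1L, 0.5, 1.5), nm[-S])
    strategy_spec(paste0("strategy_", si), P, costs, rewards)
  }
  strategies <- lapply(seq_len(config$n_strategies), make_strategy)
  model <- model_spec(states, strategies)

  ranges <- do.call(rbind, unlist(recursive = FALSE, lapply(strategies,
    function(st) {
      c(
        lapply(nm[-S], function(s) {
          base <- total_cost(st$state_costs[[s]])
          parameter_range("cost", base, base * (1 - w), base * (1 + w),
                          st$name, s, source = "synthetic")
        }),
        lapply(nm[-S], function(s) {
          base <- st$state_rewards[[s]]
          parameter_range("effectiveness", base, base * (1 - w),
                          base * (1 + w), st$name, s, source = "synthetic")
        }),
        unlist(recursive = FALSE, lapply(nm[-S], function(i) {
          to <- colnames(st$transition)[st$transition[i, ] > 0]
          lapply(to, function(j) {
            base <- st$transition[i, j]
            parameter_range("probability", base,
                            max(0, base * (1 - w)), min(1, base * (1 + w)),
                            st$name, i, j, source = "synthetic")
          })
        })))
    })))
  list(model = model, ranges = ranges)
}

#' Generate a synthetic micro-costing ledger hitting exact category totals
#'
#' Emulates an itemized hospital costing extract: for every non-zero category
#' it draws `n` positive line items, rescales them to the requested category
#' total, rounds to whole cents and lets the last item absorb the rounding
#' residual, so that [aggregate_cycle_cost()] recovers the totals exactly.
#'
#' @param seed Integer seed.
#' @param category_totals A [cost_breakdown()] (or named vector) of target
#'   totals.
#' @param n_items Total number of line items; must be at least the number of
#'   non-zero categories.
#' @return Data frame with columns `category`, `amount`.
#' @export
generate_microcosting <- function(seed, category_totals, n_items) {
  set.seed(seed)
  totals <- if (inherits(category_totals, "cost_breakdown"))
    unclass(category_totals) else cost_breakdown(amounts = category_totals)
  totals <- unclass(totals)[cost_categories()]
  nz <- names(totals)[totals > 0]
  if (n_items < length(nz))
    stop("n_items must be at least the number of non-zero categories",
         call. = FALSE)
  if (length(nz) == 0L)
    return(data.frame(category = character(0), amount = numeric(0)))
  # distribute items: one per non-zero category, remainder at random
  counts <- stats::setNames(rep(1L, length(nz)), nz)
  extra <- n_items - length(nz)
  if (extra > 0L) {
    add <- table(sample(nz, extra, replace = TRUE))
    counts[names(add)] <- counts[names(add)] + as.integer(add)
  }
  items <- lapply(nz, function(cat) {
    m <- counts[[cat]]
    raw <- stats::rexp(m) + 0.01
    amt <- round(totals[[cat]] * raw / sum(raw), 2)
    # the largest item absorbs the rounding residual so no item goes negative
    big <- which.max(amt)
    amt[big] <- round(amt[big] + (totals[[cat]] - sum(amt)), 2)
    data.frame(category = cat, amount = amt, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, items)
  rownames(out) <- NULL
  out
}
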