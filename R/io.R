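#' Write a model specification as a directory of delimited tables
#'
#' The on-disk dialect mirrors the way decision-model parameters are
#' published: one table per section, as UTF-8 CSV with dot decimal separator.
#' Files written: `settings.csv` (key/value), `states.csv`,
#' `transitions.csv` (strategy, from, to, probability), `costs.csv`
#' (strategy, state, category, amount), `rewards.csv` (strategy, state,
#' reward), `entry_costs.csv` (only when any are non-zero) and, when
#' `ranges` is supplied, `ranges.csv`.
#'
#' @param model A [model_spec()].
#' @param path Directory to write into (created if missing).
#' @param ranges Optional data frame of [parameter_range()] rows.
#' @return `path`, invisibly.
#' @export
write_model_spec <- function(model, path, ranges = NULL) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f)
    utils::write.csv(x, file.path(path, f), row.names = FALSE)

  wcsv(data.frame(key = c("horizon_cycles", "cycle_length_months",
                          "annual_discount_rate"),
                  value = c(model$horizon_cycles, model$cycle_length_months,
                            model$annual_discount_rate)), "settings.csv")
  st <- model$states
  st$initial_occupancy <- unname(model$initial_occupancy[st$name])
  wcsv(st, "states.csv")

  nm <- model$states$name
  trans <- do.call(rbind, lapply(model$strategies, function(s) {
    g <- expand.grid(from = nm, to = nm, stringsAsFactors = FALSE)
    g$strategy <- s$name
    g$probability <- s$transition[cbind(g$from, g$to)]
    g[g$probability != 0, c("strategy", "from", "to", "probability")]
  }))
  wcsv(trans, "transitions.csv")

  costs <- do.call(rbind, lapply(model$strategies, function(s) {
    do.call(rbind, lapply(nm, function(state) {
      b <- unclass(s$state_costs[[state]])
      keep <- b != 0
      if (!any(keep)) return(NULL)
      data.frame(strategy = s$name, state = state,
                 category = names(b)[keep], amount = unname(b[keep]),
                 stringsAsFactors = FALSE)
    }))
  }))
  wcsv(costs, "costs.csv")

  rewards <- do.call(rbind, lapply(model$strategies, function(s)
    data.frame(strategy = s$name, state = nm,
               reward = unname(s$state_rewards[nm]),
               stringsAsFactors = FALSE)))
  wcsv(rewards[rewards$reward != 0, ], "rewards.csv")

  entries <- do.call(rbind, lapply(model$strategies, function(s)
    data.frame(strategy = s$name, state = nm,
               amount = unname(s$entry_costs[nm]), stringsAsFactors = FALSE)))
  if (any(entries$amount != 0)) wcsv(entries[entries$amount != 0, ],
                                     "entry_costs.csv")
  if (!is.null(ranges)) wcsv(ranges, "ranges.csv")
  invisible(path)
}

#' Read and validate a model specification from delimited tables
#'
#' Reads the dialect written by [write_model_spec()] and rebuilds a validated
#' [model_spec()]; every transition-matrix and occupancy invariant is
#' enforced, and a violated row is reported by name.
#'
#' @param path Directory containing the tables.
#' @return List with `model` and `ranges` (`NULL` when no `ranges.csv` is
#'   present).
#' @export
read_model_spec <- function(path) {
  rcsv <- function(f, required = TRUE) {
    fp <- file.path(path, f)
    if (!file.exists(fp)) {
      if (required) stop("missing parameter table: ", f, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(fp, stringsAsFactors = FALSE)
  }
  settings <- rcsv("settings.csv")
  get <- function(key) {
    v <- settings$value[settings$key == key]
    if (length(v) != 1L) stop("settings.csv must define ", key, call. = FALSE)
    as.numeric(v)
  }
  st <- rcsv("states.csv")
  states <- lapply(seq_len(nrow(st)), function(i)
    health_state(st$name[i], as.logical(st$absorbing[i]), st$order_index[i]))
  nm <- st$name

  trans <- rcsv("transitions.csv")
  costs <- rcsv("costs.csv")
  rewards <- rcsv("rewards.csv")
  entries <- rcsv("entry_costs.csv", required = FALSE)

  strategies <- lapply(unique(trans$strategy), function(sname) {
    P <- matrix(0, length(nm), length(nm), dimnames = list(nm, nm))
    tr <- trans[trans$strategy == sname, ]
    bad <- !(tr$from %in% nm) | !(tr$to %in% nm)
    if (any(bad))
      stop("transitions.csv references unknown state: ",
           paste(unique(c(tr$from[bad], tr$to[bad])), collapse = ", "),
           call. = FALSE)
    P[cbind(tr$from, tr$to)] <- tr$probability
    cs <- costs[costs$strategy == sname, ]
    state_costs <- lapply(split(cs, cs$state), function(d)
      cost_breakdown(amounts = stats::setNames(d$amount, d$category)))
    rw <- rewards[rewards$strategy == sname, ]
    state_rewards <- stats::setNames(rw$reward, rw$state)
    ec <- NULL
    if (!is.null(entries)) {
      e <- entries[entries$strategy == sname, ]
      if (nrow(e) > 0L) ec <- stats::setNames(e$amount, e$state)
    }
    strategy_spec(sname, P, state_costs, state_rewards, ec)
  })

  init <- stats::setNames(st$initial_occupancy, nm)
  model <- model_spec(states, strategies,
                      horizon_cycles = get("horizon_cycles"),
                      cycle_length_months = get("cycle_length_months"),
                      annual_discount_rate = get("annual_discount_rate"),
                      initial_occupancy = init)
  ranges <- rcsv("ranges.csv", required = FALSE)
  list(model = model, ranges = ranges)
}

#' Write a plain-text validation report for a model directory
#'
#' Attempts to load the model and reports either the validated structure or
#' the first violated invariant.
#'
#' @param path Model directory, as for [read_model_spec()].
#' @param file Output text file.
#' @return `TRUE` if the model validated, `FALSE` otherwise, invisibly.
#' @export
validation_report <- function(path, file) {
  lines <- c(sprintf("validation report for %s", path))
  ok <- TRUE
  res <- tryCatch(read_model_spec(path), error = function(e) e)
  if (inherits(res, "error")) {
    ok <- FALSE
    lines <- c(lines, paste("FAIL:", conditionMessage(res)))
  } else {
    m <- res$model
    lines <- c(lines,
      sprintf("OK: %d states (%s absorbing)", nrow(m$states),
              m$states$name[m$states$absorbing]),
      sprintf("OK: %d strategies: %s", length(m$strategies),
              paste(names(m$strategies), collapse = ", ")),
      sprintf("OK: horizon %d cycles x %g months, discount %.4f",
              m$horizon_cycles, m$cycle_length_months,
              m$annual_discount_rate),
      "OK: all transition rows sum to 1 within 1e-9",
      if (!is.null(res$ranges))
        sprintf("OK: %d sensitivity ranges", nrow(res$ranges)))
  }
  writeLines(lines, file)
  invisible(ok)
}
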