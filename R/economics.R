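# Discounting, reward accumulation, ICER, dominance, net monetary benefit.

#' Discount factor at a cycle
#'
#' `(1 + rate)^(-t)`: cycle 0 is undiscounted, later cycles discounted at
#' the annual rate applied to both costs and QALYs.
#'
#' @param rate annual discount rate, non-negative.
#' @param t cycle index (vectorised), non-negative.
#' @return discount factor(s) in (0, 1].
#' @export
discount_factor <- function(rate, t) {
  if (rate < 0) abort("discount rate must be >= 0", "afcua_domain_error")
  if (any(t < 0)) abort("cycle index must be >= 0", "afcua_domain_error")
  (1 + rate)^(-t)
}

#' Construct a reward schedule
#'
#' Per-cycle state rewards (cost and utility per year of occupancy, accrued
#' at the start of each cycle) plus one-off entry rewards (cost and utility
#' decrement applied to the mass newly arriving in a state, in the arrival
#' cycle). Death accrues nothing.
#'
#' @param states state names, matching the model's state space.
#' @param state_costs,state_utilities per-cycle rewards, one per state;
#'   utilities in `[0,1]`, costs non-negative.
#' @param entry_costs,entry_disutilities one-off rewards per unit of
#'   arriving mass; disutilities non-positive.
#' @return a `cua_rewards`.
#' @export
reward_schedule <- function(states, state_costs, state_utilities,
                            entry_costs = numeric(length(states)),
                            entry_disutilities = numeric(length(states))) {
  n <- length(states)
  if (length(state_costs) != n || length(state_utilities) != n ||
      length(entry_costs) != n || length(entry_disutilities) != n)
    abort("reward vectors must have one entry per state",
          "afcua_schedule_error")
  if (any(state_costs < 0) || any(entry_costs < -1e-12))
    abort("state and entry costs must be non-negative",
          "afcua_schedule_error")
  if (any(state_utilities < 0 | state_utilities > 1))
    abort("state utilities must lie in [0,1]", "afcua_schedule_error")
  if (any(entry_disutilities > 1e-12))
    abort("entry disutilities must be <= 0", "afcua_schedule_error")
  structure(list(states = states,
                 state_costs = as.numeric(state_costs),
                 state_utilities = as.numeric(state_utilities),
                 entry_costs = stats::setNames(as.numeric(entry_costs),
                                               states),
                 entry_disutilities = stats::setNames(
                   as.numeric(entry_disutilities), states)),
            class = "cua_rewards")
}

#' Accumulate discounted rewards over a cohort trace
#'
#' `cost = sum_t w(t) df(t) [occ(t,.) . state_costs + arr(t,.) . entry_costs]`
#' and analogously for QALYs with utilities and entry disutilities, where
#' `df(t) = (1 + r)^(-t)`. Under the default end-of-cycle timing
#' (`settings$reward_timing = "end"`) state rewards count occupancy at
#' cycles 1..T -- the year spent in a state is valued once the cycle has
#' been lived, so the notional cycle-0 pre-procedure year accrues nothing;
#' `"start"` gives the start-of-cycle convention (cycles 0..T all accrue).
#' One-off entry rewards are always charged in the arrival cycle (the index
#' procedure at cycle 0 is undiscounted under both conventions). `w(t)` is
#' 1 everywhere, or 1/2 at the first and last accruing cycle when the
#' optional half-cycle correction is on.
#'
#' @param trace a `cua_trace`.
#' @param rewards a `cua_rewards` over the same state space.
#' @param settings list with `discount_rate` and optional `reward_timing`
#'   (`"end"`, the default, or `"start"`) and `half_cycle_correction` flag.
#' @return list with discounted lifetime `cost` and `qalys`.
#' @export
accumulate <- function(trace, rewards, settings) {
  if (!identical(trace$states, rewards$states))
    abort("trace and reward schedule are defined over different states",
          "afcua_schedule_error")
  timing <- settings$reward_timing
  if (is.null(timing)) timing <- "end"
  if (!timing %in% c("start", "end"))
    abort("reward_timing must be 'start' or 'end'", "afcua_config_error")
  n <- nrow(trace$occupancy)
  df <- discount_factor(settings$discount_rate, seq_len(n) - 1L)
  w <- rep(1, n)
  if (timing == "end") w[1] <- 0
  if (isTRUE(settings$half_cycle_correction)) {
    first <- if (timing == "end") 2L else 1L
    w[first] <- w[first] / 2
    w[n] <- w[n] / 2
  }
  wdf <- w * df
  cost <- sum(wdf * (trace$occupancy %*% rewards$state_costs)) +
    sum(df * (trace$arrivals %*% rewards$entry_costs))
  qalys <- sum(wdf * (trace$occupancy %*% rewards$state_utilities)) +
    sum(df * (trace$arrivals %*% rewards$entry_disutilities))
  list(cost = cost, qalys = qalys)
}

#' Incremental cost-effectiveness of one strategy against another
#'
#' Computes `delta_cost = cost_a - cost_b`, `delta_eff = qalys_a - qalys_b`,
#' the ICER `delta_cost / delta_eff` (undefined, reported as `NA`, when
#' `delta_eff = 0`), and a verdict at the willingness-to-pay threshold:
#' `dominant` if cheaper and more effective, `dominated` if costlier and
#' less effective, otherwise cost-effective exactly when the incremental
#' net monetary benefit `wtp * delta_eff - delta_cost` is positive. With
#' `delta_eff = 0` the verdict falls back to the cost sign alone.
#'
#' @param a,b `cua_strategy_result`s (or any list with `cost`, `qalys`,
#'   and optionally `strategy`); `a` is the evaluated strategy, `b` the
#'   comparator.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @return a `cua_ce_result` with fields `strategy`, `comparator`,
#'   `delta_cost`, `delta_eff`, `icer`, `nmb_diff`, `verdict`.
#' @examples
#' a <- list(strategy = "A", cost = 200, qalys = 2)
#' b <- list(strategy = "B", cost = 100, qalys = 1)
#' compute_icer(a, b, wtp = 7142)
#' @export
compute_icer <- function(a, b, wtp) {
  dc <- a$cost - b$cost
  de <- a$qalys - b$qalys
  icer <- if (de != 0) dc / de else NA_real_
  nmb_diff <- wtp * de - dc
  verdict <-
    if (dc < 0 && de > 0) "dominant"
    else if (dc > 0 && de < 0) "dominated"
    else if (de == 0) {
      if (dc < 0) "cost_effective_at_wtp" else "not_cost_effective_at_wtp"
    }
    else if (nmb_diff > 0) "cost_effective_at_wtp"
    else "not_cost_effective_at_wtp"
  structure(list(strategy = if (is.null(a$strategy)) "A" else a$strategy,
                 comparator = if (is.null(b$strategy)) "B" else b$strategy,
                 delta_cost = dc, delta_eff = de, icer = icer,
                 nmb_diff = nmb_diff, wtp = wtp, verdict = verdict),
            class = "cua_ce_result")
}

#' Net monetary benefit
#'
#' `wtp * qalys - cost`. Comparing two strategies' NMB at a threshold is
#' algebraically equivalent to the ICER-vs-threshold verdict.
#'
#' @param result a `cua_strategy_result` (or list with `cost` and `qalys`).
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @return NMB in USD.
#' @export
net_monetary_benefit <- function(result, wtp) {
  wtp * result$qalys - result$cost
}

#' @export
print.cua_ce_result <- function(x, ...) {
  cat(sprintf("%s vs %s at WTP $%s/QALY\n", x$strategy, x$comparator,
              format(x$wtp, big.mark = ",")))
  cat(sprintf("  incremental cost  $%.2f\n", x$delta_cost))
  cat(sprintf("  incremental QALYs %.4f\n", x$delta_eff))
  cat(sprintf("  ICER              %s\n",
              if (is.na(x$icer)) "undefined (no QALY difference)"
              else sprintf("$%.2f/QALY", x$icer)))
  cat(sprintf("  verdict           %s\n", x$verdict))
  invisible(x)
}
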