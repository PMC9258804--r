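# Strategy-specific Markov models for catheter ablation of paroxysmal AF.
#
# Health states: AF pre-intervention (cycle 0 only; the index ablation
# happens within it), NSR after the index ablation, AF post-intervention (a
# one-cycle tunnel in which the single permitted re-intervention is
# applied), NSR after a re-ablation (relapse from here gets no further
# procedure), AF post-re-intervention (terminal medicated AF), post-stroke,
# and death. The second NSR copy is what lets a memoryless cohort enforce
# the single-re-ablation rule exactly. Background mortality is age-indexed
# from the life table; competing exits within a cycle are combined on the
# rate scale so rows stay stochastic.

af_states <- function() {
  c("af_pre", "nsr", "af_post", "nsr_redone", "af_post_redo",
    "post_stroke", "death")
}

# Competing-risk allocation for one row, vectorised over cycles.
# rd: total death rate; rs: stroke onset rate; psd: fatality at stroke entry.
# Returns per-cycle probabilities (to_death, to_stroke, surv).
compete_exits <- function(rd, rs, psd) {
  rtot <- rd + rs
  surv <- exp(-rtot)
  p_exit <- 1 - surv
  frac_d <- rep(1, length(rtot))
  pos <- is.finite(rtot) & rtot > 0
  frac_d[pos] <- rd[pos] / rtot[pos]
  frac_d[is.infinite(rs) & is.finite(rd)] <- 0
  stroke_branch <- p_exit * (1 - frac_d)
  list(to_death = p_exit * frac_d + stroke_branch * psd,
       to_stroke = stroke_branch * (1 - psd),
       surv = surv)
}

# Rate of an annual probability, tolerating p = 1 (infinite rate) because
# terminal life-table ages and degenerate tests use it.
as_rate <- function(p) ifelse(p >= 1, Inf, -log(1 - p))

#' Build one strategy's Markov model
#'
#' Assembles the six-state space, the cycle-indexed transition array, the
#' initial occupancy (whole cohort in AF pre-intervention), and the reward
#' schedule for one ablation strategy. The index procedure's cost,
#' probability-weighted complication costs/disutility and operative death
#' apply at cycle 0. First-cycle transitions send survivors to NSR or, with
#' the first-year recurrence probability, to AF post-intervention. NSR
#' relapses at the late recurrence probability per year into the same
#' tunnel. AF post-intervention is a one-cycle tunnel: entrants receive the
#' single permitted re-intervention, split between RFA and CBA, each
#' modality charging its own procedure cost and applying its own first-year
#' recurrence, complications and operative death; failures and the
#' never-re-ablated remainder exit to terminal medicated AF. Successful
#' re-ablation leads to a second NSR state whose relapses go straight to
#' terminal medicated AF (no third procedure). Stroke risk applies from the
#' AF states (and optionally from NSR), with stroke-specific mortality at
#' entry, a first-year stroke cost/disutility in the entry cycle, then
#' chronic post-stroke cost and utility.
#'
#' @param bundle a validated `cua_bundle` (both arms are needed because a
#'   re-intervention may use the other modality).
#' @param strategy `"cba"` or `"rfa"`.
#' @return a `cua_model`: list with `space`, `matrices` (an
#'   `S x S x cycles` array), `initial`, `rewards`, `start_age`, `cycles`.
#' @export
build_model <- function(bundle, strategy = c("cba", "rfa")) {
  strategy <- match.arg(strategy)
  own <- bundle[[strategy]]
  sh <- bundle$shared
  v <- function(par) par$base
  space <- state_space(af_states())
  S <- length(space$states)
  T <- horizon_cycles(bundle)
  start_age <- v(sh$start_age)
  q_bg <- mortality(bundle$life_table, start_age + seq_len(T) - 1)
  r_bg <- as_rate(q_bg)

  psd <- v(sh$p_stroke_death)
  r_stroke <- as_rate(v(own$p_stroke))
  r_stroke_nsr <- if (isTRUE(bundle$settings$stroke_from_nsr)) r_stroke else 0
  w_rfa <- v(own$p_redo_rfa)
  w_cba <- v(own$p_redo_cba)
  w <- w_rfa + w_cba
  p1_own <- v(own$p_recur_y1)
  p1_rfa <- v(bundle$rfa$p_recur_y1)
  p1_cba <- v(bundle$cba$p_recur_y1)
  if (w > 1 + 1e-12)
    abort("re-intervention probabilities exceed 1; cannot normalise exits",
          "afcua_validation_error")

  P <- array(0, dim = c(S, S, T),
             dimnames = list(space$states, space$states, NULL))
  i <- function(s) match(s, space$states)

  # AF pre-intervention: index ablation within the cycle (operative death
  # combined with background mortality), then recurrence split.
  e <- compete_exits(r_bg + as_rate(v(sh$p_op_death)), r_stroke, psd)
  P[i("af_pre"), i("death"), ] <- e$to_death
  P[i("af_pre"), i("post_stroke"), ] <- e$to_stroke
  P[i("af_pre"), i("af_post"), ] <- e$surv * p1_own
  P[i("af_pre"), i("nsr"), ] <- e$surv * (1 - p1_own)

  # NSR after the index ablation: background death, optional stroke, late
  # relapse into the re-intervention tunnel.
  e <- compete_exits(r_bg, r_stroke_nsr, psd)
  p_late <- v(own$p_recur_late)
  P[i("nsr"), i("death"), ] <- e$to_death
  P[i("nsr"), i("post_stroke"), ] <- e$to_stroke
  P[i("nsr"), i("af_post"), ] <- e$surv * p_late
  P[i("nsr"), i("nsr"), ] <- e$surv * (1 - p_late)

  # AF post-intervention (tunnel): the re-intervention split happens here.
  e <- compete_exits(r_bg + as_rate(w * v(sh$p_op_death)), r_stroke, psd)
  redo_success <- w_rfa * (1 - p1_rfa) + w_cba * (1 - p1_cba)
  P[i("af_post"), i("death"), ] <- e$to_death
  P[i("af_post"), i("post_stroke"), ] <- e$to_stroke
  P[i("af_post"), i("nsr_redone"), ] <- e$surv * redo_success
  P[i("af_post"), i("af_post_redo"), ] <- e$surv * (1 - redo_success)

  # NSR after a successful re-ablation: behaves like NSR except relapse is
  # terminal medicated AF (no third procedure).
  e <- compete_exits(r_bg, r_stroke_nsr, psd)
  P[i("nsr_redone"), i("death"), ] <- e$to_death
  P[i("nsr_redone"), i("post_stroke"), ] <- e$to_stroke
  P[i("nsr_redone"), i("af_post_redo"), ] <- e$surv * p_late
  P[i("nsr_redone"), i("nsr_redone"), ] <- e$surv * (1 - p_late)

  # Terminal medicated AF after the re-intervention opportunity.
  e <- compete_exits(r_bg, r_stroke, psd)
  P[i("af_post_redo"), i("death"), ] <- e$to_death
  P[i("af_post_redo"), i("post_stroke"), ] <- e$to_stroke
  P[i("af_post_redo"), i("af_post_redo"), ] <- e$surv

  # Chronic post-stroke: background mortality only (the acute case fatality
  # was applied at entry).
  e <- compete_exits(r_bg, 0, psd)
  P[i("post_stroke"), i("death"), ] <- e$to_death
  P[i("post_stroke"), i("post_stroke"), ] <- e$surv

  P[i("death"), i("death"), ] <- 1

  initial <- as.numeric(space$states == "af_pre")

  compl_p <- function(blk) v(blk$p_pericardial) + v(blk$p_phrenic) +
    v(blk$p_vascular)
  compl_cost <- function(blk)
    v(blk$p_pericardial) * v(blk$cost_pericardial) +
    v(blk$p_phrenic) * v(blk$cost_phrenic) +
    v(blk$p_vascular) * v(blk$cost_vascular)
  procedure_bill <- function(blk) v(blk$cost_procedure) + compl_cost(blk)

  rewards <- reward_schedule(
    states = space$states,
    state_costs = c(v(sh$cost_af_annual), v(sh$cost_nsr_annual),
                    v(sh$cost_af_annual), v(sh$cost_nsr_annual),
                    v(sh$cost_af_annual), v(sh$cost_poststroke), 0),
    state_utilities = c(v(sh$u_af), v(sh$u_nsr), v(sh$u_af), v(sh$u_nsr),
                        v(sh$u_af), v(sh$u_poststroke), 0),
    entry_costs = c(
      af_pre = procedure_bill(own),
      nsr = 0,
      af_post = w_rfa * procedure_bill(bundle$rfa) +
                w_cba * procedure_bill(bundle$cba),
      nsr_redone = 0,
      af_post_redo = 0,
      post_stroke = v(sh$cost_stroke_y1) - v(sh$cost_poststroke),
      death = 0),
    entry_disutilities = c(
      af_pre = v(sh$du_complication) * compl_p(own),
      nsr = 0,
      af_post = v(sh$du_complication) *
        (w_rfa * compl_p(bundle$rfa) + w_cba * compl_p(bundle$cba)),
      nsr_redone = 0,
      af_post_redo = 0,
      post_stroke = v(sh$du_stroke_y1),
      death = 0))

  structure(list(space = space, matrices = P, initial = initial,
                 rewards = rewards, start_age = start_age, cycles = T,
                 strategy = strategy),
            class = "cua_model")
}

#' Discounted lifetime cost and QALYs for one strategy
#'
#' Composes [build_model()], [run_cohort()] and [accumulate()].
#'
#' @inheritParams build_model
#' @return a `cua_strategy_result`: list with `strategy`, `cost` (discounted
#'   lifetime USD), `qalys`, and the underlying `trace`.
#' @export
strategy_outcomes <- function(bundle, strategy = c("cba", "rfa")) {
  strategy <- match.arg(strategy)
  model <- build_model(bundle, strategy)
  trace <- run_cohort(model$space, model$matrices, model$initial,
                      model$cycles, start_age = model$start_age)
  res <- accumulate(trace, model$rewards, bundle$settings)
  structure(list(strategy = toupper(strategy), cost = res$cost,
                 qalys = res$qalys, trace = trace),
            class = "cua_strategy_result")
}

#' Export a model summary as JSON
#'
#' States, reward schedule, initial occupancy, and (optionally) the first
#' `k` per-cycle transition matrices.
#'
#' @param model a `cua_model` from [build_model()].
#' @param path output JSON path.
#' @param k number of leading cycles whose matrices are included.
#' @return `path`, invisibly.
#' @export
write_model_summary <- function(model, path, k = 3) {
  k <- min(k, model$cycles)
  out <- list(
    strategy = model$strategy,
    states = model$space$states,
    absorbing = model$space$absorbing,
    start_age = model$start_age,
    cycles = model$cycles,
    initial = model$initial,
    rewards = list(
      state_costs = as.list(stats::setNames(model$rewards$state_costs,
                                            model$space$states)),
      state_utilities = as.list(stats::setNames(model$rewards$state_utilities,
                                                model$space$states)),
      entry_costs = as.list(model$rewards$entry_costs),
      entry_disutilities = as.list(model$rewards$entry_disutilities)),
    matrices = lapply(seq_len(k), function(t)
      apply(model$matrices[, , t], 1, as.list)))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @export
print.cua_strategy_result <- function(x, ...) {
  cat(sprintf("%s: discounted lifetime cost $%.2f, %.3f QALYs\n",
              x$strategy, x$cost, x$qalys))
  invisible(x)
}
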