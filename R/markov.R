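# Generic Markov cohort machinery: state spaces, cycle-indexed transition
# matrices, cohort traces, and an individual-level microsimulation oracle.

#' Define a Markov state space
#'
#' @param states character vector of unique state names.
#' @param absorbing character vector of absorbing states; must be a subset
#'   of `states` and contain exactly one state named `"death"`.
#' @return a `cua_state_space`.
#' @export
state_space <- function(states, absorbing = "death") {
  if (anyDuplicated(states))
    abort("state names must be unique", "afcua_validation_error")
  if (!all(absorbing %in% states))
    abort("absorbing states must be a subset of the state list",
          "afcua_validation_error")
  if (sum(states == "death") != 1 || !"death" %in% absorbing)
    abort("state space must contain exactly one absorbing 'death' state",
          "afcua_validation_error")
  structure(list(states = states, absorbing = absorbing),
            class = "cua_state_space")
}

# Validate one per-cycle transition matrix: square over the state space,
# rows stochastic to 1e-9, absorbing rows unit vectors onto themselves.
validate_transition_matrix <- function(m, space, cycle) {
  S <- length(space$states)
  if (!is.matrix(m) || nrow(m) != S || ncol(m) != S)
    abort(sprintf("cycle %d: transition matrix must be %dx%d", cycle, S, S),
          "afcua_matrix_error")
  if (any(m < -1e-12))
    abort(sprintf("cycle %d: negative transition probability", cycle),
          "afcua_matrix_error")
  rs <- rowSums(m)
  bad <- which(abs(rs - 1) > 1e-9)
  if (length(bad))
    abort(sprintf(
      "cycle %d: row for state '%s' sums to %.12g, not 1",
      cycle, space$states[bad[1]], rs[bad[1]]), "afcua_matrix_error")
  for (a in space$absorbing) {
    i <- match(a, space$states)
    if (abs(m[i, i] - 1) > 1e-9)
      abort(sprintf("cycle %d: absorbing state '%s' row is not a unit vector",
                    cycle, a), "afcua_matrix_error")
  }
  invisible(m)
}

# Accept either a function(cycle) -> matrix (cycle in 0..cycles-1) or a
# precomputed S x S x cycles array.
matrix_at <- function(matrices, t) {
  if (is.function(matrices)) matrices(t) else matrices[, , t + 1L]
}

#' Run a Markov cohort trace
#'
#' Propagates an initial occupancy vector through cycle-indexed transition
#' matrices: `occupancy[t+1] = occupancy[t] %*% matrix(t)`. Every supplied
#' matrix is validated (row sums 1 within 1e-9, absorbing rows unit). The
#' trace also records per-cycle arrivals -- the mass flowing into each state
#' from *other* states -- which reward schedules use for one-off event costs
#' and disutilities; arrivals at cycle 0 are the initial occupancy itself.
#'
#' @param space a `cua_state_space`.
#' @param matrices a `function(cycle)` returning the transition matrix for
#'   cycle `t -> t+1` (`t` from 0), or an `S x S x cycles` array.
#' @param initial occupancy vector summing to 1.
#' @param cycles number of one-year cycles to run.
#' @param start_age cohort age at cycle 0 (annotation only).
#' @return a `cua_trace`: list with `occupancy` and `arrivals`
#'   (`(cycles+1) x S` matrices, rows = cycles 0..T), `states`, `start_age`.
#' @examples
#' sp <- state_space(c("alive", "death"))
#' m <- matrix(c(0.9, 0.1, 0, 1), 2, byrow = TRUE,
#'             dimnames = list(sp$states, sp$states))
#' run_cohort(sp, function(t) m, c(1, 0), 2)$occupancy
#' @export
run_cohort <- function(space, matrices, initial, cycles, start_age = NA) {
  S <- length(space$states)
  if (length(initial) != S || abs(sum(initial) - 1) > 1e-9)
    abort("initial occupancy must sum to 1 over the state space",
          "afcua_validation_error")
  occ <- matrix(0, cycles + 1L, S,
                dimnames = list(NULL, space$states))
  arr <- occ
  occ[1L, ] <- initial
  arr[1L, ] <- initial
  for (t in seq_len(cycles) - 1L) {
    m <- matrix_at(matrices, t)
    validate_transition_matrix(m, space, t)
    prev <- occ[t + 1L, ]
    nxt <- as.numeric(prev %*% m)
    occ[t + 2L, ] <- nxt
    arr[t + 2L, ] <- nxt - prev * diag(m)   # inflow from other states
  }
  structure(list(occupancy = occ, arrivals = arr,
                 states = space$states, start_age = start_age),
            class = "cua_trace")
}

#' Microsimulation oracle for a cohort trace
#'
#' Simulates `n_individuals` independent trajectories through the same
#' cycle-indexed transition matrices and returns the empirical occupancy
#' (and arrival) fractions as a `cua_trace`. This is an independent check
#' of [run_cohort()]: the two agree within binomial sampling error.
#' Deterministic for a fixed `seed`.
#'
#' @inheritParams run_cohort
#' @param n_individuals number of simulated subjects (>= 1).
#' @param seed integer RNG seed.
#' @return a `cua_trace` of empirical fractions.
#' @export
microsimulate <- function(space, matrices, initial, cycles, n_individuals,
                          seed, start_age = NA) {
  if (n_individuals < 1)
    abort("n_individuals must be >= 1", "afcua_domain_error")
  S <- length(space$states)
  if (length(initial) != S || abs(sum(initial) - 1) > 1e-9)
    abort("initial occupancy must sum to 1 over the state space",
          "afcua_validation_error")
  with_seed(seed, {
    state <- sample.int(S, n_individuals, replace = TRUE, prob = initial)
    occ <- matrix(0, cycles + 1L, S, dimnames = list(NULL, space$states))
    arr <- occ
    occ[1L, ] <- tabulate(state, S) / n_individuals
    arr[1L, ] <- occ[1L, ]
    for (t in seq_len(cycles) - 1L) {
      m <- matrix_at(matrices, t)
      validate_transition_matrix(m, space, t)
      new_state <- state
      for (s in seq_len(S)) {
        idx <- which(state == s)
        if (!length(idx)) next
        new_state[idx] <- sample.int(S, length(idx), replace = TRUE,
                                     prob = m[s, ])
      }
      moved <- new_state != state
      occ[t + 2L, ] <- tabulate(new_state, S) / n_individuals
      arr[t + 2L, ] <- tabulate(new_state[moved], S) / n_individuals
      state <- new_state
    }
    structure(list(occupancy = occ, arrivals = arr,
                   states = space$states, start_age = start_age),
              class = "cua_trace")
  })
}

#' @export
as.data.frame.cua_trace <- function(x, ...) {
  df <- as.data.frame(x$occupancy)
  cycle <- seq_len(nrow(df)) - 1L
  age <- if (is.na(x$start_age)) rep(NA_integer_, nrow(df))
         else x$start_age + cycle
  cbind(data.frame(cycle = cycle, age = age), df)
}

#' Write a cohort trace as CSV
#'
#' One row per cycle; columns `cycle`, `age`, then one occupancy fraction
#' per state.
#'
#' @param trace a `cua_trace`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @export
print.cua_trace <- function(x, ...) {
  T <- nrow(x$occupancy) - 1L
  cat(sprintf("Markov cohort trace: %d cycles, %d states\n",
              T, length(x$states)))
  cat(sprintf("  final death occupancy %.4f\n",
              x$occupancy[T + 1L, match("death", x$states)]))
  invisible(x)
}
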