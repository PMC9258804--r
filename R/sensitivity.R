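# Deterministic sensitivity analysis (one-way, two-way, tornado, threshold
# search) and probabilistic sensitivity analysis (Monte Carlo over the
# fitted beta/gamma parameter distributions).

# Evaluate both strategies and their comparison for one bundle.
evaluate_bundle <- function(bundle) {
  rfa <- strategy_outcomes(bundle, "rfa")
  cba <- strategy_outcomes(bundle, "cba")
  list(rfa = rfa, cba = cba,
       ce = compute_icer(cba, rfa, bundle$settings$wtp))
}

ce_row <- function(value, res) {
  data.frame(value = value,
             cost_rfa = res$rfa$cost, qalys_rfa = res$rfa$qalys,
             cost_cba = res$cba$cost, qalys_cba = res$cba$qalys,
             delta_cost = res$ce$delta_cost, delta_eff = res$ce$delta_eff,
             icer = res$ce$icer, nmb_diff = res$ce$nmb_diff,
             verdict = res$ce$verdict)
}

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the full comparison (CBA vs RFA) over a grid of values for
#' one parameter, all other parameters held at base.
#'
#' @param bundle a `cua_bundle`.
#' @param parameter dotted parameter path, e.g. `"rfa.cost_procedure"`.
#' @param grid numeric values to evaluate (default: 11 points across the
#'   parameter's DSA range).
#' @return a data frame, one row per grid value, with per-strategy outcomes,
#'   incremental results, ICER, incremental net monetary benefit and verdict.
#' @export
one_way <- function(bundle, parameter,
                    grid = seq(param_bounds(bundle, parameter)[1],
                               param_bounds(bundle, parameter)[2],
                               length.out = 11)) {
  resolve_param(bundle, parameter)   # name check up front
  if (length(grid) == 0) {
    out <- ce_row(0, evaluate_bundle(bundle))[0, ]
  } else {
    rows <- lapply(grid, function(v)
      ce_row(v, evaluate_bundle(set_param(bundle, parameter, v))))
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  }
  attr(out, "parameter") <- parameter
  out
}

#' Two-way deterministic sensitivity analysis
#'
#' Full factorial evaluation over two parameter grids; each cell is the
#' cost-effectiveness verdict of CBA vs RFA at the bundle's threshold.
#'
#' @param bundle a `cua_bundle`.
#' @param param_a,param_b dotted parameter paths.
#' @param grid_a,grid_b numeric grids (defaults: 11 points across each DSA
#'   range).
#' @return a character matrix of verdicts with `grid_a` rows and `grid_b`
#'   columns, dimnames carrying the grid values.
#' @export
two_way <- function(bundle, param_a, param_b,
                    grid_a = seq(param_bounds(bundle, param_a)[1],
                                 param_bounds(bundle, param_a)[2],
                                 length.out = 11),
                    grid_b = seq(param_bounds(bundle, param_b)[1],
                                 param_bounds(bundle, param_b)[2],
                                 length.out = 11)) {
  resolve_param(bundle, param_a)
  resolve_param(bundle, param_b)
  out <- matrix(NA_character_, length(grid_a), length(grid_b),
                dimnames = list(format(grid_a, trim = TRUE),
                                format(grid_b, trim = TRUE)))
  for (i in seq_along(grid_a)) {
    bi <- set_param(bundle, param_a, grid_a[i])
    for (j in seq_along(grid_b)) {
      res <- evaluate_bundle(set_param(bi, param_b, grid_b[j]))
      out[i, j] <- res$ce$verdict
    }
  }
  attr(out, "parameters") <- c(param_a, param_b)
  out
}

#' Default tornado parameter set
#'
#' The five parameters examined in the published one-way analysis: the two
#' procedure costs, the two first-year recurrence probabilities, and the
#' probability of re-ablation with CBA in the RFA arm.
#'
#' @return character vector of dotted parameter paths.
#' @export
tornado_parameters <- function() {
  c("rfa.cost_procedure", "cba.cost_procedure",
    "rfa.p_recur_y1", "cba.p_recur_y1", "rfa.p_redo_cba")
}

#' Tornado analysis
#'
#' Evaluates the ICER at each parameter's DSA low and high bound (all others
#' at base) and ranks parameters by the ICER spread. `crosses_wtp` flags
#' parameters whose verdict differs between the two bounds.
#'
#' @param bundle a `cua_bundle`.
#' @param parameters dotted parameter paths (default [tornado_parameters()]).
#' @return a `cua_tornado` data frame sorted by decreasing spread, with
#'   columns `parameter`, `low`, `high`, `icer_low`, `icer_high`,
#'   `nmb_low`, `nmb_high`, `spread`, `crosses_wtp`.
#' @export
tornado <- function(bundle, parameters = tornado_parameters()) {
  rows <- lapply(parameters, function(p) {
    bnd <- param_bounds(bundle, p)
    lo <- evaluate_bundle(set_param(bundle, p, bnd[["low"]]))
    hi <- evaluate_bundle(set_param(bundle, p, bnd[["high"]]))
    data.frame(parameter = p, low = bnd[["low"]], high = bnd[["high"]],
               icer_low = lo$ce$icer, icer_high = hi$ce$icer,
               nmb_low = lo$ce$nmb_diff, nmb_high = hi$ce$nmb_diff,
               spread = abs(hi$ce$icer - lo$ce$icer),
               crosses_wtp = lo$ce$verdict != hi$ce$verdict)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out <- out[order(-out$spread), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("cua_tornado", "data.frame")
  out
}

#' Find a bisection root of a continuous function
#'
#' Plain bisection: `f` must change sign over `[lower, upper]`.
#'
#' @param f function of one numeric argument.
#' @param lower,upper bracket endpoints.
#' @param tol absolute tolerance on the root's argument.
#' @param max_iter iteration cap.
#' @return list with `root`, `f_root`, `iterations`, `achieved_tolerance`.
#' @export
bisect_root <- function(f, lower, upper, tol = 0.5, max_iter = 200) {
  fl <- f(lower); fu <- f(upper)
  if (fl == 0) return(list(root = lower, f_root = 0, iterations = 0L,
                           achieved_tolerance = 0))
  if (fu == 0) return(list(root = upper, f_root = 0, iterations = 0L,
                           achieved_tolerance = 0))
  if (sign(fl) == sign(fu))
    abort(sprintf(
      "no sign change over bracket [%g, %g] (f = %g, %g): no threshold",
      lower, upper, fl, fu), "afcua_threshold_error")
  it <- 0L
  while (upper - lower > tol && it < max_iter) {
    mid <- (lower + upper) / 2
    fm <- f(mid)
    if (fm == 0) return(list(root = mid, f_root = 0, iterations = it + 1L,
                             achieved_tolerance = 0))
    if (sign(fm) == sign(fl)) {
      lower <- mid; fl <- fm
    } else {
      upper <- mid
    }
    it <- it + 1L
  }
  list(root = (lower + upper) / 2, f_root = f((lower + upper) / 2),
       iterations = it, achieved_tolerance = (upper - lower) / 2)
}

#' Threshold search on one parameter
#'
#' Finds the parameter value at which the incremental net monetary benefit
#' of CBA vs RFA, `wtp * delta_eff - delta_cost`, crosses zero -- i.e. the
#' value at which the cost-effectiveness verdict flips. Bisection to an
#' absolute tolerance in the parameter's units.
#'
#' @param bundle a `cua_bundle`.
#' @param parameter dotted parameter path.
#' @param bracket numeric `(low, high)` search interval (default: the
#'   parameter's DSA range).
#' @param wtp willingness-to-pay threshold (default: the bundle's).
#' @param tol absolute tolerance on the threshold value (default 0.5, i.e.
#'   half a dollar for cost parameters).
#' @param max_iter bisection iteration cap.
#' @return a `cua_threshold`: list with `parameter`, `value_at_threshold`,
#'   `bracket`, `achieved_tolerance`, `iterations`.
#' @export
find_threshold <- function(bundle, parameter,
                           bracket = param_bounds(bundle, parameter),
                           wtp = bundle$settings$wtp, tol = 0.5,
                           max_iter = 200) {
  resolve_param(bundle, parameter)
  f <- function(v) {
    res <- evaluate_bundle(set_param(set_param(bundle, "settings.wtp", wtp),
                                     parameter, v))
    res$ce$nmb_diff
  }
  r <- bisect_root(f, bracket[[1]], bracket[[2]], tol = tol,
                   max_iter = max_iter)
  structure(list(parameter = parameter, value_at_threshold = r$root,
                 bracket = c(low = bracket[[1]], high = bracket[[2]]),
                 achieved_tolerance = r$achieved_tolerance,
                 iterations = r$iterations, wtp = wtp),
            class = "cua_threshold")
}

#' @export
print.cua_threshold <- function(x, ...) {
  cat(sprintf(
    "threshold on %s: %.2f (bracket [%g, %g], tol %.3g, %d iterations)\n",
    x$parameter, x$value_at_threshold, x$bracket[1], x$bracket[2],
    x$achieved_tolerance, x$iterations))
  invisible(x)
}

## ---- probabilistic sensitivity analysis --------------------------------

#' Classify a PSA draw on the cost-effectiveness plane
#'
#' Six-component classification of an incremental (effect, cost) pair at a
#' willingness-to-pay threshold `wtp`:
#' C1 (quadrant IV, more effective and cheaper: superior), C2 (quadrant I,
#' ICER below `wtp`), C4 (quadrant I, ICER above `wtp`), C3 (quadrant III,
#' savings per QALY forgone above `wtp`: acceptable), C5 (quadrant III,
#' below), C6 (quadrant II, less effective and costlier: inferior).
#' Ties: `delta_eff = 0` classifies by cost sign alone (C1 if cheaper, C6 if
#' costlier, `Indiff` at the origin); `delta_cost = 0` falls in C2 or C5.
#' The cost-effective components for the new strategy are exactly
#' `{C1, C2, C3}` -- equivalently `wtp * delta_eff - delta_cost > 0`.
#'
#' @param delta_eff,delta_cost incremental QALYs and cost (vectorised).
#' @param wtp willingness-to-pay threshold.
#' @return character vector of component labels.
#' @export
classify_quadrant <- function(delta_eff, delta_cost, wtp) {
  n <- max(length(delta_eff), length(delta_cost))
  de <- rep_len(delta_eff, n); dc <- rep_len(delta_cost, n)
  out <- character(n)
  out[de > 0 & dc < 0] <- "C1"
  out[de > 0 & dc >= 0] <- ifelse(dc[de > 0 & dc >= 0] < wtp * de[de > 0 & dc >= 0],
                                  "C2", "C4")
  out[de < 0 & dc <= 0] <- ifelse(dc[de < 0 & dc <= 0] < wtp * de[de < 0 & dc <= 0],
                                  "C3", "C5")
  out[de < 0 & dc > 0] <- "C6"
  out[de == 0 & dc < 0] <- "C1"
  out[de == 0 & dc > 0] <- "C6"
  out[de == 0 & dc == 0] <- "Indiff"
  out
}

quadrant_components <- function() {
  data.frame(
    component = c("C1", "C2", "C3", "C4", "C5", "C6", "Indiff"),
    quadrant = c("IV", "I", "III", "I", "III", "II", "origin"),
    ie_sign = c("IE>0", "IE>0", "IE<0", "IE>0", "IE<0", "IE<0", "IE=0"),
    ic_sign = c("IC<0", "IC>0", "IC<0", "IC>0", "IC<0", "IC>0", "IC=0"),
    rule = c("Superior", "ICER<WTP", "ICER>WTP", "ICER>WTP", "ICER<WTP",
             "Inferior", "0/0"))
}

#' Quadrant report for a set of PSA draws
#'
#' Frequencies and proportions of the six cost-effectiveness-plane
#' components (plus the indifference origin), and the overall probability
#' that the new strategy (CBA) and the comparator (RFA) are cost-effective.
#'
#' @param samples data frame with columns `delta_eff`, `delta_cost`.
#' @param wtp willingness-to-pay threshold.
#' @return a `cua_quadrants`: the component table (data frame) with
#'   attributes `p_cost_effective_new` and `p_cost_effective_comparator`.
#' @export
quadrant_report <- function(samples, wtp) {
  comp <- classify_quadrant(samples$delta_eff, samples$delta_cost, wtp)
  tab <- quadrant_components()
  tab$frequency <- vapply(tab$component, function(k) sum(comp == k),
                          integer(1))
  tab$proportion <- tab$frequency / nrow(samples)
  p_new <- sum(tab$proportion[tab$component %in% c("C1", "C2", "C3")])
  structure(tab, class = c("cua_quadrants", "data.frame"),
            wtp = wtp,
            p_cost_effective_new = p_new,
            p_cost_effective_comparator = 1 - p_new)
}

#' Probabilistic sensitivity analysis by Monte Carlo simulation
#'
#' For each draw, every uncertain parameter is sampled from its
#' moment-matched beta/gamma distribution (shared parameters once per draw,
#' used in both arms; arm-specific parameters independently per arm), both
#' strategies are evaluated, and the incremental cost and QALYs of CBA vs
#' RFA are recorded. Deterministic for a fixed seed. The discount rate and
#' the life table are not sampled.
#'
#' @param bundle a `cua_bundle`.
#' @param n_draws number of Monte Carlo repetitions (the published analysis
#'   used 10,000).
#' @param seed integer RNG seed.
#' @return a `cua_psa`: list with `samples` (data frame: `draw`,
#'   `delta_cost`, `delta_eff`, `component`), `quadrants` (the
#'   [quadrant_report()]), `wtp`, `n_draws`, `seed`.
#' @export
run_psa <- function(bundle, n_draws = 10000, seed = 1) {
  if (n_draws < 1)
    abort("n_draws must be >= 1", "afcua_domain_error")
  wtp <- bundle$settings$wtp
  dc <- numeric(n_draws); de <- numeric(n_draws)
  with_seed(seed, {
    for (k in seq_len(n_draws)) {
      db <- draw_bundle(bundle)
      rfa <- strategy_outcomes(db, "rfa")
      cba <- strategy_outcomes(db, "cba")
      dc[k] <- cba$cost - rfa$cost
      de[k] <- cba$qalys - rfa$qalys
    }
  })
  samples <- data.frame(draw = seq_len(n_draws), delta_cost = dc,
                        delta_eff = de,
                        component = classify_quadrant(de, dc, wtp))
  structure(list(samples = samples,
                 quadrants = quadrant_report(samples, wtp),
                 wtp = wtp, n_draws = n_draws, seed = seed),
            class = "cua_psa")
}

#' Cost-effectiveness acceptability curve
#'
#' Probability that the new strategy is cost-effective -- the fraction of
#' PSA draws with positive incremental net monetary benefit
#' `wtp * delta_eff - delta_cost` -- across a grid of thresholds.
#'
#' @param samples PSA draws: a `cua_psa` or a data frame with `delta_eff`
#'   and `delta_cost` columns.
#' @param wtp_grid thresholds (USD/QALY) at which to evaluate the curve.
#' @return data frame with columns `wtp`, `probability`.
#' @export
ceac <- function(samples, wtp_grid = seq(0, 30000, by = 1000)) {
  if (inherits(samples, "cua_psa")) samples <- samples$samples
  if (is.null(samples) || nrow(samples) == 0)
    abort("CEAC needs at least one PSA draw", "afcua_domain_error")
  prob <- vapply(wtp_grid, function(l)
    mean(l * samples$delta_eff - samples$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' @export
print.cua_quadrants <- function(x, ...) {
  cat(sprintf("Cost-effectiveness plane report (WTP $%s/QALY)\n",
              format(attr(x, "wtp"), big.mark = ",")))
  print.data.frame(x, row.names = FALSE)
  cat(sprintf("P(new strategy cost-effective)  %.4f\n",
              attr(x, "p_cost_effective_new")))
  cat(sprintf("P(comparator cost-effective)    %.4f\n",
              attr(x, "p_cost_effective_comparator")))
  invisible(x)
}

#' @export
print.cua_psa <- function(x, ...) {
  cat(sprintf("PSA: %d Monte Carlo draws (seed %d)\n", x$n_draws, x$seed))
  print(x$quadrants)
  invisible(x)
}

#' @export
plot.cua_psa <- function(x, ...) {
  s <- x$samples
  graphics::plot(s$delta_eff, s$delta_cost, pch = 16, cex = 0.4,
                 col = grDevices::adjustcolor(
                   ifelse(x$wtp * s$delta_eff - s$delta_cost > 0,
                          "forestgreen", "firebrick"), 0.4),
                 xlab = "Incremental QALYs (CBA - RFA)",
                 ylab = "Incremental cost, USD (CBA - RFA)",
                 main = "Cost-effectiveness plane", ...)
  graphics::abline(h = 0, v = 0, col = "grey40")
  graphics::abline(0, x$wtp, lty = 2)
  invisible(x)
}
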