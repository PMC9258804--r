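# Main user-facing entry point: fit the base-case comparison and carry the
# pieces needed for printing, plotting and probabilistic simulation.

#' Cost-utility analysis of cryoballoon vs radiofrequency ablation
#'
#' Runs the lifetime Markov cohort model for both ablation strategies and
#' compares them at the willingness-to-pay threshold: discounted lifetime
#' cost and QALYs per strategy, incremental cost and QALYs, ICER and
#' verdict. This is the base-case analysis; use [simulate()] on the result
#' for probabilistic sensitivity analysis and [tornado()], [one_way()],
#' [two_way()], [find_threshold()] on the bundle for deterministic
#' sensitivity analysis.
#'
#' @param bundle a `cua_bundle` (default: the published base-case parameter
#'   set with the synthetic life table, [table1_bundle()]).
#' @param wtp,discount_rate optional overrides of the bundle's settings.
#' @return a `cua` object: list with `bundle`, per-strategy results `rfa`
#'   and `cba` (each with `cost`, `qalys`, `trace`), and the comparison `ce`.
#' @examples
#' fit <- cua()
#' fit
#' summary(fit)
#' @export
cua <- function(bundle = table1_bundle(), wtp = NULL, discount_rate = NULL) {
  if (!is.null(wtp)) bundle$settings$wtp <- wtp
  if (!is.null(discount_rate)) bundle$settings$discount_rate <- discount_rate
  validate_bundle(bundle)
  res <- evaluate_bundle(bundle)
  structure(list(bundle = bundle, rfa = res$rfa, cba = res$cba,
                 ce = res$ce),
            class = "cua")
}

#' Base-case results in the published table layout
#'
#' @param x a `cua` object.
#' @return data frame with rows Cost, QALYs, Incremental Cost, Incremental
#'   QALYs, ICER and columns RFA, CBA.
#' @export
results_table <- function(x) {
  data.frame(
    quantity = c("Cost($)", "QALYs", "Incremental Cost($)",
                 "Incremental QALYs", "ICER($/QALY)"),
    RFA = c(x$rfa$cost, x$rfa$qalys, NA, NA, NA),
    CBA = c(x$cba$cost, x$cba$qalys, x$ce$delta_cost, x$ce$delta_eff,
            x$ce$icer))
}

#' @export
print.cua <- function(x, ...) {
  cat("Lifetime Markov cohort cost-utility analysis: CBA vs RFA\n\n")
  tab <- results_table(x)
  tab$RFA <- ifelse(is.na(tab$RFA), "-", sprintf("%.2f", tab$RFA))
  tab$CBA <- sprintf("%.2f", tab$CBA)
  print.data.frame(tab, row.names = FALSE, right = TRUE)
  cat(sprintf("\nAt WTP $%s/QALY: CBA is %s\n",
              format(x$ce$wtp, big.mark = ","),
              gsub("_", " ", x$ce$verdict)))
  invisible(x)
}

#' @export
summary.cua <- function(object, ...) {
  x <- object
  wtp <- x$ce$wtp
  out <- list(
    results = results_table(x),
    wtp = wtp,
    verdict = x$ce$verdict,
    nmb = c(RFA = net_monetary_benefit(x$rfa, wtp),
            CBA = net_monetary_benefit(x$cba, wtp)),
    verdict_2x = compute_icer(x$cba, x$rfa, 2 * wtp)$verdict,
    horizon = horizon_cycles(x$bundle),
    discount_rate = x$bundle$settings$discount_rate)
  class(out) <- "summary.cua"
  out
}

#' @export
print.summary.cua <- function(x, ...) {
  tab <- x$results
  tab$RFA <- ifelse(is.na(tab$RFA), "-", sprintf("%.2f", tab$RFA))
  tab$CBA <- sprintf("%.2f", tab$CBA)
  print.data.frame(tab, row.names = FALSE, right = TRUE)
  cat(sprintf("\nhorizon %d one-year cycles, %.0f%% annual discounting\n",
              x$horizon, 100 * x$discount_rate))
  cat(sprintf("NMB at WTP $%s/QALY: RFA $%.0f, CBA $%.0f -> CBA %s\n",
              format(x$wtp, big.mark = ","), x$nmb[["RFA"]], x$nmb[["CBA"]],
              gsub("_", " ", x$verdict)))
  cat(sprintf("At twice the threshold ($%s): CBA %s\n",
              format(2 * x$wtp, big.mark = ","),
              gsub("_", " ", x$verdict_2x)))
  invisible(x)
}

#' @export
coef.cua <- function(object, ...) {
  b <- object$bundle
  out <- c(
    vapply(b$shared, function(p) p$base, numeric(1)),
    vapply(b$cba, function(p) p$base, numeric(1)),
    vapply(b$rfa, function(p) p$base, numeric(1)))
  names(out) <- c(paste0("shared.", names(b$shared)),
                  paste0("cba.", names(b$cba)),
                  paste0("rfa.", names(b$rfa)))
  out
}

#' Plot the cohort traces of a fitted comparison
#'
#' State occupancy over cycles for both strategies, side by side.
#'
#' @param x a `cua` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.cua <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  for (arm in c("rfa", "cba")) {
    tr <- x[[arm]]$trace
    graphics::matplot(seq_len(nrow(tr$occupancy)) - 1, tr$occupancy,
                      type = "l", lty = 1, lwd = 1.5,
                      col = seq_along(tr$states),
                      xlab = "cycle (years)", ylab = "occupancy",
                      main = toupper(arm), ...)
    graphics::legend("right", legend = tr$states, bty = "n", cex = 0.7,
                     col = seq_along(tr$states), lty = 1)
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis of a fitted comparison
#'
#' `simulate()` on a `cua` object runs [run_psa()] on its bundle.
#'
#' @param object a `cua` object.
#' @param nsim number of Monte Carlo draws.
#' @param seed integer RNG seed.
#' @param ... unused.
#' @return a `cua_psa`; see [run_psa()].
#' @export
simulate.cua <- function(object, nsim = 10000, seed = 1, ...) {
  run_psa(object$bundle, n_draws = nsim, seed = seed)
}

#' Export base-case results as CSV/JSON
#'
#' @param x a `cua` object.
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(
      rfa = list(cost = x$rfa$cost, qalys = x$rfa$qalys),
      cba = list(cost = x$cba$cost, qalys = x$cba$qalys),
      incremental = list(delta_cost = x$ce$delta_cost,
                         delta_eff = x$ce$delta_eff, icer = x$ce$icer,
                         verdict = x$ce$verdict, wtp = x$ce$wtp)),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.csv(results_table(x), path, row.names = FALSE)
  }
  invisible(path)
}
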