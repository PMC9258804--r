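# Parameter containers, moment-matched distributions, and configuration I/O.

abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "afcua_error")))
}

#' Fit a beta distribution by the method of moments
#'
#' Returns the `(alpha, beta)` shape pair whose mean and standard deviation
#' match the supplied moments exactly. Used to turn the published
#' mean +/- SD of probabilities and utilities into sampling distributions
#' for probabilistic sensitivity analysis.
#'
#' @param mean target mean, in (0, 1).
#' @param sd target standard deviation; must satisfy `sd^2 < mean * (1 - mean)`.
#' @return named numeric vector `c(alpha = , beta = )`, both positive.
#' @examples
#' fit_beta_moments(0.269, 0.0538)
#' @export
fit_beta_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    abort(sprintf("beta mean must lie in (0,1); got %g", mean),
          "afcua_moments_error")
  if (!is.finite(sd) || sd <= 0)
    abort(sprintf("beta sd must be positive; got %g", sd),
          "afcua_moments_error")
  v <- sd^2
  if (v >= mean * (1 - mean))
    abort(sprintf(
      "infeasible moments for beta: sd^2 = %g >= mean*(1-mean) = %g",
      v, mean * (1 - mean)), "afcua_moments_error")
  nu <- mean * (1 - mean) / v - 1
  c(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a gamma distribution by the method of moments
#'
#' Shape/scale parameterisation: `shape * scale = mean`,
#' `sqrt(shape) * scale = sd`. Used for cost parameters.
#'
#' @param mean target mean, positive.
#' @param sd target standard deviation, positive.
#' @return named numeric vector `c(shape = , scale = )`.
#' @examples
#' fit_gamma_moments(7751.88, 516.72)
#' @export
fit_gamma_moments <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    abort(sprintf("gamma mean must be positive; got %g", mean),
          "afcua_moments_error")
  if (!is.finite(sd) || sd <= 0)
    abort(sprintf("gamma sd must be positive; got %g", sd),
          "afcua_moments_error")
  c(shape = (mean / sd)^2, scale = sd^2 / mean)
}

#' Convert between annual probabilities and instantaneous rates
#'
#' `prob_to_rate()` returns the constant hazard whose one-year cumulative
#' incidence equals `p`; `rate_to_prob()` is its inverse. Competing risks
#' within a one-year cycle are combined on the rate scale (convert, add,
#' convert back) so that transition rows remain stochastic.
#'
#' @param p annual probability in `[0, 1)`.
#' @param r rate per year, non-negative.
#' @return the converted rate or probability.
#' @examples
#' prob_to_rate(0.05)        # 0.051293
#' rate_to_prob(prob_to_rate(0.3))
#' @export
prob_to_rate <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1))
    abort("probability must lie in [0,1) for rate conversion",
          "afcua_domain_error")
  -log(1 - p)
}

#' @rdname prob_to_rate
#' @export
rate_to_prob <- function(r) {
  if (any(!is.finite(r)) || any(r < 0))
    abort("rate must be finite and non-negative", "afcua_domain_error")
  1 - exp(-r)
}

## ---- parameter objects ------------------------------------------------

# A single model parameter: base value, uncertainty (sd, possibly NA until
# the default-SD policy is applied), distribution family, and DSA bounds.
cua_param <- function(base, sd = NA_real_, dist = c("beta", "gamma", "fixed"),
                      low = NA_real_, high = NA_real_) {
  dist <- match.arg(dist)
  structure(list(base = base, sd = sd, dist = dist, low = low, high = high),
            class = "cua_param")
}

param_kind <- function(name) {
  name <- sub("^.*\\.", "", name)   # accept dotted paths like "rfa.p_stroke"
  if (startsWith(name, "p_")) "probability"
  else if (startsWith(name, "cost_")) "cost"
  else if (startsWith(name, "u_")) "utility"
  else if (startsWith(name, "du_")) "disutility"
  else "other"
}

# Default-SD policy: parameters published without an SD get 20% of |mean|
# if beta-distributed (probabilities, utilities, disutilities) and 10% of
# mean if gamma-distributed (costs). Fractions are configurable.
apply_sd_policy <- function(par, frac_beta = 0.2, frac_gamma = 0.1) {
  if (is.na(par$sd) && par$dist != "fixed") {
    frac <- if (par$dist == "gamma") frac_gamma else frac_beta
    par$sd <- frac * abs(par$base)
  }
  par
}

# DSA bounds default to base +/- 2*SD, clipped to the parameter's domain.
apply_bounds_policy <- function(par, kind) {
  if (par$dist == "fixed") {
    if (is.na(par$low)) par$low <- par$base
    if (is.na(par$high)) par$high <- par$base
    return(par)
  }
  lo <- par$base - 2 * par$sd
  hi <- par$base + 2 * par$sd
  dom <- switch(kind,
    probability = c(0, 1),
    utility     = c(0, 1),
    disutility  = c(-1, 0),
    cost        = c(0, Inf),
    c(-Inf, Inf))
  if (is.na(par$low)) par$low <- max(lo, dom[1])
  if (is.na(par$high)) par$high <- min(hi, dom[2])
  par
}

validate_param <- function(name, par) {
  kind <- param_kind(name)
  b <- par$base
  bad <- function(bound) abort(
    sprintf("parameter '%s' violates bound: %s (base = %g)", name, bound, b),
    "afcua_validation_error")
  switch(kind,
    probability = if (b < 0 || b > 1) bad("probability in [0,1]"),
    utility     = if (b < 0 || b > 1) bad("utility in [0,1]"),
    disutility  = if (b > 0) bad("disutility <= 0"),
    cost        = if (b < 0) bad("cost >= 0"),
    invisible())
  if (!is.na(par$sd) && par$sd < 0) bad("sd >= 0")
  if (!is.na(par$low) && !is.na(par$high)) {
    if (par$low > b || b > par$high)
      bad(sprintf("low <= base <= high (low = %g, high = %g)",
                  par$low, par$high))
  }
  if (par$dist == "beta" && !is.na(par$sd) && par$sd > 0) {
    m <- abs(b)
    if (m <= 0 || m >= 1 || par$sd^2 >= m * (1 - m))
      bad("beta feasibility: sd^2 < |mean|*(1-|mean|), |mean| in (0,1)")
  }
  if (par$dist == "gamma" && b <= 0) bad("gamma mean > 0")
  invisible(par)
}

# Draw one value from a parameter's fitted distribution. Disutilities
# (negative means, beta family) are sampled on the magnitude and negated.
sample_param <- function(par) {
  if (par$dist == "fixed" || is.na(par$sd) || par$sd == 0) return(par$base)
  if (par$dist == "gamma") {
    g <- fit_gamma_moments(par$base, par$sd)
    return(stats::rgamma(1L, shape = g[["shape"]], scale = g[["scale"]]))
  }
  sgn <- if (par$base < 0) -1 else 1
  ab <- fit_beta_moments(abs(par$base), par$sd)
  sgn * stats::rbeta(1L, ab[["alpha"]], ab[["beta"]])
}

## ---- the parameter bundle --------------------------------------------

strategy_param_names <- function() {
  c("p_recur_y1", "p_recur_late", "p_redo_rfa", "p_redo_cba",
    "p_pericardial", "p_phrenic", "p_vascular", "p_stroke",
    "cost_procedure", "cost_pericardial", "cost_phrenic", "cost_vascular")
}

shared_param_names <- function() {
  c("cost_af_annual", "cost_nsr_annual", "cost_stroke_y1", "cost_poststroke",
    "u_nsr", "u_af", "u_poststroke", "du_complication", "du_stroke_y1",
    "p_op_death", "p_stroke_death", "start_age")
}

settings_names <- function() {
  c("discount_rate", "wtp", "horizon_cycles", "stroke_from_nsr",
    "half_cycle_correction", "reward_timing",
    "default_sd_probability", "default_sd_cost")
}

new_bundle <- function(shared, cba, rfa, settings, life_table) {
  b <- structure(list(shared = shared, cba = cba, rfa = rfa,
                      settings = settings, life_table = life_table),
                 class = "cua_bundle")
  validate_bundle(b)
}

#' Validate a parameter bundle
#'
#' Checks completeness, every per-parameter bound (probabilities and
#' utilities in `[0,1]`, disutilities non-positive, costs non-negative,
#' beta-moment feasibility), the re-intervention simplex
#' `p_redo_rfa + p_redo_cba <= 1`, economic settings, and the life table.
#'
#' @param bundle a `cua_bundle`.
#' @return the bundle, invisibly-checked (errors are classed conditions).
#' @export
validate_bundle <- function(bundle) {
  for (block in c("shared", "cba", "rfa", "settings"))
    if (is.null(bundle[[block]]))
      abort(sprintf("configuration is missing block '%s'", block),
            "afcua_config_error")
  expected <- list(shared = shared_param_names(),
                   cba = strategy_param_names(),
                   rfa = strategy_param_names())
  for (block in names(expected)) {
    have <- names(bundle[[block]])
    miss <- setdiff(expected[[block]], have)
    if (length(miss))
      abort(sprintf("configuration block '%s' is missing key(s): %s",
                    block, paste(miss, collapse = ", ")),
            "afcua_config_error")
    extra <- setdiff(have, expected[[block]])
    if (length(extra))
      abort(sprintf("configuration block '%s' has unknown key(s): %s",
                    block, paste(extra, collapse = ", ")),
            "afcua_config_error")
    for (nm in expected[[block]])
      validate_param(paste0(block, ".", nm), bundle[[block]][[nm]])
  }
  for (arm in c("cba", "rfa")) {
    s <- bundle[[arm]]$p_redo_rfa$base + bundle[[arm]]$p_redo_cba$base
    if (s > 1 + 1e-12)
      abort(sprintf(
        "parameter '%s.p_redo_rfa + p_redo_cba' violates bound: sum <= 1 (sum = %g)",
        arm, s), "afcua_validation_error")
  }
  st <- bundle$settings
  miss <- setdiff(c("discount_rate", "wtp"), names(st))
  if (length(miss))
    abort(sprintf("configuration block 'settings' is missing key(s): %s",
                  paste(miss, collapse = ", ")), "afcua_config_error")
  extra <- setdiff(names(st), settings_names())
  if (length(extra))
    abort(sprintf("configuration block 'settings' has unknown key(s): %s",
                  paste(extra, collapse = ", ")), "afcua_config_error")
  if (st$discount_rate < 0)
    abort("parameter 'settings.discount_rate' violates bound: >= 0",
          "afcua_validation_error")
  if (st$wtp < 0)
    abort("parameter 'settings.wtp' violates bound: >= 0",
          "afcua_validation_error")
  if (!is.null(st$horizon_cycles) && st$horizon_cycles < 1)
    abort("parameter 'settings.horizon_cycles' violates bound: >= 1",
          "afcua_validation_error")
  if (!is.null(st$reward_timing) && !st$reward_timing %in% c("start", "end"))
    abort("parameter 'settings.reward_timing' must be 'start' or 'end'",
          "afcua_validation_error")
  if (!is.null(bundle$life_table)) validate_life_table(bundle$life_table)
  bundle
}

# Number of one-year cycles actually simulated: until the cohort reaches the
# life table's terminal age, capped at 60 (death absorption plus 5%
# discounting make longer horizons numerically irrelevant).
horizon_cycles <- function(bundle) {
  st <- bundle$settings
  if (!is.null(st$horizon_cycles)) return(as.integer(st$horizon_cycles))
  start <- bundle$shared$start_age$base
  mx <- max(bundle$life_table$age)
  as.integer(min(60L, mx - start))
}

## ---- dotted-path access for DSA --------------------------------------

#' Get or set a model parameter by dotted path
#'
#' Parameters are addressed as `"block.name"`, e.g. `"rfa.cost_procedure"`,
#' `"shared.u_nsr"`, or `"settings.discount_rate"`. `set_param()` returns a
#' modified copy (bundles are immutable values).
#'
#' @param bundle a `cua_bundle`.
#' @param path dotted parameter path.
#' @param value replacement base value (for `set_param`).
#' @return `get_param`: the parameter's base value. `param_bounds`: the
#'   `(low, high)` DSA range. `set_param`: the modified bundle.
#' @export
get_param <- function(bundle, path) {
  p <- resolve_param(bundle, path)
  if (p$block == "settings") bundle$settings[[p$name]]
  else bundle[[p$block]][[p$name]]$base
}

#' @rdname get_param
#' @export
set_param <- function(bundle, path, value) {
  p <- resolve_param(bundle, path)
  if (p$block == "settings") {
    bundle$settings[[p$name]] <- value
  } else {
    bundle[[p$block]][[p$name]]$base <- value
    # keep low <= base <= high so the modified bundle still validates
    bundle[[p$block]][[p$name]]$low <-
      min(bundle[[p$block]][[p$name]]$low, value)
    bundle[[p$block]][[p$name]]$high <-
      max(bundle[[p$block]][[p$name]]$high, value)
  }
  bundle
}

#' @rdname get_param
#' @export
param_bounds <- function(bundle, path) {
  p <- resolve_param(bundle, path)
  if (p$block == "settings") {
    if (p$name == "discount_rate") return(c(low = 0, high = 0.1))
    abort(sprintf("no DSA bounds defined for '%s'", path),
          "afcua_config_error")
  }
  par <- bundle[[p$block]][[p$name]]
  if (is.na(par$low) || is.na(par$high))
    abort(sprintf("parameter '%s' has no low/high bounds", path),
          "afcua_config_error")
  c(low = par$low, high = par$high)
}

resolve_param <- function(bundle, path) {
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    abort(sprintf("parameter path must be 'block.name'; got '%s'", path),
          "afcua_name_error")
  block <- parts[1]; name <- parts[2]
  ok <- switch(block,
    shared = name %in% shared_param_names(),
    cba = , rfa = name %in% strategy_param_names(),
    settings = name %in% settings_names(),
    FALSE)
  if (!isTRUE(ok))
    abort(sprintf("unknown parameter '%s'", path), "afcua_name_error")
  list(block = block, name = name)
}

## ---- configuration file I/O -------------------------------------------

param_to_plain <- function(par) {
  out <- list(base = par$base, sd = par$sd, dist = par$dist,
              low = par$low, high = par$high)
  out[!vapply(out, function(x) is.null(x) || (is.numeric(x) && is.na(x)),
              logical(1))]
}

plain_to_param <- function(name, x, settings) {
  kind <- param_kind(name)
  default_dist <- switch(kind,
    cost = "gamma",
    probability = , utility = , disutility = "beta",
    "fixed")
  if (is.numeric(x) && length(x) == 1) {
    par <- cua_param(x, dist = default_dist)
  } else if (is.list(x)) {
    extra <- setdiff(names(x), c("base", "sd", "dist", "low", "high"))
    if (length(extra))
      abort(sprintf("parameter '%s' has unknown field(s): %s",
                    name, paste(extra, collapse = ", ")),
            "afcua_config_error")
    if (is.null(x$base))
      abort(sprintf("parameter '%s' is missing field 'base'", name),
            "afcua_config_error")
    par <- cua_param(x$base,
                     sd = if (is.null(x$sd)) NA_real_ else x$sd,
                     dist = if (is.null(x$dist)) default_dist else x$dist,
                     low = if (is.null(x$low)) NA_real_ else x$low,
                     high = if (is.null(x$high)) NA_real_ else x$high)
  } else {
    abort(sprintf("parameter '%s' must be a number or a mapping", name),
          "afcua_config_error")
  }
  par <- apply_sd_policy(par, settings$default_sd_probability,
                         settings$default_sd_cost)
  apply_bounds_policy(par, kind)
}

default_settings <- function() {
  list(discount_rate = 0.05, wtp = 7142, horizon_cycles = NULL,
       stroke_from_nsr = FALSE, half_cycle_correction = FALSE,
       reward_timing = "end",
       default_sd_probability = 0.2, default_sd_cost = 0.1)
}

#' Read a model configuration file
#'
#' The configuration is a YAML document with four blocks -- `settings`,
#' `shared`, `cba`, `rfa` -- whose keys mirror the published parameter table
#' in snake_case, plus an optional `life_table` entry giving the path
#' (relative to the configuration file) of a two-column `age,q` CSV.
#' Each parameter is either a bare number (SD then follows the default-SD
#' policy: 20% of the mean for beta-distributed quantities, 10% for costs)
#' or a mapping with fields `base`, `sd`, `dist`, `low`, `high`.
#' Unknown keys are rejected by name; every domain bound is validated.
#'
#' @param path path to the YAML configuration.
#' @param life_table optional `cua_life_table` overriding the file's
#'   `life_table` entry; if neither is given, the synthetic default
#'   [generate_life_table()] anchored at q(50) = 0.0037 is used.
#' @return a validated `cua_bundle`.
#' @seealso [table1_bundle()] for the shipped base-case parameter set.
#' @export
load_config <- function(path, life_table = NULL) {
  if (!file.exists(path))
    abort(sprintf("configuration file not found: %s", path),
          "afcua_config_error")
  raw <- yaml::read_yaml(path)
  known <- c("settings", "shared", "cba", "rfa", "life_table")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    abort(sprintf("configuration has unknown top-level key(s): %s",
                  paste(extra, collapse = ", ")), "afcua_config_error")
  st <- default_settings()
  if (is.null(raw$settings) || is.null(raw$settings$discount_rate))
    abort("configuration block 'settings' is missing key(s): discount_rate",
          "afcua_config_error")
  extra <- setdiff(names(raw$settings), settings_names())
  if (length(extra))
    abort(sprintf("configuration block 'settings' has unknown key(s): %s",
                  paste(extra, collapse = ", ")), "afcua_config_error")
  st[names(raw$settings)] <- raw$settings
  blocks <- list()
  for (block in c("shared", "cba", "rfa")) {
    if (is.null(raw[[block]]))
      abort(sprintf("configuration is missing block '%s'", block),
            "afcua_config_error")
    blocks[[block]] <- lapply_named(raw[[block]], function(nm, x)
      plain_to_param(paste0(block, ".", nm), x, st))
  }
  if ("start_age" %in% names(blocks$shared))
    blocks$shared$start_age$dist <- "fixed"
  if (is.null(life_table)) {
    if (!is.null(raw$life_table)) {
      lt_path <- raw$life_table
      if (!file.exists(lt_path))
        lt_path <- file.path(dirname(path), raw$life_table)
      life_table <- read_life_table(lt_path)
    } else {
      life_table <- generate_life_table(
        start_age = blocks$shared$start_age$base)
    }
  }
  new_bundle(blocks$shared, blocks$cba, blocks$rfa, st, life_table)
}

lapply_named <- function(x, fn) {
  out <- mapply(fn, names(x), x, SIMPLIFY = FALSE)
  names(out) <- names(x)
  out
}

#' Write a bundle back to a YAML configuration file
#'
#' @param bundle a `cua_bundle`.
#' @param path output path for the YAML file.
#' @param life_table_path optional path at which the bundle's life table is
#'   written as CSV and referenced from the configuration.
#' @return `path`, invisibly.
#' @export
write_config <- function(bundle, path, life_table_path = NULL) {
  doc <- list(settings = bundle$settings[
                !vapply(bundle$settings, is.null, logical(1))],
              shared = lapply(bundle$shared, param_to_plain),
              cba = lapply(bundle$cba, param_to_plain),
              rfa = lapply(bundle$rfa, param_to_plain))
  if (!is.null(life_table_path)) {
    write_life_table(bundle$life_table, life_table_path)
    doc$life_table <- life_table_path
  }
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @export
print.cua_bundle <- function(x, ...) {
  cat("Ablation cost-utility parameter bundle\n")
  cat(sprintf("  start age %d, horizon %d one-year cycles\n",
              as.integer(x$shared$start_age$base), horizon_cycles(x)))
  cat(sprintf("  discount rate %.1f%%/yr, WTP threshold $%s/QALY\n",
              100 * x$settings$discount_rate,
              format(x$settings$wtp, big.mark = ",")))
  cat(sprintf("  CBA procedure $%.2f, RFA procedure $%.2f\n",
              x$cba$cost_procedure$base, x$rfa$cost_procedure$base))
  cat(sprintf("  life table: ages %d-%d (q at start age %.4f)\n",
              min(x$life_table$age), max(x$life_table$age),
              mortality(x$life_table, x$shared$start_age$base)))
  invisible(x)
}
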