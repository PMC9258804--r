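# Synthetic inputs: life tables, the published base-case parameter set,
# and jittered bundles for robustness / recovery testing.

# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic Gompertz life table
#'
#' Stand-in for a national period life table: the annual death probability
#' follows `q(age) = 1 - exp(-a * exp(b * (age - start_age)))`, anchored so
#' that `q(start_age)` equals `anchor_q`, clamped to `[0,1]`, with `q = 1`
#' forced at `max_age`. The default slope `b = 0.10`/yr gives a remaining
#' life expectancy at age 50 of about 29 years when anchored at
#' `q(50) = 0.0037`, a realistic figure for a middle-income population.
#' This is a synthetic construction, not transcribed national data.
#'
#' @param start_age first tabulated age (years).
#' @param max_age terminal age at which `q` is forced to 1.
#' @param anchor_q annual death probability at `start_age`, in (0, 1).
#' @param gompertz_b log-hazard slope per year of age, non-negative.
#' @return a `cua_life_table` covering `start_age:max_age`.
#' @examples
#' lt <- generate_life_table()
#' mortality(lt, 50)   # 0.0037
#' @export
generate_life_table <- function(start_age = 50, max_age = 100,
                                anchor_q = 0.0037, gompertz_b = 0.10) {
  if (anchor_q <= 0 || anchor_q >= 1)
    abort("anchor death probability must lie in (0,1)", "afcua_domain_error")
  if (gompertz_b < 0)
    abort("Gompertz slope must be non-negative", "afcua_domain_error")
  if (max_age <= start_age)
    abort("max_age must exceed start_age", "afcua_domain_error")
  ages <- start_age:max_age
  a <- -log(1 - anchor_q)                     # anchor hazard at start_age
  q <- 1 - exp(-a * exp(gompertz_b * (ages - start_age)))
  q <- pmin(pmax(q, 0), 1)
  q[length(q)] <- 1
  life_table(ages, q)
}

#' The published base-case parameter set
#'
#' Returns the shipped default configuration: every transition probability,
#' complication probability, cost (2019-20 USD), utility and disutility of
#' the base-case analysis, with its published SD and distribution family
#' (beta for probabilities/utilities, gamma for costs). Parameters published
#' without an SD receive the default-SD policy (20% of the mean for
#' beta-distributed quantities, 10% for costs). DSA ranges default to
#' base +/- 2 SD, clipped to each parameter's domain.
#'
#' Known typographic slips in the source table are corrected here: the
#' re-intervention-with-CBA probability in the CBA arm is read as 0.0951,
#' and the phrenic-palsy cost (which the table prints with the pericardial
#' row's SD) takes the default cost SD instead.
#'
#' @param life_table optional `cua_life_table`; default is the synthetic
#'   Gompertz table anchored at q(50) = 0.0037.
#' @return a validated `cua_bundle`.
#' @examples
#' b <- table1_bundle()
#' get_param(b, "cba.cost_procedure")   # 7751.88
#' @export
table1_bundle <- function(life_table = generate_life_table()) {
  st <- default_settings()
  mk <- function(block, defs) {
    out <- lapply_named(defs, function(nm, d) {
      par <- cua_param(d[[1]],
                       sd = if (length(d) > 1) d[[2]] else NA_real_,
                       dist = switch(param_kind(nm), cost = "gamma",
                                     other = "fixed", "beta"))
      par <- apply_sd_policy(par, st$default_sd_probability,
                             st$default_sd_cost)
      apply_bounds_policy(par, param_kind(nm))
    })
    out
  }
  shared <- mk("shared", list(
    cost_af_annual  = list(372.81, 55.92),
    cost_nsr_annual = list(273.32, 40.99),
    cost_stroke_y1  = list(1804.49, 180.44),
    cost_poststroke = list(541.34, 54.13),
    u_nsr        = list(0.8, 0.00577),
    u_af         = list(0.6, 0.0721),
    u_poststroke = list(0.46, 0.0577),
    du_complication = list(-0.0314),
    du_stroke_y1    = list(-0.296),
    p_op_death      = list(0.000487),
    p_stroke_death  = list(0.3536),
    start_age       = list(50)))
  shared$start_age$dist <- "fixed"
  cba <- mk("cba", list(
    p_recur_y1   = list(0.269, 0.0538),
    p_recur_late = list(0.0938, 0.0235),
    p_redo_rfa   = list(0.5516, 0.11032),
    p_redo_cba   = list(0.0951, 0.01902),
    p_pericardial = list(0.0084),
    p_phrenic     = list(0.032),
    p_vascular    = list(0.0156),
    p_stroke      = list(0.05),
    cost_procedure   = list(7751.88, 516.72),
    cost_pericardial = list(1060.19, 106.01),
    cost_phrenic     = list(11.09),
    cost_vascular    = list(60.23)))
  rfa <- mk("rfa", list(
    p_recur_y1   = list(0.3326, 0.0665),
    p_recur_late = list(0.1055, 0.0264),
    p_redo_rfa   = list(0.5685, 0.1137),
    p_redo_cba   = list(0.0587, 0.01174),
    p_pericardial = list(0.0231),
    p_phrenic     = list(0.0005),
    p_vascular    = list(0.023),
    p_stroke      = list(0.05),
    cost_procedure   = list(5027.10, 1530.66),
    cost_pericardial = list(1060.19, 106.01),
    cost_phrenic     = list(11.09),
    cost_vascular    = list(60.23)))
  new_bundle(shared, cba, rfa, st, life_table)
}

#' Redraw every uncertain parameter of a bundle from its distribution
#'
#' Produces a perturbed copy of `bundle` in which each parameter with a
#' non-degenerate distribution is replaced by one draw from its
#' moment-matched beta/gamma distribution (the same sampling used for one
#' probabilistic-sensitivity draw). Used for robustness and recovery tests.
#'
#' @param bundle a `cua_bundle`.
#' @param seed integer RNG seed; the same seed always yields the same bundle.
#' @return a validated `cua_bundle` with redrawn base values.
#' @export
jitter_bundle <- function(bundle, seed) {
  with_seed(seed, draw_bundle(bundle))
}

# One PSA draw: shared parameters sampled once, arm-specific parameters
# sampled independently per arm; the re-intervention pair is renormalised
# onto the simplex in the rare draws where the two exceed 1 together.
draw_bundle <- function(bundle) {
  sample_block <- function(block) {
    for (nm in names(block)) {
      base <- sample_param(block[[nm]])
      block[[nm]]$base <- base
      block[[nm]]$low <- min(block[[nm]]$low, base, na.rm = TRUE)
      block[[nm]]$high <- max(block[[nm]]$high, base, na.rm = TRUE)
    }
    block
  }
  bundle$shared <- sample_block(bundle$shared)
  for (arm in c("cba", "rfa")) {
    bundle[[arm]] <- sample_block(bundle[[arm]])
    s <- bundle[[arm]]$p_redo_rfa$base + bundle[[arm]]$p_redo_cba$base
    if (s > 1) {
      bundle[[arm]]$p_redo_rfa$base <- bundle[[arm]]$p_redo_rfa$base / s
      bundle[[arm]]$p_redo_cba$base <- bundle[[arm]]$p_redo_cba$base / s
    }
  }
  bundle
}
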