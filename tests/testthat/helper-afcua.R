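# Shared fixtures, built in code.

# Two-state toy: alive/dead with constant annual death probability.
toy_space <- function() state_space(c("alive", "death"))

toy_matrix <- function(p_death = 0.1) {
  matrix(c(1 - p_death, p_death, 0, 1), 2, 2, byrow = TRUE,
         dimnames = list(c("alive", "death"), c("alive", "death")))
}

# The published parameter set on the shipped synthetic life table.
base_bundle <- function() table1_bundle()

# Degenerate bundle: recurrence, complications, stroke and operative death
# all zero, so survivors sit in NSR from cycle 1 until background death.
# u_af is set to u_nsr so lifetime QALYs collapse to the closed form
# u_nsr * discounted life expectancy.
degenerate_bundle <- function() {
  b <- base_bundle()
  zero <- c("p_recur_y1", "p_recur_late", "p_redo_rfa", "p_redo_cba",
            "p_pericardial", "p_phrenic", "p_vascular", "p_stroke")
  for (arm in c("cba", "rfa")) for (nm in zero)
    b <- set_param(b, paste0(arm, ".", nm), 0)
  b <- set_param(b, "shared.p_op_death", 0)
  b <- set_param(b, "shared.u_af", get_param(b, "shared.u_nsr"))
  b
}

# Zero every parameter SD so all sampling distributions are degenerate.
zero_sds <- function(bundle) {
  for (block in c("shared", "cba", "rfa"))
    for (nm in names(bundle[[block]]))
      bundle[[block]][[nm]]$sd <- 0
  bundle
}

shipped_config_path <- function() {
  system.file("extdata", "table1.yaml", package = "afcua")
}
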