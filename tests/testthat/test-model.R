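# Structure and behaviour of the strategy-specific ablation models.

test_that("state space carries the published health states plus death", {
  m <- build_model(base_bundle(), "cba")
  expect_setequal(m$space$states,
                  c("af_pre", "nsr", "af_post", "nsr_redone",
                    "af_post_redo", "post_stroke", "death"))
  expect_identical(m$space$absorbing, "death")
  expect_equal(sum(m$initial), 1)
  expect_equal(m$initial[match("af_pre", m$space$states)], 1)
})

test_that("every supplied transition matrix is valid at every cycle", {
  for (arm in c("cba", "rfa")) {
    m <- build_model(base_bundle(), arm)
    for (t in seq_len(m$cycles))
      expect_silent(afcua:::validate_transition_matrix(
        m$matrices[, , t], m$space, t - 1L))
  }
})

test_that("degenerate model collapses to discounted life expectancy in NSR", {
  b <- degenerate_bundle()
  lt <- b$life_table
  u <- get_param(b, "shared.u_nsr")
  T <- afcua:::horizon_cycles(b)
  r <- b$settings$discount_rate

  # closed form from the life table alone (independent of the engine):
  # survival to cycle t, NSR utility from cycle 1 (end-of-cycle accrual)
  q <- mortality(lt, 50 + 0:(T - 1))
  S <- cumprod(c(1, 1 - q))
  df <- (1 + r)^-(0:T)
  expected_end <- u * sum(df[-1] * S[-1])
  out <- strategy_outcomes(b, "cba")
  expect_equal(out$qalys, expected_end, tolerance = 1e-9)

  # under start-of-cycle accrual the closed form is u * discounted life
  # expectancy with cycle 0 counted in full
  b$settings$reward_timing <- "start"
  out2 <- strategy_outcomes(b, "cba")
  expect_equal(out2$qalys, u * life_expectancy(lt, 50, r, T),
               tolerance = 1e-9)
  # occupancy: everyone alive is in NSR from cycle 1
  tr <- out$trace
  alive <- 1 - tr$occupancy[, "death"]
  expect_equal(tr$occupancy[-1, "nsr"], alive[-1], tolerance = 1e-12)
})

test_that("certain operative death empties the cohort at cycle 1", {
  b <- base_bundle()
  b <- set_param(b, "shared.p_op_death", 1)
  for (nm in c("p_pericardial", "p_phrenic", "p_vascular"))
    b <- set_param(b, paste0("cba.", nm), 0)
  out <- strategy_outcomes(b, "cba")
  expect_equal(unname(out$trace$occupancy[2, "death"]), 1)
  # only cycle-0 accrual remains; under end-of-cycle timing that is the
  # procedure bill on the cost side and nothing on the QALY side
  expect_equal(out$qalys, 0, tolerance = 1e-12)
  expect_equal(out$cost, get_param(b, "cba.cost_procedure"),
               tolerance = 1e-9)
})

test_that("setting CBA parameters equal to RFA's makes the arms identical", {
  b <- base_bundle()
  b$cba <- b$rfa
  cba <- strategy_outcomes(b, "cba")
  rfa <- strategy_outcomes(b, "rfa")
  expect_identical(cba$cost, rfa$cost)
  expect_identical(cba$qalys, rfa$qalys)
  expect_identical(cba$trace$occupancy, rfa$trace$occupancy)
})

test_that("raising first-year recurrence never helps", {
  b <- base_bundle()
  grid <- c(0.1, 0.269, 0.4, 0.6)
  qalys <- af_time <- numeric(length(grid))
  for (i in seq_along(grid)) {
    bi <- set_param(b, "cba.p_recur_y1", grid[i])
    out <- strategy_outcomes(bi, "cba")
    qalys[i] <- out$qalys
    af_time[i] <- sum(out$trace$occupancy[, c("af_post", "af_post_redo")])
  }
  expect_true(all(diff(qalys) <= 1e-12))
  expect_true(all(diff(af_time) >= -1e-12))
})

test_that("procedure cost enters linearly via the expected number of procedures", {
  b <- base_bundle()
  delta <- 250
  out0 <- strategy_outcomes(b, "cba")
  out1 <- strategy_outcomes(set_param(b, "cba.cost_procedure",
                                      get_param(b, "cba.cost_procedure") +
                                        delta), "cba")
  tr <- out0$trace
  df <- discount_factor(b$settings$discount_rate,
                        seq_len(nrow(tr$occupancy)) - 1L)
  w_cba <- get_param(b, "cba.p_redo_cba")
  # index procedure at cycle 0 plus CBA-modality re-interventions
  expected_procs <- sum(df * tr$arrivals[, "af_pre"]) +
    w_cba * sum(df * tr$arrivals[, "af_post"])
  expect_equal(out1$cost - out0$cost, delta * expected_procs,
               tolerance = 1e-9)
  expect_identical(out1$qalys, out0$qalys)
})

test_that("discounting monotonicity: undiscounted totals dominate", {
  b <- base_bundle()
  disc <- strategy_outcomes(b, "rfa")
  b0 <- set_param(b, "settings.discount_rate", 0)
  undisc <- strategy_outcomes(b0, "rfa")
  expect_gte(undisc$cost, disc$cost)
  expect_gte(undisc$qalys, disc$qalys)
})

test_that("model summary export is well-formed JSON", {
  m <- build_model(base_bundle(), "rfa")
  f <- tempfile(fileext = ".json")
  write_model_summary(m, f, k = 2)
  js <- jsonlite::read_json(f)
  expect_identical(unlist(js$states), m$space$states)
  expect_length(js$matrices, 2)
  expect_equal(js$rewards$state_utilities$nsr, 0.8)
})
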