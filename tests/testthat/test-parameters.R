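# Distribution fitting, rate conversions, and configuration I/O.

test_that("beta method-of-moments fit reproduces its target moments", {
  # uniform: mean 1/2, variance 1/12
  ab <- fit_beta_moments(0.5, sqrt(1 / 12))
  expect_equal(unname(ab), c(1, 1), tolerance = 1e-12)

  # published first-year CBA recurrence 0.269 +/- 0.0538
  ab <- fit_beta_moments(0.269, 0.0538)
  expect_equal(ab[["alpha"]], 18.0, tolerance = 0.01)
  expect_equal(ab[["beta"]], 48.9, tolerance = 0.01)

  # fit -> recompute moments is the identity, across feasible pairs
  for (m in c(0.0005, 0.05, 0.269, 0.5, 0.8, 0.9938)) {
    s <- 0.4 * sqrt(m * (1 - m))
    ab <- fit_beta_moments(m, s)
    a <- ab[["alpha"]]; b <- ab[["beta"]]
    expect_equal(a / (a + b), m, tolerance = 1e-9)
    expect_equal(sqrt(a * b / ((a + b)^2 * (a + b + 1))), s,
                 tolerance = 1e-9)
  }

  expect_error(fit_beta_moments(0.5, 0.6), class = "afcua_moments_error")
  expect_error(fit_beta_moments(1.2, 0.1), class = "afcua_moments_error")
})

test_that("gamma method-of-moments fit reproduces its target moments", {
  g <- fit_gamma_moments(4, 2)
  expect_equal(unname(g), c(4, 1), tolerance = 1e-12)

  g <- fit_gamma_moments(7751.88, 516.72)
  expect_equal(g[["shape"]], 225.07, tolerance = 1e-4)
  expect_equal(g[["scale"]], 34.44, tolerance = 1e-3)
  for (p in list(c(4, 2), c(7751.88, 516.72), c(0.01, 0.5), c(1e6, 10))) {
    g <- fit_gamma_moments(p[1], p[2])
    expect_equal(g[["shape"]] * g[["scale"]], p[1], tolerance = 1e-9)
    expect_equal(sqrt(g[["shape"]]) * g[["scale"]], p[2], tolerance = 1e-9)
  }
  expect_error(fit_gamma_moments(-1, 1), class = "afcua_moments_error")
  expect_error(fit_gamma_moments(1, 0), class = "afcua_moments_error")
})

test_that("sampling from fitted distributions recovers the target mean", {
  n <- 1e5
  withr::with_seed(42, {
    ab <- fit_beta_moments(0.269, 0.0538)
    x <- rbeta(n, ab[["alpha"]], ab[["beta"]])
    expect_lt(abs(mean(x) - 0.269), 3 * 0.0538 / sqrt(n))
    g <- fit_gamma_moments(7751.88, 516.72)
    y <- rgamma(n, shape = g[["shape"]], scale = g[["scale"]])
    expect_lt(abs(mean(y) - 7751.88), 3 * 516.72 / sqrt(n))
  })
})

test_that("probability/rate conversions are mutual inverses", {
  expect_identical(prob_to_rate(0), 0)
  expect_equal(prob_to_rate(0.05), 0.051293, tolerance = 1e-5)
  for (p in c(0, 0.001, 0.05, 0.3, 0.9, 0.999))
    expect_equal(rate_to_prob(prob_to_rate(p)), p, tolerance = 1e-12)
  expect_error(prob_to_rate(1), class = "afcua_domain_error")
  expect_error(rate_to_prob(-0.1), class = "afcua_domain_error")
})

test_that("life-table lookup follows the step convention with terminal absorption", {
  lt <- generate_life_table()
  expect_equal(mortality(lt, 50), 0.0037)
  expect_equal(mortality(lt, 50.9), 0.0037)   # greatest table age <= request
  expect_identical(mortality(lt, max(lt$age) + 5), 1)
  expect_error(mortality(lt, 40), class = "afcua_domain_error")
  # non-decreasing in age for the Gompertz construction
  expect_true(all(diff(mortality(lt, 50:100)) >= 0))
})

test_that("the shipped configuration file loads to the published values", {
  b <- load_config(shipped_config_path())
  expect_equal(get_param(b, "cba.cost_procedure"), 7751.88)
  expect_equal(get_param(b, "rfa.cost_procedure"), 5027.10)
  expect_equal(get_param(b, "cba.p_recur_y1"), 0.269)
  expect_equal(get_param(b, "shared.u_poststroke"), 0.46)
  expect_equal(get_param(b, "shared.cost_stroke_y1"), 1804.49)
  # and matches the in-code fixture exactly, end to end
  direct <- strategy_outcomes(table1_bundle(), "rfa")
  from_file <- strategy_outcomes(b, "rfa")
  expect_identical(direct$cost, from_file$cost)
  expect_identical(direct$qalys, from_file$qalys)
})

test_that("configuration errors name the offending key or bound", {
  raw <- yaml::read_yaml(shipped_config_path())
  raw$life_table <- NULL

  bad <- raw
  bad$rfa$p_stroke <- 1.2
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_config(f), "p_stroke", class = "afcua_validation_error")

  bad <- raw
  bad$settings$discount_rate <- NULL
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_config(f), "discount_rate", class = "afcua_config_error")

  bad <- raw
  bad$shared$made_up_key <- 1
  f <- tempfile(fileext = ".yaml"); yaml::write_yaml(bad, f)
  expect_error(load_config(f), "made_up_key", class = "afcua_config_error")

  expect_error(load_config(tempfile()), class = "afcua_config_error")
})

test_that("default-SD policy and DSA bounds follow the stated conventions", {
  b <- base_bundle()
  # blank-SD probability gets 20% of mean, blank-SD cost 10% of mean
  expect_equal(b$cba$p_phrenic$sd, 0.2 * 0.032)
  expect_equal(b$rfa$cost_vascular$sd, 0.1 * 60.23)
  expect_equal(b$shared$p_stroke_death$sd, 0.2 * 0.3536)
  # phrenic-palsy cost takes the policy SD, not the pericardial row's
  expect_equal(b$cba$cost_phrenic$sd, 0.1 * 11.09)
  # bounds default to +/- 2 SD clipped to the domain
  expect_equal(unname(param_bounds(b, "rfa.p_recur_y1")),
               c(0.3326 - 2 * 0.0665, 0.3326 + 2 * 0.0665))
  expect_gte(param_bounds(b, "shared.du_stroke_y1")[["low"]], -1)
  expect_equal(unname(param_bounds(b, "settings.discount_rate")), c(0, 0.1))
})

test_that("parameter paths resolve and reject unknown names", {
  b <- base_bundle()
  expect_equal(get_param(b, "shared.u_nsr"), 0.8)
  b2 <- set_param(b, "rfa.cost_procedure", 6000)
  expect_equal(get_param(b2, "rfa.cost_procedure"), 6000)
  expect_equal(get_param(b, "rfa.cost_procedure"), 5027.10) # value semantics
  expect_error(get_param(b, "rfa.no_such"), class = "afcua_name_error")
  expect_error(set_param(b, "nonsense", 1), class = "afcua_name_error")
})

test_that("bundle validation enforces the re-intervention simplex", {
  b <- base_bundle()
  b$rfa$p_redo_rfa$base <- 0.7
  b$rfa$p_redo_cba$base <- 0.5
  b$rfa$p_redo_rfa$high <- 0.7
  b$rfa$p_redo_cba$high <- 0.5
  expect_error(validate_bundle(b), "p_redo",
               class = "afcua_validation_error")
})
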