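# Deterministic and probabilistic sensitivity analyses.

test_that("one-way sweep at the base value reproduces the base case", {
  b <- base_bundle()
  base <- cua(b)
  ow <- one_way(b, "rfa.cost_procedure",
                grid = c(4500, get_param(b, "rfa.cost_procedure"), 6500))
  mid <- ow[2, ]
  expect_equal(mid$icer, base$ce$icer, tolerance = 1e-12)
  expect_identical(mid$verdict, base$ce$verdict)
  # verdict flips from not-cost-effective to cost-effective as the
  # comparator's procedure cost rises across the sweep
  expect_identical(ow$verdict[1], "not_cost_effective_at_wtp")
  expect_identical(ow$verdict[3], "cost_effective_at_wtp")
  expect_error(one_way(b, "rfa.bogus", grid = 1),
               class = "afcua_name_error")
  expect_identical(nrow(one_way(b, "rfa.cost_procedure",
                                grid = numeric(0))), 0L)
})

test_that("two-way grid is a monotone verdict surface in the procedure costs", {
  b <- base_bundle()
  tw <- two_way(b, "rfa.cost_procedure", "cba.cost_procedure",
                grid_a = c(4000, 5027.10, 6500),
                grid_b = c(7000, 7751.88, 8500))
  expect_identical(dim(tw), c(3L, 3L))
  expect_identical(tw["5027.1", "7751.88"], cua(b)$ce$verdict)
  # raising CBA cost (left to right) never turns a cell cost-effective
  ce <- tw %in% c("cost_effective_at_wtp", "dominant")
  dim(ce) <- dim(tw)
  for (i in 1:3) expect_true(all(diff(ce[i, ]) <= 0))
  # raising RFA cost (top to bottom) never turns a cell not-cost-effective
  for (j in 1:3) expect_true(all(diff(ce[, j]) >= 0))
})

test_that("tornado entries are spread-sorted with consistent crossing flags", {
  b <- base_bundle()
  tn <- tornado(b)
  expect_true(all(diff(tn$spread) <= 1e-9))
  expect_true(all(tn$spread >= 0))
  expect_setequal(tn$parameter, tornado_parameters())
  # crossing flag means the verdict differs between the two bounds, i.e.
  # the incremental NMB changes sign
  expect_identical(tn$crosses_wtp, sign(tn$nmb_low) != sign(tn$nmb_high))

  # zero-width ranges give zero spreads
  b2 <- b
  for (p in c("cba.cost_procedure", "rfa.cost_procedure")) {
    pr <- afcua:::resolve_param(b2, p)
    b2[[pr$block]][[pr$name]]$low <- get_param(b2, p)
    b2[[pr$block]][[pr$name]]$high <- get_param(b2, p)
  }
  tn2 <- tornado(b2, c("cba.cost_procedure", "rfa.cost_procedure"))
  expect_equal(tn2$spread, c(0, 0))
  expect_false(any(tn2$crosses_wtp))
})

test_that("bisection finds linear roots and rejects same-sign brackets", {
  r <- bisect_root(function(v) v - 5, 0, 10, tol = 1e-6)
  expect_equal(r$root, 5, tolerance = 1e-5)
  expect_lte(r$achieved_tolerance, 1e-6)
  expect_error(bisect_root(function(v) v + 1, 0, 10),
               class = "afcua_threshold_error")
})

test_that("threshold search localises the verdict flip on the RFA cost", {
  b <- base_bundle()
  thr <- find_threshold(b, "rfa.cost_procedure", bracket = c(4000, 8000),
                        tol = 0.5)
  v <- thr$value_at_threshold
  expect_gt(v, 4000); expect_lt(v, 8000)
  expect_lte(thr$achieved_tolerance, 0.5)
  below <- cua(set_param(b, "rfa.cost_procedure", v - 5))$ce$verdict
  above <- cua(set_param(b, "rfa.cost_procedure", v + 5))$ce$verdict
  expect_identical(below, "not_cost_effective_at_wtp")
  expect_identical(above, "cost_effective_at_wtp")
  # a parameter whose range never flips the verdict has no threshold
  expect_error(find_threshold(b, "rfa.p_redo_cba"),
               class = "afcua_threshold_error")
})

test_that("plane classification matches the six-component rule", {
  wtp <- 7142
  expect_identical(classify_quadrant(0.1, -5, wtp), "C1")
  expect_identical(classify_quadrant(-0.1, 5, wtp), "C6")
  expect_identical(classify_quadrant(1, wtp + 1, wtp), "C4")
  expect_identical(classify_quadrant(1, wtp - 1, wtp), "C2")
  expect_identical(classify_quadrant(-1, -wtp - 1, wtp), "C3")
  expect_identical(classify_quadrant(-1, -wtp + 1, wtp), "C5")
  # ties: effect ties classify by cost alone, the origin is indifferent
  expect_identical(classify_quadrant(0, -1, wtp), "C1")
  expect_identical(classify_quadrant(0, 1, wtp), "C6")
  expect_identical(classify_quadrant(0, 0, wtp), "Indiff")
  expect_identical(classify_quadrant(1, 0, wtp), "C2")
  expect_identical(classify_quadrant(-1, 0, wtp), "C5")
  # the cost-effective components are exactly the positive-NMB half-plane
  withr::with_seed(3, {
    de <- runif(500, -1, 1); dc <- runif(500, -1e4, 1e4)
    comp <- classify_quadrant(de, dc, wtp)
    expect_identical(comp %in% c("C1", "C2", "C3"),
                     wtp * de - dc > 0)
  })
})

test_that("acceptability curve is the NMB exceedance fraction", {
  samples <- data.frame(delta_eff = c(0.5, -0.2, 0.1, 0.3),
                        delta_cost = c(1000, -500, -200, 4000))
  cc <- ceac(samples, wtp_grid = 0)
  expect_equal(cc$probability, mean(samples$delta_cost < 0))
  # identical draws step from 0 to 1 at their own ICER
  one <- data.frame(delta_eff = rep(0.2, 5), delta_cost = rep(1000, 5))
  expect_equal(ceac(one, wtp_grid = c(4999, 5001))$probability, c(0, 1))
  cc <- ceac(samples, wtp_grid = seq(0, 2e4, by = 2500))
  expect_true(all(cc$probability >= 0 & cc$probability <= 1))
  expect_error(ceac(samples[0, ]), class = "afcua_domain_error")
})

test_that("PSA is seed-reproducible and partitions its draws", {
  b <- base_bundle()
  p1 <- run_psa(b, n_draws = 40, seed = 123)
  p2 <- run_psa(b, n_draws = 40, seed = 123)
  expect_identical(p1$samples, p2$samples)
  q <- p1$quadrants
  expect_identical(sum(q$frequency), 40L)
  expect_equal(sum(q$proportion), 1, tolerance = 1e-9)
  expect_equal(attr(q, "p_cost_effective_new") +
                 attr(q, "p_cost_effective_comparator"), 1)
  # CEAC evaluated at the analysis threshold equals the quadrant probability
  expect_equal(ceac(p1, wtp_grid = b$settings$wtp)$probability,
               attr(q, "p_cost_effective_new"))
  # a single draw is a unit mass on one component
  p3 <- run_psa(b, n_draws = 1, seed = 4)
  expect_identical(sort(p3$quadrants$frequency), c(0L, 0L, 0L, 0L, 0L, 0L, 1L))
})

test_that("degenerate distributions reproduce the base case draw by draw", {
  b <- zero_sds(base_bundle())
  base <- cua(b)
  psa <- run_psa(b, n_draws = 3, seed = 99)
  expect_equal(psa$samples$delta_cost, rep(base$ce$delta_cost, 3),
               tolerance = 1e-12)
  expect_equal(psa$samples$delta_eff, rep(base$ce$delta_eff, 3),
               tolerance = 1e-12)
})

test_that("quadrant proportions agree across seeds within sampling error", {
  b <- base_bundle()
  n <- 300
  pa <- run_psa(b, n_draws = n, seed = 1)
  pb <- run_psa(b, n_draws = n, seed = 2)
  p1 <- attr(pa$quadrants, "p_cost_effective_new")
  p2 <- attr(pb$quadrants, "p_cost_effective_new")
  se <- sqrt(p1 * (1 - p1) / n + p2 * (1 - p2) / n)
  expect_lt(abs(p1 - p2), 3 * se)
})
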