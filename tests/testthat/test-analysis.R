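test_that("convergence rate recovers exact slopes and crossing times", {
  t <- seq(0, 10, by = 0.5)
  est <- convergence_rate(0.3 * (t - 4), t)
  expect_equal(est$rate, 0.3, tolerance = 1e-12)
  expect_equal(est$crossing_time, 4)
  expect_equal(est$r_squared, 1)
  expect_equal(diff(est$window) + 1L, 10L)
})

test_that("convergence rate matches the analytic tanh derivative", {
  a <- 0.2
  t <- seq(0, 60, by = 0.04 / a)  # dense sampling near the crossing
  b <- tanh(a * (t - 30))
  est <- convergence_rate(b, t)
  expect_lt(abs(est$rate - a) / a, 0.02)
  expect_lt(abs(est$crossing_time - 30), 0.5)
})

test_that("series that never cross zero raise a typed error", {
  t <- 0:20
  expect_error(convergence_rate(-1 + 0.01 * t, t),
               class = "coopnet_no_crossing")
  expect_s3_class(convergence_rate(c(-0.1, 0, 0.1), 0:2), "rate_estimate")
})

test_that("rates rescale exactly under affine time re-indexing", {
  t <- seq(0, 10, by = 0.5)
  b <- tanh(0.4 * (t - 5)) + 0.01 * sin(7 * t)
  r1 <- convergence_rate(b, t)$rate
  r2 <- convergence_rate(b, 3 + 2 * t)$rate
  expect_equal(r2, r1 / 2, tolerance = 1e-12)
})

test_that("bisection recovers the root of an injected fraction curve", {
  cfg <- network_config(n_nodes = 20, growth_degree = 2, seed = 1)
  sch <- quick_schedule(n_realizations = 10)
  logistic <- function(phi) stats::plogis((phi - 0.0103) / 0.002)
  est <- estimate_tipping_point(cfg, model_params(), sch,
                                phi_bracket = c(0, 0.05),
                                tolerance = 5e-4,
                                fraction_fun = logistic)
  expect_lt(abs(est$phi_critical - 0.0103), 5e-4)
  expect_lte(diff(est$bracket), 5e-4)
  expect_true(est$phi_critical >= est$bracket[1] &&
                est$phi_critical <= est$bracket[2])
  expect_true(all(diff(est$fraction_curve$n) == 0))
})

test_that("non-straddling brackets raise a typed bracket error", {
  cfg <- network_config(n_nodes = 20, growth_degree = 2, seed = 1)
  sch <- quick_schedule(n_realizations = 10)
  expect_error(
    estimate_tipping_point(cfg, model_params(), sch,
                           phi_bracket = c(0.04, 0.05),
                           fraction_fun = function(phi) 1),
    class = "coopnet_bracket_error")
})

test_that("stage diagnostics recover exact exponential decay", {
  t <- seq(0, 200, by = 2)
  b <- 1 - exp(-0.05 * t)
  d <- exponential_stage_diagnostics(b, t)
  expect_true(d$applicable)
  expect_equal(d$mid_slope, -0.05, tolerance = 1e-9)
  expect_equal(d$late_slope, -0.05, tolerance = 1e-9)
  expect_gt(d$r_squared, 0.999)
})

test_that("stage diagnostics locate a two-regime change point", {
  t <- seq(0, 300, by = 2)
  tb <- 150
  logy <- ifelse(t <= tb, -0.08 * t, -0.08 * tb - 0.01 * (t - tb))
  b <- 1 - exp(logy)
  d <- exponential_stage_diagnostics(b, t)
  expect_true(d$applicable)
  expect_lt(abs(d$boundary_time - tb), 10)
  expect_equal(d$mid_slope, -0.08, tolerance = 0.005)
  expect_equal(d$late_slope, -0.01, tolerance = 0.005)
  expect_lt(abs(d$late_slope), abs(d$mid_slope))
})

test_that("stage diagnostics refuse non-converging trajectories", {
  t <- 0:50
  d <- exponential_stage_diagnostics(rep(-0.8, 51), t)
  expect_false(d$applicable)
  expect_true(is.na(d$mid_slope))
})

test_that("identical sweep configurations give identical rates", {
  cfg <- network_config(n_nodes = 300, growth_degree = 6, seed = 3)
  p <- model_params(phi = 0.08)
  sch <- sim_schedule(max_sweeps = 200, absorption_tol = 1e-2,
                      n_realizations = 8, base_seed = 91)
  tab <- rate_vs_parameter(
    list(a = list(network = cfg, params = p),
         b = list(network = cfg, params = p)),
    sch, parameter = c(1, 2), n_boot = 50)
  expect_true(all(tab$crossed))
  expect_equal(tab$rate[1], tab$rate[2])
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$se > 0))
})
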