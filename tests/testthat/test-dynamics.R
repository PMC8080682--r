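test_that("response function saturates outside the noise window", {
  expect_equal(response_f(0.2, 0.1, 0.05), 1)
  expect_equal(response_f(-0.2, 0.1, -0.03), 0)
  expect_equal(response_f(0, 0.1, 0), 0.5)
  expect_equal(response_f(0, 0.1, 0, "ramp_plus_noise"), 0.5)
  expect_error(response_f(0, -1, 0), "positive")
  expect_error(response_f(0, 0.1, 0.5), "xi")
  xs <- seq(-0.3, 0.3, by = 0.01)
  for (mode in c("pure_noise", "ramp_plus_noise")) {
    vals <- response_f(xs, 0.1, 0.02, mode)
    expect_true(all(vals >= 0 & vals <= 1))
  }
})

test_that("mean response matches the integration oracle and is monotone", {
  r <- 0.1
  set.seed(1)
  for (mode in c("pure_noise", "ramp_plus_noise")) {
    for (x in c(-0.15, -0.05, 0, 0.05, 0.15)) {
      xi <- stats::runif(2e4, -r, r)
      mc <- mean(response_f(x, r, xi, mode))
      expect_lt(abs(mc - expected_f(x, r, mode)), 0.01)
    }
    ef <- vapply(seq(-0.15, 0.15, by = 0.01), expected_f, numeric(1),
                 r = r, mode = mode)
    expect_false(is.unsorted(ef))
  }
  # frozen value from the integration oracle for the ramp variant
  expect_equal(expected_f(0.05, 0.1, "ramp_plus_noise"), 0.71875,
               tolerance = 1e-6)
})

test_that("agreeing agents never move each other", {
  p <- model_params()
  for (b in c(-1, -0.3, 0.3, 1)) {
    upd <- interaction_update(b, b, 0.6, 0.5, p, xi = 0.07)
    expect_identical(upd$trace$delta_b, 0)
    expect_identical(upd$b_i_new, b)
  }
})

test_that("the two printed update forms are algebraically identical", {
  set.seed(7)
  for (k in 1:500) {
    b_i <- stats::runif(1, -1, 1); b_j <- stats::runif(1, -1, 1)
    w_plus <- stats::runif(1)
    eq_two_weight <- abs(b_i - b_j) *
      (w_plus * (1 - b_i) - (1 - w_plus) * (1 + b_i))
    eq_compact <- abs(b_i - b_j) * (2 * w_plus - b_i - 1)
    expect_equal(eq_compact, eq_two_weight, tolerance = 1e-14)
  }
})

test_that("updates clip to the behaviour range and record a full trace", {
  p <- model_params()
  # saturated response: raw jump of +4 from -1, clipped at +1
  upd <- interaction_update(-1, 1, 0.6, 2, p, xi = 0)
  expect_equal(upd$trace$w_plus, 1)
  expect_equal(upd$trace$delta_b, 4)
  expect_equal(upd$b_i_new, 1)
  # stimulus arithmetic at the standard parameters
  upd <- interaction_update(-1, 1, 0.6, 0.5, p, xi = 0)
  expect_equal(upd$trace$x, -0.6 + 0.5 + 0.05)
  expect_equal(upd$trace$w_minus, 1 - upd$trace$w_plus)
  expect_error(interaction_update(1.2, 0, 0.6, 0.5, p), "\\[-1, 1\\]")
})

test_that("initial behaviours are clipped gaussian draws", {
  expect_equal(draw_initial_behaviours(5, -0.25, 0, seed = 1),
               rep(-0.25, 5))
  expect_equal(draw_initial_behaviours(5, -5, 0.1, seed = 1), rep(-1, 5))
  b <- draw_initial_behaviours(1e5, -0.25, 0.15, seed = 2)
  expect_lt(abs(mean(b) + 0.25), 0.005)
  expect_true(all(abs(b) <= 1))
})

test_that("event selection favours hubs as persuaders", {
  net <- star_network(4)
  p <- model_params()
  st <- realization_state(rep(0.1, 5))
  set.seed(3)
  hub_as_j <- 0L
  for (k in 1:20000) {
    st <- simulation_step(st, net, p)
    tr <- st$last_trace
    if (!is.null(tr) && tr$j == 1L) hub_as_j <- hub_as_j + 1L
  }
  # i uniform, j uniform over i's neighbours: hub is j in (N-1)/N of events
  expect_lt(abs(hub_as_j / 20000 - 4 / 5), 0.015)
})

test_that("compiled engine replays the reference stepper bit for bit", {
  net <- tiny_csf(25, 3)
  p <- model_params()
  sch <- quick_schedule(max_sweeps = 30)
  for (mode in c("pure_noise", "ramp_plus_noise")) {
    pm <- model_params(middle_branch_mode = mode)
    a <- run_realization(net, pm, sch, seed = 11, engine = "cpp")
    b <- run_realization(net, pm, sch, seed = 11, engine = "r")
    expect_identical(a$mean_b, b$mean_b)
    expect_identical(a$final_behaviours, b$final_behaviours)
  }
})

test_that("trajectories are reproducible and stay in range", {
  net <- tiny_csf(40, 4)
  p <- model_params()
  sch <- quick_schedule(max_sweeps = 80)
  a <- run_realization(net, p, sch, seed = 5)
  b <- run_realization(net, p, sch, seed = 5)
  expect_identical(a$mean_b, b$mean_b)
  expect_true(all(abs(a$final_behaviours) <= 1))
  expect_true(all(abs(a$mean_b) <= 1))
  expect_equal(a$time, seq_along(a$time) - 1)
})

test_that("homogeneous extreme states are absorbing for any field", {
  net <- tiny_csf(20, 3)
  sch <- quick_schedule(max_sweeps = 10)
  for (phi in c(-0.3, 0, 0.05)) {
    p <- model_params(phi = phi)
    up <- run_realization(net, p, sch, seed = 1,
                          behaviours = rep(1, net$n_nodes))
    expect_identical(up$classification, "cooperative")
    expect_identical(up$absorb_time, 0)
    dn <- run_realization(net, p, sch, seed = 1,
                          behaviours = rep(-1, net$n_nodes))
    expect_identical(dn$classification, "defective")
  }
  # any homogeneous state is frozen: the agreement prefactor vanishes
  st <- realization_state(rep(0.3, 20))
  p <- model_params()
  set.seed(9)
  for (k in 1:200) st <- simulation_step(st, net, p)
  expect_identical(st$behaviours, rep(0.3, 20))
})

test_that("one-event expectation matches the closed-form oracle", {
  p <- model_params()
  net <- pair_network(w = 0.5)
  b0 <- c(-0.2, 0.1)
  # oracle: average over the uniform choice of updated agent, with E[f]
  # from numeric integration (no clipping in the reachable range)
  e1 <- expected_update(b0[1], b0[2], 0.6, 0.5, 0.05, 0.1, "pure_noise")
  e2 <- expected_update(b0[2], b0[1], 0.6, 0.5, 0.05, 0.1, "pure_noise")
  oracle <- ((e1 + b0[2]) / 2 + (b0[1] + e2) / 2) / 2
  means <- vapply(1:20000, function(s) {
    set.seed(s)
    st <- simulation_step(realization_state(b0), net, p)
    mean(st$behaviours)
  }, numeric(1))
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - oracle), 4 * se + 1e-4)
})

test_that("mirrored parameters give exactly mirrored single updates", {
  p_plus <- model_params(phi = 0.03)
  p_minus <- model_params(phi = -0.03)
  set.seed(13)
  for (k in 1:200) {
    b_i <- stats::runif(1, -1, 1); b_j <- stats::runif(1, -1, 1)
    w <- stats::rnorm(1, 0.5, 0.15); xi <- stats::runif(1, -0.1, 0.1)
    a <- interaction_update(b_i, b_j, 0.6, w, p_plus, xi = xi)
    m <- interaction_update(-b_i, -b_j, 0.6, w, p_minus, xi = -xi)
    expect_equal(m$b_i_new, -a$b_i_new, tolerance = 1e-12)
  }
})

test_that("mirrored ensembles are statistically indistinguishable", {
  cfg <- network_config(n_nodes = 100, growth_degree = 4, seed = 1)
  sch <- sim_schedule(max_sweeps = 200, absorption_tol = 1e-2,
                      n_realizations = 100, base_seed = 55)
  a <- run_ensemble(cfg, model_params(phi = 0.02), sch)
  b <- run_ensemble(cfg, model_params(phi = -0.02, init_mean = 0.25), sch)
  fa <- a$mean_b[, ncol(a$mean_b)]
  fb <- -b$mean_b[, ncol(b$mean_b)]
  expect_gt(stats::wilcox.test(fa, fb, exact = FALSE)$p.value, 0.01)
})
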