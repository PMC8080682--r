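test_that("social_network validates its invariants", {
  expect_error(social_network(3, rbind(c(1, 1)), 1), "self-loop")
  expect_error(social_network(3, rbind(c(1, 2), c(2, 1)), c(1, 2)),
               "duplicate")
  expect_error(social_network(3, rbind(c(1, 4)), 1), "outside")
  expect_error(social_network(3, rbind(c(1, 2)), c(1, 2)), "one weight")
  net <- social_network(3, rbind(c(1, 2), c(2, 3)), c(0.2, -0.4))
  expect_equal(node_degrees(net), c(1L, 2L, 1L))
  # weight lookup is orientation-independent in the CSR expansion
  csr <- net$csr
  w12 <- csr$w[csr$ptr[1] + 1]          # edge seen from node 1
  w21 <- csr$w[csr$ptr[2] + which(csr$nbr[(csr$ptr[2] + 1):csr$ptr[3]] == 0L)]
  expect_identical(w12, w21)
})

test_that("Holme-Kim generator is reproducible and validates input", {
  expect_error(build_holme_kim(10, 10, 0.5, 1), "growth_degree")
  expect_error(build_holme_kim(10, 2, 1.5, 1), "triad_probability")
  a <- build_holme_kim(10, 2, 0.5, seed = 7)
  b <- build_holme_kim(10, 2, 0.5, seed = 7)
  expect_identical(a$edges, b$edges)
  expect_false(identical(a$edges, build_holme_kim(10, 2, 0.5, 8)$edges))
})

test_that("Holme-Kim graphs are connected with the expected mean degree", {
  n <- 200; k0 <- 4
  degs <- vapply(1:20, function(s) {
    net <- build_holme_kim(n, k0, 0.5, seed = s)
    expect_true(is_connected_network(net))
    mean(node_degrees(net))
  }, numeric(1))
  # growth adds k0 edges per new node: mean degree ~ 2 k0 (1 - k0/n)
  expect_lt(abs(mean(degs) - 2 * k0 * (1 - k0 / n)), 0.2)
  # heavy tail: max degree far above the mean, unlike any grid
  net <- build_holme_kim(1089, 8, 0.5, seed = 1)
  expect_gt(max(node_degrees(net)), 4 * mean(node_degrees(net)))
})

test_that("triad formation raises clustering above preferential attachment", {
  cc <- function(p, seeds) {
    vapply(seeds, function(s) {
      g <- as_igraph(build_holme_kim(300, 4, p, seed = s))
      igraph::transitivity(g, type = "average")
    }, numeric(1))
  }
  cc0 <- cc(0, 1:50)
  cc5 <- cc(0.5, 51:100)
  expect_lt(stats::t.test(cc5, cc0, alternative = "greater")$p.value, 1e-6)
  expect_gt(mean(cc5), 2 * mean(cc0))
})

test_that("periodic grids are regular with the documented degrees", {
  cases <- list(von_neumann4 = 4L, moore8 = 8L, manhattan2_12 = 12L,
                degree16 = 16L, chebyshev2_24 = 24L)
  for (nm in names(cases)) {
    net <- build_periodic_grid(13, nm)
    expect_equal(net$n_nodes, 169L)
    expect_true(all(node_degrees(net) == cases[[nm]]))
    expect_equal(nrow(net$edges), 169L * cases[[nm]] / 2L)
    expect_true(is_connected_network(net))
  }
})

test_that("degree16 neighbourhood has 16 symmetric offsets", {
  off <- coopnet:::grid_offsets("degree16")
  expect_equal(nrow(off), 16L)
  # symmetric: the negation of every offset is present
  key <- paste(off$dr, off$dc)
  expect_setequal(paste(-off$dr, -off$dc), key)
  expect_false(any(off$dr == 0 & off$dc == 0))
})

test_that("too-small grids are rejected when the neighbourhood wraps", {
  expect_error(build_periodic_grid(3, "chebyshev2_24"), "too small")
  expect_error(build_periodic_grid(4, "degree16"), "too small")
  expect_s3_class(build_periodic_grid(5, "chebyshev2_24"),
                  "social_network")
})

test_that("edge weights follow the configured normal distribution", {
  net <- build_periodic_grid(33, "manhattan2_12")  # 6534 edges
  w0 <- assign_edge_weights(net, 0.5, 0, seed = 1)
  expect_true(all(w0$weights == 0.5))
  net <- assign_edge_weights(net, 0.5, 0.15, seed = 2)
  net2 <- assign_edge_weights(net, 0.5, 0.15, seed = 2)
  expect_identical(net$weights, net2$weights)
  expect_gt(nrow(net$edges), 6000)
  expect_lt(abs(mean(net$weights) - 0.5), 0.01)
  expect_lt(abs(stats::sd(net$weights) - 0.15), 0.01)
  expect_gt(min(net$weights), -1)  # negative draws retained, not clipped
})

test_that("edge-list files round-trip and reject malformed input", {
  path <- withr::local_tempfile(fileext = ".edges")
  writeLines("0 1 0.5", path)
  net <- load_edge_list(path)
  expect_equal(net$n_nodes, 2L)
  expect_equal(net$weights, 0.5)

  csf <- tiny_csf(40, 4)
  write_edge_list(csf, path)
  back <- load_edge_list(path, n_nodes = csf$n_nodes)
  expect_identical(back$edges[order(back$edges[, 1], back$edges[, 2]), ],
                   csf$edges[order(csf$edges[, 1], csf$edges[, 2]), ])
  o1 <- order(csf$edges[, 1], csf$edges[, 2])
  o2 <- order(back$edges[, 1], back$edges[, 2])
  expect_equal(back$weights[o2], csf$weights[o1])

  writeLines("0 0 1.0", path)
  expect_error(load_edge_list(path), "line 1.*self-loop")
  writeLines(c("0 1 0.5", "1 0 0.2"), path)
  expect_error(load_edge_list(path), "line 2.*duplicate")
  writeLines("0 1 abc", path)
  expect_error(load_edge_list(path), "line 1.*non-numeric")
})

test_that("generate_network reproduces topology and weights from one seed", {
  cfg <- network_config(n_nodes = 60, growth_degree = 3, seed = 9)
  n1 <- generate_network(cfg)
  n2 <- generate_network(cfg)
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$weights, n2$weights)
  expect_error(network_config(topology = "hexagon"), "topology")
  expect_error(network_config(growth_degree = 2000, n_nodes = 100),
               "growth_degree")
})
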