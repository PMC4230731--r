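test_that("effective drive combines intrinsic and network fields", {
  p <- mean_field_problem(two_node_bi_adj(), c(1.2, 0.7), 1)
  expect_equal(effective_drive(p, c(0, 0)), c(0, 0))
  p0 <- mean_field_problem(two_node_bi_adj(), c(1.2, 0.7), 0)
  expect_equal(effective_drive(p0, c(0.4, 0.5)), c(1.2 * 0.4, 0.7 * 0.5))
  pk <- mean_field_problem(two_node_bi_adj(), 0, 1)
  expect_equal(effective_drive(pk, c(0.3, 0.5)), c(0.5, 0.3))
  expect_error(effective_drive(p, c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("Bessel form and quadrature of the locking integral agree", {
  pb <- mean_field_problem(matrix(0, 1, 1), 10, 0)  # drive X = 10 * r
  for (x in c(0.01, 0.05, 0.2, 0.5, 1, 2, 5, 10)) {
    b <- self_consistency_map(pb, x / 10, method = "bessel")
    q <- self_consistency_map(pb, x / 10, method = "quadrature")
    expect_lt(abs(b - q), 1e-8)
  }
  ## non-unit sd normal too
  ps <- mean_field_problem(matrix(0, 1, 1), 3,
                           0, density = normal_freq_density(sd = 2))
  for (r in c(0.2, 0.6, 1)) {
    expect_lt(abs(self_consistency_map(ps, r, method = "bessel") -
                    self_consistency_map(ps, r, method = "quadrature")),
              1e-8)
  }
})

test_that("self-consistency map has the expected fixed-point structure", {
  p <- mean_field_problem(two_node_bi_adj(), 1, 0.5)
  expect_equal(self_consistency_map(p, c(0, 0)), c(0, 0))
  ## full-locking limit: huge intrinsic coupling drives the map to 1
  pbig <- mean_field_problem(matrix(0, 1, 1), 60, 0)
  expect_gt(self_consistency_map(pbig, 1), 0.999)
  ## monotone: componentwise larger input never decreases the output
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(runif(9, 0, 1), 3); diag(A) <- 0
    pr <- mean_field_problem(A, runif(3, 0, 1.4), runif(1, 0, 2))
    r1 <- runif(3)
    r2 <- pmin(r1 + runif(3, 0, 1 - max(r1)), 1)
    expect_true(all(self_consistency_map(pr, r2) >=
                      self_consistency_map(pr, r1) - 1e-12))
  }
})

test_that("single-node critical coupling is recovered two ways", {
  Kc_lin <- single_node_critical_coupling(normal_freq_density())
  Kc_bis <- single_node_critical_coupling(normal_freq_density(),
                                          method = "bisection")
  expect_equal(Kc_lin, sqrt(8 / pi), tolerance = 1e-12)
  expect_lt(abs(Kc_bis - sqrt(8 / pi)), 1e-8)
  ## scaling: doubling the sd halves g(0), doubling K_c
  expect_equal(single_node_critical_coupling(normal_freq_density(sd = 2)),
               2 * sqrt(8 / pi), tolerance = 1e-12)
  ## uniform density on [-sqrt(3), sqrt(3)]: K_c = 2 / (pi g(0))
  uni <- uniform_freq_density()
  expect_equal(single_node_critical_coupling(uni),
               2 / (pi * uni$g0), tolerance = 1e-12)
  expect_lt(abs(single_node_critical_coupling(uni, "bisection") -
                  2 / (pi * uni$g0)), 1e-6)
})

test_that("asymmetric or zero-mass densities are rejected", {
  expect_error(freq_density(function(w) dnorm(w, mean = 0.5)), "symmetric")
  shifted <- structure(list(g = function(w) dnorm(w), g0 = 0,
                            type = "broken", sd = 1),
                       class = "freq_density")
  expect_error(single_node_critical_coupling(shifted), "onset")
})

test_that("solver returns the correct branch for decoupled nodes", {
  Kc <- KC_NORMAL
  s0 <- solve_mean_field(mean_field_problem(two_node_bi_adj(0), 0.8 * Kc,
                                            0))
  expect_equal(s0$node_r, c(0, 0))
  expect_identical(s0$branch, "zero")
  s1 <- solve_mean_field(mean_field_problem(two_node_bi_adj(0),
                                            c(2, 0.5 * Kc), 0))
  expect_gt(s1$node_r[1], 0.5)
  expect_equal(s1$node_r[2], 0)
  expect_identical(s1$branch, "locked")
})

test_that("locked-branch fixed point matches a large-N simulation", {
  sol <- solve_mean_field(mean_field_problem(matrix(0, 1, 1), 2, 0))
  spec <- modular_network_spec(matrix(0, 1, 1), 2,
                               oscillators_per_node = 1e4)
  sim <- mean(simulated_mean_r(spec, 50, seed = 3)$node_r)
  expect_lt(abs(sol$node_r[1] - sim), 0.02)
})

test_that("two-node solve crosses onset where the eigenvalue analysis says", {
  Kc <- KC_NORMAL
  K <- 0.5 * Kc
  kc <- kappa_c_eigen(two_node_bi_adj(), K, Kc)$kappa_c
  below <- solve_mean_field(mean_field_problem(two_node_bi_adj(), K,
                                               0.95 * kc))
  above <- solve_mean_field(mean_field_problem(two_node_bi_adj(), K,
                                               1.05 * kc))
  expect_identical(below$branch, "zero")
  expect_identical(above$branch, "locked")
  expect_true(all(above$node_r > 0))
})

test_that("analytic global order parameter is the mean of node r", {
  expect_equal(global_order_parameter(c(1, 1, 1)), 1)
  expect_equal(global_order_parameter(c(1, 0)), 0.5)
  ## 3-cycle beyond onset: analytic R matches the simulated global R
  Kc <- KC_NORMAL
  A <- cycle_adjacency(3)
  kc <- kappa_c_eigen(A, 0.5 * Kc, Kc)$kappa_c
  sol <- solve_mean_field(mean_field_problem(A, 0.5 * Kc, 1.5 * kc))
  expect_equal(global_order_parameter(sol), mean(sol$node_r))
  spec <- modular_network_spec(A, 0.5 * Kc, global_coupling = 1.5 * kc,
                               oscillators_per_node = 2000)
  sim <- simulated_mean_r(spec, 60, seed = 6)
  expect_lt(abs(global_order_parameter(sol) - sim$R), 0.05)
})

test_that("unidirectional drive leaves the analytic downstream at zero but
           the finite-size drift shrinks with N", {
  Kc <- KC_NORMAL
  A <- matrix(c(0, 1, 0, 0), 2)   # node 1 drives node 2
  K <- 0.5 * Kc
  sol <- solve_mean_field(mean_field_problem(A, K, 1))
  expect_equal(sol$node_r, c(0, 0))
  r_at <- function(N) {
    spec <- modular_network_spec(A, K, global_coupling = 1,
                                 oscillators_per_node = N)
    simulated_mean_r(spec, 40, seed = 17)$node_r[2]
  }
  expect_gt(r_at(400), r_at(3600))
})
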