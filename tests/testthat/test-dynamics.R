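test_that("OR derivative at the origin equals unrepressed production", {
  net <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.5,
                     production_basal = 0.1, production_max = 7)
  f <- cfr_rhs(net, coupling_schedule("constant", 2))
  expect_equal(f(0, c(0, 0, 0)), rep(0.1 + 7, 3))
})

test_that("OR symmetric fixed point from a root-finding oracle has zero derivative", {
  net <- cfr_network(3, "all_pairs", "OR", coupling_forward = 1,
                     coupling_reverse = 1, production_basal = 0.05,
                     production_max = 10, hill_coefficient = 3)
  g <- 0.7
  # oracle: scalar root of x = a0 + b / (1 + 2 g x^h), solved independently
  xstar <- uniroot(function(x) 0.05 + 10 / (1 + 2 * g * x^3) - x,
                   c(0, 11), tol = 1e-14)$root
  f <- cfr_rhs(net, coupling_schedule("constant", g))
  expect_equal(f(0, rep(xstar, 3)), rep(0, 3), tolerance = 1e-10)
})

test_that("knockout nulls production so the derivative is pure decay", {
  net <- knockout_genes(double_or_net(), 1)
  f <- cfr_rhs(net, coupling_schedule("constant", 0.2))
  x <- c(2.5, 1, 1)
  expect_identical(f(0, x)[1], -2.5)
})

test_that("AND repression vanishes when any single input is low", {
  net <- cfr_network(3, "all_pairs", "AND", coupling_reverse = 0.3)
  f <- cfr_rhs(net, coupling_schedule("constant", 100))
  d <- f(0, c(0.5, 8, 0))  # gene 1's repressors are genes 2 (high) and 3 (zero)
  expect_equal(d[1], 0.05 + 10 - 0.5, tolerance = 1e-12)
})

test_that("AND symmetric fixed point matches the x^(2h) root oracle", {
  net <- cfr_network(3, "all_pairs", "AND", coupling_forward = 1,
                     coupling_reverse = 1)
  g <- 1e-3
  xstar <- uniroot(function(x) 0.05 + 10 / (1 + g * x^6) - x, c(0, 11),
                   tol = 1e-14)$root
  f <- cfr_rhs(net, coupling_schedule("constant", g))
  expect_equal(f(0, rep(xstar, 3)), rep(0, 3), tolerance = 1e-10)
})

test_that("weighted AND reduces to the plain product for equal strengths", {
  # equal incoming strengths: exponents are h on each repressor
  net <- cfr_network(3, "all_pairs", "AND", coupling_forward = 0.6,
                     coupling_reverse = 0.6)
  g <- 0.01
  x <- c(1.5, 2, 3)
  f <- cfr_rhs(net, coupling_schedule("constant", g))
  manual <- 0.05 + 10 / (1 + g * 0.6 * (x[2] * x[3])^3) - x[1]
  expect_equal(f(0, x)[1], manual, tolerance = 1e-12)
})

test_that("the classic repressilator preset sustains a finite-period oscillation", {
  p <- cfr_preset("repressilator")
  tr <- simulate_network(p$network, p$schedule, x0 = c(1.0, 1.05, 0.95),
                         t_max = 200, n_out = 2000)
  keep <- tr$times > 100
  amps <- apply(tr$x[keep, ], 2, function(v) max(v) - min(v))
  expect_true(all(amps > 0.5))
  per <- oscillation_period(tr)
  expect_true(is.finite(per) && per > 0)
})

test_that("weak coupling relaxes the repressilator to a stable equilibrium", {
  net <- repressilator_net()
  g <- 0.05
  # linear-stability oracle: leading eigenvalue of the analytic Jacobian
  xs <- symmetric_equilibrium(net, g)
  lead <- max(Re(eigen(network_jacobian(net, g, rep(xs, 3)),
                       only.values = TRUE)$values))
  expect_lt(lead, 0)
  # the spiral decay rate at this coupling is slow (leading real part
  # about -0.018), so the transient needs several hundred time units
  tr <- simulate_network(net, coupling_schedule("constant", g),
                         x0 = c(1.0, 1.05, 0.95), t_max = 700, n_out = 2000)
  keep <- tr$times > 600
  amps <- apply(tr$x[keep, ], 2, function(v) max(v) - min(v))
  expect_true(all(amps < 1e-4))
})

test_that("halving integrator tolerances leaves trajectories unchanged to 1e-5", {
  net <- double_or_net()
  sch <- coupling_schedule("constant", 0.15)
  x0 <- perturbed_start(net, 0.15, seed = 4)
  tr1 <- simulate_network(net, sch, x0, t_max = 100, n_out = 500)
  tr2 <- simulate_network(net, sch, x0, t_max = 100, n_out = 500,
                          rtol = 5e-9, atol = 5e-11)
  rel <- max(abs(tr1$x - tr2$x)) / max(abs(tr1$x))
  expect_lt(rel, 1e-5)
})

test_that("states stay nonnegative and asymptotically bounded", {
  set.seed(31)
  for (k in 1:6) {
    n <- sample(3:5, 1)
    topo <- sample(c("ring_neighbors", "all_pairs"), 1)
    net <- cfr_network(n, topo, "OR",
                       coupling_reverse = runif(1, 0.05, 0.5),
                       coupling_extra = if (topo == "all_pairs") 1 else 0,
                       production_basal = runif(1, 0, 0.2),
                       production_max = runif(1, 5, 15))
    g <- 10^runif(1, -1.5, 0.5)
    x0 <- runif(n, 0, 20)
    tr <- simulate_network(net, coupling_schedule("constant", g), x0,
                           t_max = 120, n_out = 600)
    expect_true(all(tr$x >= 0))
    bound <- (net$production_basal[1] + net$production_max[1]) /
      net$degradation[1]
    expect_true(all(tr$x[tr$times > 60, ] <= bound + 1e-6))
  }
})

test_that("trajectory time grid is strictly increasing and metadata re-runs it", {
  net <- double_or_net()
  sch <- coupling_schedule("constant", 0.15)
  x0 <- c(1, 2, 3)
  tr <- simulate_network(net, sch, x0, t_max = 50, n_out = 300)
  expect_true(all(diff(tr$times) > 0))
  tr2 <- simulate_network(net, sch, tr$settings$x0, t_max = tr$settings$t_max,
                          n_out = tr$settings$n_out, rtol = tr$settings$rtol,
                          atol = tr$settings$atol, method = tr$settings$method)
  expect_identical(tr$x, tr2$x)
})

test_that("trajectories round-trip through tidy CSV", {
  net <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1)
  sch <- coupling_schedule("linear_ramp", 0.01, 0.3, t_start = 0, t_end = 80)
  sig <- signal_protocol(2, 0.5, t_on = 10, t_off = 40)
  tr <- simulate_network(net, sch, c(1, 2, 3), t_max = 100, signals = sig,
                         n_out = 200)
  path <- tempfile(fileext = ".csv")
  write_trajectory(tr, path)
  back <- read_trajectory(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_equal(back$times, tr$times)
  expect_equal(back$g, tr$g)
  expect_equal(back$network$coupling_forward, tr$network$coupling_forward)
  expect_equal(back$schedule$kind, "linear_ramp")
  expect_equal(back$signals[[1]]$amplitude, 0.5)
  unlink(path)
})

test_that("trajectories round-trip through the parquet cache", {
  skip_if_not_installed("arrow")
  net <- double_or_net()
  tr <- simulate_network(net, coupling_schedule("constant", 0.15),
                         c(1, 2, 3), t_max = 50, n_out = 200)
  path <- tempfile(fileext = ".parquet")
  write_trajectory_cache(tr, path)
  back <- read_trajectory_cache(path)
  expect_equal(back$x, tr$x, tolerance = 1e-12)
  expect_equal(back$network$n_genes, 3)
  unlink(path)
})

test_that("invalid starts and horizons are rejected", {
  net <- double_or_net()
  sch <- coupling_schedule("constant", 0.1)
  expect_error(simulate_network(net, sch, c(-1, 0, 0), t_max = 10),
               "nonnegative")
  expect_error(simulate_network(net, sch, c(1, 1), t_max = 10), "length")
  expect_error(simulate_network(net, sch, c(1, 1, 1), t_max = 0), "t_max")
})
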