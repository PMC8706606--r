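test_that("symmetric equilibrium is exact at g = 0 and solves the scalar root", {
  net <- double_or_net()
  expect_identical(symmetric_equilibrium(net, 0), 10.05)
  # alpha0 = 0, beta = 10, h = 2, OR, two repressors, g = 1:
  # x (1 + 2 x^2) = 10, verified by substitution
  net2 <- cfr_network(3, "all_pairs", "OR", coupling_forward = 1,
                      coupling_reverse = 1, hill_coefficient = 2,
                      production_basal = 0, production_max = 10)
  x <- symmetric_equilibrium(net2, 1)
  expect_lt(abs(x * (1 + 2 * x^2) - 10), 1e-12)
})

test_that("symmetric equilibrium decreases monotonically towards alpha0", {
  net <- double_or_net()
  gs <- c(0.01, 0.1, 1, 10, 1e3, 1e10)
  xs <- vapply(gs, function(g) symmetric_equilibrium(net, g), numeric(1))
  expect_true(all(diff(xs) < 0))
  expect_equal(xs[length(xs)], net$production_basal[1], tolerance = 1e-3)
})

test_that("analytic Jacobian is diagonal decay at zero coupling", {
  net <- cfr_network(4, "all_pairs", "OR", coupling_reverse = 0.2,
                     degradation = c(1, 2, 3, 4))
  expect_equal(network_jacobian(net, 0, c(1, 2, 3, 4)),
               diag(-c(1, 2, 3, 4)))
})

test_that("analytic Jacobian matches central finite differences", {
  fd_jac <- function(net, g, x, eps = 1e-6) {
    f <- cfr_rhs(net, coupling_schedule("constant", g))
    n <- length(x)
    J <- matrix(0, n, n)
    for (j in 1:n) {
      e <- numeric(n); e[j] <- eps
      J[, j] <- (f(0, x + e) - f(0, x - e)) / (2 * eps)
    }
    J
  }
  set.seed(17)
  for (k in 1:10) {
    n <- sample(3:5, 1)
    gate <- sample(c("OR", "AND"), 1)
    net <- cfr_network(n, "all_pairs", gate,
                       coupling_forward = runif(1, 0.5, 2),
                       coupling_reverse = runif(1, 0.1, 0.9),
                       coupling_extra = runif(1, 0.2, 1.5),
                       hill_coefficient = runif(1, 2, 4))
    g <- 10^runif(1, -2, 0.5)
    x <- runif(n, 0.2, 6)
    Ja <- network_jacobian(net, g, x)
    Jn <- fd_jac(net, g, x)
    expect_lt(max(abs(Ja - Jn)) / max(abs(Jn)), 1e-6)
  }
})

test_that("symmetric-point Jacobian has the circulant closed-form spectrum", {
  net <- cfr_network(5, "all_pairs", "OR", coupling_forward = 0.4,
                     coupling_reverse = 0.1, coupling_extra = c(1, 0.1))
  g <- 0.2
  xs <- symmetric_equilibrium(net, g)
  J <- network_jacobian(net, g, rep(xs, 5))
  ev <- sort(Re(eigen(J, only.values = TRUE)$values))
  # closed form: -delta - kappa * lambda_k(C), C the circulant coupling matrix
  W <- coupling_matrix(net)
  h <- net$hill_coefficient
  D <- 1 + g * sum(W[1, ]) * xs^h
  kap <- net$production_max[1] * g * h * xs^(h - 1) / D^2
  lam <- fft(W[1, ])  # eigenvalues of the circulant generated by row 1
  ev_closed <- sort(Re(-net$degradation[1] - kap * lam))
  expect_equal(ev, ev_closed, tolerance = 1e-8)
})

test_that("winner-take-all branch exists, is accurate and stabilizes at high g", {
  net <- double_or_net()
  w <- wta_equilibrium(net, 0.5)
  expect_false(is.null(w))
  expect_lt(w$residual, 1e-10)
  expect_true(w$stable)
  expect_gt(w$x[w$hi], 3 * max(w$x[-w$hi]))
  br <- equilibrium_branch(net, c(0.2, 0.5, 1, 2), "asymmetric")
  expect_true(all(br$residual < 1e-10))
  expect_true(all(br$stable))
})

test_that("the classic repressilator has no fate-specialized equilibria", {
  net <- repressilator_net()
  for (g in c(0.5, 2, 10, 40)) {
    expect_null(wta_equilibrium(net, g))
  }
})

test_that("boundary finding brackets both onsets for the double repressilator", {
  b <- cached("bd_double_or", regime_boundaries(double_or_net(), c(1e-3, 5)))
  expect_false(is.na(b$g_lower))
  expect_false(is.na(b$g_upper))
  expect_lt(b$g_lower, b$g_upper)
  expect_lt(diff(b$lower_bracket) / b$g_lower, 2e-3)
  expect_lt(diff(b$upper_bracket) / b$g_upper, 2e-3)
})

test_that("boundaries are invariant under matched nondimensional rescaling", {
  b1 <- cached("bd_double_or", regime_boundaries(double_or_net(), c(1e-3, 5)))
  net2 <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1,
                      production_basal = 0.1, production_max = 20,
                      degradation = 2)
  b2 <- regime_boundaries(net2, c(1e-3, 5))
  expect_equal(b2$g_lower, b1$g_lower, tolerance = 5e-3)
  expect_equal(b2$g_upper, b1$g_upper, tolerance = 5e-3)
})

test_that("non-symmetric networks are refused by symmetric analyses", {
  biased <- cfr_preset("double-or-biased")$network
  expect_error(symmetric_equilibrium(biased, 0.1), "symmetric")
  expect_error(regime_boundaries(biased), "symmetric")
})

test_that("boundaries serialize to JSON with absent boundaries as null", {
  b <- regime_boundaries(repressilator_net(), c(1e-3, 50))
  js <- jsonlite::fromJSON(boundaries_to_json(b))
  expect_false(is.null(js$g_lower))
  expect_true(is.null(js$g_upper))
  expect_match(paste(js$notes, collapse = " "), "regime absent")
})
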