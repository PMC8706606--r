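test_that("build_network constructs the classic repressilator from a mapping", {
  net <- build_network(list(n_genes = 3, topology = "cyclic", gate = "OR"))
  expect_s3_class(net, "cfr_network")
  expect_equal(net$coupling_reverse, rep(0, 3))
  W <- coupling_matrix(net)
  expect_equal(W[2, 1], 1)  # gene 2 repressed by its upstream neighbour
  expect_equal(W[1, 3], 1)
  expect_equal(sum(W > 0), 3)
})

test_that("equal-strength all-pairs config expands to forward == reverse", {
  net <- build_network(list(n_genes = 3, topology = "all_pairs", gate = "OR",
                            coupling_forward = 1, coupling_reverse = 1))
  expect_equal(net$coupling_forward, net$coupling_reverse)
  W <- coupling_matrix(net)
  expect_true(all(W[upper.tri(W)] == t(W)[upper.tri(W)]))
})

test_that("invalid network configurations are rejected", {
  expect_error(cfr_network(1, "cyclic", "OR"), "n_genes")
  expect_error(cfr_network(2, "cyclic", "AND"), "AND")
  expect_error(cfr_network(3, "cyclic", "OR", production_max = -1),
               "nonnegative")
  expect_error(cfr_network(3, "cyclic", "OR", degradation = 0), "positive")
  expect_error(cfr_network(3, "cyclic", "OR", coupling_reverse = 0.5),
               "cyclic")
  expect_error(cfr_network(3, "cyclic", "OR", hill_coefficient = -2),
               "hill")
  expect_error(build_network(list(n_genes = 3, topology = "cyclic",
                                  gate = "OR", frobnicate = 1)),
               "frobnicate")
  expect_error(cfr_network(4, "all_pairs", "OR", coupling_extra = 0),
               "coupling_extra")
})

test_that("coupling_extra is graded by cyclic distance", {
  net <- cfr_network(5, "all_pairs", "OR", coupling_forward = 0.4,
                     coupling_reverse = 0.1, coupling_extra = c(1, 0.25))
  W <- coupling_matrix(net)
  expect_equal(W[3, 1], 1)     # distance 2
  expect_equal(W[4, 1], 0.25)  # distance 3
  expect_equal(W[2, 1], 0.4)   # forward neighbour
  expect_equal(W[1, 2], 0.1)   # reverse neighbour
})

test_that("effective coupling scales the relative matrix by g(t)", {
  net <- cfr_network(3, "all_pairs", "OR", coupling_forward = 1,
                     coupling_reverse = 0.5)
  expect_equal(effective_coupling(net, coupling_schedule("constant", 0), 3),
               matrix(0, 3, 3))
  ramp <- coupling_schedule("linear_ramp", 0, 10, t_start = 0, t_end = 100)
  W50 <- effective_coupling(net, ramp, 50)
  expect_equal(W50[2, 1], 5)          # forward entry at ramp midpoint
  expect_equal(W50[1, 2], 2.5)        # reverse entry
  Wc <- effective_coupling(net, coupling_schedule("constant", 4), 0)
  expect_equal(Wc[2, 1], 4)
  expect_equal(Wc[1, 2], 2)
  # knockout leaves the matrix untouched
  expect_equal(coupling_matrix(knockout_genes(net, 1)), coupling_matrix(net))
})

test_that("coupling schedules evaluate and invert correctly", {
  cs <- coupling_schedule("constant", 2)
  expect_equal(g_at(cs, c(-5, 0, 100)), c(2, 2, 2))
  lr <- coupling_schedule("linear_ramp", 1, 3, t_start = 10, t_end = 20)
  expect_equal(g_at(lr, c(0, 10, 15, 20, 99)), c(1, 1, 2, 3, 3))
  expect_equal(time_of_g(lr, 2), 15)
  expect_true(is.na(time_of_g(lr, 5)))
  pw <- coupling_schedule("piecewise_linear", times = c(0, 5, 10),
                          values = c(0, 1, 1))
  expect_equal(g_at(pw, c(2.5, 7, 20)), c(0.5, 1, 1))
  expect_equal(time_of_g(pw, 0.5), 2.5)
  expect_error(coupling_schedule("linear_ramp", 3, 1, 0, 10), "nondecreasing")
  expect_error(coupling_schedule("piecewise_linear", times = c(0, 0),
                                 values = c(1, 2)), "strictly increasing")
})

test_that("signal protocols switch on and off and validate inputs", {
  sig <- signal_protocol(2, 1.5, t_on = 10, t_off = 20)
  expect_equal(signal_at(sig, 5, 3), c(0, 0, 0))
  expect_equal(signal_at(sig, 15, 3), c(0, 1.5, 0))
  expect_equal(signal_at(sig, 20, 3), c(0, 0, 0))  # half-open window
  expect_equal(signal_at(list(sig, signal_protocol(2, 1)), 15, 3),
               c(0, 2.5, 0))
  expect_error(signal_protocol(2, -1), "amplitude")
  expect_error(signal_protocol(0, 1), "target_gene")
  expect_error(signal_at(signal_protocol(9, 1), 0, 3), "exceeds")
})

test_that("amplitude-zero signal leaves the derivative bit-identical", {
  net <- double_or_net()
  f0 <- cfr_rhs(net, coupling_schedule("constant", 0.15))
  f1 <- cfr_rhs(net, coupling_schedule("constant", 0.15),
                signals = signal_protocol(1, 0))
  x <- c(1.2, 0.4, 3.3)
  expect_identical(f0(7, x), f1(7, x))
})

test_that("cyclic relabeling commutes with simulation", {
  net <- double_or_net()
  x0 <- c(1.1, 0.9, 1.4)
  sch <- coupling_schedule("constant", 0.12)
  tr <- simulate_network(net, sch, x0, t_max = 60, n_out = 400)
  for (shift in 1:2) {
    rot <- rotate_network(net, shift)
    perm <- ((seq_len(3) - 1 + shift) %% 3) + 1  # new label of old gene i
    x0r <- numeric(3)
    x0r[perm] <- x0
    trr <- simulate_network(rot, sch, x0r, t_max = 60, n_out = 400)
    expect_equal(trr$x[, perm], tr$x, tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("zero coupling decouples genes to alpha0 + beta", {
  for (topo in c("cyclic", "ring_neighbors", "all_pairs")) {
    for (gate in if (topo == "cyclic") "OR" else c("OR", "AND")) {
      net <- cfr_network(4, topo, gate,
                         coupling_reverse = if (topo == "cyclic") 0 else 0.3,
                         coupling_extra = if (topo == "all_pairs") 1 else 0)
      tr <- simulate_network(net, coupling_schedule("constant", 0),
                             x0 = c(0.2, 5, 1, 9), t_max = 40, n_out = 300)
      expect_equal(unname(tr$x[300, ]),
                   rep(net$production_basal[1] + net$production_max[1], 4),
                   tolerance = 1e-6)
    }
  }
})

test_that("knockout masking validates and refuses total knockout", {
  net <- double_or_net()
  expect_error(knockout_genes(net, 5), "out of range")
  expect_error(knockout_genes(knockout_genes(net, 1:2), 3), "every gene")
  expect_true(knockout_genes(net, 2)$knockout[2])
})
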