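test_that("the three response modes are recognized at constant coupling", {
  net <- double_or_net()
  # below the window: stable symmetric equilibrium
  tr_lo <- sim_const(net, 0.02, seed = 2, t_max = 200)
  r_lo <- classify_regime(tr_lo)
  expect_equal(r_lo$label, "multipotent")
  expect_lt(diff(range(r_lo$means)) / mean(r_lo$means), 1e-3)
  # inside the window
  tr_mid <- sim_const(net, 0.15, seed = 2, t_max = 400)
  r_mid <- classify_regime(tr_mid)
  expect_equal(r_mid$label, "oscillatory")
  expect_equal(length(unique(r_mid$dwell$substate)), 3)
  # far above: winner-take-all from a desymmetrized start
  tr_hi <- sim_const(net, 0.6, seed = 2, t_max = 300)
  r_hi <- classify_regime(tr_hi)
  expect_equal(r_hi$label, "differentiated")
  expect_length(r_hi$dominant, 1)
})

test_that("classification refuses ramped trajectories unless piecewise", {
  net <- double_or_net()
  sch <- coupling_schedule("linear_ramp", 0.01, 0.4, t_start = 0, t_end = 200)
  tr <- simulate_network(net, sch, c(1, 1.1, 0.9), t_max = 200, n_out = 800)
  expect_error(classify_regime(tr), "piecewise")
  pw <- classify_piecewise(tr, n_windows = 6)
  expect_equal(nrow(pw), 6)
})

test_that("symmetric oscillation dwell fractions are equal and tile the window", {
  net <- double_or_net()
  tr <- sim_const(net, 0.15, seed = 5, t_max = 600, n_out = 5000)
  dw <- dwell_times(tr)
  fr <- attr(dw, "fractions")
  expect_equal(sum(dw$duration), max(dw$t_exit) - min(dw$t_entry),
               tolerance = 1e-9)
  expect_equal(sum(fr), 1, tolerance = 1e-6)
  expect_true(all(abs(fr - 1 / 3) < 0.02))
  # contiguous, non-overlapping, no zero-duration states
  expect_true(all(dw$duration > 0))
  expect_equal(dw$t_entry[-1], dw$t_exit[-nrow(dw)])
})

test_that("the cyclic sub-state order is constant within a run", {
  net <- double_or_net()
  tr <- sim_const(net, 0.15, seed = 5, t_max = 600, n_out = 5000)
  dw <- dwell_times(tr)
  s <- as.integer(dw$substate)
  n <- 3L
  succ <- s[-1][match(1:3, s[-length(s)])]  # first observed successor per state
  for (k in seq_len(length(s) - 1)) {
    expect_equal(s[k + 1], succ[s[k]])
  }
})

test_that("period is consistent across genes and integration accuracy", {
  net <- double_or_net()
  tr <- sim_const(net, 0.15, seed = 3, t_max = 400, n_out = 4000)
  p1 <- oscillation_period(tr, gene = 1)
  p2 <- oscillation_period(tr, gene = 2)
  p3 <- oscillation_period(tr, gene = 3)
  expect_lt(abs(p2 - p1) / p1, 0.01)
  expect_lt(abs(p3 - p1) / p1, 0.01)
  # refined-tolerance reference integration agrees within 2%
  ref <- simulate_network(net, coupling_schedule("constant", 0.15),
                          tr$settings$x0, t_max = 400, n_out = 8000,
                          rtol = 1e-10, atol = 1e-12)
  expect_lt(abs(oscillation_period(ref) - p1) / p1, 0.02)
})

test_that("period errors on non-oscillatory trajectories", {
  net <- double_or_net()
  tr <- sim_const(net, 0.02, seed = 1, t_max = 200)
  expect_error(oscillation_period(tr), "not oscillating")
})

test_that("classification is invariant under relabeling and joint rescaling", {
  net <- double_or_net()
  tr <- sim_const(net, 0.15, seed = 6, t_max = 400)
  lab <- classify_regime(tr)$label
  # relabeling
  rot <- rotate_network(net, 1)
  x0 <- perturbed_start(net, 0.15, 6)
  x0r <- x0[c(3, 1, 2)]
  x0r <- x0[((seq_len(3) - 2) %% 3) + 1]
  trr <- simulate_network(rot, coupling_schedule("constant", 0.15),
                          x0r, t_max = 400, n_out = 3000)
  expect_equal(classify_regime(trr)$label, lab)
  # rescaling time and rates jointly: delta, alpha0, beta doubled, horizon halved
  net2 <- cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1,
                      production_basal = 0.1, production_max = 20,
                      degradation = 2)
  tr2 <- simulate_network(net2, coupling_schedule("constant", 0.15),
                          perturbed_start(net2, 0.15, 6), t_max = 200,
                          n_out = 3000)
  expect_equal(classify_regime(tr2)$label, lab)
})

test_that("AND-gate sub-states are co-dominant pairs", {
  p <- cfr_preset("double-and")
  tr <- sim_const(p$network, p$schedule$g_start, seed = 2, t_max = 500,
                  n_out = 4000)
  r <- classify_regime(tr)
  expect_equal(r$label, "oscillatory")
  fr <- attr(r$dwell, "fractions")
  expect_true(all(grepl("^\\d\\+\\d$", names(fr))))
  expect_equal(sum(fr), 1, tolerance = 1e-6)
})

test_that("dwell analysis warns and returns empty on steady trajectories", {
  net <- double_or_net()
  tr <- sim_const(net, 0.02, seed = 1, t_max = 100)
  expect_warning(dw <- dwell_times(tr), "no sub-state crossings")
  expect_equal(nrow(dw), 0)
})

test_that("regime reports serialize to JSON", {
  net <- double_or_net()
  tr <- sim_const(net, 0.15, seed = 2, t_max = 300)
  r <- classify_regime(tr)
  js <- jsonlite::fromJSON(regime_to_json(r))
  expect_equal(js$label, "oscillatory")
  expect_length(js$means, 3)
  path <- tempfile(fileext = ".json")
  regime_to_json(r, path)
  expect_true(file.exists(path))
  unlink(path)
})
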