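# shared builders for the test suite

double_or_net <- function() {
  cfr_network(3, "all_pairs", "OR", coupling_reverse = 0.1)
}

repressilator_net <- function() {
  cfr_network(3, "cyclic", "OR")
}

# simulate at constant g from a seeded perturbed symmetric start
sim_const <- function(net, g, seed = 1, t_max = 400, n_out = 3000, ...) {
  simulate_network(net, coupling_schedule("constant", g),
                   x0 = perturbed_start(net, g, seed), t_max = t_max,
                   n_out = n_out, ...)
}

# memoised store for expensive shared computations (per test run)
.acc_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .acc_cache)) {
    assign(key, force(expr), envir = .acc_cache)
  }
  get(key, envir = .acc_cache)
}
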