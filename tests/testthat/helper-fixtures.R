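# Shared fixtures. The closed-loop reference run is expensive (tens of
# seconds), so it is computed once per test session and reused by the
# conservation, periodicity and stroke-volume tests.

.fixture_env <- new.env(parent = emptyenv())

closed_loop_sim <- function(n_cycles = 20) {
  key <- paste0("closed_", n_cycles)
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- run_simulation(closed_loop_network(depth = 1),
                                          solver_config(),
                                          n_cycles = n_cycles)
  .fixture_env[[key]]
}

random_geometry <- function() {
  vessel_geometry(length = runif(1, 0.005, 0.3),
                  radius = runif(1, 5e-4, 0.015),
                  thickness = runif(1, 1e-4, 2e-3),
                  youngs_modulus = runif(1, 1e5, 2e6),
                  stress_relax = runif(1, 0, 0.05))
}

random_params <- function() {
  lumped_params(R = 10^runif(1, 4, 9), C = 10^runif(1, -12, -8),
                I = 10^runif(1, 3, 7), Rv = 10^runif(1, 4, 7))
}

# smallest legal pressure-driven network: one PV vessel + one RCR terminal
minimal_network <- function(mu_in = 1000) {
  load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = mu_in),
    segments = list(
      list(id = "ves", type = "PV",
           params = list(R = 1e6, C = 1e-10, I = 1e4)),
      list(id = "term", type = "PP_BC_TERMINAL", parent = "ves",
           params = list(R = 1e6, C = 1e-10, I = 1e4),
           terminal = list(RTP = 1e7, RTD = 1e8, CT = 1e-9)))))
}
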