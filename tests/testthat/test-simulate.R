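# Integration, periodicity detection, result serialization.

test_that("a capacitor discharging through a resistor follows the exponential closed form", {
  # terminal capacitor decoupled from its vessel by a huge proximal
  # resistance: ud' = -ud/(RTD CT) exactly
  RTD <- 1e8; CT <- 1e-8
  net <- load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = 0),
    segments = list(list(id = "t", type = "PP_BC_TERMINAL",
      params = list(R = 1e7, C = 1e-10, I = 1e4),
      terminal = list(RTP = 1e14, RTD = RTD, CT = CT),
      initial = list(ud = 1000)))))
  sim <- run_simulation(net, solver_config(rtol = 1e-9), duration = 2)
  expect_lt(max(abs(sim$states[, "t.ud"] -
                    1000 * exp(-sim$time / (RTD * CT)))) / 1000, 1e-3)
})

test_that("zero input and zero state stay identically zero; reruns are bit-compatible", {
  net <- load_network(list(loop = "open",
    inflow = list(kind = "pulse", amplitude = 0, systole = 0.3, period = 1),
    segments = list(
      list(id = "a", type = "VV", params = list(R = 1e5, C = 1e-10, I = 1e4)),
      list(id = "t", type = "PP_BC_TERMINAL", parent = "a",
           params = list(R = 1e6, C = 1e-10, I = 1e4),
           terminal = list(RTP = 1e7, RTD = 1e8, CT = 1e-9)))))
  sim <- run_simulation(net, solver_config(), duration = 1)
  expect_true(all(sim$states == 0))

  net2 <- minimal_network()
  s1 <- run_simulation(net2, solver_config(), duration = 0.4)
  s2 <- run_simulation(net2, solver_config(), duration = 0.4)
  expect_identical(s1$states, s2$states)
})

test_that("passive networks respond linearly: scaling the inflow scales every state", {
  mk <- function(amp) load_network(list(loop = "open",
    inflow = list(kind = "pulse", amplitude = amp, systole = 0.3, period = 1),
    segments = list(
      list(id = "a", type = "VV", params = list(R = 1e5, C = 1e-9, I = 1e4)),
      list(id = "t", type = "PP_BC_TERMINAL", parent = "a",
           params = list(R = 1e6, C = 1e-9, I = 1e4),
           terminal = list(RTP = 1e7, RTD = 1e8, CT = 1e-9)))))
  tight <- solver_config(rtol = 1e-9)
  s1 <- run_simulation(mk(1e-5), tight, n_cycles = 2)
  s3 <- run_simulation(mk(3e-5), tight, n_cycles = 2)
  scale <- pmax(apply(abs(s3$states), 2, max), 1e-300)
  expect_lt(max(abs(s3$states - 3 * s1$states) %*% diag(1 / scale)), 1e-5)
})

test_that("periodicity detection: driven dissipative networks converge; vacuous threshold", {
  net <- minimal_network()
  net$inflow <- list(kind = "pressure",
                     fun = inflow_pulse(1000, 0.3, 1), period = 1,
                     config = list(kind = "pulse"))
  sim <- run_simulation(net, solver_config(), n_cycles = 6)
  pd <- detect_periodic_state(sim, tol = 1e-3)
  expect_true(pd$converged)
  expect_lte(pd$cycle, 6)
  # metrics decrease as the transient dies away
  expect_lt(pd$metric[length(pd$metric)], pd$metric[1])
  # tol = Inf accepts the first comparable cycle
  expect_equal(detect_periodic_state(sim, tol = Inf)$cycle, 2L)
  # constant input: consecutive "cycles" identical once steady
  net2 <- minimal_network(mu_in = 1000)
  sim2 <- run_simulation(net2, solver_config(), duration = 4)
  sim2$period <- 1
  expect_true(detect_periodic_state(sim2, tol = 1e-6)$converged)
})

test_that("results round-trip through CSV and summaries recompute from the trajectory", {
  net <- minimal_network()
  net$inflow <- list(kind = "pressure", fun = inflow_pulse(1000, 0.3, 1),
                     period = 1, config = list(kind = "pulse"))
  sim <- run_simulation(net, solver_config(), n_cycles = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_results(sim, path)
  back <- read_results(path)
  # column count: states + derived outputs; time is the first column
  expect_equal(ncol(back$states),
               ncol(sim$states) + ncol(sim$globals))
  expect_equal(back$states[, colnames(sim$states)], sim$states,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(back$time, sim$time, tolerance = 1e-12)
  expect_identical(unname(back$units[1]), "Pa")

  s <- cycle_summaries(sim)
  one <- s[s$cycle == 2 & s$state == "ves.u", ]
  blk <- sim$states[sim$time >= 1 & sim$time <= 2, "ves.u"]
  expect_equal(one$systolic, max(blk))
  expect_equal(one$diastolic, min(blk))
})

test_that("explicit and stiff integrators agree on a small network", {
  net <- minimal_network()
  net$inflow <- list(kind = "pressure", fun = inflow_pulse(1000, 0.3, 1),
                     period = 1, config = list(kind = "pulse"))
  sb <- run_simulation(net, solver_config(method = "bdf", rtol = 1e-8),
                       duration = 1)
  se <- run_simulation(net, solver_config(method = "lsoda", rtol = 1e-8),
                       duration = 1)
  scale <- pmax(apply(abs(sb$states), 2, max), 1e-300)
  expect_lt(max(abs(sb$states - se$states) %*% diag(1 / scale)), 1e-4)
})

test_that("tightening the tolerance changes the solution less than the tolerance implies", {
  net <- minimal_network()
  net$inflow <- list(kind = "pressure", fun = inflow_pulse(1000, 0.3, 1),
                     period = 1, config = list(kind = "pulse"))
  s1 <- run_simulation(net, solver_config(rtol = 1e-7), n_cycles = 2)
  s2 <- run_simulation(net, solver_config(rtol = 1e-9), n_cycles = 2)
  scale <- pmax(apply(abs(s2$states), 2, max), 1e-300)
  expect_lt(max(abs(s1$states - s2$states) %*% diag(1 / scale)), 1e-4)
})

test_that("duration arguments are validated", {
  net <- minimal_network()
  expect_error(run_simulation(net, solver_config()), "duration or n_cycles")
  expect_error(run_simulation(net, solver_config(), n_cycles = 2),
               "periodic drive")
})
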