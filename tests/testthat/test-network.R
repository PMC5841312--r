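# Config parsing, topology validation, assembly, fixture generation.

test_that("a minimal one-vessel-plus-terminal config loads", {
  net <- minimal_network()
  expect_s3_class(net, "bg_network")
  expect_length(net$segments, 2)
  expect_equal(nrow(validate_topology(net)), 0)
  expect_identical(net$segments$ves$children, "term")
})

test_that("geometry-only configs derive the lumped parameters from the closed forms", {
  g <- list(length = 0.07, radius = 0.004, thickness = 4e-4,
            youngs_modulus = 6e5, stress_relax = 0.02)
  net <- load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = 0),
    segments = list(list(id = "s", type = "PV", geometry = g,
                         outlet = list(kind = "flow", value = 0)))))
  p <- net$segments$s$params
  nu <- 0.004; rho <- 1040
  expect_equal(p$R, 8 * nu * g$length / (pi * g$radius^4))
  expect_equal(p$C, 2 * pi * g$radius^3 * g$length /
                 (g$thickness * g$youngs_modulus))
  expect_equal(p$I, rho * g$length / (pi * g$radius^2))
  expect_equal(p$Rv, g$stress_relax / p$C)
})

test_that("type-compatibility violations are reported as data, with the rule named", {
  # mu-mu segment used as a junction parent (its outlet supplies flow)
  cfg <- list(loop = "open", inflow = list(kind = "pressure", value = 0),
    segments = list(
      list(id = "p", type = "PP", params = list(R = 1e6, C = 1e-10, I = 1e4)),
      list(id = "d1", type = "PP_BC_TERMINAL", parent = "p",
           params = list(R = 1e6, C = 1e-10, I = 1e4),
           terminal = list(RTP = 1e7, RTD = 1e8, CT = 1e-9)),
      list(id = "d2", type = "PP_BC_TERMINAL", parent = "p",
           params = list(R = 1e6, C = 1e-10, I = 1e4),
           terminal = list(RTP = 1e7, RTD = 1e8, CT = 1e-9))))
  spec <- load_network(cfg, validate = FALSE)
  v <- validate_topology(spec)
  expect_true("split-parent" %in% v$rule)
  expect_error(load_network(cfg), "split-parent")

  # a merge fed by a mu-upsilon daughter (must be mu-mu)
  cfg2 <- list(loop = "open", inflow = list(kind = "pressure", value = 0),
    segments = list(
      list(id = "a", type = "PV", params = list(R = 1e6, C = 1e-10, I = 1e4)),
      list(id = "b", type = "PP", params = list(R = 1e6, C = 1e-10, I = 1e4)),
      list(id = "m", type = "VV_MERGE", parent = list("a", "b"),
           params = list(R = 1e6, C = 1e-10, I = 1e4),
           outlet = list(kind = "flow", value = 0))))
  v2 <- validate_topology(load_network(cfg2, validate = FALSE))
  expect_true("merge-daughter-type" %in% v2$rule)
  expect_true(any(v2$segment == "a"))

  # disconnected extra segment
  cfg3 <- list(loop = "open", inflow = list(kind = "pressure", value = 0),
    segments = list(
      list(id = "s", type = "PV", params = list(R = 1e6, C = 1e-10, I = 1e4),
           outlet = list(kind = "flow", value = 0)),
      list(id = "orphan", type = "PV", parent = "ghost",
           params = list(R = 1e6, C = 1e-10, I = 1e4))))
  expect_error(load_network(cfg3), "unknown parent")
  cfg3$segments[[2]]$parent <- NULL
  cfg3$segments[[2]]$outlet <- list(kind = "flow", value = 0)
  v3 <- validate_topology(load_network(cfg3, validate = FALSE))
  # second root is fine structurally but flags open-loop single-root rule
  expect_true("root" %in% v3$rule)

  # flow inflow into a pressure-demanding root
  cfg4 <- list(loop = "open", inflow = list(kind = "pulse"),
    segments = list(list(id = "s", type = "PV",
      params = list(R = 1e6, C = 1e-10, I = 1e4),
      outlet = list(kind = "flow", value = 0))))
  v4 <- validate_topology(load_network(cfg4, validate = FALSE))
  expect_true("root-causality" %in% v4$rule)
})

test_that("load errors name the offending path", {
  expect_error(load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = 0),
    segments = list(list(id = "t", type = "PP_BC_TERMINAL",
                         params = list(R = 1, C = 1, I = 1))))),
    "missing its terminal")
  expect_error(load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = 0),
    segments = list(
      list(id = "x", type = "PV", params = list(R = 1, C = 1, I = 1)),
      list(id = "x", type = "PV", params = list(R = 1, C = 1, I = 1))))),
    "duplicate segment id")
  expect_error(load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = 0),
    segments = list(list(id = "s", type = "PV",
      geometry = list(length = 0.1, radius = 0.005,
                      youngs_modulus = "4 parsecs"))))),
    "unknown unit")
})

test_that("tree fixture: counts, scaling and equal-split terminal scaling", {
  root <- vessel_geometry(0.05, 0.005, 5e-4, 4e5)
  tpl <- terminal_params(RTP = 5e7, RTD = 5.8e8, CT = 2.5e-9)
  for (depth in 0:2) {
    net <- generate_tree_fixture(depth, root, terminal = tpl)
    segs <- net$segments
    is_term <- vapply(segs, function(s) s$type == "PP_BC_TERMINAL", TRUE)
    expect_length(segs, 2^(depth + 1) - 1 + 2^depth)  # vessels + terminals
    expect_equal(sum(is_term), 2^depth)
    expect_equal(nrow(validate_topology(net)), 0)
    # radius scaling per generation
    expect_equal(segs[["v0_1"]]$geometry$radius, root$radius)
    if (depth >= 1)
      expect_equal(segs[["v1_1"]]$geometry$radius, root$radius * 0.75)
    # total terminal conductance equals the template's (equal split)
    g_leaf <- vapply(segs[is_term], function(s)
      1 / (s$terminal$RTP + s$terminal$RTD), 0)
    expect_equal(sum(g_leaf), 1 / (tpl$RTP + tpl$RTD))
  }
  expect_error(generate_tree_fixture(40, root), "underflow")
})

test_that("serialization round-trips to an identical network", {
  net <- generate_tree_fixture(1, vessel_geometry(0.05, 0.005, 5e-4, 4e5))
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  net2 <- load_network(path)
  expect_identical(names(net2$segments), names(net$segments))
  for (id in names(net$segments)) {
    a <- net$segments[[id]]; b <- net2$segments[[id]]
    expect_equal(a$params, b$params, tolerance = 1e-12)
    expect_identical(a$type, b$type)
    expect_identical(a$parent, b$parent)
    expect_equal(a$terminal, b$terminal)
  }
  expect_equal(net2$blood, net$blood)
  expect_equal(net2$thickness_fit, net$thickness_fit)
})

test_that("the assembled RHS of a single segment reproduces the element equations", {
  # PV segment, constant inlet pressure, blocked outlet
  net <- load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = 1234),
    segments = list(list(id = "s", type = "PV",
      params = list(R = 1e6, C = 1e-10, I = 1e4),
      outlet = list(kind = "flow", value = 0)))))
  m <- assemble_rhs(net)
  expect_equal(m$n, 2)
  y <- c(500, 3e-5); names(y) <- m$state_names
  d <- m$rhs(0, y)[[1]]
  ref <- deriv_pv(c(u = 500, v = 3e-5), list(u_in = 1234, v_out = 0),
                  net$segments$s$params)
  expect_identical(unname(d), unname(ref))
})

test_that("a bifurcation's assembled RHS vanishes at the independently solved steady state", {
  # root VV + two identical terminals, constant inflow
  qbar <- 2e-6
  R0 <- 2e5; R1 <- 8e5; RTP <- 1e7; RTD <- 1e8
  cfg <- list(loop = "open",
    inflow = list(kind = "table", time = c(0, 10), flow = c(qbar, qbar)),
    segments = list(
      list(id = "root", type = "VV",
           params = list(R = R0, C = 1e-10, I = 1e4)),
      list(id = "L", type = "PP_BC_TERMINAL", parent = "root",
           params = list(R = R1, C = 1e-10, I = 1e4),
           terminal = list(RTP = RTP, RTD = RTD, CT = 1e-9)),
      list(id = "Rg", type = "PP_BC_TERMINAL", parent = "root",
           params = list(R = R1, C = 1e-10, I = 1e4),
           terminal = list(RTP = RTP, RTD = RTD, CT = 1e-9))))
  net <- load_network(cfg)
  m <- assemble_rhs(net)
  # independent steady-state algebra: each daughter carries qbar/2
  v1 <- qbar / 2
  ud1 <- v1 * RTD                      # terminal capacitor
  u1 <- ud1 + v1 * RTP                 # daughter wall capacitor (mu_out = 0)
  uin1 <- u1 + v1 * R1                 # junction pressure = root distal cap
  u0 <- uin1 + qbar * R0               # root proximal cap
  y <- stats::setNames(numeric(m$n), m$state_names)
  y["root.u"] <- u0; y["root.v"] <- qbar; y["root.ud"] <- uin1
  y["L.u"] <- u1; y["L.v"] <- v1; y["L.ud"] <- ud1
  y["Rg.u"] <- u1; y["Rg.v"] <- v1; y["Rg.ud"] <- ud1
  d <- m$rhs(0.5, y)[[1]]
  expect_equal(max(abs(d)), 0, tolerance = 1e-9)
})

test_that("segment declaration order does not change the trajectories", {
  mk <- function(order) {
    segs <- list(
      list(id = "b", type = "PP_BC_TERMINAL", parent = "a",
           params = list(R = 1e6, C = 1e-10, I = 1e4),
           terminal = list(RTP = 1e7, RTD = 1e8, CT = 1e-9)),
      list(id = "a", type = "VV", params = list(R = 1e5, C = 1e-10, I = 1e4)))
    load_network(list(loop = "open",
      inflow = list(kind = "pulse", amplitude = 1e-5, systole = 0.3,
                    period = 1),
      segments = segs[order]))
  }
  s1 <- run_simulation(mk(1:2), solver_config(), duration = 0.5)
  s2 <- run_simulation(mk(2:1), solver_config(), duration = 0.5)
  expect_identical(s1$states, s2$states)
})

test_that("the example config in extdata loads, validates and references its inflow CSV", {
  path <- system.file("extdata", "example-network.json", package = "hemobond")
  skip_if(path == "", "extdata not installed")
  net <- load_network(path)
  expect_length(net$segments, 3)
  expect_true(net$segments$right$viscoelastic)
  expect_equal(net$inflow$period, 1)
  expect_equal(net$inflow$fun(0.15), 6e-5 * sin(pi * 0.15 / 0.3),
               tolerance = 1e-3)
})
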