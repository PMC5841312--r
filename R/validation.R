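#' Compare two periodic waveforms
#'
#' Root-mean-square error between a test and a reference waveform over the
#' last common whole cycle, resampled onto a shared uniform grid, expressed
#' both absolutely and as a percentage of the reference systolic value (its
#' per-cycle maximum).
#'
#' @param test,reference lists or data.frames with components `time` (s)
#'   and `value`.
#' @param period cycle length (s).
#' @param n_grid resampling points per cycle.
#' @return list of class `bg_wavecmp`: `rmse`, `normalization` (reference
#'   systolic value), `relative_rmse_pct`.
#' @export
compare_waveforms <- function(test, reference, period, n_grid = 512) {
  tt <- test$time; tv <- test$value %||% test[[2]]
  rt <- reference$time; rv <- reference$value %||% reference[[2]]
  t_end <- min(max(tt), max(rt))
  t_start <- t_end - period
  if (t_start < max(min(tt), min(rt)) - 1e-9)
    stop("waveforms do not share a common whole cycle of length ", period,
         call. = FALSE)
  grid <- seq(t_start, t_end, length.out = n_grid)
  a <- stats::approx(tt, tv, xout = grid)$y
  b <- stats::approx(rt, rv, xout = grid)$y
  rmse <- sqrt(mean((a - b)^2))
  norm <- max(b)
  structure(list(rmse = rmse, normalization = norm,
                 relative_rmse_pct = 100 * rmse / norm),
            class = "bg_wavecmp")
}

#' Matched desk-scale 0D / 1D test cases
#'
#' Builds the bond-graph network and the corresponding 1D vessel tree for
#' the two validation cases: a short single vessel with an RCR outlet, and
#' a symmetric bifurcation whose daughters are lumped terminal segments.
#' Both share the same geometry-derived R/C/I (so the lumped parameters are
#' exactly the Poiseuille/compliance/inertance closed forms of the 1D tube),
#' the same RCR outlets, and the same periodic half-sine inflow.
#'
#' @param case "single-vessel" or "bifurcation".
#' @param n_cells 1D cells per vessel.
#' @return list with `network` (a `bg_network`), `vessels_1d`
#'   ([oned_vessel] list), `inflow` (function), `period`, and `probes`
#'   (how each 0D probe maps onto the state/global columns).
#' @export
desk_case <- function(case = c("single-vessel", "bifurcation"),
                      n_cells = 32) {
  case <- match.arg(case)
  blood <- blood_properties()
  inflow_cfg <- list(kind = "pulse", amplitude = 6e-5, systole = 0.3,
                     period = 1)
  parent_geom <- vessel_geometry(length = 0.03, radius = 0.005,
                                 thickness = 0.00075, youngs_modulus = 8e5)
  if (case == "single-vessel") {
    term <- terminal_params(RTP = 5e7, RTD = 5.8e8, CT = 3e-9)
    net <- load_network(list(loop = "open", blood = unclass(blood),
      inflow = inflow_cfg,
      segments = list(list(id = "vessel", type = "VV",
        geometry = unclass(parent_geom), terminal = unclass(term),
        outlet = list(kind = "rcr")))))
    v1d <- list(oned_vessel("vessel", parent_geom, terminal = term,
                            n_cells = n_cells))
    probes <- list(vessel = list(p = c("vessel.u", "vessel.ud"),
                                 q = "vessel.v"))
  } else {
    dgeom <- vessel_geometry(length = 0.025, radius = 0.0037,
                             thickness = 0.0006, youngs_modulus = 8e5)
    term <- terminal_params(RTP = 1e8, RTD = 1.16e9, CT = 1.5e-9)
    seg_d <- function(id) list(id = id, type = "PP_BC_TERMINAL",
      parent = "parent", geometry = unclass(dgeom), terminal = unclass(term))
    net <- load_network(list(loop = "open", blood = unclass(blood),
      inflow = inflow_cfg,
      segments = list(
        list(id = "parent", type = "VV", geometry = unclass(parent_geom)),
        seg_d("d1"), seg_d("d2"))))
    v1d <- list(oned_vessel("parent", parent_geom, n_cells = n_cells),
                oned_vessel("d1", dgeom, parent = "parent", terminal = term,
                            n_cells = n_cells),
                oned_vessel("d2", dgeom, parent = "parent", terminal = term,
                            n_cells = n_cells))
    probes <- list(parent = list(p = c("parent.u", "parent.ud"),
                                 q = "parent.v"),
                   d1 = list(p = "d1.u", q = "d1.v"),
                   d2 = list(p = "d2.u", q = "d2.v"))
  }
  inflow_fun <- inflow_pulse(inflow_cfg$amplitude, inflow_cfg$systole,
                             inflow_cfg$period)
  list(network = net, vessels_1d = v1d, inflow = inflow_fun,
       period = inflow_cfg$period, probes = probes, case = case)
}

#' 0D-vs-1D waveform comparison
#'
#' Runs the bond-graph model and the 1D finite-volume reference on a
#' matched desk-scale case, driven to a periodic state by the same
#' half-sine inflow, and reports the relative RMSE of pressure and flow at
#' each probe location over the last cycle, normalized by the reference
#' systolic value. The 0D pressure probe is the segment's capacitor
#' pressure state (the mean of the two end capacitors for a two-capacitor
#' segment, as the midpoint representative); the 0D flow probe is the
#' segment's 1-junction flow. Both are compared against the 1D midpoint.
#'
#' @param case "single-vessel" or "bifurcation".
#' @param cycles cycles to simulate (enough to reach periodicity).
#' @param n_cells 1D cells per vessel.
#' @param solver a [solver_config] for the 0D run.
#' @return data.frame with one row per (location, quantity): `rmse`,
#'   `normalization`, `relative_rmse_pct`.
#' @export
compare_0d_1d <- function(case = c("single-vessel", "bifurcation"),
                          cycles = 10, n_cells = 32,
                          solver = solver_config()) {
  dc <- desk_case(case, n_cells = n_cells)
  sim <- run_simulation(dc$network, solver = solver, n_cycles = cycles)
  ref <- solve_1d_reference(dc$vessels_1d, dc$inflow,
                            duration = cycles * dc$period,
                            dt_out = solver$dt_out)
  rows <- list()
  for (loc in names(dc$probes)) {
    pr <- dc$probes[[loc]]
    p0 <- rowMeans(sim$states[, pr$p, drop = FALSE])
    q0 <- sim$states[, pr$q]
    for (quantity in c("pressure", "flow")) {
      testw <- list(time = sim$time,
                    value = if (quantity == "pressure") p0 else q0)
      refw <- list(time = ref$time,
                   value = if (quantity == "pressure") ref$probes[[loc]]$p
                           else ref$probes[[loc]]$q)
      cmp <- compare_waveforms(testw, refw, dc$period)
      rows[[length(rows) + 1L]] <- data.frame(
        case = dc$case, location = loc, quantity = quantity,
        rmse = cmp$rmse, normalization = cmp$normalization,
        relative_rmse_pct = cmp$relative_rmse_pct)
    }
  }
  do.call(rbind, rows)
}

#' Default closed-loop cardiovascular network
#'
#' Four-chamber variable-elastance heart, four orifice valves, pulmonary
#' artery/vein and systemic venous compartments (all from [heart_defaults],
#' overridable via `heart`), and a small symmetric arterial tree: a
#' flow-inlet aortic root followed by `depth` generations of bifurcations
#' ending in RCR terminals that drain into the venous compartment.
#'
#' @param depth arterial tree depth (>= 0).
#' @param heart optional heart-block overrides (config-list form).
#' @return a closed-loop `bg_network`.
#' @export
closed_loop_network <- function(depth = 1, heart = NULL) {
  root <- vessel_geometry(length = 0.2, radius = 0.012,
                          youngs_modulus = 3e5)
  ratio <- 0.75
  term <- terminal_params(RTP = 1.5e7, RTD = 1.2e8, CT = 1.2e-8)
  n_leaf <- 2^depth
  fit <- thickness_fit()
  geom_at <- function(g) list(length = root$length * ratio^g,
                              radius = root$radius * ratio^g,
                              youngs_modulus = root$youngs_modulus)
  segs <- list()
  add <- function(s) segs[[length(segs) + 1L]] <<- s
  for (g in 0:depth) for (k in seq_len(2^g)) {
    id <- sprintf("a%d_%d", g, k)
    parent <- if (g == 0) NULL else sprintf("a%d_%d", g - 1L, (k + 1L) %/% 2L)
    type <- if (g == 0) "VV" else if (g < depth) "PV_SPLIT" else "PV"
    add(list(id = id, type = type, parent = parent, geometry = geom_at(g)))
  }
  for (k in seq_len(n_leaf))
    add(list(id = sprintf("t%d", k), type = "PP_BC_TERMINAL",
             parent = sprintf("a%d_%d", depth, k),
             geometry = geom_at(depth + 1L),
             terminal = list(RTP = term$RTP * n_leaf,
                             RTD = term$RTD * n_leaf,
                             CT = term$CT / n_leaf)))
  load_network(list(version = 1L, loop = "closed", segments = segs,
                    heart = heart))
}

#' Closed-form validation battery
#'
#' Bundles the analytic checks the lumped model must reproduce:
#' \itemize{
#'   \item RC discharge: an isolated terminal capacitor decays as
#'     exp(-t/(RTD CT));
#'   \item Poiseuille steady flow: a constant pressure difference across a
#'     mu-mu segment drives the steady flow dP/R;
#'   \item Windkessel steady state: a constant inflow drops
#'     inflow (RTP + RTD) across the RCR terminal;
#'   \item Windkessel diastolic decay: after inflow stops the terminal
#'     pressure decays with time constant RTD CT;
#'   \item mu-mu / chain structural equivalence: the mu-mu segment
#'     trajectory equals a mu-upsilon + upsilon-mu chain sharing the middle
#'     capacitor, with R and I halved on each side;
#'   \item closed-loop conservation: total blood volume drifts by less than
#'     0.1 percent over ten cardiac cycles.
#' }
#'
#' @param include_closed_loop logical; the closed-loop conservation check
#'   takes a few seconds, the rest are sub-second.
#' @return data.frame with one row per check: `check`, `computed`,
#'   `expected`, `tol` (relative), `pass`.
#' @export
analytic_battery <- function(include_closed_loop = TRUE) {
  rows <- list()
  note <- function(check, computed, expected, tol) {
    err <- if (expected == 0) abs(computed) else
      abs(computed - expected) / abs(expected)
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, computed = computed, expected = expected, tol = tol,
      pass = err < tol)
  }
  tight <- solver_config(rtol = 1e-10, atol_pressure = 1e-8,
                         atol_flow = 1e-14)

  ## RC discharge: terminal capacitor decoupled from its vessel by a huge
  ## proximal resistance, initial charge 1000 Pa, tau = RTD * CT = 1 s
  RTD <- 1e8; CT <- 1e-8
  net <- load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = 0),
    segments = list(list(id = "t", type = "PP_BC_TERMINAL",
      params = list(R = 1e7, C = 1e-10, I = 1e4),
      terminal = list(RTP = 1e14, RTD = RTD, CT = CT),
      initial = list(ud = 1000)))))
  sim <- run_simulation(net, tight, duration = 2)
  err <- max(abs(sim$states[, "t.ud"] -
                 1000 * exp(-sim$time / (RTD * CT)))) / 1000
  note("rc_discharge_max_rel_err", err, 0, 1e-3)

  ## Poiseuille steady flow through a mu-mu segment
  R <- 1e7; dP <- 1000
  net <- load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = dP),
    segments = list(list(id = "s", type = "PP",
      params = list(R = R, C = 1e-9, I = 1e5),
      outlet = list(kind = "pressure", value = 0)))))
  sim <- run_simulation(net, tight, duration = 1)
  note("poiseuille_steady_flow",
       sim$states[nrow(sim$states), "s.v"], dP / R, 1e-5)

  ## Windkessel steady pressure drop under constant inflow
  RTP <- 1e6; qbar <- 1e-6
  net <- load_network(list(loop = "open",
    inflow = list(kind = "table", time = c(0, 10), flow = c(qbar, qbar)),
    segments = list(list(id = "w", type = "VV",
      params = list(R = 1e5, C = 1e-11, I = 1e4),
      terminal = list(RTP = RTP, RTD = RTD, CT = CT),
      outlet = list(kind = "rcr")))))
  sim <- run_simulation(net, tight, duration = 8)
  note("windkessel_steady_drop",
       sim$states[nrow(sim$states), "w.ud"], qbar * (RTP + RTD), 1e-3)

  ## Windkessel diastolic decay constant (no inflow, both caps charged)
  net <- load_network(list(loop = "open",
    inflow = list(kind = "table", time = c(0, 10), flow = c(0, 0)),
    segments = list(list(id = "w", type = "VV",
      params = list(R = 1e5, C = 1e-11, I = 1e4),
      terminal = list(RTP = RTP, RTD = RTD, CT = CT),
      outlet = list(kind = "rcr"),
      initial = list(u = 1000, ud = 1000, udt = 1000)))))
  sim <- run_simulation(net, tight, duration = 3)
  win <- sim$time >= 0.5 & sim$time <= 2.5
  tau_fit <- -1 / stats::coef(stats::lm(
    log(sim$states[win, "w.udt"]) ~ sim$time[win]))[[2]]
  note("windkessel_decay_tau", tau_fit, RTD * CT, 0.01)

  ## mu-mu vs mu-upsilon + upsilon-mu chain
  eq <- pp_chain_equivalence()
  note("pp_chain_max_rel_dev", eq$max_rel_dev, 0, 1e-6)

  ## closed-loop volume conservation over ten cycles
  if (include_closed_loop) {
    sim <- run_simulation(closed_loop_network(depth = 1), solver_config(),
                          n_cycles = 10)
    vol <- total_blood_volume(sim)
    note("closed_loop_volume_drift", max(abs(vol - vol[1])) / vol[1],
         0, 1e-3)
  }
  do.call(rbind, rows)
}

#' mu-mu segment versus its two-element chain
#'
#' Simulates one mu-mu (PP) segment between constant pressure boundaries
#' through the network assembler, and the equivalent chain built directly
#' from the [deriv_pv] and [deriv_vp] primitives sharing the middle
#' capacitor with R and I halved on each side, and returns the maximum
#' relative deviation between the two trajectories.
#'
#' @param R,C,I segment parameters.
#' @param u_in,u_out boundary pressures (Pa).
#' @param duration simulated time (s).
#' @return list with `max_rel_dev` and the two trajectory matrices.
#' @export
pp_chain_equivalence <- function(R = 1e7, C = 1e-9, I = 1e5,
                                 u_in = 1000, u_out = 0, duration = 0.5) {
  tight <- solver_config(rtol = 1e-10, atol_pressure = 1e-8,
                         atol_flow = 1e-14)
  net <- load_network(list(loop = "open",
    inflow = list(kind = "pressure", value = u_in),
    segments = list(list(id = "s", type = "PP",
      params = list(R = R, C = C, I = I),
      outlet = list(kind = "pressure", value = u_out)))))
  sim <- run_simulation(net, tight, duration = duration)
  pp <- sim$states[, c("s.u", "s.v", "s.vd")]

  half <- lumped_params(R = R / 2, C = C, I = I / 2)
  chain_rhs <- function(t, y, parms) {
    st_pv <- c(u = y[[1]], v = y[[2]])
    st_vp <- c(u = y[[1]], v = y[[3]])
    d_pv <- deriv_pv(st_pv, list(u_in = u_in, v_out = y[[3]]), half)
    d_vp <- deriv_vp(st_vp, list(v_in = y[[2]], u_out = u_out), half)
    list(c(d_pv[["u"]], d_pv[["v"]], d_vp[["v"]]))
  }
  times <- seq(0, duration, by = tight$dt_out)
  ch <- deSolve::ode(c(0, 0, 0), times, chain_rhs, NULL, method = "bdf",
                     rtol = 1e-10, atol = c(1e-8, 1e-14, 1e-14))
  scale <- pmax(apply(abs(pp), 2, max), 1e-300)
  dev <- max(t(abs(pp - ch[, 2:4])) / scale)
  list(max_rel_dev = dev, pp = pp, chain = unclass(ch)[, 2:4])
}
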