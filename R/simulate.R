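#' Solver configuration
#'
#' Defaults mirror the reference simulation setup: variable-step stiff
#' multistep (BDF) integration reported on a 0.001 s output grid with
#' relative tolerance 1e-7. Absolute tolerances are set per state from its
#' unit (pressures carry much larger magnitudes than flows and volumes).
#'
#' @param method deSolve method: "bdf" (stiff multistep, default), "lsoda",
#'   or an explicit method such as "ode45" for cross-checks.
#' @param rtol relative tolerance.
#' @param atol_pressure,atol_flow,atol_volume absolute tolerances (Pa,
#'   m^3/s, m^3).
#' @param dt_out output/reporting step (s); the integrator chooses its own
#'   internal steps.
#' @param max_step maximum internal step (s), `Inf` to leave it to the
#'   integrator.
#' @return object of class `bg_solver`.
#' @export
solver_config <- function(method = "bdf", rtol = 1e-7,
                          atol_pressure = 1e-6, atol_flow = 1e-12,
                          atol_volume = 1e-12, dt_out = 0.001,
                          max_step = Inf) {
  structure(list(method = method, rtol = rtol,
                 atol_pressure = atol_pressure, atol_flow = atol_flow,
                 atol_volume = atol_volume, dt_out = dt_out,
                 max_step = max_step), class = "bg_solver")
}

#' Integrate a network to (or toward) its periodic state
#'
#' Assembles the network (unless a pre-assembled model from [assemble_rhs]
#' is given), integrates the stiff ODE system over the requested duration,
#' and returns time-stamped trajectories of every state plus the derived
#' algebraic outputs (chamber pressures, valve flows, terminal distal
#' flows, viscoelastic wall pressures). The model has no stochastic
#' component: re-running with identical inputs reproduces the trajectories
#' exactly.
#'
#' @param spec a `bg_network`, or the result of [assemble_rhs].
#' @param solver a [solver_config].
#' @param duration total simulated time (s); alternatively give `n_cycles`.
#' @param n_cycles number of cardiac/inflow cycles to simulate.
#' @param y0 initial state; defaults to the model's default initial state.
#' @return object of class `bg_simulation`: list with `time`, `states`
#'   (matrix time x states), `globals` (matrix of derived outputs), `units`,
#'   `model`, `period`, `summaries` (see [cycle_summaries]) and solver
#'   `diagnostics`.
#' @export
run_simulation <- function(spec, solver = solver_config(), duration = NULL,
                           n_cycles = NULL, y0 = NULL) {
  model <- if (inherits(spec, "bg_network")) assemble_rhs(spec) else spec
  if (is.null(duration)) {
    if (is.null(n_cycles))
      stop("give either duration or n_cycles", call. = FALSE)
    if (is.null(model$period) || is.na(model$period))
      stop("n_cycles needs a periodic drive (inflow period or heart timing)",
           call. = FALSE)
    duration <- n_cycles * model$period
  }
  stopifnot(duration > 0)
  if (is.null(y0)) y0 <- model$y0
  times <- seq(0, duration, by = solver$dt_out)
  atol <- ifelse(model$units == "Pa", solver$atol_pressure,
                 ifelse(model$units == "m3/s", solver$atol_flow,
                        solver$atol_volume))
  hmax <- if (is.finite(solver$max_step)) solver$max_step else NULL
  sol <- deSolve::ode(y = y0, times = times, func = model$rhs, parms = NULL,
                      method = solver$method, rtol = solver$rtol,
                      atol = atol, hmax = hmax)
  diag <- list(istate = attr(sol, "istate"), rstate = attr(sol, "rstate"))
  tlast <- sol[nrow(sol), 1]
  if (tlast < duration - solver$dt_out / 2)
    stop("integrator failed at t = ", signif(tlast, 6), " s", call. = FALSE)
  mat <- unclass(sol)
  bad <- which(!is.finite(mat))
  if (length(bad)) {
    col <- colnames(mat)[ceiling(bad[1] / nrow(mat))]
    stop("non-finite state '", col, "' during integration", call. = FALSE)
  }
  states <- mat[, model$state_names, drop = FALSE]
  globals <- if (length(model$global_names))
    mat[, model$global_names, drop = FALSE] else NULL
  qcols <- grep("\\.q$", model$state_names, value = TRUE)
  for (qc in qcols)
    if (min(states[, qc]) < 0)
      warning("chamber volume ", qc, " became negative (min ",
              signif(min(states[, qc]), 4), " m^3)", call. = FALSE)
  res <- structure(list(time = mat[, 1], states = states, globals = globals,
                        units = model$units, model = model,
                        period = model$period,
                        diagnostics = diag, solver = solver),
                   class = "bg_simulation")
  res$summaries <- tryCatch(cycle_summaries(res), error = function(e) NULL)
  res
}

## trajectories split into whole cycles: list of matrices (points x states)
.cycle_blocks <- function(result, period = result$period) {
  if (is.null(period) || is.na(period))
    stop("result has no cycle period", call. = FALSE)
  dt <- result$time[2] - result$time[1]
  npc <- round(period / dt)
  ncyc <- floor((length(result$time) - 1L) / npc)
  lapply(seq_len(ncyc), function(k)
    result$states[((k - 1L) * npc + 1L):(k * npc + 1L), , drop = FALSE])
}

#' Per-cycle summaries
#'
#' For every whole cycle: systolic (max), diastolic (min) and mean of each
#' pressure state; stroke volume (max minus min) of each volume state; and
#' the relative L2 change of the full state trajectory against the previous
#' cycle (the periodicity metric of [detect_periodic_state]).
#'
#' @param result a `bg_simulation`.
#' @param period cycle length (s).
#' @return data.frame, one row per (cycle, state).
#' @export
cycle_summaries <- function(result, period = result$period) {
  blocks <- .cycle_blocks(result, period)
  if (!length(blocks)) return(NULL)
  scale <- apply(abs(result$states), 2, max)
  rows <- list()
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    chg <- if (k == 1L) NA_real_ else {
      d <- b - blocks[[k - 1L]]
      num <- sqrt(colMeans(d^2)) / pmax(scale, 1e-300)
      max(num)
    }
    for (s in colnames(b)) {
      u <- result$units[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        cycle = k, state = s, unit = u,
        systolic = max(b[, s]), diastolic = min(b[, s]),
        mean = mean(b[, s]),
        stroke = if (u == "m3") max(b[, s]) - min(b[, s]) else NA_real_,
        l2_change = chg)
    }
  }
  do.call(rbind, rows)
}

#' Detect the periodic state
#'
#' Finds the first cycle whose full state trajectory differs from the
#' previous cycle by less than `tol` in relative L2 norm (per state,
#' normalized by the state's overall magnitude; the maximum over states
#' must fall below `tol`). Comparisons and reported waveforms should use
#' that cycle onward.
#'
#' @param result a `bg_simulation` covering at least two whole cycles.
#' @param tol relative L2 threshold (default 1e-3).
#' @param period cycle length (s).
#' @return list with `converged` (logical), `cycle` (index of the first
#'   periodic cycle, NA if not converged) and `metric` (per-cycle change).
#' @export
detect_periodic_state <- function(result, tol = 1e-3,
                                  period = result$period) {
  blocks <- .cycle_blocks(result, period)
  if (length(blocks) < 2L)
    stop("need at least two whole cycles to detect periodicity", call. = FALSE)
  scale <- pmax(apply(abs(result$states), 2, max), 1e-300)
  metric <- vapply(seq_along(blocks)[-1L], function(k) {
    d <- blocks[[k]] - blocks[[k - 1L]]
    max(sqrt(colMeans(d^2)) / scale)
  }, 0)
  hit <- which(metric < tol)
  list(converged = length(hit) > 0L,
       cycle = if (length(hit)) hit[1] + 1L else NA_integer_,
       metric = metric)
}

#' Total stored blood volume along a trajectory
#'
#' Sum of chamber volumes and of every capacitor's stored volume
#' (compliance times its pressure state, including terminal and
#' pulmonary/venous capacitors). In a closed loop this is conserved up to
#' integrator tolerance.
#'
#' @param result a `bg_simulation`.
#' @return numeric vector, one total volume (m^3) per output time.
#' @export
total_blood_volume <- function(result) {
  drop(result$states %*% result$model$vol_coef)
}

#' Write / read simulation trajectories as CSV
#'
#' Plain CSV with header `time_s,<segment>.<slot>,...` (derived outputs
#' appended after the states) and a leading `#` comment row carrying the
#' units. The round trip through [read_results] is lossless to double
#' precision.
#'
#' @param result a `bg_simulation`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_results <- function(result, path) {
  m <- cbind(time_s = result$time, result$states)
  units <- c("s", unname(result$units[colnames(result$states)]))
  if (!is.null(result$globals)) {
    m <- cbind(m, result$globals)
    gu <- ifelse(grepl("\\.v$|\\.vd$", colnames(result$globals)),
                 "m3/s", "Pa")
    units <- c(units, gu)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# units: ", paste(units, collapse = ",")), con)
  utils::write.table(m, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @return `read_results`: list with `time`, `states` (all non-time
#'   columns) and `units`.
#' @export
read_results <- function(path) {
  first <- readLines(path, n = 1L)
  units <- if (startsWith(first, "# units: "))
    strsplit(sub("^# units: ", "", first), ",")[[1]] else NULL
  d <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  if (!is.null(units)) units <- stats::setNames(units[-1], colnames(m))
  list(time = d[[1]], states = m, units = units)
}
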