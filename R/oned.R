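## Minimal one-dimensional blood-flow reference solver.
##
## Conservative finite-volume discretization of the 1D mass/momentum
## equations for an incompressible fluid in a compliant vessel,
##
##   dA/dt + dQ/dx = 0
##   dQ/dt + d(Q^2/A + A^2/(2 rho C'))/dx = -8 pi nu Q / (rho A)
##
## with the linear-elastic tube law p = (A - A0)/C', whose compliance per
## unit length C' = 2 pi r^3/(h E) matches the lumped wall compliance, and
## a flat-profile friction term consistent with the Poiseuille resistance
## per unit length. Rusanov (local Lax-Friedrichs) fluxes, explicit Euler
## stepping under CFL control, linearized-characteristic treatment of the
## inflow, RCR-outlet and junction boundaries. First-order and
## self-convergent: it serves as an independent desk-scale reference for
## the lumped model, not as a production 1D solver.

#' One-dimensional vessel specification
#'
#' @param id vessel identifier.
#' @param geom a [vessel_geometry] with explicit thickness.
#' @param parent id of the feeding vessel, or `NULL` for the root.
#' @param terminal a [terminal_params] RCR outlet (leaves only).
#' @param n_cells number of finite-volume cells (>= 16).
#' @return list describing one 1D vessel.
#' @export
oned_vessel <- function(id, geom, parent = NULL, terminal = NULL,
                        n_cells = 32) {
  if (n_cells < 16) stop("need at least 16 cells per vessel", call. = FALSE)
  if (is.null(geom$thickness))
    stop("1D vessel needs an explicit wall thickness", call. = FALSE)
  list(id = id, geom = geom, parent = parent, terminal = terminal,
       n_cells = as.integer(n_cells))
}

#' Solve the 1D reference problem
#'
#' Integrates a small vessel tree (a single vessel or a bifurcation in the
#' intended use) driven by a periodic inflow at the root and drained
#' through RCR Windkessel outlets at the leaves. Pressure and flow are
#' recorded at each vessel's midpoint cell on the output grid.
#'
#' @param vessels list of [oned_vessel]s forming a tree (one root).
#' @param inflow function of time returning the root inflow (m^3 s^-1).
#' @param duration total simulated time (s).
#' @param blood a [blood_properties].
#' @param dt_out output/reporting step (s).
#' @param cfl CFL number in (0, 1).
#' @return list with `time`, `probes` (per vessel: list with midpoint
#'   pressure `p` (Pa) and flow `q` (m^3/s)), `terminal_pressure` (final
#'   RCR capacitor pressures), `dt` (last internal step) and `steps`.
#' @export
solve_1d_reference <- function(vessels, inflow, duration,
                               blood = blood_properties(),
                               dt_out = 1e-3, cfl = 0.45) {
  ids <- vapply(vessels, `[[`, "", "id")
  names(vessels) <- ids
  rho <- blood$density
  fric <- 8 * pi * blood$viscosity / rho
  root <- ids[vapply(vessels, function(v) is.null(v$parent), TRUE)]
  if (length(root) != 1L) stop("1D tree needs exactly one root", call. = FALSE)
  children <- lapply(ids, function(id)
    ids[vapply(vessels, function(v) identical(v$parent, id), TRUE)])
  names(children) <- ids

  V <- lapply(vessels, function(v) {
    g <- v$geom
    A0 <- pi * g$radius^2
    Cp <- 2 * pi * g$radius^3 / (g$thickness * g$youngs_modulus)
    list(n = v$n_cells, dx = g$length / v$n_cells, A0 = A0, Cp = Cp,
         c0 = sqrt(A0 / (rho * Cp)), terminal = v$terminal,
         mid = as.integer(ceiling(v$n_cells / 2)))
  })
  A <- lapply(V, function(v) rep(v$A0, v$n))
  Q <- lapply(V, function(v) rep(0, v$n))
  pT <- lapply(V, function(v) if (!is.null(v$terminal)) 0 else NULL)

  times <- seq(0, duration, by = dt_out)
  nout <- length(times)
  probes <- lapply(ids, function(id)
    list(p = numeric(nout), q = numeric(nout)))
  names(probes) <- ids
  record <- function(k) {
    for (id in ids) {
      v <- V[[id]]; m <- v$mid
      probes[[id]]$p[k] <<- (A[[id]][m] - v$A0) / v$Cp
      probes[[id]]$q[k] <<- Q[[id]][m]
    }
  }
  record(1L)

  t <- 0; k <- 2L; steps <- 0L; dt <- NA_real_
  flux <- function(a, q, Cp) {
    cbind(q, q * q / a + a * a / (2 * rho * Cp))
  }
  while (k <= nout) {
    ## CFL step from current wave speeds
    dt <- Inf
    for (id in ids) {
      v <- V[[id]]
      lam <- max(abs(Q[[id]] / A[[id]]) + sqrt(A[[id]] / (rho * v$Cp)))
      dt <- min(dt, cfl * v$dx / lam)
    }
    if (!is.finite(dt) || dt <= 0)
      stop("1D solver diverged (non-finite wave speed) at t = ",
           signif(t, 6), call. = FALSE)
    newA <- A; newQ <- Q
    for (id in ids) {
      v <- V[[id]]; n <- v$n
      a <- A[[id]]; q <- Q[[id]]
      u <- q / a
      p <- (a - v$A0) / v$Cp
      c <- sqrt(a / (rho * v$Cp))
      F <- flux(a, q, v$Cp)
      ## internal faces (Rusanov)
      i <- seq_len(n - 1L)
      lam <- pmax(abs(u[i]) + c[i], abs(u[i + 1L]) + c[i + 1L])
      fA <- 0.5 * (F[i, 1] + F[i + 1L, 1]) - 0.5 * lam * (a[i + 1L] - a[i])
      fQ <- 0.5 * (F[i, 2] + F[i + 1L, 2]) - 0.5 * lam * (q[i + 1L] - q[i])
      ## inlet face
      if (id == root) {
        qin <- inflow(t)
        wm <- u[1] - p[1] / (rho * v$c0)
        af <- a[1]
        for (it in 1:3) {
          uf <- qin / af
          pf <- rho * v$c0 * (uf - wm)
          af <- max(v$A0 + v$Cp * pf, 0.5 * v$A0)
        }
        fin <- flux(af, qin, v$Cp)
      } else {
        fin <- NULL   # junction faces handled after the vessel loop
      }
      ## outlet face
      if (!is.null(v$terminal)) {
        term <- v$terminal
        wp <- u[n] + p[n] / (rho * v$c0)
        pf <- (a[n] * wp + (pT[[id]] + term$mu_out) / term$RTP) /
          (a[n] / (rho * v$c0) + 1 / term$RTP)
        qf <- (pf - pT[[id]] - term$mu_out) / term$RTP
        af <- max(v$A0 + v$Cp * pf, 0.5 * v$A0)
        fout <- flux(af, qf, v$Cp)
        pT[[id]] <- pT[[id]] + dt * (qf - pT[[id]] / term$RTD) / term$CT
      } else fout <- NULL
      V[[id]]$fA <- c(if (!is.null(fin)) fin[1, 1] else NA, fA,
                      if (!is.null(fout)) fout[1, 1] else NA)
      V[[id]]$fQ <- c(if (!is.null(fin)) fin[1, 2] else NA, fQ,
                      if (!is.null(fout)) fout[1, 2] else NA)
    }
    ## junction faces: common pressure from linearized characteristics,
    ## mass conservation across parent outlet and child inlets
    for (id in ids) {
      ch <- children[[id]]
      if (!length(ch)) next
      v <- V[[id]]; n <- v$n
      a <- A[[id]]; q <- Q[[id]]
      up <- q[n] / a[n]; pp <- (a[n] - v$A0) / v$Cp
      wp <- up + pp / (rho * v$c0)
      num <- a[n] * wp; den <- a[n] / (rho * v$c0)
      wmd <- numeric(length(ch)); ad <- numeric(length(ch))
      for (j in seq_along(ch)) {
        d <- V[[ch[j]]]
        a1 <- A[[ch[j]]][1]; q1 <- Q[[ch[j]]][1]
        wmd[j] <- q1 / a1 - (a1 - d$A0) / d$Cp / (rho * d$c0)
        ad[j] <- a1
        num <- num - a1 * wmd[j]
        den <- den + a1 / (rho * d$c0)
      }
      pJ <- num / den
      uf <- wp - pJ / (rho * v$c0)
      af <- max(v$A0 + v$Cp * pJ, 0.5 * v$A0)
      fo <- flux(af, af * uf, v$Cp)
      V[[id]]$fA[n + 1L] <- fo[1, 1]; V[[id]]$fQ[n + 1L] <- fo[1, 2]
      for (j in seq_along(ch)) {
        d <- V[[ch[j]]]
        ud <- wmd[j] + pJ / (rho * d$c0)
        afd <- max(d$A0 + d$Cp * pJ, 0.5 * d$A0)
        fi <- flux(afd, afd * ud, d$Cp)
        V[[ch[j]]]$fA[1] <- fi[1, 1]; V[[ch[j]]]$fQ[1] <- fi[1, 2]
      }
    }
    ## conservative update + friction source
    for (id in ids) {
      v <- V[[id]]; n <- v$n
      dA <- (v$fA[1:n] - v$fA[2:(n + 1L)]) / v$dx
      dQ <- (v$fQ[1:n] - v$fQ[2:(n + 1L)]) / v$dx -
        fric * Q[[id]] / A[[id]]
      newA[[id]] <- A[[id]] + dt * dA
      newQ[[id]] <- Q[[id]] + dt * dQ
      if (any(!is.finite(newA[[id]])) || any(newA[[id]] <= 0))
        stop("1D solver diverged in vessel '", id, "' at t = ",
             signif(t, 6), call. = FALSE)
    }
    A <- newA; Q <- newQ
    t <- t + dt; steps <- steps + 1L
    while (k <= nout && t >= times[k] - 1e-12) { record(k); k <- k + 1L }
  }
  list(time = times, probes = probes,
       terminal_pressure = unlist(pT), dt = dt, steps = steps)
}
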