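## Four-chamber variable-elastance heart with orifice-model valves, plus the
## lumped pulmonary and systemic venous compartments that close the loop.

#' Cardiac timing constants
#'
#' @param T cardiac period (s).
#' @param Tvc,Tvr ventricular contraction / relaxation durations (s),
#'   Tvc + Tvr <= T.
#' @param tac,Tac atrial contraction onset and duration (s),
#'   tac + Tac <= T.
#' @param tar,Tar atrial relaxation onset and duration (s); the relaxation
#'   tail may wrap past T into the next cycle. For continuity of the atrial
#'   activation, tar defaults to tac + Tac.
#' @return object of class `bg_timing`.
#' @export
cardiac_timing <- function(T = 1, Tvc = 0.3, Tvr = 0.15,
                           tac = 0.80, Tac = 0.17,
                           tar = tac + Tac, Tar = 0.17) {
  stopifnot(T > 0, Tvc > 0, Tvr > 0, Tac > 0, Tar > 0)
  if (Tvc + Tvr > T) stop("Tvc + Tvr must not exceed T", call. = FALSE)
  if (tac < 0 || tac + Tac > T) stop("atrial contraction must fit in [0, T]", call. = FALSE)
  if (tar < tac + Tac) stop("atrial relaxation cannot start before contraction ends", call. = FALSE)
  structure(list(T = T, Tvc = Tvc, Tvr = Tvr, tac = tac, Tac = Tac,
                 tar = tar, Tar = Tar), class = "bg_timing")
}

#' Ventricular activation function
#'
#' Piecewise-cosine activation e_v(t) in [0, 1]: raised-cosine upstroke over
#' the contraction interval [0, Tvc], raised-cosine decay over the
#' relaxation interval (Tvc, Tvc + Tvr], zero for the rest of the cycle.
#' Continuous and T-periodic; times outside [0, T) are reduced modulo T.
#'
#' @param t time (s), vectorized.
#' @param timing a [cardiac_timing].
#' @return activation value(s) in [0, 1].
#' @export
ventricle_activation <- function(t, timing = cardiac_timing()) {
  tt <- t %% timing$T
  out <- numeric(length(tt))
  i1 <- tt <= timing$Tvc
  out[i1] <- 0.5 * (1 - cos(pi * tt[i1] / timing$Tvc))
  i2 <- tt > timing$Tvc & tt <= timing$Tvc + timing$Tvr
  out[i2] <- 0.5 * (1 + cos(pi * (tt[i2] - timing$Tvc) / timing$Tvr))
  out
}

#' Atrial activation function
#'
#' Four-branch piecewise-cosine activation e_a(t): zero until contraction
#' onset tac, raised-cosine upstroke over (tac, tac + Tac], raised-cosine
#' relaxation from tar over duration Tar, with the relaxation tail wrapping
#' past T onto [0, tar + Tar - T] when tar + Tar > T.
#'
#' @inheritParams ventricle_activation
#' @return activation value(s) in [0, 1].
#' @export
atrium_activation <- function(t, timing = cardiac_timing()) {
  tt <- t %% timing$T
  out <- numeric(length(tt))
  wrap <- timing$tar + timing$Tar - timing$T
  i1 <- tt <= wrap          # wrapped relaxation tail (empty if no wrap)
  out[i1] <- 0.5 * (1 + cos(pi * (tt[i1] + timing$T - timing$tar) / timing$Tar))
  i3 <- tt > timing$tac & tt <= timing$tac + timing$Tac
  out[i3] <- 0.5 * (1 - cos(pi * (tt[i3] - timing$tac) / timing$Tac))
  i4 <- tt > timing$tac + timing$Tac &
    tt <= pmin(timing$tar + timing$Tar, timing$T)
  out[i4] <- 0.5 * (1 + cos(pi * (tt[i4] - timing$tar) / timing$Tar))
  out
}

#' Chamber elastance parameters
#'
#' Time-varying elastance E(t) = EB + e(t) EA, with e(t) the ventricular or
#' atrial activation. The equivalent time-varying compliance is
#' C(t) = 1/E(t).
#'
#' @param EA elastance amplitude (Pa m^-3), >= 0.
#' @param EB elastance baseline (Pa m^-3), > 0.
#' @param q0 dead volume of the chamber (m^3), >= 0.
#' @param kind "ventricle" or "atrium" (selects the activation function).
#' @return object of class `bg_chamber`.
#' @export
chamber_params <- function(EA, EB, q0, kind = c("ventricle", "atrium")) {
  kind <- match.arg(kind)
  EA <- parse_quantity(EA, "chamber$EA"); EB <- parse_quantity(EB, "chamber$EB")
  q0 <- parse_quantity(q0, "chamber$q0")
  if (EA < 0 || EB <= 0 || q0 < 0)
    stop("chamber requires EA >= 0, EB > 0, q0 >= 0", call. = FALSE)
  structure(list(EA = EA, EB = EB, q0 = q0, kind = kind), class = "bg_chamber")
}

#' Chamber pressure from volume
#'
#' mu = (q - q0) E(t), E(t) = EB + e(t) EA with the kind-appropriate
#' activation.
#'
#' @param q chamber volume (m^3).
#' @param t time (s).
#' @param params a [chamber_params].
#' @param timing a [cardiac_timing].
#' @return pressure (Pa).
#' @export
chamber_pressure <- function(q, t, params, timing = cardiac_timing()) {
  e <- if (params$kind == "ventricle") ventricle_activation(t, timing)
       else atrium_activation(t, timing)
  (q - params$q0) * (params$EB + e * params$EA)
}

#' Chamber volume derivative
#'
#' dq/dt = inflow - outflow (conservation of blood in the chamber).
#'
#' @param inflow,outflow flows (m^3 s^-1).
#' @return volume derivative (m^3 s^-1).
#' @export
chamber_volume_deriv <- function(inflow, outflow) inflow - outflow

#' Heart valve parameters
#'
#' Orifice-model valve: a two-state opening coefficient alpha (1 when the
#' upstream pressure exceeds the downstream pressure, else 0) times a
#' nonlinear pressure-flow law. The default law is the square-root orifice
#' relation flow = coeff * sqrt(max(dp, 0)) with `coeff` in
#' m^3 s^-1 Pa^-1/2; a linear-diode law (flow = coeff * max(dp, 0), coeff in
#' m^3 s^-1 Pa^-1) is available for sensitivity checks. Inside the
#' integrator the hard 0/1 switch is replaced by a sharp logistic of width
#' `width` (Pa) so the stiff multistep method never sees a discontinuous
#' right-hand side; the hard rule is used when reporting valve state.
#'
#' @param coeff valve flow coefficient (units set by `law`), > 0.
#' @param law "orifice" (square root) or "linear".
#' @param width smoothing width of the opening switch (Pa), > 0.
#' @return object of class `bg_valve`.
#' @export
valve_params <- function(coeff, law = c("orifice", "linear"), width = 1) {
  law <- match.arg(law)
  coeff <- parse_quantity(coeff, "valve$coeff")
  if (coeff <= 0 || width <= 0)
    stop("valve requires coeff > 0 and width > 0", call. = FALSE)
  structure(list(coeff = coeff, law = law, width = width), class = "bg_valve")
}

#' Valve flow from the orifice model
#'
#' Non-negative flow through a valve given upstream and downstream
#' pressures. With `smooth = FALSE` the exact two-state law is used:
#' alpha = 1 iff mu_up > mu_down, flow = alpha * coeff * Phi(mu_up -
#' mu_down). With `smooth = TRUE` (used inside the integrator) alpha is a
#' logistic in the pressure difference and Phi is regularized near zero so
#' the flow is smooth; the flow remains >= 0 in both modes.
#'
#' @param mu_up,mu_down upstream / downstream pressures (Pa), vectorized.
#' @param valve a [valve_params].
#' @param smooth logical; smooth switching for integration.
#' @return flow (m^3 s^-1), always >= 0.
#' @export
valve_flow <- function(mu_up, mu_down, valve, smooth = FALSE) {
  dp <- mu_up - mu_down
  if (!smooth) {
    alpha <- as.numeric(dp > 0)
    phi <- if (valve$law == "orifice") sqrt(pmax(dp, 0)) else pmax(dp, 0)
    return(alpha * valve$coeff * phi)
  }
  w <- valve$width
  alpha <- stats::plogis(dp / w)
  pos <- 0.5 * (dp + sqrt(dp * dp + w * w))   # smooth positive part
  phi <- if (valve$law == "orifice") sqrt(pos) else pos
  alpha * valve$coeff * phi
}

#' Valve opening coefficient (hard rule)
#'
#' alpha = 1 when mu_up > mu_down, else 0; used for reporting valve state.
#'
#' @inheritParams valve_flow
#' @return 0/1 vector.
#' @export
valve_state <- function(mu_up, mu_down, valve = NULL) as.numeric(mu_up > mu_down)

#' Default heart, pulmonary and venous parameter block
#'
#' Physiologically standard defaults (SI units): left/right ventricular and
#' atrial elastances and dead volumes, shared cardiac timing, four
#' square-root-orifice valves, and the three lumped flow-inlet/pressure-outlet
#' compartments closing the loop (pulmonary arteries `par`, pulmonary veins
#' `pvn`, systemic veins `svn`). All values can be overridden through the
#' `heart` block of a network config.
#'
#' @return nested list with `chambers`, `timing`, `valves`, `compartments`,
#'   and initial filling volumes `fill` (m^3).
#' @export
heart_defaults <- function() {
  mm <- 133.322
  list(
    chambers = list(
      lv = chamber_params(EA = 2.4 * mm / 1e-6, EB = 0.10 * mm / 1e-6,
                          q0 = 5e-6, kind = "ventricle"),
      rv = chamber_params(EA = 1.05 * mm / 1e-6, EB = 0.10 * mm / 1e-6,
                          q0 = 10e-6, kind = "ventricle"),
      la = chamber_params(EA = 0.10 * mm / 1e-6, EB = 0.15 * mm / 1e-6,
                          q0 = 4e-6, kind = "atrium"),
      ra = chamber_params(EA = 0.10 * mm / 1e-6, EB = 0.15 * mm / 1e-6,
                          q0 = 4e-6, kind = "atrium")),
    timing = cardiac_timing(),
    valves = list(
      mitral = valve_params(3.5e-5), aortic = valve_params(3.0e-5),
      tricuspid = valve_params(3.5e-5), pulmonary = valve_params(3.0e-5)),
    compartments = list(
      par = lumped_params(R = 1.0e7, C = 3.0e-8, I = 5e5),
      pvn = lumped_params(R = 6.0e6, C = 6.0e-8, I = 5e5),
      svn = lumped_params(R = 6.7e6, C = 7.5e-7, I = 5e5)),
    fill = c(lv = 1.0e-4, rv = 1.0e-4, la = 4e-5, ra = 4e-5)
  )
}
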