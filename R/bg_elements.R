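## Bond-graph compartment library.
##
## Each vessel segment is a parallel C (wall compliance) with a series R-I
## (viscous loss + blood inertia), wired through a 0-junction (common
## pressure, flows sum to zero) and a 1-junction (common flow, pressures sum
## to zero). Seven segment types differ only in which boundary covariable
## (pressure or flow) each end receives; the type therefore fixes both the
## state layout and the causality of the couplings:
##
##   PV (mu-upsilon)   pressure in, flow out    states u, v
##   VP (upsilon-mu)   flow in, pressure out    states u, v
##   PP (mu-mu)        pressure both ends       states u, v, vd
##   VV (upsilon-ups.) flow both ends           states u, v, ud
##   PV_SPLIT          PV parent of a branch    states u, v
##   VV_MERGE          VV parent of a merge     states u, v, ud
##   PP_BC_TERMINAL    PV + RCR Windkessel      states u, v, ud
##
## u is a capacitor pressure (Pa), v a 1-junction flow (m^3/s), ud the
## distal capacitor pressure (VV/merge) or the terminal capacitor pressure
## (terminal), vd the distal flow (PP). Viscoelastic (Voigt) variants store
## the elastic part of the wall pressure (uv, and udv for the two-capacitor
## types) and expose the total pressure algebraically.

#' Segment type tags
#' @return character vector of the supported segment type tags.
#' @export
segment_types <- function() {
  c("PV", "VP", "PP", "VV", "PV_SPLIT", "VV_MERGE", "PP_BC_TERMINAL")
}

#' State slots of a segment type
#'
#' The state-vector width of a compartment is fixed by its type tag and the
#' viscoelastic flag. For viscoelastic walls the stored capacitor state is
#' the elastic pressure (`uv`/`udv`) and the total wall pressure becomes an
#' algebraic output, so the width matches the elastic variant.
#'
#' @param tag one of [segment_types()].
#' @param viscoelastic logical; Voigt wall?
#' @return character vector of slot names, in state-vector order.
#' @export
seg_state_slots <- function(tag, viscoelastic = FALSE) {
  tag <- match.arg(tag, segment_types())
  slots <- switch(tag,
    PV = , VP = , PV_SPLIT = c("u", "v"),
    PP = c("u", "v", "vd"),
    VV = , VV_MERGE = c("u", "v", "ud"),
    PP_BC_TERMINAL = c("u", "v", "ud"))
  if (viscoelastic) {
    slots[slots == "u"] <- "uv"
    if (tag %in% c("VV", "VV_MERGE")) slots[slots == "ud"] <- "udv"
  }
  slots
}

#' RCR Windkessel terminal parameters
#'
#' Proximal resistance RTP in series with the parallel pair of terminal
#' compliance CT and distal resistance RTD; `mu_out` is the venous
#' reference pressure the distal end drains to (rewired to the venous
#' compartment pressure in a closed loop).
#'
#' @param RTP,RTD terminal resistances (Pa s m^-3), > 0.
#' @param CT terminal compliance (m^3 Pa^-1), > 0.
#' @param mu_out outflow reference pressure (Pa).
#' @return object of class `bg_terminal`.
#' @export
terminal_params <- function(RTP, RTD, CT, mu_out = 0) {
  RTP <- parse_quantity(RTP, "terminal$RTP")
  RTD <- parse_quantity(RTD, "terminal$RTD")
  CT <- parse_quantity(CT, "terminal$CT")
  mu_out <- parse_quantity(mu_out, "terminal$mu_out")
  if (RTP <= 0 || RTD <= 0 || CT <= 0)
    stop("terminal parameters RTP, RTD, CT must be > 0", call. = FALSE)
  structure(list(RTP = RTP, RTD = RTD, CT = CT, mu_out = mu_out),
            class = "bg_terminal")
}

#' Elastic segment time derivatives
#'
#' Pure derivative functions for each elastic segment type. States and
#' derivatives are named numeric vectors (see [seg_state_slots]); `bc`
#' carries exactly the boundary covariables demanded by the type's
#' causality.
#'
#' `deriv_pv`: du = (v - v_out)/C, dv = (u_in - u - v R)/I.
#'
#' @param state named numeric state vector.
#' @param bc list of boundary covariables: `u_in`/`v_out` (PV),
#'   `v_in`/`u_out` (VP), `u_in`/`u_out` (PP, terminal), `v_in`/`v_out`
#'   (VV), `u_in`/`v_daughters` (split), `vd_in`/`v_out` (merge).
#' @param params a [lumped_params].
#' @return named numeric vector of time derivatives.
#' @export
deriv_pv <- function(state, bc, params) {
  c(u = (state[["v"]] - bc$v_out) / params$C,
    v = (bc$u_in - state[["u"]] - state[["v"]] * params$R) / params$I)
}

#' @rdname deriv_pv
#' @export
deriv_vp <- function(state, bc, params) {
  c(u = (bc$v_in - state[["v"]]) / params$C,
    v = (state[["u"]] - bc$u_out - state[["v"]] * params$R) / params$I)
}

#' @rdname deriv_pv
#' @export
deriv_pp <- function(state, bc, params) {
  c(u = (state[["v"]] - state[["vd"]]) / params$C,
    v = (bc$u_in - state[["u"]] - state[["v"]] * (params$R / 2)) / (params$I / 2),
    vd = (state[["u"]] - bc$u_out - state[["vd"]] * (params$R / 2)) / (params$I / 2))
}

#' @rdname deriv_pv
#' @export
deriv_vv <- function(state, bc, params) {
  c(u = (bc$v_in - state[["v"]]) / (params$C / 2),
    v = (state[["u"]] - state[["ud"]] - state[["v"]] * params$R) / params$I,
    ud = (state[["v"]] - bc$v_out) / (params$C / 2))
}

#' @rdname deriv_pv
#' @export
deriv_pv_split <- function(state, bc, params) {
  c(u = (state[["v"]] - sum(bc$v_daughters)) / params$C,
    v = (bc$u_in - state[["u"]] - state[["v"]] * params$R) / params$I)
}

#' @rdname deriv_pv
#' @export
deriv_vv_merge <- function(state, bc, params) {
  c(u = (sum(bc$vd_in) - state[["v"]]) / (params$C / 2),
    v = (state[["u"]] - state[["ud"]] - state[["v"]] * params$R) / params$I,
    ud = (state[["v"]] - bc$v_out) / (params$C / 2))
}

#' @rdname deriv_pv
#' @param terminal a [terminal_params] (terminal type only).
#' @details For the terminal type the distal flow vd = (u - ud - mu_out)/RTP
#'   is algebraic, not a state; it is attached to the returned vector as
#'   attribute `"vd"`.
#' @export
deriv_pp_bc_terminal <- function(state, bc, params, terminal) {
  vd <- (state[["u"]] - state[["ud"]] - bc$u_out) / terminal$RTP
  d <- c(u = (state[["v"]] - vd) / params$C,
         v = (bc$u_in - state[["u"]] - state[["v"]] * params$R) / params$I,
         ud = (vd - state[["ud"]] / terminal$RTD) / terminal$CT)
  attr(d, "vd") <- vd
  d
}

## Net flow into each wall capacitor, from states and boundary covariables
## only (all exposed flows in an assembled network are states, so this never
## needs a neighbour's pressure).
.cap_inflow <- function(tag, state, bc, vd = NULL) {
  switch(tag,
    PV = c(u = state[["v"]] - bc$v_out),
    VP = c(u = bc$v_in - state[["v"]]),
    PP = c(u = state[["v"]] - state[["vd"]]),
    VV = c(u = bc$v_in - state[["v"]], ud = state[["v"]] - bc$v_out),
    PV_SPLIT = c(u = state[["v"]] - sum(bc$v_daughters)),
    VV_MERGE = c(u = sum(bc$vd_in) - state[["v"]], ud = state[["v"]] - bc$v_out),
    PP_BC_TERMINAL = c(u = state[["v"]] - vd))
}

## Effective (total) wall pressures of a viscoelastic segment: the Voigt
## dashpot adds (net capacitor inflow) * Rv on top of the stored elastic
## pressure. Half-capacitors (VV types) carry dashpot 2*Rv each so that
## Rv_half * C_half = f still holds. For the terminal the algebraic distal
## flow feeds back into the net inflow; the resulting linear relation is
## solved in closed form.
.visco_pressures <- function(tag, state, bc, params, terminal = NULL) {
  Rv <- params$Rv
  if (tag == "PP_BC_TERMINAL") {
    k <- Rv / terminal$RTP
    u <- (state[["uv"]] + state[["v"]] * Rv +
            (state[["ud"]] + bc$u_out) * k) / (1 + k)
    vd <- (u - state[["ud"]] - bc$u_out) / terminal$RTP
    return(list(u = u, vd = vd))
  }
  if (tag %in% c("VV", "VV_MERGE")) {
    vin <- if (tag == "VV") bc$v_in else sum(bc$vd_in)
    return(list(u = state[["uv"]] + (vin - state[["v"]]) * 2 * Rv,
                ud = state[["udv"]] + (state[["v"]] - bc$v_out) * 2 * Rv))
  }
  net <- switch(tag,
    PV = state[["v"]] - bc$v_out,
    VP = bc$v_in - state[["v"]],
    PP = state[["v"]] - state[["vd"]],
    PV_SPLIT = state[["v"]] - sum(bc$v_daughters))
  list(u = state[["uv"]] + net * Rv)
}

#' Evaluate one segment (elastic or viscoelastic)
#'
#' Unified dispatcher used by the network assembler and by
#' [apply_viscoelastic]. For viscoelastic segments the stored states are the
#' elastic wall pressures; the returned `pressures` entry holds the
#' effective (total) capacitor pressures which neighbours see.
#'
#' @inheritParams deriv_pv
#' @param tag segment type tag.
#' @param viscoelastic logical.
#' @param terminal [terminal_params] for the terminal type.
#' @return list with `deriv` (named per the actual state slots),
#'   `pressures` (named list, effective `u` and possibly `ud`) and, for the
#'   terminal type, the algebraic distal flow `vd`.
#' @export
deriv_segment <- function(tag, state, bc, params, viscoelastic = FALSE,
                          terminal = NULL) {
  tag <- match.arg(tag, segment_types())
  fn <- switch(tag,
    PV = deriv_pv, VP = deriv_vp, PP = deriv_pp, VV = deriv_vv,
    PV_SPLIT = deriv_pv_split, VV_MERGE = deriv_vv_merge,
    PP_BC_TERMINAL = function(s, b, p) deriv_pp_bc_terminal(s, b, p, terminal))
  if (!viscoelastic) {
    d <- fn(state, bc, params)
    vd <- attr(d, "vd")
    attributes(d) <- list(names = names(d))
    pr <- list(u = state[["u"]])
    if ("ud" %in% names(state) && tag != "PP_BC_TERMINAL") pr$ud <- state[["ud"]]
    return(list(deriv = d, pressures = pr, vd = vd))
  }
  eff <- .visco_pressures(tag, state, bc, params, terminal)
  est <- state
  names(est)[names(est) == "uv"] <- "u"
  names(est)[names(est) == "udv"] <- "ud"
  est[["u"]] <- eff$u
  if (!is.null(eff$ud)) est[["ud"]] <- eff$ud
  d <- fn(est, bc, params)
  vd <- attr(d, "vd")
  attributes(d) <- list(names = names(d))
  names(d)[names(d) == "u"] <- "uv"
  if (tag %in% c("VV", "VV_MERGE")) names(d)[names(d) == "ud"] <- "udv"
  list(deriv = d, pressures = eff[setdiff(names(eff), "vd")], vd = eff$vd)
}

#' Voigt viscoelastic wrapper
#'
#' Wraps any base segment type with a Voigt (spring-dashpot in parallel)
#' wall: the capacitor pressure becomes algebraic,
#' u = uv + (net capacitor inflow) Rv, while the stored state evolves as
#' duv = (net capacitor inflow)/C. With Rv = 0 this reduces exactly to the
#' elastic element.
#'
#' @inheritParams deriv_segment
#' @return as [deriv_segment] with `viscoelastic = TRUE`.
#' @export
apply_viscoelastic <- function(state, bc, params, tag = "PV", terminal = NULL) {
  deriv_segment(tag, state, bc, params, viscoelastic = TRUE, terminal = terminal)
}
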