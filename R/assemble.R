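## Global ODE assembly: flatten a validated network (plus, in closed-loop
## mode, the four heart chambers, four valves and the pulmonary/venous
## compartments) into one state vector and a pure right-hand-side function.
##
## Coupling pattern: at every parent->child interface one side supplies the
## pressure covariable and the other the flow covariable, exactly as the
## segment types' causality dictates. All exposed flows are states, so the
## effective (possibly viscoelastic) capacitor pressures every neighbour
## sees can be computed in a single pass before the derivative pass.

.CLOSED_IDS <- c("par", "pvn", "svn", "lv", "rv", "la", "ra")

#' Assemble the network right-hand side
#'
#' Builds the flat state vector layout (deterministic: user segments in
#' id-sorted order, then the pulmonary/venous compartments, then the
#' chamber volumes) and a pure derivative function `rhs(t, y)` returning
#' `list(dy, globals)` in the form deSolve expects. The `globals` are
#' derived algebraic outputs: chamber pressures, valve flows, terminal
#' distal flows and the effective wall pressures of viscoelastic segments.
#'
#' @param spec a validated `bg_network`.
#' @return list with `n` (state count), `state_names`, `index` (named
#'   integer positions), `units`, `rhs`, `global_names`, `y0` (default
#'   initial state), `vol_coef` (total stored blood volume is
#'   `sum(vol_coef * y)`), `cap_coef`/`inert_coef` (stored-energy
#'   coefficients: energy = sum(cap u^2 + inert v^2)/2), `period`, and the
#'   input `spec`.
#' @export
assemble_rhs <- function(spec) {
  stopifnot(inherits(spec, "bg_network"))
  v <- validate_topology(spec)
  if (nrow(v) > 0L) stop("network fails validation; see validate_topology()",
                         call. = FALSE)
  closed <- spec$loop == "closed"
  nodes <- spec$segments
  if (closed) {
    if (any(names(nodes) %in% .CLOSED_IDS))
      stop("segment ids ", paste(intersect(names(nodes), .CLOSED_IDS),
           collapse = ", "), " are reserved in closed-loop mode", call. = FALSE)
    mk <- function(nm) list(id = nm, type = "VP", viscoelastic = FALSE,
                            geometry = NULL,
                            params = spec$heart$compartments[[nm]],
                            terminal = NULL, parent = character(0),
                            children = character(0), outlet = NULL,
                            initial = NULL)
    comp <- list(par = mk("par"), pvn = mk("pvn"), svn = mk("svn"))
    comp$par$children <- "pvn"
    comp$pvn$parent <- "par"
    nodes <- c(nodes, comp)
  }

  ## ---- state layout -------------------------------------------------
  state_names <- character(0); units <- character(0)
  vol_coef <- numeric(0); cap_coef <- numeric(0); inert_coef <- numeric(0)
  for (id in names(nodes)) {
    n <- nodes[[id]]
    slots <- seg_state_slots(n$type, n$viscoelastic)
    has_rcr <- !is.null(n$outlet) && n$outlet$kind == "rcr"
    if (has_rcr && n$type != "PP_BC_TERMINAL") slots <- c(slots, "udt")
    nodes[[id]]$slots <- slots
    p <- n$params
    for (s in slots) {
      state_names <- c(state_names, paste0(id, ".", s))
      half <- n$type %in% c("VV", "VV_MERGE") && s %in% c("u", "ud", "uv", "udv")
      vol_coef <- c(vol_coef, switch(s,
        u = , uv = if (half) p$C / 2 else p$C,
        ud = , udv = if (n$type == "PP_BC_TERMINAL") n$terminal$CT
                     else p$C / 2,
        udt = n$terminal$CT,
        v = , vd = 0))
      cap_coef <- c(cap_coef, vol_coef[length(vol_coef)])
      inert_coef <- c(inert_coef, switch(s,
        v = , vd = if (n$type == "PP") p$I / 2 else p$I,
        0))
      units <- c(units, if (s %in% c("v", "vd")) "m3/s" else "Pa")
    }
  }
  chambers <- if (closed) names(spec$heart$chambers) else character(0)
  for (ch in chambers) {
    state_names <- c(state_names, paste0(ch, ".q"))
    units <- c(units, "m3")
    vol_coef <- c(vol_coef, 1); cap_coef <- c(cap_coef, 0)
    inert_coef <- c(inert_coef, 0)
  }
  nstate <- length(state_names)
  index <- stats::setNames(seq_len(nstate), state_names)
  names(units) <- state_names
  for (id in names(nodes))
    nodes[[id]]$ix <- index[paste0(id, ".", nodes[[id]]$slots)]
  q_ix <- if (closed) index[paste0(chambers, ".q")] else integer(0)

  ## ---- wiring -------------------------------------------------------
  flow_out_ix <- function(id) {    # the state carrying a node's outlet flow
    n <- nodes[[id]]
    switch(n$type, VP = n$ix[[paste0(id, ".v")]],
           PP = n$ix[[paste0(id, ".vd")]],
           stop("node ", id, " does not expose an outlet flow"))
  }
  inlet_flow_ix <- function(id) nodes[[id]]$ix[[paste0(id, ".v")]]

  rcr_ids <- names(nodes)[vapply(nodes, function(n)
    !is.null(n$outlet) && n$outlet$kind == "rcr", TRUE)]
  rcr_cap_ix <- vapply(rcr_ids, function(id)
    nodes[[id]]$ix[[paste0(id, ".",
      if (nodes[[id]]$type == "PP_BC_TERMINAL") "ud" else "udt")]], 0L)
  rcr_rtd <- vapply(rcr_ids, function(id) nodes[[id]]$terminal$RTD, 0)

  for (id in names(nodes)) {
    n <- nodes[[id]]
    ## inlet
    if (.inlet_demands_pressure(n$type)) {
      nodes[[id]]$uin <- if (length(n$parent)) list(kind = "parent",
        parent = n$parent[1]) else list(kind = "bc", fun = spec$inflow$fun)
    } else {
      if (length(n$parent)) {
        nodes[[id]]$vin <- list(kind = "states",
          ix = vapply(n$parent, flow_out_ix, 0L))
      } else if (closed && id == "par") {
        nodes[[id]]$vin <- list(kind = "valve", valve = "pulmonary")
      } else if (closed && id == "svn") {
        nodes[[id]]$vin <- list(kind = "venous_return")
      } else if (closed) {
        nodes[[id]]$vin <- list(kind = "valve", valve = "aortic")
      } else {
        nodes[[id]]$vin <- list(kind = "bc", fun = spec$inflow$fun)
      }
    }
    ## outlet
    flow_out_type <- n$type %in% c("PV", "PV_SPLIT", "VV", "VV_MERGE",
                                   "PP_BC_TERMINAL")
    if (length(n$children)) {
      if (flow_out_type) {
        nodes[[id]]$vout <- list(kind = "states",
          ix = vapply(n$children, inlet_flow_ix, 0L))
      } else {
        nodes[[id]]$uout <- list(kind = "child", child = n$children[1])
      }
    } else if (!is.null(n$outlet)) {
      o <- n$outlet
      if (o$kind == "rcr") {
        nodes[[id]]$vout <- list(kind = "rcr")
      } else if (o$kind == "flow") {
        nodes[[id]]$vout <- list(kind = "bc",
          fun = local({ val <- o$value; function(t) val }))
      } else {
        nodes[[id]]$uout <- list(kind = "bc",
          fun = local({ val <- o$value; function(t) val }))
      }
    } else if (closed && id == "pvn") {
      nodes[[id]]$uout <- list(kind = "chamber", chamber = "la")
    } else if (closed && id == "svn") {
      nodes[[id]]$uout <- list(kind = "chamber", chamber = "ra")
    }
  }
  node_ids <- names(nodes)
  node_n <- length(nodes)
  root_id <- if (closed)
    setdiff(spec$roots, .CLOSED_IDS)[1] else spec$roots[1]
  svn_u_ix <- if (closed) nodes$svn$ix[["svn.u"]] else NA_integer_

  heart <- spec$heart
  timing <- if (closed) heart$timing

  ## globals layout
  global_names <- character(0)
  if (closed) global_names <- c(paste0(chambers, ".u"),
    paste0(c("mitral", "aortic", "tricuspid", "pulmonary"), ".v"))
  for (id in node_ids) {
    n <- nodes[[id]]
    if (n$viscoelastic) {
      global_names <- c(global_names, paste0(id, ".u"))
      if (n$type %in% c("VV", "VV_MERGE"))
        global_names <- c(global_names, paste0(id, ".ud"))
    }
    if (!is.null(n$outlet) && n$outlet$kind == "rcr" &&
        n$type != "PP_BC_TERMINAL")
      global_names <- c(global_names, paste0(id, ".vd"))
    if (n$type == "PP_BC_TERMINAL")
      global_names <- c(global_names, paste0(id, ".vd"))
  }

  ## ---- right-hand side ---------------------------------------------
  rhs <- function(t, y, parms = NULL) {
    glob <- stats::setNames(numeric(length(global_names)), global_names)

    if (closed) {
      u_ch <- vapply(chambers, function(ch)
        chamber_pressure(y[[q_ix[[paste0(ch, ".q")]]]], t,
                         heart$chambers[[ch]], timing), 0)
      glob[paste0(chambers, ".u")] <- u_ch
    }

    ## pass 1: exposures (effective capacitor pressures + boundary flows)
    press_in <- stats::setNames(rep(NA_real_, node_n), node_ids)
    press_out <- press_in
    vout_val <- press_in   # resolved outlet flow (v_out) per node
    vin_val <- press_in
    vd_val <- press_in     # algebraic RCR distal flow
    venous_return <- sum(y[rcr_cap_ix] / rcr_rtd)

    for (id in node_ids) {
      n <- nodes[[id]]
      st <- y[n$ix]; names(st) <- n$slots
      p <- n$params
      ## resolved inlet flow (only defined for flow-demand inlets)
      if (!is.null(n$vin)) {
        vin_val[[id]] <- switch(n$vin$kind,
          states = sum(y[n$vin$ix]),
          bc = n$vin$fun(t),
          valve = NA_real_,            # filled after valve pass (elastic only)
          venous_return = venous_return)
      }
      ## resolved outlet flow
      if (!is.null(n$vout)) {
        vout_val[[id]] <- switch(n$vout$kind,
          states = sum(y[n$vout$ix]),
          bc = n$vout$fun(t),
          rcr = NA_real_)              # resolved below (needs eff pressure)
      }
      ## effective pressures and RCR distal flow
      term <- n$terminal
      if (!n$viscoelastic) {
        u <- st[["u"]]
        ud <- if ("ud" %in% n$slots) st[["ud"]] else NA_real_
        if (!is.null(n$vout) && n$vout$kind == "rcr") {
          muref <- if (closed) y[[svn_u_ix]] else term$mu_out
          cap <- if (n$type == "PP_BC_TERMINAL") st[["ud"]] else st[["udt"]]
          feed <- if (n$type == "PP_BC_TERMINAL") u else ud
          vd_val[[id]] <- (feed - cap - muref) / term$RTP
          if (n$type != "PP_BC_TERMINAL") vout_val[[id]] <- vd_val[[id]]
        }
      } else {
        Rv <- p$Rv
        if (n$type %in% c("VV", "VV_MERGE")) {
          u <- st[["uv"]] + (vin_val[[id]] - st[["v"]]) * 2 * Rv
          if (!is.null(n$vout) && n$vout$kind == "rcr") {
            muref <- if (closed) y[[svn_u_ix]] else term$mu_out
            vo <- (st[["udv"]] + 2 * Rv * st[["v"]] - st[["udt"]] - muref) /
              (term$RTP + 2 * Rv)
            vd_val[[id]] <- vo; vout_val[[id]] <- vo
          }
          ud <- st[["udv"]] + (st[["v"]] - vout_val[[id]]) * 2 * Rv
        } else if (n$type == "PP_BC_TERMINAL") {
          muref <- if (closed) y[[svn_u_ix]] else term$mu_out
          k <- Rv / term$RTP
          u <- (st[["uv"]] + st[["v"]] * Rv + (st[["ud"]] + muref) * k) /
            (1 + k)
          vd_val[[id]] <- (u - st[["ud"]] - muref) / term$RTP
          ud <- NA_real_
        } else {
          net <- switch(n$type,
            PV = , PV_SPLIT = st[["v"]] - vout_val[[id]],
            VP = vin_val[[id]] - st[["v"]],
            PP = st[["v"]] - st[["vd"]])
          u <- st[["uv"]] + net * Rv
          ud <- NA_real_
        }
        glob[[paste0(id, ".u")]] <- u
        if (n$type %in% c("VV", "VV_MERGE")) glob[[paste0(id, ".ud")]] <- ud
      }
      if (!.inlet_demands_pressure(n$type)) press_in[[id]] <- u
      press_out[[id]] <- if (n$type %in% c("PV", "PV_SPLIT")) u
                         else if (n$type %in% c("VV", "VV_MERGE")) ud
                         else NA_real_
      if (!is.na(vd_val[[id]])) glob[[paste0(id, ".vd")]] <- vd_val[[id]]
    }

    ## valve flows (closed loop)
    if (closed) {
      vq <- c(
        mitral = valve_flow(u_ch[["la"]], u_ch[["lv"]],
                            heart$valves$mitral, smooth = TRUE),
        aortic = valve_flow(u_ch[["lv"]], press_in[[root_id]],
                            heart$valves$aortic, smooth = TRUE),
        tricuspid = valve_flow(u_ch[["ra"]], u_ch[["rv"]],
                               heart$valves$tricuspid, smooth = TRUE),
        pulmonary = valve_flow(u_ch[["rv"]], press_in[["par"]],
                               heart$valves$pulmonary, smooth = TRUE))
      glob[paste0(names(vq), ".v")] <- vq
      for (id in node_ids)
        if (!is.null(nodes[[id]]$vin) && nodes[[id]]$vin$kind == "valve")
          vin_val[[id]] <- vq[[nodes[[id]]$vin$valve]]
    }

    ## pass 2: derivatives
    dy <- numeric(nstate)
    for (id in node_ids) {
      n <- nodes[[id]]
      st <- y[n$ix]; names(st) <- n$slots
      bc <- list()
      if (.inlet_demands_pressure(n$type)) {
        bc$u_in <- if (n$uin$kind == "bc") n$uin$fun(t)
                   else press_out[[n$uin$parent]]
      } else if (n$type == "VV_MERGE") {
        bc$vd_in <- if (n$vin$kind == "states") y[n$vin$ix] else vin_val[[id]]
      } else bc$v_in <- vin_val[[id]]
      if (n$type %in% c("VP", "PP")) {
        bc$u_out <- if (is.null(n$uout)) 0 else switch(n$uout$kind,
          child = press_in[[n$uout$child]],
          bc = n$uout$fun(t),
          chamber = u_ch[[n$uout$chamber]])
      } else if (n$type == "PP_BC_TERMINAL") {
        bc$u_out <- if (closed) y[[svn_u_ix]] else n$terminal$mu_out
      } else if (n$type == "PV_SPLIT") {
        bc$v_daughters <- if (n$vout$kind == "states") y[n$vout$ix]
                          else vout_val[[id]]
      } else bc$v_out <- vout_val[[id]]

      has_udt <- "udt" %in% n$slots
      core <- st[setdiff(n$slots, "udt")]
      d <- deriv_segment(n$type, core, bc, n$params,
                         viscoelastic = n$viscoelastic,
                         terminal = n$terminal)
      dy[n$ix[paste0(id, ".", setdiff(n$slots, "udt"))]] <- d$deriv
      if (has_udt) {
        term <- n$terminal
        dy[n$ix[[paste0(id, ".udt")]]] <-
          (vd_val[[id]] - st[["udt"]] / term$RTD) / term$CT
      }
    }

    if (closed) {
      dq <- c(lv = vq[["mitral"]] - vq[["aortic"]],
              rv = vq[["tricuspid"]] - vq[["pulmonary"]],
              la = y[[nodes$pvn$ix[["pvn.v"]]]] - vq[["mitral"]],
              ra = y[[nodes$svn$ix[["svn.v"]]]] - vq[["tricuspid"]])
      dy[q_ix[paste0(names(dq), ".q")]] <- dq
    }
    list(dy, glob)
  }

  ## ---- default initial state ----------------------------------------
  y0 <- numeric(nstate)
  if (closed) {
    art <- mmHg_to_pa(80); ven <- mmHg_to_pa(5)
    for (id in node_ids) {
      n <- nodes[[id]]
      base <- if (id %in% c("par", "pvn", "svn")) ven else art
      for (s in intersect(n$slots, c("u", "ud", "uv", "udv", "udt")))
        y0[[n$ix[[paste0(id, ".", s)]]]] <- base
    }
    for (ch in chambers)
      y0[[q_ix[[paste0(ch, ".q")]]]] <-
        heart$chambers[[ch]]$q0 + heart$fill[[ch]]
  }
  for (id in names(spec$segments)) {
    ini <- spec$segments[[id]]$initial
    if (!is.null(ini))
      for (s in names(ini)) {
        nm <- paste0(id, ".", s)
        if (!nm %in% state_names)
          stop("initial override for unknown state ", nm, call. = FALSE)
        y0[[index[[nm]]]] <- ini[[s]]
      }
  }
  names(y0) <- state_names

  period <- if (closed) timing$T else spec$inflow$period
  list(n = nstate, state_names = state_names, index = index, units = units,
       rhs = rhs, global_names = global_names, y0 = y0,
       vol_coef = vol_coef, cap_coef = cap_coef, inert_coef = inert_coef,
       period = period, spec = spec, nodes = nodes)
}
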