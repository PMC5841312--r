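## Network description: declarative JSON config -> validated NetworkSpec.
##
## A network is a directed vessel graph (edges in the direction of blood
## flow), optional RCR terminals at the leaves, boundary attachments at the
## root, and -- in closed-loop mode -- the heart/pulmonary/venous block.

.inlet_demands_pressure <- function(tag)
  tag %in% c("PV", "PP", "PV_SPLIT", "PP_BC_TERMINAL")

.outlet_supplies_pressure <- function(tag)
  tag %in% c("PV", "PV_SPLIT", "VV", "VV_MERGE")

.as_chr <- function(x) if (is.null(x) || length(x) == 0L) character(0) else
  as.character(unlist(x))

#' Load and resolve a network description
#'
#' Reads the declarative network config (JSON file path, JSON string, or an
#' equivalent R list), normalizes all quantities to SI, derives lumped
#' parameters from geometry where no explicit parameters are given, injects
#' defaults, and resolves the topology. Validation ([validate_topology]) is
#' run and any violation raises an error naming the offending segments.
#'
#' @param x config: path to a JSON file, a JSON string, or a list.
#' @param validate logical; raise on topology violations (default TRUE).
#' @return object of class `bg_network`.
#' @export
load_network <- function(x, validate = TRUE) {
  dir <- NULL
  cfg <- if (is.character(x) && length(x) == 1L) {
    if (file.exists(x)) dir <- dirname(x)
    jsonlite::fromJSON(x, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  } else if (is.list(x)) x else
    stop("config must be a path, JSON string, or list", call. = FALSE)

  loop <- match.arg(cfg$loop %||% "open", c("open", "closed"))
  blood <- do.call(blood_properties, cfg$blood %||% list())
  fit <- do.call(thickness_fit, cfg$thickness_fit %||% list())

  if (is.null(cfg$segments) || length(cfg$segments) == 0L)
    stop("config has no segments", call. = FALSE)
  ids <- vapply(cfg$segments, function(s) as.character(s$id %||%
    stop("segment without id", call. = FALSE)), "")
  if (anyDuplicated(ids))
    stop("duplicate segment id: ", ids[duplicated(ids)][1], call. = FALSE)

  segs <- lapply(cfg$segments, function(s) .resolve_segment(s, blood, fit))
  names(segs) <- ids
  segs <- segs[order(ids)]   # deterministic ordering by segment id

  ## children from parent declarations
  for (id in names(segs)) segs[[id]]$children <- character(0)
  for (id in names(segs)) {
    for (p in segs[[id]]$parent) {
      if (!p %in% names(segs))
        stop("segment '", id, "' references unknown parent '", p, "'",
             call. = FALSE)
      segs[[p]]$children <- sort(c(segs[[p]]$children, id))
    }
  }
  roots <- names(segs)[vapply(segs, function(s) length(s$parent) == 0L, TRUE)]

  inflow <- if (!is.null(cfg$inflow)) .resolve_inflow(cfg$inflow, dir) else NULL
  heart <- if (loop == "closed") .resolve_heart(cfg$heart %||% list()) else NULL
  if (loop == "open" && is.null(inflow))
    stop("open-loop config requires an 'inflow' block", call. = FALSE)

  spec <- structure(list(version = cfg$version %||% 1L, loop = loop,
                         blood = blood, thickness_fit = fit,
                         segments = segs, roots = roots,
                         inflow = inflow, heart = heart),
                    class = "bg_network")
  if (validate) {
    v <- validate_topology(spec)
    if (nrow(v) > 0L)
      stop("invalid network topology:\n", paste0("  [", v$rule, "] ",
           v$segment, ": ", v$message, collapse = "\n"), call. = FALSE)
  }
  spec
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.resolve_segment <- function(s, blood, fit) {
  id <- as.character(s$id)
  tag <- match.arg(s$type, segment_types())
  visc <- isTRUE(s$viscoelastic)
  geom <- NULL
  if (!is.null(s$geometry)) {
    g <- s$geometry
    geom <- vessel_geometry(length = g$length, radius = g$radius,
                            thickness = g$thickness,
                            youngs_modulus = g$youngs_modulus,
                            stress_relax = g$stress_relax %||% 0)
    if (is.null(geom$thickness))
      geom$thickness <- wall_thickness(geom$radius, fit)
  }
  params <- if (!is.null(s$params)) {
    do.call(lumped_params, s$params)
  } else if (!is.null(geom)) {
    lumped_from_geometry(geom, blood, fit)
  } else stop("segment '", id, "' has neither geometry nor params",
              call. = FALSE)
  if (visc && params$Rv <= 0)
    stop("segment '", id, "' is viscoelastic but has Rv = 0 ",
         "(set stress_relax or params$Rv)", call. = FALSE)

  terminal <- if (!is.null(s$terminal)) do.call(terminal_params, s$terminal)
  outlet <- s$outlet
  if (tag == "PP_BC_TERMINAL") {
    if (is.null(terminal))
      stop("terminal segment '", id, "' is missing its terminal params",
           call. = FALSE)
    outlet <- list(kind = "rcr")
  }
  if (!is.null(outlet)) {
    outlet$kind <- match.arg(outlet$kind, c("rcr", "flow", "pressure"))
    if (outlet$kind == "rcr" && is.null(terminal))
      stop("segment '", id, "' has an rcr outlet but no terminal params",
           call. = FALSE)
    if (outlet$kind == "rcr" &&
        !tag %in% c("PP_BC_TERMINAL", "VV", "VV_MERGE"))
      stop("segment '", id, "': an rcr outlet requires a ",
           "pressure-supplying distal capacitor (PP_BC_TERMINAL, VV or ",
           "VV_MERGE)", call. = FALSE)
    if (outlet$kind %in% c("flow", "pressure"))
      outlet$value <- parse_quantity(outlet$value %||% 0,
                                     paste0(id, "$outlet$value"))
  }
  initial <- if (!is.null(s$initial))
    vapply(s$initial, parse_quantity, 0, what = paste0(id, "$initial"))
  list(id = id, type = tag, viscoelastic = visc, geometry = geom,
       params = params, terminal = terminal,
       parent = .as_chr(s$parent), outlet = outlet, initial = initial)
}

.resolve_inflow <- function(inf, dir = NULL) {
  kind <- match.arg(inf$kind, c("pulse", "table", "csv", "pressure"))
  if (kind == "pulse") {
    f <- inflow_pulse(amplitude = parse_quantity(inf$amplitude %||% 1e-4, "inflow$amplitude"),
                      systole = inf$systole %||% 0.3,
                      period = inf$period %||% 1)
    list(kind = "flow", fun = f, period = attr(f, "period"), config = inf)
  } else if (kind == "table") {
    f <- inflow_table(unlist(inf$time), unlist(inf$flow))
    list(kind = "flow", fun = f, period = attr(f, "period"), config = inf)
  } else if (kind == "csv") {
    p <- inf$path
    if (!file.exists(p) && !is.null(dir)) p <- file.path(dir, p)
    f <- inflow_from_csv(p)
    list(kind = "flow", fun = f, period = attr(f, "period"), config = inf)
  } else {
    val <- parse_quantity(inf$value %||% 0, "inflow$value")
    list(kind = "pressure", fun = function(t) rep(val, length(t)),
         period = inf$period %||% NA_real_, config = inf)
  }
}

.resolve_heart <- function(h) {
  def <- heart_defaults()
  ch <- def$chambers
  for (nm in names(ch)) {
    o <- h$chambers[[nm]]
    if (!is.null(o))
      ch[[nm]] <- chamber_params(EA = o$EA %||% ch[[nm]]$EA,
                                 EB = o$EB %||% ch[[nm]]$EB,
                                 q0 = o$q0 %||% ch[[nm]]$q0,
                                 kind = ch[[nm]]$kind)
  }
  tm <- def$timing
  if (!is.null(h$timing)) {
    a <- h$timing
    tac <- a$tac %||% tm$tac; Tac <- a$Tac %||% tm$Tac
    tm <- cardiac_timing(T = a$T %||% tm$T, Tvc = a$Tvc %||% tm$Tvc,
                         Tvr = a$Tvr %||% tm$Tvr, tac = tac, Tac = Tac,
                         tar = a$tar %||% (tac + Tac), Tar = a$Tar %||% tm$Tar)
  }
  vv <- def$valves
  for (nm in names(vv)) {
    o <- h$valves[[nm]]
    if (!is.null(o))
      vv[[nm]] <- valve_params(coeff = o$coeff %||% vv[[nm]]$coeff,
                               law = o$law %||% vv[[nm]]$law,
                               width = o$width %||% vv[[nm]]$width)
  }
  cp <- def$compartments
  for (nm in names(cp)) {
    o <- h$compartments[[nm]]
    if (!is.null(o))
      cp[[nm]] <- lumped_params(R = o$R %||% cp[[nm]]$R,
                                C = o$C %||% cp[[nm]]$C,
                                I = o$I %||% cp[[nm]]$I,
                                Rv = o$Rv %||% cp[[nm]]$Rv)
  }
  fill <- def$fill
  if (!is.null(h$fill))
    for (nm in intersect(names(h$fill), names(fill)))
      fill[[nm]] <- parse_quantity(h$fill[[nm]], paste0("heart$fill$", nm))
  list(chambers = ch, timing = tm, valves = vv, compartments = cp,
       fill = fill)
}

#' Validate network topology and type compatibility
#'
#' Checks connectivity, acyclicity (open loop), the segment-type
#' compatibility restrictions at junctions (only pressure-supplying parents
#' may feed pressure-demanding daughters and vice versa; a flow-supplying
#' outlet cannot split; merge feeders must be mu-mu type), terminal
#' placement, and boundary-condition causality at the root. Violations are
#' returned as data, not raised.
#'
#' @param spec a `bg_network`.
#' @return data.frame with columns `rule`, `segment`, `message`; zero rows
#'   iff the network is valid.
#' @export
validate_topology <- function(spec) {
  v <- list()
  bad <- function(rule, segment, message)
    v[[length(v) + 1L]] <<- data.frame(rule = rule, segment = segment,
                                       message = message)
  segs <- spec$segments

  if (length(spec$roots) == 0L)
    bad("root", "-", "no root segment (every segment has a parent)")
  if (spec$loop == "open" && length(spec$roots) > 1L)
    bad("root", paste(spec$roots, collapse = ","),
        "open-loop network must have exactly one root")

  ## connectivity: directed reach from the roots
  seen <- character(0); queue <- spec$roots
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]
    if (id %in% seen) next
    seen <- c(seen, id)
    queue <- c(queue, segs[[id]]$children)
  }
  for (id in setdiff(names(segs), seen))
    bad("connectivity", id, "segment not reachable from the root")

  ## acyclicity via repeated leaf-stripping (Kahn)
  indeg <- vapply(segs, function(s) length(s$parent), 0L)
  queue <- names(indeg)[indeg == 0L]; removed <- 0L
  while (length(queue)) {
    id <- queue[1]; queue <- queue[-1]; removed <- removed + 1L
    for (ch in segs[[id]]$children) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (removed < length(segs))
    bad("acyclic", paste(names(indeg)[indeg > 0L], collapse = ","),
        "vessel graph contains a directed cycle")

  for (id in names(segs)) {
    s <- segs[[id]]
    ## edge causality
    for (ch in s$children) {
      cs <- segs[[ch]]
      if (.outlet_supplies_pressure(s$type) && !.inlet_demands_pressure(cs$type))
        bad("junction-causality", ch, paste0(
          "parent '", id, "' supplies pressure but '", ch,
          "' (", cs$type, ") demands flow at its inlet"))
      if (!.outlet_supplies_pressure(s$type) && .inlet_demands_pressure(cs$type))
        bad("junction-causality", ch, paste0(
          "parent '", id, "' supplies flow but '", ch,
          "' (", cs$type, ") demands pressure at its inlet"))
    }
    ## splitting: only a 0-junction (pressure-supplying) parent may have
    ## several daughters, and it must be a split-capable type
    if (length(s$children) > 1L) {
      if (!.outlet_supplies_pressure(s$type))
        bad("split-parent", id, paste0(s$type,
            " outlet supplies flow; it cannot feed ", length(s$children),
            " daughters"))
      else if (!s$type %in% c("PV_SPLIT", "VV", "VV_MERGE"))
        bad("split-parent", id, paste0(
          "junction parents must be mu-upsilon-split or upsilon-upsilon ",
          "type, not ", s$type))
    }
    ## merging
    if (length(s$parent) > 1L) {
      if (s$type != "VV_MERGE")
        bad("merge-type", id,
            "only VV_MERGE segments may be fed by several parents")
      for (p in s$parent)
        if (segs[[p]]$type != "PP")
          bad("merge-daughter-type", p,
              "merge feeders must be basic mu-mu (PP) segments")
    }
    if (s$type == "VV_MERGE" && length(s$parent) == 1L &&
        segs[[s$parent]]$type != "PP")
      bad("merge-daughter-type", s$parent,
          "merge feeders must be basic mu-mu (PP) segments")
    ## terminals and leaves
    if (s$type == "PP_BC_TERMINAL" && length(s$children) > 0L)
      bad("terminal-leaf", id, "terminal segments must be leaves")
    if (length(s$children) == 0L && is.null(s$outlet))
      bad("leaf-boundary", id,
          "leaf has no terminal or explicit outlet boundary")
    if (spec$loop == "closed" && length(s$children) == 0L &&
        (is.null(s$outlet) || s$outlet$kind != "rcr"))
      bad("closed-leaf", id, "closed-loop leaves must be RCR terminals")
    ## viscoelastic segments may not sit directly downstream of a valve
    if (spec$loop == "closed" && id %in% spec$roots && s$viscoelastic)
      bad("valve-viscoelastic", id,
          "the valve-fed root segment cannot be viscoelastic")
  }

  ## root causality vs the boundary attachment
  for (rid in spec$roots) {
    s <- segs[[rid]]
    if (spec$loop == "closed") {
      if (.inlet_demands_pressure(s$type))
        bad("root-causality", rid,
            "closed-loop root is fed by the aortic valve (a flow); it must be a flow-inlet type (VP/VV/VV_MERGE)")
    } else if (!is.null(spec$inflow)) {
      if (spec$inflow$kind == "flow" && .inlet_demands_pressure(s$type))
        bad("root-causality", rid,
            "prescribed-flow inflow requires a flow-inlet root type (VP/VV/VV_MERGE)")
      if (spec$inflow$kind == "pressure" && !.inlet_demands_pressure(s$type))
        bad("root-causality", rid,
            "prescribed-pressure inflow requires a pressure-inlet root type (PV/PP/PV_SPLIT)")
    }
  }

  if (length(v) == 0L)
    data.frame(rule = character(0), segment = character(0),
               message = character(0))
  else do.call(rbind, v)
}

#' Serialize a network back to JSON
#'
#' Writes the resolved network (geometry plus derived lumped parameters) in
#' the same config dialect accepted by [load_network]; a load -> write ->
#' load round trip yields an identical network.
#'
#' @param spec a `bg_network`.
#' @param path output file; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
write_network <- function(spec, path = NULL) {
  segs <- lapply(spec$segments, function(s) {
    out <- list(id = s$id, type = s$type, viscoelastic = s$viscoelastic)
    if (length(s$parent)) out$parent <- as.list(s$parent)
    if (!is.null(s$geometry)) out$geometry <- s$geometry[
      !vapply(s$geometry, is.null, TRUE)]
    out$params <- unclass(s$params)
    if (!is.null(s$terminal)) out$terminal <- unclass(s$terminal)
    if (!is.null(s$outlet) && s$type != "PP_BC_TERMINAL") out$outlet <- s$outlet
    if (!is.null(s$initial)) out$initial <- as.list(s$initial)
    out
  })
  cfg <- list(version = spec$version, loop = spec$loop,
              blood = unclass(spec$blood),
              thickness_fit = unclass(spec$thickness_fit),
              segments = unname(segs))
  if (!is.null(spec$inflow)) cfg$inflow <- spec$inflow$config
  if (!is.null(spec$heart)) {
    h <- spec$heart
    cfg$heart <- list(
      chambers = lapply(h$chambers, function(x) unclass(x)[c("EA", "EB", "q0")]),
      timing = unclass(h$timing),
      valves = lapply(h$valves, unclass),
      compartments = lapply(h$compartments, function(x) unclass(x)),
      fill = as.list(h$fill))
  }
  js <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}

#' Generate a symmetric binary-tree network fixture
#'
#' Synthetic stand-in for an anatomically detailed arterial tree: a
#' flow-inlet root vessel, generations of bifurcating mu-upsilon-split
#' vessels with radius and length scaled by `ratio` per generation, and an
#' RCR terminal behind every leaf vessel. The terminal template describes
#' the total (parallel-equivalent) peripheral bed; each leaf receives the
#' template resistances multiplied, and the compliance divided, by the leaf
#' count, so every leaf carries equal flow and the total terminal
#' conductance equals the template's.
#'
#' @param depth generations of bifurcation (>= 0); depth d gives
#'   2^(d+1) - 1 vessels and 2^d terminals.
#' @param root a [vessel_geometry] for the root vessel.
#' @param ratio per-generation radius/length scale factor in (0, 1).
#' @param terminal a [terminal_params] template (total peripheral bed).
#' @param blood a [blood_properties].
#' @param inflow inflow block (list) as in the JSON config; default a
#'   half-sine pulse.
#' @param min_radius smallest admissible radius (m); deeper trees error.
#' @param viscoelastic logical; Voigt walls for all vessels.
#' @return a `bg_network` (open loop).
#' @export
generate_tree_fixture <- function(depth, root, ratio = 0.75,
                                  terminal = terminal_params(RTP = 5e7,
                                    RTD = 5.8e8, CT = 2.5e-9),
                                  blood = blood_properties(),
                                  inflow = list(kind = "pulse",
                                    amplitude = 1e-4, systole = 0.3,
                                    period = 1),
                                  min_radius = 1e-5,
                                  viscoelastic = FALSE) {
  stopifnot(depth >= 0, ratio > 0, ratio < 1)
  if (root$radius * ratio^(depth + 1) < min_radius)
    stop("fixture error: radii underflow min_radius at depth ", depth,
         call. = FALSE)
  n_leaf <- 2^depth
  geom_at <- function(g) list(length = root$length * ratio^g,
                              radius = root$radius * ratio^g,
                              thickness = if (!is.null(root$thickness))
                                root$thickness * ratio^g,
                              youngs_modulus = root$youngs_modulus,
                              stress_relax = root$stress_relax)
  segs <- list()
  add <- function(s) segs[[length(segs) + 1L]] <<- s
  ## vessels: ids v<gen>_<k>, root v0_1
  for (g in 0:depth) {
    for (k in seq_len(2^g)) {
      id <- sprintf("v%d_%d", g, k)
      parent <- if (g == 0) NULL else sprintf("v%d_%d", g - 1L, (k + 1L) %/% 2L)
      type <- if (g == 0) "VV" else if (g < depth) "PV_SPLIT" else "PV"
      if (g == 0 && depth == 0) type <- "VV"
      add(list(id = id, type = type, parent = parent,
               viscoelastic = viscoelastic, geometry = geom_at(g)))
    }
  }
  ## one RCR terminal behind each leaf vessel
  for (k in seq_len(n_leaf)) {
    add(list(id = sprintf("t%d", k), type = "PP_BC_TERMINAL",
             parent = sprintf("v%d_%d", depth, k),
             viscoelastic = viscoelastic,
             geometry = geom_at(depth + 1L),
             terminal = list(RTP = terminal$RTP * n_leaf,
                             RTD = terminal$RTD * n_leaf,
                             CT = terminal$CT / n_leaf,
                             mu_out = terminal$mu_out)))
  }
  load_network(list(version = 1L, loop = "open",
                    blood = unclass(blood), inflow = inflow,
                    segments = segs))
}
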