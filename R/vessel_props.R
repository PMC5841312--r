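#' Blood properties
#'
#' Dynamic viscosity and mass density of blood. Defaults are the standard
#' values for human blood: 0.004 Pa s and 1040 kg m^-3. In bond-graph unit
#' aliases these are J s m^-3 and J s^2 m^-5 respectively.
#'
#' @param viscosity dynamic viscosity (Pa s), > 0.
#' @param density mass density (kg m^-3), > 0.
#' @return object of class `bg_blood`.
#' @export
blood_properties <- function(viscosity = 0.004, density = 1040) {
  viscosity <- parse_quantity(viscosity, "blood$viscosity")
  density <- parse_quantity(density, "blood$density")
  if (!is.finite(viscosity) || viscosity < 0)
    stop("blood viscosity must be >= 0", call. = FALSE)
  if (!is.finite(density) || density <= 0)
    stop("blood density must be > 0", call. = FALSE)
  structure(list(viscosity = viscosity, density = density),
            class = "bg_blood")
}

#' Vessel segment geometry
#'
#' Physical description of one cylindrical vessel segment, from which the
#' lumped resistance, compliance, inertance and wall damping are derived.
#'
#' @param length vessel length l (m), > 0.
#' @param radius lumen radius r (m), > 0.
#' @param thickness wall thickness h (m), > 0; `NULL` to derive it from the
#'   network's thickness fit ([wall_thickness]).
#' @param youngs_modulus Young's modulus E of the wall (Pa), > 0.
#' @param stress_relax stress-relaxation time constant f (s), >= 0;
#'   0 means a purely elastic wall.
#' @return object of class `bg_geometry`.
#' @export
vessel_geometry <- function(length, radius, thickness = NULL,
                            youngs_modulus, stress_relax = 0) {
  length <- parse_quantity(length, "geometry$length")
  radius <- parse_quantity(radius, "geometry$radius")
  youngs_modulus <- parse_quantity(youngs_modulus, "geometry$youngs_modulus")
  stress_relax <- parse_quantity(stress_relax, "geometry$stress_relax")
  if (!is.null(thickness)) thickness <- parse_quantity(thickness, "geometry$thickness")
  if (!is.finite(length) || length <= 0 || !is.finite(radius) || radius <= 0)
    stop("invalid geometry: length and radius must be > 0", call. = FALSE)
  if (!is.null(thickness) && (!is.finite(thickness) || thickness <= 0))
    stop("invalid geometry: thickness must be > 0", call. = FALSE)
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("invalid geometry: Young's modulus must be > 0", call. = FALSE)
  if (!is.finite(stress_relax) || stress_relax < 0)
    stop("invalid geometry: stress-relaxation time must be >= 0", call. = FALSE)
  structure(list(length = length, radius = radius, thickness = thickness,
                 youngs_modulus = youngs_modulus, stress_relax = stress_relax),
            class = "bg_geometry")
}

#' Wall thickness fit
#'
#' Two-exponential fit h(r0) = r0 (a e^{b r0} + c e^{d r0}) relating lumen
#' radius to wall thickness, used when a segment does not state its
#' thickness explicitly. The default coefficients give h/r0 between about
#' 0.10 and 0.15 across radii of 0.5-15 mm, a typical arterial range.
#'
#' @param a,c dimensionless amplitudes.
#' @param b,d exponential rates (m^-1).
#' @return object of class `bg_thickness_fit`.
#' @export
thickness_fit <- function(a = 0.09, b = -2000, c = 0.11, d = -5) {
  for (v in list(a, b, c, d))
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("thickness fit coefficients must be finite numbers", call. = FALSE)
  structure(list(a = a, b = b, c = c, d = d), class = "bg_thickness_fit")
}

#' Wall thickness from lumen radius
#'
#' Evaluates h = r0 (a e^{b r0} + c e^{d r0}).
#'
#' @param r0 lumen radius (m), > 0. Vectorized.
#' @param fit a [thickness_fit].
#' @return wall thickness (m).
#' @export
wall_thickness <- function(r0, fit = thickness_fit()) {
  if (any(!is.finite(r0)) || any(r0 <= 0))
    stop("invalid geometry: radius must be > 0", call. = FALSE)
  h <- r0 * (fit$a * exp(fit$b * r0) + fit$c * exp(fit$d * r0))
  if (any(h <= 0))
    stop("invalid thickness fit: h(r0) <= 0 at r0 = ",
         format(r0[which(h <= 0)[1]]), call. = FALSE)
  h
}

#' Poiseuille resistance of a vessel segment
#'
#' R = 8 nu l / (pi r^4): viscous resistance of fully developed laminar
#' flow in a straight cylindrical vessel.
#'
#' @param geom a [vessel_geometry].
#' @param blood a [blood_properties].
#' @return resistance (Pa s m^-3).
#' @export
poiseuille_resistance <- function(geom, blood = blood_properties()) {
  8 * blood$viscosity * geom$length / (pi * geom$radius^4)
}

#' Wall compliance of a vessel segment
#'
#' C = 2 pi r^3 l / (h E): volume stored per unit pressure for a thin-walled
#' linear-elastic cylinder.
#'
#' @inheritParams poiseuille_resistance
#' @param fit thickness fit used when `geom$thickness` is `NULL`.
#' @return compliance (m^3 Pa^-1).
#' @export
wall_compliance <- function(geom, fit = thickness_fit()) {
  h <- if (is.null(geom$thickness)) wall_thickness(geom$radius, fit) else geom$thickness
  if (h <= 0 || geom$youngs_modulus <= 0)
    stop("invalid geometry: thickness and Young's modulus must be > 0", call. = FALSE)
  2 * pi * geom$radius^3 * geom$length / (h * geom$youngs_modulus)
}

#' Blood inertance of a vessel segment
#'
#' I = rho l / (pi r^2): pressure per unit flow acceleration of the blood
#' column in the segment.
#'
#' @inheritParams poiseuille_resistance
#' @return inertance (Pa s^2 m^-3).
#' @export
blood_inertance <- function(geom, blood = blood_properties()) {
  blood$density * geom$length / (pi * geom$radius^2)
}

#' Viscous wall damping (Voigt dashpot)
#'
#' Rv = f / C, relating the stress-relaxation time constant f of the wall
#' to the dashpot resistance of the Voigt viscoelastic model.
#'
#' @param compliance wall compliance C (m^3 Pa^-1), > 0.
#' @param f stress-relaxation time constant (s), >= 0.
#' @return damping resistance (Pa s m^-3); 0 for a purely elastic wall.
#' @export
viscous_wall_damping <- function(compliance, f) {
  if (compliance <= 0) stop("compliance must be > 0", call. = FALSE)
  if (f < 0) stop("stress-relaxation time must be >= 0", call. = FALSE)
  f / compliance
}

#' Lumped bond-graph parameters
#'
#' Bundle of R, C, I and Rv for one segment, either computed from geometry
#' ([lumped_from_geometry]) or given explicitly.
#'
#' @param R resistance (Pa s m^-3), > 0.
#' @param C compliance (m^3 Pa^-1), > 0.
#' @param I inertance (Pa s^2 m^-3), > 0.
#' @param Rv viscoelastic wall damping (Pa s m^-3), >= 0.
#' @return object of class `bg_lumped` with a `units` attribute.
#' @export
lumped_params <- function(R, C, I, Rv = 0) {
  R <- parse_quantity(R, "params$R"); C <- parse_quantity(C, "params$C")
  I <- parse_quantity(I, "params$I"); Rv <- parse_quantity(Rv, "params$Rv")
  if (!all(is.finite(c(R, C, I, Rv))) || R <= 0 || C <= 0 || I <= 0 || Rv < 0)
    stop("lumped parameters require R, C, I > 0 and Rv >= 0", call. = FALSE)
  structure(list(R = R, C = C, I = I, Rv = Rv),
            units = c(R = "Pa.s/m3", C = "m3/Pa", I = "Pa.s2/m3", Rv = "Pa.s/m3"),
            class = "bg_lumped")
}

#' @rdname lumped_params
#' @inheritParams wall_compliance
#' @inheritParams poiseuille_resistance
#' @export
lumped_from_geometry <- function(geom, blood = blood_properties(),
                                 fit = thickness_fit()) {
  C <- wall_compliance(geom, fit)
  lumped_params(R = poiseuille_resistance(geom, blood),
                C = C,
                I = blood_inertance(geom, blood),
                Rv = viscous_wall_damping(C, geom$stress_relax))
}
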