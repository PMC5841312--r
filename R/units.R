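#' Unit helpers
#'
#' The package works in strict SI internally: pressure in Pa, flow in
#' m^3 s^-1, volume in m^3, time in s. The bond-graph unit aliases
#' (pressure as energy density J m^-3, flow as m^3 s^-1, resistance as
#' J s m^-6, compliance as m^3 J^-1 m^3) are numerically identical to the
#' SI forms and are recorded only as metadata. Conversion from clinical
#' units happens at the I/O boundary: config values may be strings with an
#' explicit unit suffix ("80 mmHg", "1.5 ml", "0.05 mmHg.s/ml"), converted
#' on load.
#'
#' @param x pressure in mmHg (for [mmHg_to_pa]) or Pa (for [pa_to_mmhg]).
#' @return numeric, converted value.
#' @examples
#' mmHg_to_pa(1)     # 133.322
#' pa_to_mmhg(133.322)
#' @export
mmHg_to_pa <- function(x) x * 133.322

#' @rdname mmHg_to_pa
#' @export
pa_to_mmhg <- function(x) x / 133.322

## Multiplicative factors to SI for the unit suffixes accepted in configs.
.unit_factors <- c(
  "Pa"        = 1,
  "kPa"       = 1e3,
  "mmHg"      = 133.322,
  "m3"        = 1,
  "ml"        = 1e-6,
  "l"         = 1e-3,
  "m"         = 1,
  "cm"        = 1e-2,
  "mm"        = 1e-3,
  "s"         = 1,
  "ms"        = 1e-3,
  "m3/s"      = 1,
  "ml/s"      = 1e-6,
  "Pa.s/m3"   = 1,
  "mmHg.s/ml" = 133.322 / 1e-6,
  "m3/Pa"     = 1,
  "ml/mmHg"   = 1e-6 / 133.322,
  "Pa.s2/m3"  = 1,
  "mmHg.s2/ml" = 133.322 / 1e-6,
  "Pa.s"      = 1
)

#' Parse a config quantity into SI
#'
#' Accepts a bare number (already SI) or a string "<number> <unit>" with a
#' unit drawn from the supported suffixes (Pa, kPa, mmHg, m3, ml, l, m, cm,
#' mm, s, ms, m3/s, ml/s, Pa.s/m3, mmHg.s/ml, m3/Pa, ml/mmHg, Pa.s2/m3,
#' mmHg.s2/ml, Pa.s).
#'
#' @param x numeric or string quantity.
#' @param what name used in error messages.
#' @return numeric scalar in SI units.
#' @export
parse_quantity <- function(x, what = "value") {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.character(x) || length(x) != 1L)
    stop("cannot parse quantity for '", what, "'", call. = FALSE)
  m <- regmatches(x, regexec("^\\s*([-+0-9.eE]+)\\s*([A-Za-z][A-Za-z0-9./]*)\\s*$", x))[[1]]
  if (length(m) != 3L)
    stop("unit parse failure at '", what, "': \"", x, "\"", call. = FALSE)
  val <- suppressWarnings(as.numeric(m[2]))
  if (is.na(val))
    stop("unit parse failure at '", what, "': \"", x, "\"", call. = FALSE)
  fac <- .unit_factors[m[3]]
  if (is.na(fac))
    stop("unknown unit '", m[3], "' at '", what, "'", call. = FALSE)
  val * unname(fac)
}
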