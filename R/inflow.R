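#' Parametric half-sine inflow pulse
#'
#' Periodic inflow waveform q(t) = amplitude * sin(pi t'/systole) for
#' t' = t mod period < systole, and 0 for the rest of the cycle: a minimal
#' systolic ejection pulse.
#'
#' @param amplitude peak flow (m^3 s^-1).
#' @param systole ejection duration (s), < period.
#' @param period cycle length (s).
#' @return function of time returning flow; attribute `period` carries the
#'   cycle length.
#' @export
inflow_pulse <- function(amplitude = 1e-4, systole = 0.3, period = 1) {
  stopifnot(amplitude >= 0, systole > 0, period > systole)
  f <- function(t) {
    tt <- t %% period
    ifelse(tt < systole, amplitude * sin(pi * tt / systole), 0)
  }
  attr(f, "period") <- period
  f
}

#' Sampled inflow waveform with periodic linear interpolation
#'
#' @param time sample times (s), increasing from 0; the last sample defines
#'   the period.
#' @param flow flows at the sample times (m^3 s^-1).
#' @return function of time; attribute `period` as in [inflow_pulse].
#' @export
inflow_table <- function(time, flow) {
  if (length(time) != length(flow) || length(time) < 2L)
    stop("inflow table needs matching time/flow vectors of length >= 2", call. = FALSE)
  if (is.unsorted(time, strictly = TRUE) || time[1] < 0)
    stop("inflow table times must be strictly increasing and >= 0", call. = FALSE)
  period <- time[length(time)]
  f <- function(t) {
    stats::approx(time, flow, xout = t %% period, rule = 2)$y
  }
  attr(f, "period") <- period
  f
}

#' Read an inflow waveform from CSV
#'
#' Expects columns `time_s` and `flow_m3s`; lines starting with `#` are
#' skipped.
#'
#' @param path CSV file path.
#' @return as [inflow_table].
#' @export
inflow_from_csv <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time_s", "flow_m3s") %in% names(d)))
    stop("inflow CSV must have columns time_s, flow_m3s: ", path, call. = FALSE)
  inflow_table(d$time_s, d$flow_m3s)
}
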