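#' @export
print.bg_network <- function(x, ...) {
  n_term <- sum(vapply(x$segments, function(s)
    s$type == "PP_BC_TERMINAL", TRUE))
  cat("<bg_network> ", x$loop, "-loop, ", length(x$segments),
      " segments (", n_term, " terminals)",
      if (!is.null(x$heart)) ", heart + pulmonary/venous compartments",
      "\n", sep = "")
  invisible(x)
}

#' @export
print.bg_simulation <- function(x, ...) {
  cat("<bg_simulation> ", length(x$time), " time points over ",
      signif(max(x$time), 4), " s, ", ncol(x$states), " states\n", sep = "")
  if (!is.null(x$period) && !is.na(x$period)) {
    pd <- tryCatch(detect_periodic_state(x), error = function(e) NULL)
    if (!is.null(pd))
      cat(if (pd$converged) paste0("periodic from cycle ", pd$cycle)
          else "not yet periodic", " (tol 1e-3)\n", sep = "")
  }
  invisible(x)
}

#' @export
print.bg_wavecmp <- function(x, ...) {
  cat("<waveform comparison> RMSE ", signif(x$rmse, 4),
      " (", signif(x$relative_rmse_pct, 3),
      "% of reference systolic ", signif(x$normalization, 4), ")\n",
      sep = "")
  invisible(x)
}
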