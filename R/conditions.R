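# Classed conditions so callers can distinguish failure modes
# (no_equilibrium, insufficient_data, all_fits_rejected, ...).

csd_error <- function(class, message, ...) {
  stop(structure(
    class = c(paste0("csd_", class), "csd_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

csd_warn <- function(class, message, ...) {
  warning(structure(
    class = c(paste0("csd_", class), "csd_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    csd_error("config", sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    csd_error("config", sprintf("`%s` must be > 0", name))
  invisible(x)
}
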