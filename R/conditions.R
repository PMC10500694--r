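# Classed conditions so callers (and the CLI front end) can map error kinds
# to exit codes without string matching.

presat_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "presatr_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_invalid <- function(msg) presat_stop(msg, "presatr_invalid_input")
stop_config  <- function(msg) presat_stop(msg, "presatr_config_error")
stop_parse   <- function(msg) presat_stop(msg, "presatr_parse_error")
stop_numeric <- function(msg) presat_stop(msg, "presatr_numeric_error")

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  if (positive && x <= 0) stop_invalid(sprintf("'%s' must be > 0", name))
  if (nonneg && x < 0) stop_invalid(sprintf("'%s' must be >= 0", name))
  invisible(x)
}
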