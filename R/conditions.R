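# Classed conditions used throughout so callers can distinguish bad input
# from a fit that failed to converge.

rf_stop <- function(msg, class, call = sys.call(-1), data = NULL) {
  cond <- structure(
    class = c(paste0("rhodofit_", class), "rhodofit_error", "error", "condition"),
    list(message = msg, call = call, data = data)
  )
  stop(cond)
}

rf_warn <- function(msg, class) {
  cond <- structure(
    class = c(paste0("rhodofit_", class), "rhodofit_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

# scalar numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
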