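# Classed conditions used across the funnel.  Every error raised by the
# package carries "cholscreen_error" plus a specific subclass so callers can
# distinguish malformed input (format_error), contract violations
# (validation_error) and degenerate numerics without parsing messages.

abort <- function(message, class, ...) {
  cond <- structure(
    class = c(class, "cholscreen_error", "error", "condition"),
    list(message = message, call = sys.call(-1L), ...)
  )
  stop(cond)
}

#' @keywords internal
format_error <- function(message, ...) abort(message, "format_error", ...)

#' @keywords internal
validation_error <- function(message, ...) abort(message, "validation_error", ...)
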