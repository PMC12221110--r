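# Structured conditions. Every error raised by the package carries the
# superclass "tado2i_error" plus one of the specific classes below, which the
# CLI maps to exit codes (parameter/range/degenerate -> 3, parse -> 4,
# usage -> 2).

tado2i_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tado2i_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

parameter_error <- function(message, ...) {
  tado2i_error("tado2i_parameter_error", message, ..., call = sys.call(-1))
}

range_error <- function(message, ...) {
  tado2i_error("tado2i_range_error", message, ..., call = sys.call(-1))
}

degenerate_error <- function(message, ...) {
  tado2i_error("tado2i_degenerate_error", message, ..., call = sys.call(-1))
}

parse_error <- function(message, ...) {
  tado2i_error("tado2i_parse_error", message, ..., call = sys.call(-1))
}

usage_error <- function(message, ...) {
  tado2i_error("tado2i_usage_error", message, ..., call = sys.call(-1))
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    parameter_error(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}
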