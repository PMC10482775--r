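# Internal helpers: structured conditions and numeric formatting.

#' @keywords internal
aq_error <- function(class, message, ..., call = sys.call(-1)) {
  stop(structure(
    class = c(class, "aq_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

aq_schema_error      <- function(msg, ...) aq_error("aq_schema_error", msg, ...)
aq_referential_error <- function(msg, ...) aq_error("aq_referential_error", msg, ...)
aq_uniqueness_error  <- function(msg, ...) aq_error("aq_uniqueness_error", msg, ...)
aq_io_error          <- function(msg, ...) aq_error("aq_io_error", msg, ...)
aq_invalid_injection   <- function(msg, ...) aq_error("aq_invalid_injection", msg, ...)
aq_invalid_calibration <- function(msg, ...) aq_error("aq_invalid_calibration", msg, ...)

#' Round half away from zero
#'
#' Reporting convention for integer percentages. `base::round()` rounds
#' half to even (2.5 -> 2), which does not reproduce conventionally
#' rounded printed tables (2.5 -> 3).
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# stopifnot-like scalar checks with domain errors
check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0)) {
    aq_schema_error(sprintf("'%s' must be finite and > 0", name))
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    aq_schema_error(sprintf("'%s' must be finite and >= 0", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# full-precision numeric formatting for delimited output (round-trip exact)
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "" else sprintf("%.17g", v)
  }, character(1))
  out
}
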