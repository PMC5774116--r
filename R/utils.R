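#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used for all reported percentages so that
#' e.g. 57.15 renders as 57.2 rather than banker's-rounded 57.1.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @keywords internal
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

# stopifnot-style check with a formatted message
.check <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == trunc(x)
}

.is_prob <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x <= 1
}
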