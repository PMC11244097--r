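# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even. Formulation reports conventionally
#' round half up (9.045 -> 9.05), so report-facing numbers go through this.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stopifnot-style check with a formatted message
abort_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
  invisible(NULL)
}

is_number <- function(x) is.numeric(x) && all(is.finite(x))
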