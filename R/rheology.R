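#' Construct a rheological temperature sweep
#'
#' Storage modulus G' recorded along a monotone temperature ramp (either
#' direction). Thermoresponsive poloxamer systems show a step in G' at the
#' sol-gel transition: gel (high G') above the transition temperature, sol
#' below.
#'
#' @param temperatures Degrees C, strictly monotone, at least 5 points.
#' @param g_prime Storage modulus G', Pa, same length.
#' @return A list of class `rheo_sweep`.
#' @export
rheo_sweep <- function(temperatures, g_prime) {
  abort_if(length(temperatures) != length(g_prime), "length mismatch")
  abort_if(length(temperatures) < 5, "need at least 5 points")
  d <- diff(temperatures)
  abort_if(!(all(d > 0) || all(d < 0)), "temperatures must be strictly monotone")
  abort_if(any(!is.finite(g_prime)), "non-finite storage modulus")
  structure(list(temperatures = as.numeric(temperatures),
                 g_prime = as.numeric(g_prime)),
            class = "rheo_sweep")
}

#' @export
print.rheo_sweep <- function(x, ...) {
  cat(sprintf("<rheo_sweep> %d points, %g to %g degC, G' %g to %g Pa\n",
              length(x$temperatures), x$temperatures[1],
              x$temperatures[length(x$temperatures)],
              min(x$g_prime), max(x$g_prime)))
  invisible(x)
}

#' Detect the sol-gel transition temperature from a G' sweep
#'
#' The transition interval is taken as the adjacent-pair temperature window
#' with the largest variation in storage modulus (maximal |dG'/dT| by finite
#' differences); the reported transition temperature is the midpoint of that
#' window. A curve whose local variation never stands out (flat, or exactly
#' linear so every window ties) has no detectable transition and raises an
#' error. The result does not depend on the sweep direction.
#'
#' @param sweep A [rheo_sweep()].
#' @param tol Relative tolerance: the spread of |dG'/dT| across windows must
#'   exceed `tol` times its maximum, and the maximum must be positive.
#' @return List with `t_solgel` (degC), `interval` (the two bracketing
#'   temperatures, ascending) and `max_slope` (Pa/degC).
#' @export
detect_sol_gel <- function(sweep, tol = 1e-8) {
  abort_if(!inherits(sweep, "rheo_sweep"), "need a rheo_sweep")
  Tt <- sweep$temperatures
  slope <- abs(diff(sweep$g_prime) / diff(Tt))
  mx <- max(slope)
  abort_if(mx <= 0 || diff(range(slope)) <= tol * mx,
           "no transition: storage-modulus variation is uniform across the sweep")
  i <- which.max(slope)
  interval <- sort(c(Tt[i], Tt[i + 1]))
  list(t_solgel = mean(interval), interval = interval, max_slope = mx)
}
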