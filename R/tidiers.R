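# broom-style tidy()/glance() methods for the package's fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted response-surface model
#'
#' One row per model term with the coded-factor estimate, its standard error
#' and partial-F (equivalently t) test, plus the exactly re-expressed
#' actual-factor estimate.
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`, `estimate_actual`.
#' @export
tidy.rsm_fit <- function(x, ...) {
  d <- rsm_diagnostics(x)
  out <- d$term_tests
  # actual coefficients live on the actual (X1, X2, ...) basis; a pruned
  # coded model can re-expand to extra lower-order monomials, so align the
  # shared monomials by exponent vector
  key <- function(tt) vapply(tt, paste, character(1), collapse = ",")
  idx <- match(key(x$terms), key(x$terms_actual))
  out$estimate_actual <- unname(x$coef_actual[idx])
  out
}

#' Glance at a fitted response-surface model
#'
#' @param x An `rsm_fit`.
#' @param ... Unused.
#' @return One-row tibble with `r2`, `adj_r2`, `pred_r2`, `press`,
#'   `adeq_precision`, `model_p`, `sigma`, `n_obs`, `n_terms`.
#' @export
glance.rsm_fit <- function(x, ...) {
  d <- rsm_diagnostics(x)
  tibble::tibble(r2 = d$r2, adj_r2 = d$adj_r2, pred_r2 = d$pred_r2,
                 press = d$press, adeq_precision = d$adeq_precision,
                 model_p = d$model_p, sigma = d$sigma, n_obs = d$n_obs,
                 n_terms = d$n_terms)
}

#' Tidy a kinetics fit
#'
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`k`, and `Qinf` for the
#'   first-order model).
#' @export
tidy.kinetics_fit <- function(x, ...) {
  out <- tibble::tibble(term = "k", estimate = x$k)
  if (is.finite(x$Qinf)) {
    out <- dplyr::bind_rows(out, tibble::tibble(term = "Qinf",
                                                estimate = x$Qinf))
  }
  out
}

#' Glance at a kinetics fit
#'
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return One-row tibble with `model`, `r2`, `n_obs`.
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(model = x$model, r2 = x$r2, n_obs = length(x$times))
}

#' Tidy an optimization result
#'
#' @param x An `optimum_result`.
#' @param ... Unused.
#' @return The per-criterion prediction tibble (response, goal, bounds,
#'   predicted value, individual desirability).
#' @export
tidy.optimum_result <- function(x, ...) x$predictions

#' Glance at an optimization result
#'
#' @param x An `optimum_result`.
#' @param ... Unused.
#' @return One-row tibble with the optimal factor levels, the composite
#'   desirability `D`, and the degeneracy flag.
#' @export
glance.optimum_result <- function(x, ...) {
  dplyr::bind_cols(tibble::as_tibble(as.list(x$factors)),
                   tibble::tibble(D = x$D, degenerate = x$degenerate))
}
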