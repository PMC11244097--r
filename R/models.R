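#' Construct a response-surface model from known coefficients
#'
#' Wraps a polynomial over the factors of a design space, e.g. an equation
#' transcribed from a report, so it can be evaluated, optimized against, or
#' used as generating truth by the synthetic-data module. Coefficients may be
#' supplied in the actual-factor parameterization, the coded one, or both
#' (when both are given they are kept verbatim; no consistency is enforced,
#' since published equations are independently rounded).
#'
#' @param response Response name.
#' @param space A [factor_space()].
#' @param family Model family, see [rsm_terms()].
#' @param coef_actual,coef_coded Numeric coefficient vectors in the term order
#'   of [rsm_terms()] (intercept, main effects, interactions, squares). At
#'   least one must be given; the missing one is derived by exact
#'   reparameterization.
#' @param units Response units (for printing).
#' @return An object of class `rsm_model`.
#' @export
rsm_model <- function(response, space, family, coef_actual = NULL,
                      coef_coded = NULL, units = "") {
  terms <- rsm_terms(family, space)
  abort_if(is.null(coef_actual) && is.null(coef_coded),
           "supply coef_actual and/or coef_coded")
  chk <- function(v, what) {
    abort_if(length(v) != length(terms),
             "%s must have %d coefficients for family '%s'", what,
             length(terms), family)
    stats::setNames(as.numeric(v), names(terms))
  }
  if (!is.null(coef_actual)) coef_actual <- chk(coef_actual, "coef_actual")
  if (!is.null(coef_coded)) coef_coded <- chk(coef_coded, "coef_coded")
  derived <- character(0)
  if (is.null(coef_actual)) {
    ca <- recode_coefficients(coef_coded, terms, space, "coded_to_actual")
    coef_actual <- align_coefs(ca, terms, space, coded = FALSE)
    derived <- "actual"
  }
  if (is.null(coef_coded)) {
    cc <- recode_coefficients(coef_actual, actual_terms(terms), space,
                              "actual_to_coded")
    coef_coded <- align_coefs(cc, terms, space, coded = TRUE)
    derived <- "coded"
  }
  structure(
    list(response = response, space = space, family = family, terms = terms,
         coef_actual = coef_actual, coef_coded = coef_coded, units = units,
         derived = derived),
    class = "rsm_model"
  )
}

# terms relabelled on the actual basis (X1, X2, ...)
actual_terms <- function(terms) {
  k <- length(terms[[1]])
  stats::setNames(terms, vapply(terms, term_label, character(1),
                                labels = paste0("X", seq_len(k))))
}

# map a reparam_poly result back onto the canonical term order, zero-filling
align_coefs <- function(rp, terms, space, coded) {
  labels <- if (coded) space$coded else paste0("X", seq_len(nrow(space)))
  want <- vapply(terms, term_label, character(1), labels = labels)
  out <- stats::setNames(numeric(length(want)), names(terms))
  for (i in seq_along(want)) {
    j <- match(want[i], names(rp))
    if (!is.na(j)) out[i] <- rp[j]
  }
  # any mass on terms outside the family set would be an internal error
  extra <- setdiff(names(rp)[abs(rp) > 1e-12], want)
  abort_if(length(extra) > 0, "reparameterization produced unexpected terms: %s",
           paste(extra, collapse = ", "))
  out
}

#' Predict from a response-surface model
#'
#' @param object An `rsm_model`.
#' @param newdata Data frame with one column per factor in actual units
#'   (columns named as in the factor space), or a numeric matrix in factor
#'   order.
#' @param parameterization Evaluate the `"actual"`-factor equation (default,
#'   the form used for prediction) or the `"coded"` one after coding the
#'   inputs.
#' @param ... Unused.
#' @return Numeric vector of predicted response values.
#' @export
predict.rsm_model <- function(object, newdata,
                              parameterization = c("actual", "coded"), ...) {
  parameterization <- match.arg(parameterization)
  X <- factor_levels_matrix(newdata, object$space)
  if (parameterization == "actual") {
    eval_terms(object$coef_actual, object$terms, X)
  } else {
    U <- sweep(sweep(X, 2, object$space$center, `-`), 2, object$space$half_range, `/`)
    eval_terms(object$coef_coded, object$terms, U)
  }
}

factor_levels_matrix <- function(newdata, space) {
  if (is.matrix(newdata)) {
    abort_if(ncol(newdata) != nrow(space), "expected %d factor columns", nrow(space))
    return(newdata)
  }
  miss <- setdiff(space$factor, names(newdata))
  abort_if(length(miss) > 0, "newdata lacks factor column(s): %s",
           paste(miss, collapse = ", "))
  as.matrix(as.data.frame(newdata)[, space$factor, drop = FALSE])
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf("<rsm_model> %s (%s)%s\n", x$response, x$family,
              if (nzchar(x$units)) paste0(" [", x$units, "]") else ""))
  eq <- function(coefs) {
    paste(sprintf("%+.4g %s", unname(coefs),
                  ifelse(names(coefs) == "Intercept", "", names(coefs))),
          collapse = " ")
  }
  cat("  coded : Y =", eq(x$coef_coded), "\n")
  ca <- x$coef_actual
  names(ca) <- vapply(x$terms, term_label, character(1),
                      labels = paste0("X", seq_len(nrow(x$space))))
  names(ca)[1] <- "Intercept"
  cat("  actual: Y =", eq(ca), "\n")
  invisible(x)
}

#' Published response models of the emulgel study
#'
#' The six significant response-surface equations reported for the ciclopirox
#' olamine emulgel (pH, oil-droplet median size D50, sol-gel transition
#' temperature, release flux, firmness, work of shear), each carrying the
#' reported coded-factor and actual-factor coefficient sets verbatim. These
#' serve as prediction equations and as the default generating truth of the
#' synthetic-data module.
#'
#' @return Named list of [rsm_model()] objects with elements `ph`, `d50`,
#'   `tsolgel`, `flux`, `firmness`, `work_shear`.
#' @examples
#' m <- emulgel_models()
#' predict(m$d50, tibble::tibble(mineral_oil = 38.27, polysorbate_80 = 6.56))
#' @export
emulgel_models <- function() {
  fs <- emulgel_factor_space()
  list(
    ph = rsm_model(
      "ph", fs, "quadratic", units = "pH",
      coef_coded = c(9.04, 0.03, 0.02, -0.01, -0.06, -0.06),
      coef_actual = c(8.7681, 0.0110, 0.0308, -0.00013, -0.00015, -0.0023)),
    d50 = rsm_model(
      "d50", fs, "linear", units = "um",
      coef_coded = c(0.38, -0.03, -0.09),
      coef_actual = c(0.5209, -0.0017, -0.0181)),
    tsolgel = rsm_model(
      "tsolgel", fs, "quadratic", units = "degC",
      coef_coded = c(9.11, 0.92, -2.83, -0.13, 2.08, 1.33),
      coef_actual = c(16.4028, -0.2604, -1.0625, -0.0013, 0.0052, 0.0533)),
    flux = rsm_model(
      "flux", fs, "linear", units = "mg/cm2",
      coef_coded = c(1.48, 0.04, -0.18),
      coef_actual = c(1.5979, 0.0020, -0.0352)),
    firmness = rsm_model(
      "firmness", fs, "quadratic", units = "N",
      coef_coded = c(2.48, 0.04, 0.35, -0.10, -0.01, -0.78),
      coef_actual = c(1.1347, 0.0079, 0.4109, -0.0010, -0.00002, -0.0311)),
    work_shear = rsm_model(
      "work_shear", fs, "quadratic", units = "N*s",
      coef_coded = c(3.78, -0.05, 0.56, -0.21, 0.05, -1.24),
      coef_actual = c(1.8356, 0.0012, 0.6723, -0.0021, 0.00012, -0.0497))
  )
}

#' Published oil-droplet percentile measurements of the emulgel study
#'
#' Per-run means and standard deviations of the D10/D50/D90 droplet-size
#' percentiles (um) for the nine design runs, five laser-diffraction
#' measurements per sample. One standard deviation (run E-5, D50) is printed
#' with a garbled decimal in the source table and is transcribed as 0.016.
#'
#' @return A tibble with columns `run_id`, `percentile` (`d10`/`d50`/`d90`),
#'   `mean`, `sd`.
#' @export
emulgel_particle_sizes <- function() {
  runs <- paste0("E-", 1:9)
  d10m <- c(0.309, 0.377, 0.338, 0.192, 0.151, 0.221, 0.252, 0.282, 0.252)
  d10s <- c(0.011, 0.043, 0.043, 0.016, 0.010, 0.010, 0.015, 0.013, 0.020)
  d50m <- c(0.461, 0.512, 0.422, 0.295, 0.240, 0.336, 0.374, 0.434, 0.381)
  d50s <- c(0.009, 0.019, 0.032, 0.015, 0.016, 0.015, 0.026, 0.028, 0.028)
  d90m <- c(0.900, 1.002, 0.737, 0.499, 0.413, 0.557, 0.659, 0.884, 0.664)
  d90s <- c(0.010, 0.050, 0.029, 0.015, 0.008, 0.011, 0.027, 0.014, 0.021)
  tibble::tibble(
    run_id = rep(runs, 3),
    percentile = rep(c("d10", "d50", "d90"), each = 9),
    mean = c(d10m, d50m, d90m),
    sd = c(d10s, d50s, d90s)
  )
}
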