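#' Construct an in-vitro release profile
#'
#' Holds the sampled acceptor-medium concentrations of a flow-through release
#' test together with the cell geometry: medium volume V, withdrawn sample
#' volume V_s (replaced with fresh medium after each sampling), diffusion
#' area, and the drug dose loaded in the donor phase. Defaults mirror a
#' typical semi-solid release test: 50 mL acceptor medium, 1 mL samples taken
#' hourly, 1.33 cm2 diffusion area, 10 mg dose (1.0 g of a 1 % formulation).
#'
#' @param times Sampling times in hours, strictly increasing, all > 0.
#' @param concentrations Sampled concentrations, mg/mL, one per time.
#' @param volume Acceptor medium volume V, mL.
#' @param sample_volume Withdrawn volume V_s, mL (0 = no withdrawal).
#' @param area Diffusion area, cm2.
#' @param dose Drug dose in the donor phase, mg.
#' @return A list of class `release_profile`.
#' @export
release_profile <- function(times, concentrations, volume = 50,
                            sample_volume = 1, area = 1.33, dose = 10) {
  abort_if(length(times) != length(concentrations),
           "times and concentrations must have equal length")
  abort_if(any(diff(times) <= 0) || times[1] <= 0,
           "times must be strictly increasing and start above 0")
  abort_if(any(concentrations < 0), "negative concentration at t = %g h",
           times[which(concentrations < 0)[1]])
  abort_if(volume <= sample_volume || sample_volume < 0,
           "need volume > sample_volume >= 0")
  abort_if(area <= 0, "diffusion area must be positive")
  abort_if(dose <= 0, "dose must be positive")
  structure(list(times = as.numeric(times),
                 concentrations = as.numeric(concentrations),
                 volume = volume, sample_volume = sample_volume,
                 area = area, dose = dose),
            class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat(sprintf("<release_profile> %d samples over %g h (V = %g mL, Vs = %g mL, area = %g cm2, dose = %g mg)\n",
              length(x$times), max(x$times), x$volume, x$sample_volume,
              x$area, x$dose))
  invisible(x)
}

#' Cumulative amount released, corrected for sampling withdrawal
#'
#' Each withdrawn sample removes drug from the acceptor medium, so raw
#' concentrations underestimate later release. The standard correction adds
#' back the withdrawn fraction: corrected C_n = C_n + (V_s / V) * sum of
#' C_i over earlier samples; the cumulative amount is the corrected
#' concentration times the medium volume. With V_s = 0 this reduces to
#' C_n * V exactly.
#'
#' @param profile A [release_profile()].
#' @return Tibble with `time_h`, `concentration`, `concentration_corrected`
#'   (mg/mL) and `cumulative_mg`. A non-monotone cumulative series triggers a
#'   warning, never a mutation of the data.
#' @export
cumulative_release <- function(profile) {
  abort_if(!inherits(profile, "release_profile"), "need a release_profile")
  C <- profile$concentrations
  prior <- c(0, cumsum(C)[-length(C)])
  corrected <- C + (profile$sample_volume / profile$volume) * prior
  cum <- corrected * profile$volume
  if (any(diff(cum) < 0)) {
    warning("corrected cumulative release is not monotone non-decreasing",
            call. = FALSE)
  }
  tibble::tibble(time_h = profile$times, concentration = C,
                 concentration_corrected = corrected, cumulative_mg = cum)
}

#' Release flux per diffusion area
#'
#' The default definition is the corrected cumulative amount released at the
#' final sampling time divided by the diffusion area (mg/cm2). The
#' alternative `"slope"` method fits a straight line through the origin to
#' cumulative amount vs time and reports its slope per area (mg/cm2/h).
#'
#' @param profile A [release_profile()].
#' @param method `"cumulative"` (default) or `"slope"`.
#' @return Scalar flux.
#' @export
release_flux <- function(profile, method = c("cumulative", "slope")) {
  method <- match.arg(method)
  cr <- suppressWarnings(cumulative_release(profile))
  if (method == "cumulative") {
    cr$cumulative_mg[nrow(cr)] / profile$area
  } else {
    sum(cr$time_h * cr$cumulative_mg) / sum(cr$time_h^2) / profile$area
  }
}

#' Fit release-kinetics models to a cumulative release series
#'
#' First-order kinetics fits the saturating exponential
#' Q(t) = Qinf * (1 - exp(-k t)) by nonlinear least squares with Qinf bounded
#' by the dose (this form stays well conditioned where log-linearization of
#' late, near-plateau points does not). Zero-order (Q = k t) and Higuchi
#' (Q = k sqrt(t)) are linear least squares through the origin. R-squared is
#' computed on the model's own scale against the observed cumulative amounts.
#'
#' @param times Hours, strictly increasing.
#' @param cumulative Cumulative amounts released, mg.
#' @param dose Dose, mg; upper bound for Qinf.
#' @param model `"first_order"`, `"zero_order"` or `"higuchi"`.
#' @return A list of class `kinetics_fit` with `model`, `k`, `Qinf` (NA for
#'   the linear models), `r2`, `fitted`.
#' @export
fit_kinetics <- function(times, cumulative, dose,
                         model = c("first_order", "zero_order", "higuchi")) {
  model <- match.arg(model)
  abort_if(length(times) < 3, "need at least 3 time points")
  abort_if(length(times) != length(cumulative), "length mismatch")
  abort_if(any(cumulative > dose + 1e-9), "cumulative release exceeds the dose")
  sst <- sum((cumulative - mean(cumulative))^2)
  r2_of <- function(fitted) 1 - sum((cumulative - fitted)^2) / sst

  if (model == "zero_order") {
    k <- sum(times * cumulative) / sum(times^2)
    fitted <- k * times
    return(structure(list(model = model, k = k, Qinf = NA_real_,
                          r2 = r2_of(fitted), fitted = fitted, times = times),
                     class = "kinetics_fit"))
  }
  if (model == "higuchi") {
    s <- sqrt(times)
    k <- sum(s * cumulative) / sum(s^2)
    fitted <- k * s
    return(structure(list(model = model, k = k, Qinf = NA_real_,
                          r2 = r2_of(fitted), fitted = fitted, times = times),
                     class = "kinetics_fit"))
  }

  # first order: several bounded starts (Qinf at the dose and near the
  # observed plateau; k from the two-point log slope), keep the best SSE
  q1 <- max(min(cumulative[1] / dose, 0.999), 1e-6)
  k0 <- -log(1 - q1) / times[1]
  dat <- data.frame(t = times, q = cumulative)
  qmax <- max(cumulative)
  inits <- list(c(Qinf = min(dose, qmax * 1.1), k = k0),
                c(Qinf = min(dose, qmax * 1.5), k = k0),
                c(Qinf = dose, k = k0),
                c(Qinf = min(dose, qmax * 1.2), k = 0.5))
  fit <- NULL; errs <- character(0)
  for (st in inits) {
    cand <- tryCatch(
      minpack.lm::nlsLM(q ~ Qinf * (1 - exp(-k * t)), data = dat,
                        start = as.list(st),
                        lower = c(Qinf = 1e-9, k = 1e-9),
                        upper = c(Qinf = dose, k = Inf),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(cand) &&
        (is.null(fit) || stats::deviance(cand) < stats::deviance(fit))) {
      fit <- cand
    }
  }
  abort_if(is.null(fit), "first-order fit failed to converge: %s",
           paste(unique(errs), collapse = "; "))
  cf <- stats::coef(fit)
  fitted <- cf[["Qinf"]] * (1 - exp(-cf[["k"]] * times))
  structure(list(model = model, k = cf[["k"]], Qinf = cf[["Qinf"]],
                 r2 = r2_of(fitted), fitted = fitted, times = times),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> %s: k = %.4g%s, R2 = %.4f\n", x$model, x$k,
              if (is.finite(x$Qinf)) sprintf(", Qinf = %.4g mg", x$Qinf) else "",
              x$r2))
  invisible(x)
}
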