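# Synthetic-data generators emulating the emulgel study's measurements:
# replicate response tables around the published response-surface equations,
# in-vitro release profiles with sampling/replacement dilution, storage-
# modulus temperature sweeps, and lognormal oil-droplet size percentiles.
# All generators are pure functions of (arguments, seed).

#' Default generator configuration
#'
#' The generating truth defaults to the published actual-factor equations
#' ([emulgel_models()]); replicate noise is additive Gaussian with per-
#' response standard deviations at the magnitude of the published replicate
#' SDs (droplet size: about 0.02 um) or, where no SDs are printed, at 1-3 %
#' relative error typical of the instrument class (pH meter, rotational
#' rheometer ramp, texture analyzer, release assay). Particle size uses 5
#' replicates per run, everything else 3.
#'
#' @param true_models Named list of `rsm_model`/`rsm_fit` generating truths.
#' @param noise_sd Named numeric vector of replicate SDs (response units).
#' @param replicates Named integer vector of replicates per response.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(true_models = emulgel_models(),
                             noise_sd = c(ph = 0.02, d50 = 0.02, tsolgel = 0.3,
                                          flux = 0.04, firmness = 0.08,
                                          work_shear = 0.12),
                             replicates = c(ph = 3, d50 = 5, tsolgel = 3,
                                            flux = 3, firmness = 3,
                                            work_shear = 3)) {
  abort_if(any(noise_sd < 0), "noise_sd must be >= 0")
  abort_if(any(replicates < 1), "replicates must be >= 1")
  miss <- setdiff(names(true_models), names(noise_sd))
  abort_if(length(miss) > 0, "noise_sd missing for response(s): %s",
           paste(miss, collapse = ", "))
  miss <- setdiff(names(true_models), names(replicates))
  abort_if(length(miss) > 0, "replicates missing for response(s): %s",
           paste(miss, collapse = ", "))
  structure(list(true_models = true_models, noise_sd = noise_sd,
                 replicates = replicates),
            class = "generator_config")
}

#' Simulate a replicate response table over a design
#'
#' For every run, response and replicate: value = actual-factor model
#' prediction + Normal(0, noise_sd). Non-physical predictions (negative
#' droplet size, pH outside 0-14) abort with the offending run named.
#'
#' @param design A `design_table`.
#' @param config A [generator_config()].
#' @param seed Integer seed; fixed seed implies identical output.
#' @return Tibble with `run_id`, `replicate_id`, `response_name`, `value`.
#' @export
simulate_responses <- function(design, config = generator_config(), seed = 1) {
  abort_if(!inherits(config, "generator_config"), "need a generator_config")
  preds <- lapply(config$true_models, predict, newdata = design)
  for (resp in names(preds)) {
    pr <- preds[[resp]]
    bad <- which(pr <= 0 & resp %in% c("d50", "firmness", "work_shear", "flux") |
                   (resp == "ph" & (pr < 0 | pr > 14)))
    abort_if(length(bad) > 0, "non-physical %s prediction in run %s", resp,
             design$run_id[bad[1]])
  }
  withr::with_seed(seed, {
    dplyr::bind_rows(lapply(names(preds), function(resp) {
      reps <- config$replicates[[resp]]
      sd <- config$noise_sd[[resp]]
      tidyr::expand_grid(run_id = design$run_id,
                         replicate_id = seq_len(reps)) |>
        dplyr::mutate(
          response_name = resp,
          value = rep(preds[[resp]], each = reps) +
            stats::rnorm(nrow(design) * reps, 0, sd)
        )
    }))
  })
}

#' Solve the first-order rate constant for a target release flux
#'
#' Finds k such that Qinf * (1 - exp(-k * t_end)) / area equals the target
#' flux.
#'
#' @param flux Target flux, mg/cm2.
#' @param Qinf Releasable amount, mg.
#' @param area Diffusion area, cm2.
#' @param t_end End of the test, h.
#' @return Rate constant k, 1/h.
#' @export
solve_release_rate <- function(flux, Qinf, area = 1.33, t_end = 6) {
  q <- flux * area / Qinf
  abort_if(q <= 0 || q >= 1, "target flux implies a release fraction outside (0, 1)")
  -log(1 - q) / t_end
}

#' Simulate an in-vitro release profile
#'
#' Forward-simulates the true released mass and converts it into sampled
#' acceptor-medium concentrations, removing `sample_volume` (with its drug
#' content) and replacing it with fresh medium after each sampling -- the
#' dilution the analysis has to correct for. The underlying release law is
#' Q(t) = Qinf * (1 - exp(-(k t)^shape)): `shape = 1` is ideal first-order
#' kinetics, while the default slight stretching (shape < 1) emulates real
#' semi-solid profiles whose first-order fits are good but not perfect.
#' Multiplicative lognormal measurement noise is applied to the sampled
#' concentrations. The true released-mass series is attached for oracle
#' checks.
#'
#' @param k Rate constant, 1/h.
#' @param Qinf Releasable amount, mg (must not exceed `dose`).
#' @param times Sampling schedule, h, strictly increasing.
#' @param volume,sample_volume,area,dose Cell geometry as in
#'   [release_profile()].
#' @param shape Stretching exponent of the release law (1 = ideal).
#' @param noise_cv Coefficient of variation of the measurement noise; 0
#'   disables it.
#' @param seed Integer seed.
#' @return A [release_profile()] with attribute `true_release` (tibble
#'   `time_h`, `released_mg`).
#' @export
simulate_release <- function(k, Qinf, times = 1:6, volume = 50,
                             sample_volume = 1, area = 1.33, dose = 10,
                             shape = 1, noise_cv = 0, seed = 1) {
  abort_if(k <= 0, "k must be positive")
  abort_if(Qinf > dose + 1e-12, "Qinf exceeds the dose")
  abort_if(any(diff(times) <= 0) || times[1] <= 0,
           "sampling schedule must be strictly increasing and start above 0")
  Q <- Qinf * (1 - exp(-(k * times)^shape))
  mass <- numeric(length(times))   # drug mass in medium just before sampling
  carry <- 0
  for (i in seq_along(times)) {
    released_step <- Q[i] - (if (i == 1) 0 else Q[i - 1])
    mass[i] <- carry + released_step
    carry <- mass[i] * (1 - sample_volume / volume)
  }
  conc <- mass / volume
  if (noise_cv > 0) {
    conc <- withr::with_seed(seed, {
      conc * stats::rlnorm(length(conc), -noise_cv^2 / 2, noise_cv)
    })
  }
  out <- release_profile(times, conc, volume = volume,
                         sample_volume = sample_volume, area = area,
                         dose = dose)
  attr(out, "true_release") <- tibble::tibble(time_h = times, released_mg = Q)
  out
}

#' Simulate a storage-modulus temperature sweep
#'
#' A logistic step in G' centred on the transition temperature: gel plateau
#' above it, sol plateau below (thermoresponsive poloxamer behaviour), with
#' multiplicative measurement noise.
#'
#' @param t_transition Transition temperature, degC.
#' @param g_gel,g_sol Plateau moduli above/below the transition, Pa.
#' @param width Logistic width of the step, degC.
#' @param temperatures Ramp schedule, degC (default 40 down to 0 in 1 degC
#'   steps, the usual 1 degC/min ramp sampled each minute).
#' @param noise_cv Multiplicative noise CV; 0 disables it.
#' @param seed Integer seed.
#' @return A [rheo_sweep()].
#' @export
simulate_rheosweep <- function(t_transition, g_gel = 1e4, g_sol = 10,
                               width = 1.2, temperatures = seq(40, 0, by = -1),
                               noise_cv = 0.02, seed = 1) {
  abort_if(width <= 0, "width must be positive")
  g <- g_sol + (g_gel - g_sol) * stats::plogis((temperatures - t_transition) / width)
  if (noise_cv > 0) {
    g <- withr::with_seed(seed, {
      g * stats::rlnorm(length(g), -noise_cv^2 / 2, noise_cv)
    })
  }
  rheo_sweep(temperatures, g)
}

#' Simulate repeated particle-size percentile measurements
#'
#' Oil-droplet diameters are modelled as lognormal with the given median and
#' log-scale sigma; each simulated measurement reports the D10/D50/D90
#' quantiles of that law perturbed by a small multiplicative measurement
#' error, mirroring repeated laser-diffraction runs on one sample.
#'
#' @param median Median droplet size (D50), um.
#' @param sigma Lognormal shape (SD of log size), > 0.
#' @param n_measurements Number of repeated measurements (default 5).
#' @param noise_cv Measurement CV on each reported percentile.
#' @param seed Integer seed.
#' @return Tibble with `measurement`, `d10`, `d50`, `d90` (um).
#' @export
simulate_particles <- function(median, sigma, n_measurements = 5,
                               noise_cv = 0.02, seed = 1) {
  abort_if(sigma <= 0, "sigma must be positive")
  abort_if(median <= 0, "median must be positive")
  q <- stats::qlnorm(c(0.1, 0.5, 0.9), meanlog = log(median), sdlog = sigma)
  withr::with_seed(seed, {
    noise <- matrix(stats::rlnorm(3 * n_measurements, -noise_cv^2 / 2, noise_cv),
                    ncol = 3)
    tibble::tibble(
      measurement = seq_len(n_measurements),
      d10 = q[1] * noise[, 1], d50 = q[2] * noise[, 2], d90 = q[3] * noise[, 3]
    )
  })
}

#' Summarize percentile measurements as means and SDs
#'
#' @param percentiles Output of [simulate_particles()] (or any tibble with
#'   `d10`, `d50`, `d90` columns).
#' @return Tibble with `percentile`, `mean`, `sd` in the layout of
#'   [emulgel_particle_sizes()].
#' @export
summarize_percentiles <- function(percentiles) {
  percentiles |>
    tidyr::pivot_longer(dplyr::all_of(c("d10", "d50", "d90")),
                        names_to = "percentile", values_to = "value") |>
    dplyr::group_by(.data$percentile) |>
    dplyr::summarise(mean = mean(.data$value), sd = stats::sd(.data$value),
                     .groups = "drop")
}
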