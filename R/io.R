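# CSV readers/writers for the workbench's table dialects. All files are
# comma-separated UTF-8 with a header row and "." decimals; percentages are
# stored as numbers 0-100.

design_csv_cols <- c(run_id = "run_id", coded_A = "coded_A", coded_B = "coded_B",
                     mineral_oil = "oil_pct", polysorbate_80 = "polysorbate_pct",
                     poloxamer_407 = "poloxamer_pct", purified_water = "water_pct",
                     ciclopirox_olamine = "cpo_pct")

#' Write / read a design table as CSV
#'
#' Columns: `run_id`, `oil_pct`, `polysorbate_pct`, `coded_A`, `coded_B`,
#' `poloxamer_pct`, `water_pct`, `cpo_pct`.
#'
#' @param design A completed emulgel `design_table`.
#' @param path File path.
#' @return `write_design_csv()` returns `path` invisibly; `read_design_csv()`
#'   returns a `design_table` with the emulgel factor space attached.
#' @export
write_design_csv <- function(design, path) {
  miss <- setdiff(names(design_csv_cols), names(design))
  abort_if(length(miss) > 0, "design lacks column(s): %s",
           paste(miss, collapse = ", "))
  out <- design[, names(design_csv_cols)]
  names(out) <- unname(design_csv_cols)
  out <- out[, c("run_id", "oil_pct", "polysorbate_pct", "coded_A", "coded_B",
                 "poloxamer_pct", "water_pct", "cpo_pct")]
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  miss <- setdiff(unname(design_csv_cols), names(raw))
  abort_if(length(miss) > 0, "design CSV lacks column(s): %s",
           paste(miss, collapse = ", "))
  out <- raw
  names(out) <- names(design_csv_cols)[match(names(raw), unname(design_csv_cols))]
  out <- tibble::as_tibble(out)
  attr(out, "factor_space") <- emulgel_factor_space()
  class(out) <- c("design_table", class(out))
  out
}

#' Write / read replicate response tables as CSV
#'
#' Columns: `run_id`, `replicate_id`, `response_name`, `value`.
#'
#' @param responses Tibble as produced by [simulate_responses()].
#' @param path File path.
#' @return The path (write, invisibly) or the tibble (read).
#' @export
write_responses_csv <- function(responses, path) {
  need <- c("run_id", "replicate_id", "response_name", "value")
  miss <- setdiff(need, names(responses))
  abort_if(length(miss) > 0, "responses lack column(s): %s",
           paste(miss, collapse = ", "))
  readr::write_csv(responses[, need], path)
  invisible(path)
}

#' @rdname write_responses_csv
#' @export
read_responses_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("run_id", "replicate_id", "response_name", "value")
  miss <- setdiff(need, names(out))
  abort_if(length(miss) > 0, "response CSV lacks column(s): %s",
           paste(miss, collapse = ", "))
  out
}

#' Write / read release profiles as CSV
#'
#' Columns: `run_id`, `time_h`, `concentration_mg_per_ml`.
#'
#' @param profiles Named list of [release_profile()] objects (names = run
#'   ids).
#' @param path File path.
#' @return The path (write, invisibly); `read_release_csv()` returns a named
#'   list of `release_profile` objects built with the supplied geometry.
#' @param volume,sample_volume,area,dose Cell geometry used to rebuild the
#'   profiles on read.
#' @export
write_release_csv <- function(profiles, path) {
  rows <- dplyr::bind_rows(lapply(names(profiles), function(id) {
    p <- profiles[[id]]
    tibble::tibble(run_id = id, time_h = p$times,
                   concentration_mg_per_ml = p$concentrations)
  }))
  readr::write_csv(rows, path)
  invisible(path)
}

#' @rdname write_release_csv
#' @export
read_release_csv <- function(path, volume = 50, sample_volume = 1,
                             area = 1.33, dose = 10) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("run_id", "time_h", "concentration_mg_per_ml")
  miss <- setdiff(need, names(raw))
  abort_if(length(miss) > 0, "release CSV lacks column(s): %s",
           paste(miss, collapse = ", "))
  split(raw, raw$run_id) |>
    lapply(function(d) {
      release_profile(d$time_h, d$concentration_mg_per_ml, volume = volume,
                      sample_volume = sample_volume, area = area, dose = dose)
    })
}

#' Write / read rheology sweeps as CSV
#'
#' Columns: `run_id`, `temperature_C`, `g_prime_Pa`.
#'
#' @param sweeps Named list of [rheo_sweep()] objects.
#' @param path File path.
#' @return The path (write, invisibly) or a named list of `rheo_sweep`
#'   objects (read).
#' @export
write_rheology_csv <- function(sweeps, path) {
  rows <- dplyr::bind_rows(lapply(names(sweeps), function(id) {
    s <- sweeps[[id]]
    tibble::tibble(run_id = id, temperature_C = s$temperatures,
                   g_prime_Pa = s$g_prime)
  }))
  readr::write_csv(rows, path)
  invisible(path)
}

#' Read desirability criteria from a YAML or JSON configuration file
#'
#' The file holds a list of entries with keys `response`, `goal` and
#' optionally `low`, `high`, `target`, `weight`, `importance`, mirroring the
#' arguments of [criterion()]. The format is inferred from the extension
#' (`.yaml`/`.yml` needs the yaml package; anything else is parsed as JSON).
#'
#' @param path File path.
#' @return A list of [criterion()] objects ready for
#'   [optimize_desirability()] or [run_config()].
#' @export
read_criteria <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    abort_if(!requireNamespace("yaml", quietly = TRUE),
             "reading YAML criteria needs the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = FALSE)
  }
  lapply(raw, function(e) {
    abort_if(is.null(e$response) || is.null(e$goal),
             "each criterion entry needs 'response' and 'goal'")
    criterion(e$response, e$goal,
              low = e$low, high = e$high, target = e$target,
              weight = e$weight %||% 1, importance = e$importance %||% 1)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname write_rheology_csv
#' @export
read_rheology_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("run_id", "temperature_C", "g_prime_Pa")
  miss <- setdiff(need, names(raw))
  abort_if(length(miss) > 0, "rheology CSV lacks column(s): %s",
           paste(miss, collapse = ", "))
  split(raw, raw$run_id) |>
    lapply(function(d) rheo_sweep(d$temperature_C, d$g_prime_Pa))
}
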