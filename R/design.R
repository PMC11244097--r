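#' Define a factor space for a response-surface design
#'
#' A factor space holds the experimental range of each formulation factor and
#' the affine map between actual levels (here % w/w) and coded levels, where
#' the design centre maps to 0 and the range limits to -1/+1. Coded levels
#' make coefficients of fitted polynomials directly comparable across factors.
#'
#' @param names Character vector of factor names.
#' @param low,high Numeric vectors of the lower/upper actual level per factor.
#' @param coded_labels Single-letter labels used for coded columns and model
#'   terms; defaults to `A`, `B`, ...
#' @return A tibble of class `factor_space` with columns `factor`, `coded`,
#'   `low`, `high`, `center`, `half_range`.
#' @examples
#' factor_space(c("mineral_oil", "polysorbate_80"), low = c(10, 0), high = c(50, 10))
#' @export
factor_space <- function(names, low, high,
                         coded_labels = LETTERS[seq_along(names)]) {
  abort_if(length(names) < 1L, "at least one factor is required")
  abort_if(length(low) != length(names) || length(high) != length(names),
           "`low` and `high` must have one value per factor")
  abort_if(anyDuplicated(names) > 0L, "factor names must be unique")
  abort_if(!is_number(low) || !is_number(high), "factor limits must be finite numbers")
  bad <- which(low >= high)
  abort_if(length(bad) > 0L, "factor '%s' has low >= high", names[bad[1]])
  out <- tibble::tibble(
    factor = as.character(names),
    coded = as.character(coded_labels),
    low = as.numeric(low),
    high = as.numeric(high),
    center = (low + high) / 2,
    half_range = (high - low) / 2
  )
  class(out) <- c("factor_space", class(out))
  out
}

#' Factor space of the ciclopirox olamine emulgel study
#'
#' Mineral oil 10-50 % w/w (coded A) and polysorbate 80 0-10 % w/w (coded B).
#'
#' @return A [factor_space()].
#' @export
emulgel_factor_space <- function() {
  factor_space(c("mineral_oil", "polysorbate_80"), low = c(10, 0), high = c(50, 10))
}

fs_row <- function(space, fct) {
  i <- match(fct, space$factor)
  if (is.na(i)) i <- match(fct, space$coded)
  abort_if(is.na(i), "unknown factor '%s'", fct)
  space[i, ]
}

#' Convert between actual and coded factor levels
#'
#' `to_coded()` maps an actual level x to (x - center) / half_range;
#' `from_coded()` is its exact inverse. Values outside [-1, 1] are allowed
#' (they represent extrapolation beyond the design region).
#'
#' @param x Numeric vector of levels.
#' @param space A [factor_space()].
#' @param factor Factor name (or coded label) identifying the factor.
#' @return Numeric vector of converted levels.
#' @examples
#' fs <- emulgel_factor_space()
#' to_coded(50, fs, "mineral_oil")    # +1
#' from_coded(0.4135, fs, "mineral_oil")
#' @export
to_coded <- function(x, space, factor) {
  r <- fs_row(space, factor)
  (x - r$center) / r$half_range
}

#' @rdname to_coded
#' @export
from_coded <- function(x, space, factor) {
  r <- fs_row(space, factor)
  r$center + x * r$half_range
}

#' Generate a face-centred central composite design
#'
#' Builds the face-centred CCD (axial distance alpha = 1): the 2^k factorial
#' corners, 2k axial points on the face centres, and centre point(s). For two
#' factors this is the 9-run design of a 3^2 grid without replicated centres.
#' Runs are ordered factorial, axial, centre with labels `R-1` ... `R-n`.
#'
#' @param space A [factor_space()].
#' @param center_points Number of centre-point runs (default 1). More centre
#'   replicates allow pure-error estimates.
#' @return A tibble of class `design_table`, one row per run, with `run_id`,
#'   one `coded_<label>` column and one actual column per factor. The factor
#'   space travels along as attribute `factor_space`.
#' @examples
#' ccd_design(emulgel_factor_space())
#' @export
ccd_design <- function(space, center_points = 1L) {
  abort_if(!inherits(space, "factor_space"), "`space` must be a factor_space")
  abort_if(any(space$half_range <= 0), "degenerate factor with zero half-range")
  abort_if(center_points < 1L, "at least one centre point is required")
  k <- nrow(space)

  corners <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  axial <- matrix(0, nrow = 2L * k, ncol = k)
  for (i in seq_len(k)) {
    axial[2L * i - 1L, i] <- -1
    axial[2L * i, i] <- 1
  }
  centre <- matrix(0, nrow = center_points, ncol = k)
  coded <- rbind(corners, axial, centre)
  colnames(coded) <- space$coded

  actual <- sweep(sweep(coded, 2L, space$half_range, `*`), 2L, space$center, `+`)
  colnames(actual) <- space$factor

  out <- tibble::as_tibble(coded, .name_repair = ~ paste0("coded_", .x))
  out <- dplyr::bind_cols(
    tibble::tibble(run_id = paste0("R-", seq_len(nrow(coded)))),
    out,
    tibble::as_tibble(actual)
  )
  attr(out, "factor_space") <- space
  class(out) <- c("design_table", class(out))
  out
}

#' Complete emulgel design runs into full formulation recipes
#'
#' For each run the gelling-agent (poloxamer 407) share follows a linear rule
#' in the oil content, ciclopirox olamine is fixed, and purified water takes
#' the balance so the components sum to 100 % w/w. Default rule,
#' poloxamer = 25 - 0.25 * oil, reproduces the published compositions
#' (22.5 / 17.5 / 12.5 % poloxamer at 10 / 30 / 50 % oil).
#'
#' @param design A `design_table` (or any data frame) with `mineral_oil` and
#'   `polysorbate_80` columns in % w/w.
#' @param poloxamer_intercept,poloxamer_slope Coefficients of the linear
#'   poloxamer rule (% w/w and %/% respectively).
#' @param cpo Ciclopirox olamine content, % w/w (default 1).
#' @return The input with added columns `poloxamer_407`, `purified_water`,
#'   `ciclopirox_olamine` and `hydrogel` (poloxamer + water + drug).
#' @examples
#' ccd_design(emulgel_factor_space()) |> complete_formulation()
#' @export
complete_formulation <- function(design, poloxamer_intercept = 25,
                                 poloxamer_slope = -0.25, cpo = 1) {
  abort_if(!all(c("mineral_oil", "polysorbate_80") %in% names(design)),
           "`design` needs columns mineral_oil and polysorbate_80")
  oil <- design$mineral_oil
  pol <- design$polysorbate_80
  poloxamer <- poloxamer_intercept + poloxamer_slope * oil
  water <- 100 - oil - pol - poloxamer - cpo
  comp <- list(mineral_oil = oil, polysorbate_80 = pol,
               poloxamer_407 = poloxamer, purified_water = water,
               ciclopirox_olamine = rep(cpo, length(oil)))
  for (nm in names(comp)) {
    bad <- which(comp[[nm]] < 0)
    abort_if(length(bad) > 0L, "component '%s' is negative (%.4g %%) in run %d",
             nm, comp[[nm]][bad[1]], bad[1])
  }
  total <- oil + pol + poloxamer + water + cpo
  abort_if(any(abs(total - 100) > 1e-9), "formulation percentages do not sum to 100")
  design$poloxamer_407 <- poloxamer
  design$purified_water <- water
  design$ciclopirox_olamine <- rep(cpo, length(oil))
  design$hydrogel <- poloxamer + water + cpo
  design
}

#' The nine-run emulgel design of the ciclopirox olamine study
#'
#' The face-centred CCD over 10-50 % mineral oil and 0-10 % polysorbate 80,
#' completed into full formulations and presented in the published run order
#' E-1 ... E-9 (centre run E-1 with no polysorbate first, centre point E-9
#' last).
#'
#' @return A `design_table` with formulation columns.
#' @examples
#' emulgel_design()
#' @export
emulgel_design <- function() {
  space <- emulgel_factor_space()
  d <- complete_formulation(ccd_design(space))
  # published run order, expressed as coded (A, B) pairs
  pub <- list(`E-1` = c(0, -1), `E-2` = c(-1, -1), `E-3` = c(-1, 0),
              `E-4` = c(0, 1), `E-5` = c(1, 1), `E-6` = c(-1, 1),
              `E-7` = c(1, 0), `E-8` = c(1, -1), `E-9` = c(0, 0))
  idx <- vapply(pub, function(ab) {
    which(d$coded_A == ab[1] & d$coded_B == ab[2])
  }, integer(1))
  out <- d[idx, ]
  out$run_id <- names(pub)
  attr(out, "factor_space") <- space
  class(out) <- c("design_table", class(out))
  out
}
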