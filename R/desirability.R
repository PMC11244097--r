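#' Define a desirability criterion for one response
#'
#' Derringer-Suich desirability maps a response value onto [0, 1] according
#' to a goal. For `maximize`, d = ((y - L)/(U - L))^w clipped to [0, 1]; for
#' `minimize`, d = ((U - y)/(U - L))^w; for `target`, a two-sided ramp rising
#' from L to the target and falling back to U; `in_range` is the indicator of
#' [L, U]. Bounds left `NULL` are resolved later from the range of model
#' predictions over the design runs (the conventional default when explicit
#' limits are not stated).
#'
#' @param response Response name (must match a model name at optimization).
#' @param goal One of `"maximize"`, `"minimize"`, `"target"`, `"in_range"`.
#' @param low,high Lower/upper bound L and U in response units.
#' @param target Target value (goal `"target"` only), with L < target < U.
#' @param weight Shape exponent w >= 0 (1 = linear ramp).
#' @param importance Relative exponent in the composite desirability.
#' @return A list of class `criterion`.
#' @export
criterion <- function(response, goal = c("maximize", "minimize", "target", "in_range"),
                      low = NULL, high = NULL, target = NULL,
                      weight = 1, importance = 1) {
  goal <- match.arg(goal)
  abort_if(weight < 0, "weight must be >= 0")
  abort_if(importance < 0, "importance must be >= 0")
  if (!is.null(low) && !is.null(high)) {
    abort_if(low >= high, "criterion '%s': need low < high", response)
  }
  if (goal == "target") {
    abort_if(is.null(target), "goal 'target' needs a target value")
  }
  structure(list(response = response, goal = goal, low = low, high = high,
                 target = target, weight = weight, importance = importance),
            class = "criterion")
}

#' Individual desirability of response values
#'
#' @param y Numeric vector of response values.
#' @param crit A [criterion()] with resolved bounds.
#' @return Numeric vector of desirabilities in [0, 1].
#' @export
desirability <- function(y, crit) {
  abort_if(is.null(crit$low) || is.null(crit$high),
           "criterion '%s' has unresolved bounds", crit$response)
  L <- crit$low; U <- crit$high; w <- crit$weight
  abort_if(U == L, "criterion '%s': bounds are degenerate (L = U)", crit$response)
  clip01 <- function(z) pmin(1, pmax(0, z))
  switch(crit$goal,
    maximize = clip01((y - L) / (U - L))^w,
    minimize = clip01((U - y) / (U - L))^w,
    target = {
      t0 <- crit$target
      up <- clip01((y - L) / (t0 - L))
      dn <- clip01((U - y) / (U - t0))
      pmin(up, dn)^w
    },
    in_range = as.numeric(y >= L & y <= U)
  )
}

#' Composite (overall) desirability
#'
#' Importance-weighted geometric mean D = (prod d_i^r_i)^(1 / sum r_i); any
#' zero individual desirability forces D = 0.
#'
#' @param d Numeric vector of individual desirabilities in [0, 1].
#' @param importance Numeric vector of importances (recycled scalar allowed).
#' @return Scalar composite desirability.
#' @export
composite_desirability <- function(d, importance = 1) {
  abort_if(any(d < 0 | d > 1), "desirabilities must lie in [0, 1]")
  r <- rep_len(importance, length(d))
  abort_if(sum(r) <= 0, "importances must have positive sum")
  if (any(d == 0)) return(0)
  exp(sum(r * log(d)) / sum(r))
}

resolve_bounds <- function(criteria, models, design) {
  lapply(criteria, function(cr) {
    if (!is.null(cr$low) && !is.null(cr$high)) return(cr)
    abort_if(is.null(design),
             "criterion '%s' has no bounds and no design to derive them from",
             cr$response)
    pr <- predict(models[[cr$response]], design)
    if (is.null(cr$low)) cr$low <- min(pr)
    if (is.null(cr$high)) cr$high <- max(pr)
    abort_if(cr$low >= cr$high,
             "criterion '%s': derived bounds are degenerate", cr$response)
    cr
  })
}

#' Optimize composite desirability over the factor space
#'
#' Maximizes the composite desirability of several fitted (or transcribed)
#' response models over the rectangular actual-factor region: a dense grid
#' evaluation followed by local refinement (Nelder-Mead within bounds via
#' L-BFGS-B) from the best grid cell and from seeded random starts. Flat
#' ridges are broken deterministically toward the design centre.
#'
#' @param models Named list of `rsm_model` / `rsm_fit` objects covering every
#'   criterion response.
#' @param criteria List of [criterion()] objects.
#' @param space A [factor_space()] defining the search box.
#' @param design Optional `design_table` used to resolve unset criterion
#'   bounds from the per-response prediction extremes over the design runs.
#' @param grid_step Grid resolution in actual units (default 0.05).
#' @param n_starts Number of seeded random refinement starts (default 8).
#' @param seed Integer seed making the random starts reproducible.
#' @return List of class `optimum_result`: `factors` (named optimum), tibble
#'   `predictions` (response, goal, low, high, predicted, desirability),
#'   `D` (composite), `trace` (refinement starts), `grid` (coarse D surface
#'   for plotting), and `degenerate` (TRUE when D = 0 everywhere).
#' @examples
#' mods <- emulgel_models()
#' crit <- list(criterion("flux", "maximize"), criterion("tsolgel", "minimize"),
#'              criterion("d50", "minimize"))
#' optimize_desirability(mods[c("flux", "tsolgel", "d50")], crit,
#'                       emulgel_factor_space(), emulgel_design(), seed = 1)
#' @export
optimize_desirability <- function(models, criteria, space, design = NULL,
                                  grid_step = 0.05, n_starts = 8, seed = NULL) {
  miss <- setdiff(vapply(criteria, `[[`, "", "response"), names(models))
  abort_if(length(miss) > 0, "no model supplied for criterion response(s): %s",
           paste(miss, collapse = ", "))
  criteria <- resolve_bounds(criteria, models, design)
  imp <- vapply(criteria, `[[`, 1, "importance")

  objective <- function(X) {
    # X: n x k matrix of actual levels; returns composite D per row
    d_mat <- vapply(criteria, function(cr) {
      y <- predict(models[[cr$response]], X)
      abort_if(any(!is.finite(y)), "model '%s' predicts non-finite values",
               cr$response)
      desirability(y, cr)
    }, numeric(nrow(X)))
    d_mat <- matrix(d_mat, nrow = nrow(X))
    apply(d_mat, 1, composite_desirability, importance = imp)
  }

  grids <- lapply(seq_len(nrow(space)), function(i) {
    seq(space$low[i], space$high[i], by = grid_step)
  })
  G <- as.matrix(expand.grid(grids))
  colnames(G) <- space$factor
  Dg <- objective(G)

  best_D <- max(Dg)
  degenerate <- best_D <= 0
  # deterministic tie-break: nearest to the design centre
  ties <- which(Dg >= best_D - 1e-12)
  dist2 <- rowSums(sweep(G[ties, , drop = FALSE], 2, space$center, `-`)^2)
  start0 <- G[ties[which.min(dist2)], ]

  starts <- list(start0)
  if (n_starts > 0) {
    rand <- withr::with_seed(
      if (is.null(seed)) 0L else seed,
      matrix(stats::runif(n_starts * nrow(space), space$low, space$high),
             ncol = nrow(space), byrow = TRUE)
    )
    starts <- c(starts, lapply(seq_len(n_starts), function(i) rand[i, ]))
  }

  neg_obj <- function(x) -objective(matrix(x, nrow = 1))
  trace <- lapply(seq_along(starts), function(i) {
    o <- stats::optim(starts[[i]], neg_obj, method = "L-BFGS-B",
                      lower = space$low, upper = space$high,
                      control = list(factr = 1e4))
    list(start = starts[[i]], par = o$par, D = -o$value,
         converged = o$convergence == 0)
  })
  Ds <- vapply(trace, `[[`, 1, "D")
  cand_par <- lapply(trace, `[[`, "par")
  # keep the grid winner if refinement cannot beat it (within tie tolerance,
  # prefer the centre-most point)
  cand_par <- c(cand_par, list(start0))
  Ds <- c(Ds, best_D)
  top <- max(Ds)
  tied <- which(Ds >= top - 1e-9)
  cdist <- vapply(cand_par[tied], function(p) sum((p - space$center)^2), 1)
  opt <- cand_par[[tied[which.min(cdist)]]]
  opt_D <- objective(matrix(opt, nrow = 1))

  preds <- dplyr::bind_rows(lapply(criteria, function(cr) {
    y <- predict(models[[cr$response]], matrix(opt, nrow = 1))
    tibble::tibble(response = cr$response, goal = cr$goal, low = cr$low,
                   high = cr$high, predicted = y,
                   desirability = desirability(y, cr))
  }))
  structure(
    list(factors = stats::setNames(as.numeric(opt), space$factor),
         predictions = preds, D = as.numeric(opt_D),
         degenerate = degenerate, criteria = criteria,
         trace = trace, space = space,
         grid = tibble::as_tibble(cbind(as.data.frame(G), D = Dg))),
    class = "optimum_result"
  )
}

#' @export
print.optimum_result <- function(x, ...) {
  cat("<optimum_result>\n  factors:",
      paste(sprintf("%s = %.4g", names(x$factors), x$factors), collapse = ", "),
      sprintf("\n  composite desirability D = %.4f%s\n", x$D,
              if (x$degenerate) " (degenerate: D = 0 everywhere)" else ""))
  print(x$predictions)
  invisible(x)
}
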