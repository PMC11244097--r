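#' Fit a polynomial response-surface model on coded factors
#'
#' Ordinary least squares of a response on the coded-factor polynomial of the
#' requested family (or an explicit term subset). The response may be given as
#' one value per design run or as a replicate table, in which case every
#' measurement enters as its own observation. Coefficients are reported in
#' the coded parameterization and, by exact algebraic substitution, in the
#' actual-factor one; the two forms agree at every point to machine precision.
#'
#' @param design A `design_table` from [ccd_design()] / [emulgel_design()].
#' @param y Either a numeric vector with one value per run (in design row
#'   order), or a data frame with columns `run_id` and `value` (replicate
#'   rows allowed).
#' @param family Model family passed to [rsm_terms()]; ignored when `terms`
#'   is supplied.
#' @param terms Optional named list of exponent vectors (a subset of a family
#'   term set, e.g. from [prune_terms()]).
#' @param response Response name carried into reports.
#' @return An object of class `rsm_fit`: the coefficient sets, residuals,
#'   leverages and the data needed to refit (used by [prune_terms()] and
#'   [select_model()]). Supports [predict()], [tidy()], [glance()] and
#'   [autoplot()].
#' @examples
#' des <- emulgel_design()
#' d50 <- emulgel_particle_sizes() |> dplyr::filter(percentile == "d50")
#' fit <- rsm_fit(des, d50$mean, family = "linear", response = "d50")
#' glance(fit)
#' @export
rsm_fit <- function(design, y, family = "quadratic", terms = NULL,
                    response = "y") {
  space <- attr(design, "factor_space")
  abort_if(is.null(space), "`design` has no factor_space attribute")
  if (is.null(terms)) terms <- rsm_terms(family, space)

  if (is.data.frame(y)) {
    abort_if(!all(c("run_id", "value") %in% names(y)),
             "replicate `y` needs columns run_id and value")
    idx <- match(y$run_id, design$run_id)
    abort_if(anyNA(idx), "unknown run_id in response table: %s",
             paste(unique(y$run_id[is.na(idx)]), collapse = ", "))
    rows <- idx
    yy <- as.numeric(y$value)
  } else {
    abort_if(length(y) != nrow(design),
             "`y` must have one value per design run (%d)", nrow(design))
    rows <- seq_len(nrow(design))
    yy <- as.numeric(y)
  }
  abort_if(!all(is.finite(yy)), "response contains non-finite values")

  coded_cols <- paste0("coded_", space$coded)
  U <- as.matrix(as.data.frame(design)[rows, coded_cols, drop = FALSE])
  colnames(U) <- space$coded
  M <- term_matrix(terms, U)
  p <- ncol(M)
  n <- nrow(M)
  abort_if(n < p + 1, "need at least %d observations for %d terms", p + 1, p)

  qrM <- qr(M)
  if (qrM$rank < p) {
    dropped <- colnames(M)[qrM$pivot[(qrM$rank + 1):p]]
    stop(sprintf("model matrix is rank deficient; collinear term(s): %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  coef_coded <- stats::setNames(drop(qr.coef(qrM, yy)), colnames(M))
  fitted <- drop(M %*% coef_coded)
  resid <- yy - fitted
  hat <- rowSums(qr.Q(qrM)[, seq_len(p), drop = FALSE]^2)
  sse <- sum(resid^2)
  sst <- sum((yy - mean(yy))^2)
  mse <- sse / (n - p)

  ca <- recode_coefficients(coef_coded, terms, space, "coded_to_actual")
  coef_actual <- align_to_closure(ca, terms, space)

  structure(
    list(response = response, space = space, terms = terms,
         coef_coded = coef_coded, coef_actual = coef_actual$coefs,
         terms_actual = coef_actual$terms,
         n_obs = n, n_terms = p, fitted = fitted, residuals = resid,
         hat = hat, sse = sse, sst = sst, mse = mse,
         design = design, rows = rows, y = yy,
         xtx_inv = chol2inv(qr.R(qrM)[seq_len(p), seq_len(p), drop = FALSE])),
    class = "rsm_fit"
  )
}

# closure of the term set after substitution (pruned models may gain parents)
align_to_closure <- function(rp, terms, space) {
  list(coefs = rp, terms = attr(rp, "terms"))
}

#' @export
print.rsm_fit <- function(x, ...) {
  cat(sprintf("<rsm_fit> %s: %d term(s), %d obs\n", x$response, x$n_terms, x$n_obs))
  cat("  coded coefficients:\n")
  print(round(x$coef_coded, 6))
  invisible(x)
}

#' Predict from a fitted response-surface model
#'
#' @param object An `rsm_fit`.
#' @param newdata Data frame with the factor columns in actual units, or
#'   matrix in factor order. Defaults to the design the model was fitted on.
#' @param parameterization `"actual"` (default) or `"coded"`; the two agree to
#'   machine precision and exist to demonstrate exactly that.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.rsm_fit <- function(object, newdata = NULL,
                            parameterization = c("actual", "coded"), ...) {
  parameterization <- match.arg(parameterization)
  if (is.null(newdata)) newdata <- object$design
  X <- factor_levels_matrix(newdata, object$space)
  if (parameterization == "actual") {
    eval_terms(object$coef_actual, object$terms_actual, X)
  } else {
    U <- sweep(sweep(X, 2, object$space$center, `-`), 2,
               object$space$half_range, `/`)
    eval_terms(object$coef_coded, object$terms, U)
  }
}

#' Model-fit diagnostics in design-of-experiments convention
#'
#' Computes the summary used to judge response-surface fits: the regression
#' F-test p-value, R-squared and its adjusted form, PRESS (leave-one-out
#' prediction error via the hat-diagonal shortcut e_i / (1 - h_ii)) with the
#' derived predicted R-squared, adequate precision (range of predictions at
#' the design points divided by their average standard error,
#' sqrt(p * MSE / n)), and partial-F p-values per term.
#'
#' @param fit An `rsm_fit`.
#' @return A list of class `rsm_diagnostics` with elements `model_p`, `r2`,
#'   `adj_r2`, `press`, `pred_r2`, `adeq_precision`, `sigma`, and a tibble
#'   `term_tests` (term, estimate, std_error, statistic, p_value).
#' @export
rsm_diagnostics <- function(fit) {
  n <- fit$n_obs; p <- fit$n_terms
  abort_if(n <= p, "diagnostics need residual degrees of freedom")
  abort_if(any(fit$hat >= 1 - 1e-12), "PRESS undefined for interpolating model")
  r2 <- 1 - fit$sse / fit$sst
  adj_r2 <- 1 - (1 - r2) * (n - 1) / (n - p)
  press <- sum((fit$residuals / (1 - fit$hat))^2)
  pred_r2 <- 1 - press / fit$sst
  adeq <- diff(range(fit$fitted)) / sqrt(p * fit$mse / n)

  df1 <- p - 1; df2 <- n - p
  ssr <- fit$sst - fit$sse
  model_p <- if (df1 > 0) {
    stats::pf((ssr / df1) / fit$mse, df1, df2, lower.tail = FALSE)
  } else NA_real_
  se <- sqrt(diag(fit$xtx_inv) * fit$mse)
  tval <- fit$coef_coded / se
  pval <- 2 * stats::pt(abs(tval), df2, lower.tail = FALSE)
  term_tests <- tibble::tibble(
    term = names(fit$coef_coded), estimate = unname(fit$coef_coded),
    std_error = unname(se), statistic = unname(tval), p_value = unname(pval)
  )
  structure(
    list(response = fit$response, model_p = model_p, r2 = r2, adj_r2 = adj_r2,
         press = press, pred_r2 = pred_r2, adeq_precision = adeq,
         sigma = sqrt(fit$mse), n_obs = n, n_terms = p,
         term_tests = term_tests),
    class = "rsm_diagnostics"
  )
}

#' @export
print.rsm_diagnostics <- function(x, ...) {
  cat(sprintf(
    "<rsm_diagnostics> %s: p = %.4g, R2 = %.4f, adj R2 = %.4f, pred R2 = %.4f, adeq precision = %.1f\n",
    x$response, x$model_p, x$r2, x$adj_r2, x$pred_r2, x$adeq_precision))
  invisible(x)
}

# terms that must stay because a retained higher-order term contains them
hierarchy_required <- function(terms) {
  req <- rep(FALSE, length(terms))
  for (t in seq_along(terms)) {
    e <- terms[[t]]
    if (term_order(e) < 2) next
    for (s in seq_along(terms)) {
      if (s == t) next
      es <- terms[[s]]
      if (term_order(es) >= term_order(e)) next
      if (term_order(es) == 0) next
      if (all(es <= e)) req[s] <- TRUE
    }
  }
  req
}

#' Backward elimination of insignificant model terms
#'
#' Removes, one at a time with a refit after each removal, the term with the
#' largest partial-F p-value above the threshold, never removing the
#' intercept nor a term required to support hierarchy (a square or
#' interaction keeps its parent main effects in the model regardless of their
#' p-values). A single-pass variant drops all offending terms at once.
#'
#' @param fit An `rsm_fit`.
#' @param threshold Retention p-value threshold (default 0.10).
#' @param sequential Refit after each single removal (default) or prune in
#'   one pass.
#' @return The pruned `rsm_fit`.
#' @export
prune_terms <- function(fit, threshold = 0.10, sequential = TRUE) {
  repeat {
    diag <- rsm_diagnostics(fit)
    terms <- fit$terms
    pvals <- diag$term_tests$p_value
    removable <- !hierarchy_required(terms) &
      names(terms) != "Intercept" & pvals > threshold
    if (!any(removable)) return(fit)
    drop_idx <- if (sequential) {
      which(removable)[which.max(pvals[removable])]
    } else {
      which(removable)
    }
    new_terms <- terms[-drop_idx]
    if (length(new_terms) == length(terms)) return(fit)
    fit <- rsm_fit(fit$design,
                   tibble::tibble(run_id = fit$design$run_id[fit$rows],
                                  value = fit$y),
                   terms = new_terms, response = fit$response)
    if (!sequential) return(fit)
  }
}

#' Select a response-surface model family
#'
#' Follows design-of-experiments software practice in two stages. First the
#' sequential model sum of squares suggests a family: walking up the
#' candidate hierarchy (linear, two-factor interaction, quadratic), the
#' highest family whose block of added terms is jointly significant
#' (incremental F-test, `alpha_seq`, default 0.01 so that with two added blocks the chance of a spurious family upgrade stays near 2 %) is suggested, so pure noise never buys
#' extra terms. Then the suggested family is checked against the adequacy
#' rules used to validate a model: model p-value < `p_max`, adjusted minus
#' predicted R-squared < `r2_gap_max`, adequate precision > `adeq_min`. If
#' the suggestion fails those rules but another candidate passes all three,
#' the passing candidate with the highest predicted R-squared is returned
#' instead; if nothing qualifies the suggestion is returned flagged
#' `validated = FALSE`.
#'
#' @param design,y,response As in [rsm_fit()].
#' @param candidates Character vector of families to try (subset of linear,
#'   2FI, quadratic; order of increasing complexity is enforced internally).
#' @param p_max,r2_gap_max,adeq_min Adequacy thresholds.
#' @param alpha_seq Significance level of the sequential added-term F-tests.
#' @return List of class `rsm_selection`: `fit` (the chosen `rsm_fit`),
#'   `family`, `validated`, and `candidates` (a tibble of per-family
#'   diagnostics including the sequential p-value of each added block).
#' @export
select_model <- function(design, y, response = "y",
                         candidates = c("linear", "2FI", "quadratic"),
                         p_max = 0.05, r2_gap_max = 0.2, adeq_min = 4,
                         alpha_seq = 0.01) {
  order_all <- c("linear", "2FI", "quadratic")
  candidates <- order_all[order_all %in% candidates]
  fits <- list(); rows <- list()
  for (fam in candidates) {
    f <- try(rsm_fit(design, y, family = fam, response = response), silent = TRUE)
    if (inherits(f, "try-error")) next
    d <- try(rsm_diagnostics(f), silent = TRUE)
    if (inherits(d, "try-error")) next
    fits[[fam]] <- f
    rows[[fam]] <- tibble::tibble(
      family = fam, model_p = d$model_p, adj_r2 = d$adj_r2,
      pred_r2 = d$pred_r2, adeq_precision = d$adeq_precision,
      seq_p = NA_real_,
      qualifies = is.finite(d$model_p) && d$model_p < p_max &&
        (d$adj_r2 - d$pred_r2) < r2_gap_max && d$adeq_precision > adeq_min
    )
  }
  abort_if(length(fits) < 1, "no candidate family could be fitted")
  tab <- dplyr::bind_rows(rows)

  # sequential model sum of squares: F-test of each family's added terms
  # against the residual of the larger model
  fams <- names(fits)
  suggested <- fams[1]
  for (i in seq_along(fams)[-1]) {
    small <- fits[[fams[i - 1]]]; big <- fits[[fams[i]]]
    df_add <- big$n_terms - small$n_terms
    if (df_add <= 0) next
    fstat <- ((small$sse - big$sse) / df_add) / big$mse
    p_add <- stats::pf(fstat, df_add, big$n_obs - big$n_terms,
                       lower.tail = FALSE)
    tab$seq_p[tab$family == fams[i]] <- p_add
    if (is.finite(p_add) && p_add < alpha_seq) suggested <- fams[i]
  }

  best <- suggested
  if (!tab$qualifies[tab$family == suggested] && any(tab$qualifies)) {
    pool <- tab[tab$qualifies, ]
    best <- pool$family[order(-pool$pred_r2)][1]
  }
  structure(
    list(fit = fits[[best]], family = best,
         validated = tab$qualifies[tab$family == best],
         candidates = tab),
    class = "rsm_selection"
  )
}

#' @export
print.rsm_selection <- function(x, ...) {
  cat(sprintf("<rsm_selection> %s -> %s%s\n", x$fit$response, x$family,
              if (x$validated) "" else " (no family met the adequacy rules)"))
  print(x$candidates)
  invisible(x)
}
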