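# Polynomial terms over design factors, represented as integer exponent
# vectors (one exponent per factor). "AB" over two factors is c(1, 1),
# "A2" is c(2, 0). This makes exact reparameterization between coded and
# actual factors a mechanical binomial expansion.

term_label <- function(expo, labels) {
  if (all(expo == 0)) return("Intercept")
  parts <- character(0)
  for (i in seq_along(expo)) {
    if (expo[i] == 1) parts <- c(parts, labels[i])
    if (expo[i] >= 2) parts <- c(parts, paste0(labels[i], expo[i]))
  }
  paste(parts, collapse = "")
}

#' Term set of a response-surface model family
#'
#' @param family `"linear"` (intercept + main effects), `"2FI"` (adds all
#'   pairwise interactions) or `"quadratic"` (adds pure squares).
#' @param space A [factor_space()] giving the factors and their coded labels.
#' @return Named list of integer exponent vectors, one per term, in the
#'   conventional order intercept, main effects, interactions, squares.
#' @export
rsm_terms <- function(family = c("linear", "2FI", "quadratic"), space) {
  family <- match.arg(family)
  k <- nrow(space)
  terms <- list(rep(0L, k))
  for (i in seq_len(k)) {
    e <- rep(0L, k); e[i] <- 1L
    terms <- c(terms, list(e))
  }
  if (family %in% c("2FI", "quadratic") && k >= 2) {
    for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
      e <- rep(0L, k); e[i] <- 1L; e[j] <- 1L
      terms <- c(terms, list(e))
    }
  }
  if (family == "quadratic") {
    for (i in seq_len(k)) {
      e <- rep(0L, k); e[i] <- 2L
      terms <- c(terms, list(e))
    }
  }
  names(terms) <- vapply(terms, term_label, character(1), labels = space$coded)
  terms
}

term_order <- function(expo) sum(expo)

# Evaluate sum_t coef_t * prod_i X[, i]^expo_i for an n x k matrix X.
eval_terms <- function(coefs, terms, X) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  for (t in seq_along(terms)) {
    col <- rep(1, nrow(X))
    e <- terms[[t]]
    for (i in seq_along(e)) if (e[i] > 0) col <- col * X[, i]^e[i]
    out <- out + unname(coefs[t]) * col
  }
  unname(out)
}

# Model matrix of the term set on a coded (or actual) level matrix.
term_matrix <- function(terms, X) {
  X <- as.matrix(X)
  M <- matrix(1, nrow = nrow(X), ncol = length(terms),
              dimnames = list(NULL, names(terms)))
  for (t in seq_along(terms)) {
    e <- terms[[t]]
    for (i in seq_along(e)) if (e[i] > 0) M[, t] <- M[, t] * X[, i]^e[i]
  }
  M
}

# Exact polynomial reparameterization: substitute variable i <- a_i + b_i * w_i
# into each monomial and collect coefficients on the w basis. Returns a named
# coefficient vector over the closure of the input term set.
reparam_poly <- function(coefs, terms, a, b, labels) {
  acc <- new.env(parent = emptyenv())
  add <- function(expo, val) {
    key <- paste(expo, collapse = ",")
    acc[[key]] <- (if (is.null(acc[[key]])) 0 else acc[[key]]) + val
  }
  k <- length(a)
  for (t in seq_along(terms)) {
    e <- terms[[t]]
    # per-factor expansion of (a_i + b_i w_i)^{e_i}: list of (power, weight)
    per <- lapply(seq_len(k), function(i) {
      p <- e[i]
      j <- 0:p
      list(pow = j, w = choose(p, j) * a[i]^(p - j) * b[i]^j)
    })
    grid <- expand.grid(lapply(per, function(x) seq_along(x$pow)))
    for (r in seq_len(nrow(grid))) {
      expo <- integer(k); w <- coefs[t]
      for (i in seq_len(k)) {
        sel <- grid[r, i]
        expo[i] <- per[[i]]$pow[sel]
        w <- w * per[[i]]$w[sel]
      }
      add(expo, w)
    }
  }
  keys <- ls(acc)
  expos <- lapply(keys, function(kk) as.integer(strsplit(kk, ",")[[1]]))
  vals <- vapply(keys, function(kk) acc[[kk]], numeric(1))
  # canonical order: by degree; within a degree interactions before pure
  # powers, and earlier factors first
  wgt <- vapply(expos, function(e) sum(e * 100^rev(seq_along(e))), numeric(1))
  ord <- order(vapply(expos, term_order, numeric(1)),
               vapply(expos, max, numeric(1)),
               -wgt)
  out <- vals[ord]
  names(out) <- vapply(expos[ord], term_label, character(1), labels = labels)
  attr(out, "terms") <- stats::setNames(expos[ord], names(out))
  out
}

#' Re-express model coefficients between coded and actual factors
#'
#' Exact algebraic substitution of the affine coded/actual map of the factor
#' space into the polynomial (binomial expansion, coefficients collected), so
#' the two parameterizations predict identically at every point.
#'
#' @param coefs Named numeric coefficient vector.
#' @param terms Named list of exponent vectors matching `coefs` (e.g. from
#'   [rsm_terms()]).
#' @param space A [factor_space()].
#' @param direction `"coded_to_actual"` or `"actual_to_coded"`.
#' @return Named coefficient vector on the target basis, with the matching
#'   exponent-vector list in attribute `"terms"`.
#' @export
recode_coefficients <- function(coefs, terms, space,
                                direction = c("coded_to_actual", "actual_to_coded")) {
  direction <- match.arg(direction)
  if (direction == "coded_to_actual") {
    # coded u_i = -c_i/h_i + (1/h_i) x_i, result on actual basis x
    reparam_poly(coefs, terms, a = -space$center / space$half_range,
                 b = 1 / space$half_range, labels = paste0("X", seq_len(nrow(space))))
  } else {
    # actual x_i = c_i + h_i u_i, result on coded basis u
    reparam_poly(coefs, terms, a = space$center, b = space$half_range,
                 labels = space$coded)
  }
}
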