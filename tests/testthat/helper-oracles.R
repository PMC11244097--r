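# Independent oracles used to cross-check the package's own computations.

# PRESS by explicitly refitting with each observation left out, predicting it
# from the reduced fit (no hat-matrix shortcut anywhere).
loo_press_oracle <- function(design, y, family = "linear") {
  if (!is.data.frame(y)) {
    y <- tibble::tibble(run_id = design$run_id, value = as.numeric(y))
  }
  n <- nrow(y)
  errs <- vapply(seq_len(n), function(i) {
    fit_i <- rsm_fit(design, y[-i, ], family = family)
    row <- design[match(y$run_id[i], design$run_id), ]
    y$value[i] - predict(fit_i, row)
  }, numeric(1))
  sum(errs^2)
}

# Spearman rho by direct definition on another route: 1 - 6*sum(d^2)/(n^3-n)
# (valid without ties only).
spearman_untied_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n^3 - n)
}

# Exact permutation p-value for Spearman by full enumeration with explicit
# correlation calls (independent of the package's vectorized path).
spearman_perm_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  obs <- stats::cor(rx, ry)
  perms <- asplit(perms_matrix(length(y)), 1)
  vals <- vapply(perms, function(p) stats::cor(rx, ry[p]), numeric(1))
  mean(abs(vals) >= abs(obs) - 1e-12)
}

perms_matrix <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perms_matrix(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# Exact Mann-Whitney p by enumerating every group assignment and recomputing
# U from scratch for each.
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  u_of <- function(idx) {
    xs <- pooled[idx]; ys <- pooled[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * (N - n1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}

# Kruskal-Wallis H via the mean-rank formulation:
# H = (N - 1) * sum n_j (rbar_j - rbar)^2 / sum (r_i - rbar)^2
kw_meanrank_oracle <- function(values, groups) {
  r <- rank(values)
  rbar <- mean(r)
  num <- sum(tapply(r, groups, function(g) length(g) * (mean(g) - rbar)^2))
  den <- sum((r - rbar)^2)
  (length(values) - 1) * num / den
}

# Log-linearized first-order fit: regress log(1 - Q/Qinf) on t through the
# origin for known Qinf (cross-check of the nonlinear route).
loglinear_first_order_k <- function(times, cumulative, Qinf) {
  z <- log(1 - cumulative / Qinf)
  -sum(times * z) / sum(times^2)
}
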