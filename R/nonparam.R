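# Nonparametric toolkit built from first principles on midranks: Spearman
# correlation, Mann-Whitney and Kruskal-Wallis, with exact small-sample
# p-values by enumeration and tie-corrected large-sample approximations.

#' Midranks of a sample
#'
#' Ranks with ties sharing the average of the ranks they span; midranks
#' always sum to n(n+1)/2.
#'
#' @param x Numeric vector.
#' @return Numeric vector of midranks.
#' @export
midranks <- function(x) rank(x, ties.method = "average")

# all permutations of a vector, one per row (used for exact enumeration)
all_permutations <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1L, 1L))
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(v[i], all_permutations(v[-i]))
  }))
}

#' Spearman rank correlation with a tie-safe exact small-sample p-value
#'
#' rho is the Pearson correlation of the midranks of the two variables
#' (tie-safe by construction). The two-sided p-value uses the exact
#' permutation distribution of rho (all n! orderings) for n < 10 and the
#' t-approximation t = rho * sqrt((n - 2) / (1 - rho^2)) with n - 2 degrees
#' of freedom otherwise.
#'
#' @param x,y Numeric vectors of equal length, n >= 3.
#' @return An object of class `htest` with `estimate` (rho), `p.value` and
#'   the method used.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  abort_if(length(y) != n, "x and y must have equal length")
  abort_if(n < 3, "need n >= 3")
  abort_if(any(!is.finite(x)) || any(!is.finite(y)), "values must be finite")
  rx <- midranks(x); ry <- midranks(y)
  xc <- rx - mean(rx); yc <- ry - mean(ry)
  ssx <- sum(xc^2); ssy <- sum(yc^2)
  abort_if(ssx == 0 || ssy == 0, "zero rank variance (all values tied)")
  rho <- sum(xc * yc) / sqrt(ssx * ssy)

  if (n < 10) {
    P <- all_permutations(seq_len(n))
    rho_all <- (matrix(yc[P], nrow = nrow(P)) %*% xc) / sqrt(ssx * ssy)
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
    method <- "Spearman rank correlation (exact permutation)"
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
    method <- "Spearman rank correlation (t approximation)"
  }
  structure(list(statistic = c(S = sum((rx - ry)^2)), parameter = c(n = n),
                 estimate = c(rho = rho), p.value = min(p, 1),
                 method = method,
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

mw_u_from_ranks <- function(r, n1) {
  sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
}

#' Mann-Whitney U test for two independent samples
#'
#' U is computed from midrank sums (U for `x`; U + U' = n1 * n2 always). The
#' two-sided p-value is exact -- enumeration of all rank assignments -- when
#' n1 + n2 <= 12 and the pooled sample has no ties, and otherwise uses the
#' tie-corrected normal approximation without continuity correction.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return An object of class `htest` with `statistic` (U for `x`) and
#'   `p.value`.
#' @export
mann_whitney_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  abort_if(n1 < 1 || n2 < 1, "both samples must be non-empty")
  pooled <- c(x, y); N <- n1 + n2
  r <- midranks(pooled)
  U <- mw_u_from_ranks(r, n1)
  mu <- n1 * n2 / 2
  ties <- any(duplicated(pooled))

  if (N <= 12 && !ties) {
    combs <- utils::combn(N, n1)
    rr <- sort(r)
    U_all <- apply(combs, 2, function(idx) sum(rr[idx]) - n1 * (n1 + 1) / 2)
    p <- mean(abs(U_all - mu) >= abs(U - mu) - 1e-12)
    method <- "Mann-Whitney U test (exact)"
  } else {
    tab <- table(pooled)
    tie_term <- sum(tab^3 - tab) / (N * (N - 1))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term)
    if (sigma2 <= 0) {
      # every pooled value tied: U sits exactly at its null midpoint
      p <- 1
      method <- "Mann-Whitney U test (degenerate: all values tied)"
    } else {
      z <- (U - mu) / sqrt(sigma2)
      p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
      method <- "Mann-Whitney U test (tie-corrected normal approximation)"
    }
  }
  structure(list(statistic = c(U = U), parameter = c(n1 = n1, n2 = n2),
                 p.value = min(p, 1), method = method,
                 data.name = paste(deparse(substitute(x)), "and",
                                   deparse(substitute(y)))),
            class = "htest")
}

#' Kruskal-Wallis test for three or more independent samples
#'
#' Tie-corrected H statistic with a chi-square reference distribution on
#' g - 1 degrees of freedom.
#'
#' @param values Numeric vector of all observations, or a list of numeric
#'   group vectors (then `groups` is ignored).
#' @param groups Group labels, same length as `values`.
#' @return An object of class `htest` with `statistic` (H) and `p.value`.
#' @export
kruskal_wallis_test <- function(values, groups = NULL) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  abort_if(length(values) != length(groups), "values and groups length mismatch")
  g <- unique(groups)
  abort_if(length(g) < 3, "need at least 3 groups")
  abort_if(all(values == values[1]), "all values identical")
  N <- length(values)
  r <- midranks(values)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, sum)^2 / tapply(r, groups, length)) - 3 * (N + 1)
  tab <- table(values)
  correction <- 1 - sum(tab^3 - tab) / (N^3 - N)
  abort_if(correction <= 0, "tie correction degenerate")
  H <- H / correction
  df <- length(g) - 1
  p <- stats::pchisq(H, df, lower.tail = FALSE)
  structure(list(statistic = c(H = H), parameter = c(df = df),
                 p.value = p,
                 method = "Kruskal-Wallis test (tie-corrected, chi-square approximation)",
                 data.name = deparse(substitute(values))),
            class = "htest")
}
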