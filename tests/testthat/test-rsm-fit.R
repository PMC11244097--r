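des <- emulgel_design()
fs <- emulgel_factor_space()
d50_means <- subset(emulgel_particle_sizes(), percentile == "d50")$mean

test_that("least squares on the orthogonal design recovers the closed-form solution", {
  fit <- rsm_fit(des, d50_means, family = "linear", response = "d50")
  # orthogonal 3-level design: intercept = grand mean, slopes = contrast sums / 6
  expect_equal(unname(fit$coef_coded["Intercept"]), mean(d50_means))
  expect_equal(unname(fit$coef_coded["A"]), sum(des$coded_A * d50_means) / 6)
  expect_equal(unname(fit$coef_coded["B"]), sum(des$coded_B * d50_means) / 6)
  expect_equal(unname(round(fit$coef_coded, 4)), c(0.3839, -0.0370, -0.0893))
})

test_that("noiseless generated data are interpolated exactly and constants are flat", {
  truth <- c(2, 0.5, -1.2, 0.3, -0.7, 0.15)
  U <- as.matrix(des[, c("coded_A", "coded_B")])
  y <- truth[1] + truth[2] * U[, 1] + truth[3] * U[, 2] +
    truth[4] * U[, 1] * U[, 2] + truth[5] * U[, 1]^2 + truth[6] * U[, 2]^2
  # quadratic needs n >= p + 1 = 7: add a replicated centre observation
  y_rep <- tibble::tibble(run_id = c(des$run_id, "E-9"), value = c(y, y[9]))
  fit <- rsm_fit(des, y_rep, family = "quadratic")
  expect_equal(unname(fit$coef_coded), truth, tolerance = 1e-9)

  cfit <- rsm_fit(des, rep(3.7, 9), family = "linear")
  expect_equal(unname(cfit$coef_coded), c(3.7, 0, 0), tolerance = 1e-12)
})

test_that("replicate-level fits accept long tables and weight runs by replicates", {
  reps <- tibble::tibble(
    run_id = rep(des$run_id, each = 2),
    value = rep(d50_means, each = 2) + rep(c(-0.01, 0.01), 9))
  fit <- rsm_fit(des, reps, family = "linear")
  # balanced replicates at the run means leave the coefficients unchanged
  expect_equal(unname(fit$coef_coded["Intercept"]), mean(d50_means))
  expect_equal(fit$n_obs, 18)
  expect_error(rsm_fit(des, tibble::tibble(run_id = "E-99", value = 1)), "E-99")
})

test_that("rank-deficient model matrices fail with the collinear term named", {
  degenerate <- factor_space(c("u", "v"), c(0, 0), c(1, 1))
  d <- ccd_design(degenerate)
  d$coded_B <- d$coded_A   # force collinearity
  expect_error(rsm_fit(d, rnorm(9), family = "linear"), "collinear")
})

test_that("coded and actual parameterizations agree everywhere", {
  set.seed(42)
  for (fam in c("linear", "2FI", "quadratic")) {
    y <- rnorm(9, 5, 1)
    fit <- rsm_fit(des, y, family = fam)
    pts <- tibble::tibble(mineral_oil = runif(1000, 0, 70),
                          polysorbate_80 = runif(1000, -5, 15))
    expect_equal(predict(fit, pts, parameterization = "actual"),
                 predict(fit, pts, parameterization = "coded"),
                 tolerance = 1e-9)
  }
})

test_that("reparameterization is an exact involution on random coefficient vectors", {
  set.seed(7)
  terms <- rsm_terms("quadratic", fs)
  for (i in 1:20) {
    b <- setNames(rnorm(6), names(terms))
    a <- recode_coefficients(b, terms, fs, "coded_to_actual")
    b2 <- recode_coefficients(a, attr(a, "terms"), fs, "actual_to_coded")
    expect_equal(b2[names(terms)], b, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("hand-substituted linear recode matches the algebraic route", {
  terms <- rsm_terms("linear", fs)
  b <- c(Intercept = 0.38, A = -0.03, B = -0.09)
  a <- recode_coefficients(b, terms, fs, "coded_to_actual")
  # substitute A = (X1-30)/20, B = (X2-5)/5 by hand
  expect_equal(unname(a["Intercept"]), 0.38 + 0.03 * 30 / 20 + 0.09 * 5 / 5)
  expect_equal(unname(a["X1"]), -0.03 / 20)
  expect_equal(unname(a["X2"]), -0.09 / 5)
})

test_that("diagnostics match their definitions and the brute-force LOO oracle", {
  fit <- rsm_fit(des, d50_means, family = "linear", response = "d50")
  g <- glance(fit)
  expect_equal(g$r2, 1 - fit$sse / fit$sst)
  expect_equal(g$adj_r2, 1 - (1 - g$r2) * 8 / 6)
  expect_gt(g$press, fit$sse)
  expect_equal(g$press, loo_press_oracle(des, d50_means, "linear"),
               tolerance = 1e-10)
  expect_equal(g$pred_r2, 1 - g$press / fit$sst, tolerance = 1e-12)

  # quadratic responses too, at replicate level
  set.seed(11)
  y <- tibble::tibble(run_id = rep(des$run_id, each = 3),
                      value = rep(predict(emulgel_models()$tsolgel, des), each = 3) +
                        rnorm(27, 0, 0.3))
  qfit <- rsm_fit(des, y, family = "quadratic")
  expect_equal(glance(qfit)$press, loo_press_oracle(des, y, "quadratic"),
               tolerance = 1e-10)
})

test_that("noiseless linear data give unit R2 in all three flavours", {
  y <- 1 + 2 * des$coded_A - 3 * des$coded_B
  g <- glance(rsm_fit(des, y, family = "linear"))
  expect_equal(g$r2, 1)
  expect_equal(g$adj_r2, 1)
  expect_equal(g$pred_r2, 1)
})

test_that("a fit that interpolates some points refuses to report PRESS", {
  # two runs observed once each under a 3-term model: their leverages are 1,
  # so leave-one-out prediction is undefined there
  y <- tibble::tibble(run_id = c("E-1", "E-1", "E-2", "E-5"),
                      value = c(1, 1.1, 2, 3))
  fit <- rsm_fit(des, y, family = "linear")
  expect_error(rsm_diagnostics(fit), "PRESS undefined")
})

test_that("backward elimination honours the threshold and hierarchy", {
  # strong squares, dead interaction: AB leaves, A and B stay for hierarchy
  set.seed(3)
  U <- des[, c("coded_A", "coded_B")]
  y <- tibble::tibble(
    run_id = rep(des$run_id, each = 3),
    value = rep(5 + 0 * U$coded_A + 0 * U$coded_B + 0 * U$coded_A * U$coded_B +
                  2 * U$coded_A^2 + 2 * U$coded_B^2, each = 3) + rnorm(27, 0, 0.05))
  fit <- rsm_fit(des, y, family = "quadratic")
  pruned <- prune_terms(fit, threshold = 0.10)
  kept <- names(pruned$terms)
  expect_true(all(c("Intercept", "A", "B", "A2", "B2") %in% kept))
  expect_false("AB" %in% kept)

  # all-significant model is left untouched
  y2 <- tibble::tibble(
    run_id = rep(des$run_id, each = 3),
    value = rep(5 + 2 * U$coded_A - 3 * U$coded_B, each = 3) + rnorm(27, 0, 0.05))
  fit2 <- rsm_fit(des, y2, family = "linear")
  expect_equal(names(prune_terms(fit2)$terms), names(fit2$terms))
})

test_that("pruning strips an inert factor entirely when hierarchy allows", {
  # Y = 2 + 3A + tiny noise, quadratic start: selection keeps only A terms
  # With retention threshold 0.10 each of the four null terms survives
  # pruning with probability near 0.10, so the exact linear-in-A form is
  # reached in about 0.9^4 ~ 2/3 of worlds; the signal term must survive
  # always, and surviving null terms must be rare (near-nominal rate).
  hits <- 0; null_kept <- 0
  for (s in 1:60) {
    set.seed(s)
    y <- tibble::tibble(
      run_id = rep(des$run_id, each = 3),
      value = rep(2 + 3 * des$coded_A, each = 3) + rnorm(27, 0, 0.01))
    pruned <- prune_terms(rsm_fit(des, y, family = "quadratic"))
    kept <- names(pruned$terms)
    expect_true(all(c("Intercept", "A") %in% kept))
    if (setequal(kept, c("Intercept", "A"))) hits <- hits + 1
    null_kept <- null_kept + length(setdiff(kept, c("Intercept", "A")))
  }
  expect_gte(hits / 60, 0.45)
  # on average at most ~0.4 null terms kept per world (nominal expectation)
  expect_lte(null_kept / 60, 0.8)
})

test_that("family selection applies the three adequacy rules", {
  mods <- emulgel_models()
  set.seed(21)
  mk <- function(model, sd) {
    tibble::tibble(run_id = rep(des$run_id, each = 3),
                   value = rep(predict(model, des), each = 3) + rnorm(27, 0, sd))
  }
  sel_lin <- select_model(des, mk(mods$d50, 0.02), response = "d50")
  expect_equal(sel_lin$family, "linear")
  expect_true(sel_lin$validated)

  sel_quad <- select_model(des, mk(mods$tsolgel, 0.3), response = "tsolgel")
  expect_equal(sel_quad$family, "quadratic")
  expect_true(sel_quad$validated)

  noise_only <- tibble::tibble(run_id = rep(des$run_id, each = 3),
                               value = rnorm(27))
  sel_noise <- select_model(des, noise_only)
  expect_false(sel_noise$validated)
})

test_that("linear coefficient estimates do not move when AB enters the model", {
  set.seed(5)
  y <- rnorm(9, 10, 2)
  lin <- rsm_fit(des, y, family = "linear")
  tfi <- rsm_fit(des, y, family = "2FI")
  expect_equal(lin$coef_coded[c("A", "B")], tfi$coef_coded[c("A", "B")],
               tolerance = 1e-12)
})
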