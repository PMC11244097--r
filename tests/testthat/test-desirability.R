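test_that("individual desirability implements the Derringer-Suich ramps", {
  up <- criterion("y", "maximize", low = 2, high = 10)
  expect_equal(desirability(10, up), 1)
  expect_equal(desirability(2, up), 0)
  expect_equal(desirability(6, up), 0.5)
  expect_equal(desirability(c(-5, 50), up), c(0, 1))  # clipped outside bounds
  # weight reshapes after clipping
  expect_equal(desirability(6, criterion("y", "maximize", low = 2, high = 10,
                                         weight = 2)), 0.25)
  dn <- criterion("y", "minimize", low = 2, high = 10)
  expect_equal(desirability(2, dn), 1)
  expect_equal(desirability(10, dn), 0)
  tg <- criterion("y", "target", low = 0, high = 10, target = 4)
  expect_equal(desirability(4, tg), 1)
  expect_equal(desirability(2, tg), 0.5)
  expect_equal(desirability(7, tg), 0.5)
  expect_equal(desirability(c(-1, 11), tg), c(0, 0))
  rg <- criterion("y", "in_range", low = 1, high = 3)
  expect_equal(desirability(c(0, 2, 4), rg), c(0, 1, 0))
  expect_error(desirability(1, criterion("y", "maximize", low = 3, high = 3)))
})

test_that("desirability is monotone in the goal direction and affine-equivariant", {
  y <- seq(-2, 15, length.out = 200)
  up <- desirability(y, criterion("y", "maximize", low = 1, high = 9, weight = 1.7))
  expect_true(all(diff(up) >= 0))
  dn <- desirability(y, criterion("y", "minimize", low = 1, high = 9, weight = 0.6))
  expect_true(all(diff(dn) <= 0))
  # rescaling response and bounds together leaves d unchanged
  a <- 3.7; b <- -2.1
  up2 <- desirability(a * y + b,
                      criterion("y", "maximize", low = a * 1 + b, high = a * 9 + b,
                                weight = 1.7))
  expect_equal(up2, up, tolerance = 1e-12)
})

test_that("composite desirability is the importance-weighted geometric mean", {
  expect_equal(composite_desirability(c(0.25, 1)), 0.5)
  expect_equal(composite_desirability(c(0.4, 0.5, 0.9)), (0.4 * 0.5 * 0.9)^(1/3))
  expect_equal(composite_desirability(c(0.2, 0, 0.9)), 0)
  # importance weighting: r = (2, 1) => (d1^2 d2)^(1/3)
  expect_equal(composite_desirability(c(0.5, 0.8), importance = c(2, 1)),
               (0.5^2 * 0.8)^(1/3))
  expect_error(composite_desirability(c(0.5, 1.2)))
})

test_that("the optimizer finds boundary and closed-form interior optima", {
  fs <- emulgel_factor_space()
  des <- emulgel_design()
  inc <- rsm_model("y", fs, "linear", coef_coded = c(5, 2, 0))
  opt <- optimize_desirability(list(y = inc), list(criterion("y", "maximize")),
                               fs, des, seed = 1)
  expect_equal(unname(opt$factors["mineral_oil"]), 50, tolerance = 1e-6)

  # concave quadratic: stationary point at A = 0.25, B = -0.2 in coded units
  conc <- rsm_model("y", fs, "quadratic",
                    coef_coded = c(10, 0.5, -0.4, 0, -1, -1))
  # bounds wide enough that d is strictly increasing in y at the optimum
  opt2 <- optimize_desirability(
    list(y = conc), list(criterion("y", "maximize", low = 0, high = 20)),
    fs, des, seed = 1)
  expect_equal(unname(opt2$factors), c(30 + 0.25 * 20, 5 - 0.2 * 5),
               tolerance = 1e-4)
  expect_equal(opt2$D, predict(conc, matrix(opt2$factors, nrow = 1)) / 20,
               tolerance = 1e-9)
})

test_that("conflicting criteria cap D and disjoint windows are flagged degenerate", {
  fs <- emulgel_factor_space()
  des <- emulgel_design()
  m <- emulgel_models()$flux
  # maximize and minimize the same response over shared bounds: the product
  # d (1 - d) peaks at the midpoint, so D = sqrt(1/4) = 1/2 and no better
  opt <- optimize_desirability(
    list(flux = m),
    list(criterion("flux", "maximize"), criterion("flux", "minimize")),
    fs, des, seed = 1, n_starts = 2)
  expect_false(opt$degenerate)
  expect_equal(opt$D, 0.5, tolerance = 1e-6)
  # two in_range windows that no prediction can satisfy at once: D = 0
  # everywhere, flagged degenerate
  opt0 <- optimize_desirability(
    list(flux = m),
    list(criterion("flux", "in_range", low = 0, high = 1),
         criterion("flux", "in_range", low = 2, high = 3)),
    fs, des, seed = 1, n_starts = 2)
  expect_true(opt0$degenerate)
  expect_equal(opt0$D, 0)
})

test_that("optimization is deterministic given a seed and robust to start count", {
  fs <- emulgel_factor_space()
  des <- emulgel_design()
  mods <- emulgel_models()[c("flux", "tsolgel", "d50")]
  crit <- list(criterion("flux", "maximize"), criterion("tsolgel", "minimize"),
               criterion("d50", "minimize"))
  o1 <- optimize_desirability(mods, crit, fs, des, seed = 11)
  o2 <- optimize_desirability(mods, crit, fs, des, seed = 11)
  expect_identical(o1$factors, o2$factors)
  expect_identical(o1$D, o2$D)
  # pure grid (no random starts) agrees with multistart to 1e-4 in D
  o3 <- optimize_desirability(mods, crit, fs, des, n_starts = 0)
  expect_lt(abs(o3$D - o1$D), 1e-4)
  # composite reported is the geometric mean of the reported individuals
  expect_equal(o1$D, composite_desirability(o1$predictions$desirability),
               tolerance = 1e-9)
})

test_that("missing models and unresolvable bounds are caught", {
  fs <- emulgel_factor_space()
  expect_error(optimize_desirability(list(), list(criterion("flux", "maximize")),
                                     fs, emulgel_design()), "flux")
  expect_error(
    optimize_desirability(emulgel_models()["flux"],
                          list(criterion("flux", "maximize")), fs,
                          design = NULL),
    "no design")
})
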