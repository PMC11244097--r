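test_that("Spearman rho handles monotone data, ties and known hand values", {
  expect_equal(unname(spearman_test(1:8, (1:8)^3)$estimate), 1)
  expect_equal(unname(spearman_test(1:8, -(1:8))$estimate), -1)

  # design polysorbate levels vs reported mean droplet size: -54/sqrt(3240)
  des <- emulgel_design()
  d50 <- subset(emulgel_particle_sizes(), percentile == "d50")$mean
  st <- spearman_test(des$polysorbate_80, d50)
  expect_equal(unname(st$estimate), -54 / sqrt(3240), tolerance = 1e-12)
  expect_lt(st$p.value, 0.01)

  # invariance under strictly monotone transforms
  set.seed(2)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- spearman_test(x, y)$estimate
  expect_equal(spearman_test(exp(x), y)$estimate, r0)
  expect_equal(spearman_test(x, y^3 + 5 * y)$estimate, r0)

  # untied rho agrees with the 1 - 6 sum d^2 / (n^3 - n) formula
  expect_equal(unname(spearman_test(x, y)$estimate),
               spearman_untied_oracle(x, y))
  # and with the reference implementation
  expect_equal(unname(spearman_test(x, y)$estimate),
               unname(cor.test(x, y, method = "spearman")$estimate))

  expect_error(spearman_test(rep(1, 5), 1:5), "zero rank variance")
})

test_that("exact Spearman permutation p matches full enumeration at n = 5", {
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(5); y <- rnorm(5)
    expect_equal(spearman_test(x, y)$p.value, spearman_perm_oracle(x, y))
  }
})

test_that("Mann-Whitney U comes from midrank sums with U + U' = n1 n2", {
  expect_equal(unname(mann_whitney_test(1:3, c(10, 20, 30))$statistic), 0)
  expect_equal(unname(mann_whitney_test(c(10, 20, 30), 1:3)$statistic), 9)
  # identical singletons land on the tie midpoint
  expect_equal(unname(mann_whitney_test(5, 5)$statistic), 0.5)
  set.seed(13)
  for (i in 1:10) {
    x <- rnorm(4); y <- rnorm(6)
    u1 <- unname(mann_whitney_test(x, y)$statistic)
    u2 <- unname(mann_whitney_test(y, x)$statistic)
    expect_equal(u1 + u2, length(x) * length(y))
  }
})

test_that("exact Mann-Whitney p matches assignment enumeration at (3, 3)", {
  set.seed(17)
  for (i in 1:5) {
    x <- rnorm(3); y <- rnorm(3)
    expect_equal(mann_whitney_test(x, y)$p.value, mw_enum_oracle(x, y))
  }
  # reference implementation agrees where it is also exact
  x <- c(1.2, 3.4, 0.8); y <- c(2.2, 5.1, 4.4)
  expect_equal(mann_whitney_test(x, y)$p.value,
               wilcox.test(x, y, exact = TRUE)$p.value)
})

test_that("Kruskal-Wallis H matches hand computation and the mean-rank oracle", {
  kw <- kruskal_wallis_test(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(kw$statistic), 32 / 7)  # 12/(6*7) * 179/2 - 21
  expect_gt(kw$p.value, 0.05)                 # n = 6 cannot reach 0.05 here
  expect_equal(unname(kw$statistic),
               kw_meanrank_oracle(1:6, rep(1:3, each = 2)))

  set.seed(31)
  for (i in 1:50) {
    v <- sample(1:8, 12, replace = TRUE)  # ties on purpose
    g <- rep(1:3, each = 4)
    expect_equal(unname(kruskal_wallis_test(v, g)$statistic),
                 unname(kruskal.test(v, g)$statistic), tolerance = 1e-12)
  }
  expect_error(kruskal_wallis_test(rep(2, 9), rep(1:3, 3)), "identical")
  expect_error(kruskal_wallis_test(1:4, c(1, 1, 2, 2)), "3 groups")
})

test_that("identically drawn groups give near-null Kruskal-Wallis behaviour", {
  set.seed(5)
  p <- vapply(1:60, function(i) {
    kruskal_wallis_test(rnorm(30), rep(1:3, each = 10))$p.value
  }, numeric(1))
  expect_gt(median(p), 0.3)
})

test_that("all three tests hold the 0.05 level over seeded null simulations", {
  set.seed(20260926)
  n_sim <- 2000
  rej <- c(spearman = 0, mw = 0, kw = 0)
  for (i in seq_len(n_sim)) {
    x <- rnorm(10); y <- rnorm(10); z <- rnorm(10)
    if (spearman_test(x, y)$p.value < 0.05) rej["spearman"] <- rej["spearman"] + 1
    if (mann_whitney_test(x, y)$p.value < 0.05) rej["mw"] <- rej["mw"] + 1
    if (kruskal_wallis_test(c(x, y, z), rep(1:3, each = 10))$p.value < 0.05) {
      rej["kw"] <- rej["kw"] + 1
    }
  }
  rates <- rej / n_sim
  expect_true(all(rates >= 0.03 & rates <= 0.07),
              info = paste(names(rates), round(rates, 4), collapse = ", "))
})
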