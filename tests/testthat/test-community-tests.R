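test_that("permanova agrees with the reference implementation and detects no signal in identical clouds", {
  set.seed(42)
  X <- matrix(rnorm(60), 30, 2)
  g <- factor(rep(c("a", "b", "c"), each = 10))
  X[g == "b", ] <- X[g == "b", ] + 1
  r <- permanova(X, g, n_perm = 499, seed = 7)
  ref <- vegan::adonis2(stats::dist(X) ~ g, permutations = 499)
  expect_equal(r$F, ref$F[1], tolerance = 1e-10)
  expect_equal(r$R2, ref$R2[1], tolerance = 1e-10)
  expect_lt(r$p, 0.05)

  # two identical point clouds: no between-group variance
  Y <- rbind(X[1:10, ], X[1:10, ])
  g2 <- factor(rep(c("a", "b"), each = 10))
  r2 <- permanova(Y, g2, n_perm = 199, seed = 1)
  expect_lt(r2$R2, 1e-10)
  expect_gt(r2$p, 0.5)

  expect_error(permanova(X, factor(rep("a", 30))), "2 groups")
})

test_that("permanova F is invariant to rigid rotation and translation", {
  set.seed(9)
  X <- matrix(rnorm(50), 25, 2)
  g <- factor(rep(c("a", "b"), length.out = 25))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Xr <- sweep(X %*% R, 2, c(3, -5), "+")
  expect_equal(permanova(X, g, n_perm = 0)$F, permanova(Xr, g, n_perm = 0)$F,
               tolerance = 1e-10)
})

test_that("pairwise permanovas cover all level pairs", {
  set.seed(2)
  X <- matrix(rnorm(90), 45, 2)
  g <- factor(rep(c("a", "b", "c"), each = 15))
  X[g == "c", 1] <- X[g == "c", 1] + 3
  pw <- pairwise_permanova(X, g, n_perm = 199, seed = 5)
  expect_identical(nrow(pw), 3L)
  expect_setequal(paste(pw$group1, pw$group2), c("a b", "a c", "b c"))
  expect_gt(pw$R2[pw$group1 == "a" & pw$group2 == "c"], 0.2)
  expect_lt(pw$R2[pw$group1 == "a" & pw$group2 == "b"], 0.1)
})

test_that("permdisp flags inflated dispersion and not centroid shifts", {
  set.seed(31)
  n <- 50
  base <- matrix(rnorm(2 * n), n, 2)
  # equal shape, shifted centroid: dispersion must not differ
  X <- rbind(base, sweep(matrix(rnorm(2 * n), n, 2), 2, c(4, 0), "+"))
  g <- factor(rep(c("a", "b"), each = n))
  r <- permdisp(X, g, n_perm = 199, seed = 3)
  expect_gt(r$p, 0.05)

  # one group scaled x3: dispersion differs
  X2 <- rbind(base, 3 * matrix(rnorm(2 * n), n, 2))
  r2 <- permdisp(X2, g, n_perm = 199, seed = 3)
  expect_lt(r2$p, 0.05)
  expect_identical(dim(r2$pairwise), c(1L, 4L))

  # identical data in all groups: F = 0
  X3 <- rbind(base, base)
  r3 <- permdisp(X3, g, n_perm = 99, seed = 1)
  expect_lt(r3$F, 1e-10)
})

test_that("simulated-p chi-square matches closed forms and margin properties", {
  perfect <- matrix(c(10, 0, 0, 10), 2, 2)
  r <- chi_square_sim(perfect, B = 2000, seed = 1)
  expect_equal(r$statistic, 20)
  expect_lt(r$p_sim, 0.01)

  indep <- matrix(5, 2, 2)
  r2 <- chi_square_sim(indep, B = 500, seed = 1)
  expect_equal(r2$statistic, 0)
  expect_true(all(r2$SR == 0))

  set.seed(8)
  tab <- matrix(rpois(12, 30), 3, 4)
  r3 <- chi_square_sim(tab, B = 500, seed = 2)
  # chi-square statistic equals the direct O/E computation
  expect_equal(r3$statistic, sum((r3$observed - r3$expected)^2 / r3$expected))
  # expected table preserves margins; O - E sums to zero per row and column
  expect_equal(rowSums(r3$expected), rowSums(tab), ignore_attr = TRUE)
  expect_equal(unname(rowSums(r3$observed - r3$expected)), rep(0, 3))
  expect_equal(unname(colSums(r3$observed - r3$expected)), rep(0, 4))
  # pearson-mode residuals are (O-E)/sqrt(E)
  r4 <- chi_square_sim(tab, B = 500, seed = 2, residuals = "pearson")
  expect_equal(unclass(r4$SR), (r3$observed - r3$expected) / sqrt(r3$expected),
               ignore_attr = TRUE)

  # Monte-Carlo p agrees with the asymptotic p for large balanced counts
  big <- matrix(c(60, 40, 40, 60), 2, 2)
  r5 <- chi_square_sim(big, B = 1e4, seed = 3)
  asym <- stats::chisq.test(big, correct = FALSE)$p.value
  expect_equal(r5$p_sim, asym, tolerance = 0.015)

  withzero <- rbind(tab, 0)
  expect_warning(chi_square_sim(withzero, B = 500, seed = 1), "zero-margin")
})

test_that("permutation p-values are uniform under label exchangeability", {
  set.seed(77)
  ps <- replicate(300, {
    X <- matrix(rnorm(40), 20, 2)
    permanova(X, factor(rep(c("a", "b"), each = 10)), n_perm = 99)$p
  })
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
  expect_true(mean(ps <= 0.05) >= 0.02 && mean(ps <= 0.05) <= 0.09)
})
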