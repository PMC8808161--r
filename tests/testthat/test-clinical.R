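test_that("Kruskal-Wallis behaves at degenerate and exact-permutation cases", {
  same <- list(c(1, 2, 3), c(1, 2, 3))
  res <- kruskalWallis(same)
  expect_equal(res$H, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  # exact permutation null for {1,2,3} vs {4,5,6}: all 20 label assignments
  g <- kruskalWallis(list(c(1, 2, 3), c(4, 5, 6)))
  pooled <- 1:6
  combos <- utils::combn(6, 3)
  hs <- apply(combos, 2, function(idx)
    kruskalWallis(list(pooled[idx], pooled[-idx]))$H)
  pExact <- mean(hs >= g$H - 1e-12)
  expect_equal(pExact, 2 / 20)  # only the two extreme splits reach H
  # the chi-squared approximation agrees with the permutation tail to its
  # usual small-sample accuracy
  expect_lt(abs(g$p - pExact), 0.06)

  # invariance under monotone transforms of the pooled data
  a <- list(rnorm(10), rnorm(8) + 1, rnorm(9))
  expect_equal(kruskalWallis(a)$H,
               kruskalWallis(lapply(a, function(v) exp(v)))$H,
               tolerance = 1e-12)
  expect_error(kruskalWallis(list(1:3)), "2 groups")
})

test_that("Dunn's post-hoc matches the hand formula and is order-symmetric", {
  groups <- list(a = c(1, 3, 5), b = c(2, 4, 6), c = c(20, 25, 30))
  res <- dunnPosthoc(groups)

  # hand computation: pooled ranks, tie-corrected variance
  pooled <- unlist(groups)
  N <- length(pooled)
  r <- rank(pooled)
  rb <- tapply(r, rep(1:3, each = 3), mean)
  ties <- table(pooled)
  tt <- sum(ties^3 - ties) / (12 * (N - 1))
  sig <- sqrt((N * (N + 1) / 12 - tt) * (1 / 3 + 1 / 3))
  zab <- (rb[1] - rb[2]) / sig
  expect_equal(res$z[res$group_a == "a" & res$group_b == "b"], unname(zab),
               tolerance = 1e-9)
  expect_equal(res$p[res$group_a == "a" & res$group_b == "b"],
               unname(2 * pnorm(-abs(zab))), tolerance = 1e-9)
  # two similar groups among three: their pairwise p is large
  expect_gt(res$p[res$group_a == "a" & res$group_b == "b"], 0.5)
  expect_lt(res$p[res$group_a == "a" & res$group_b == "c"], 0.05)

  # reordering groups flips signs but not magnitudes
  res2 <- dunnPosthoc(groups[c(2, 1, 3)])
  expect_equal(abs(res2$z[res2$group_a == "b" & res2$group_b == "a"]),
               abs(res$z[res$group_a == "a" & res$group_b == "b"]),
               tolerance = 1e-12)
  withBH <- dunnPosthoc(groups, p_adjust = "bh")
  expect_true(all(withBH$adj_p >= withBH$p))
  expect_error(dunnPosthoc(groups[1:2]), "3 groups")
})

test_that("chi-squared matches independence and the 2x2 closed form", {
  # proportional to the outer product of its margins: X2 = 0
  tab <- matrix(c(12L, 24L, 6L, 12L), 2)
  res <- chiSquared(tab)
  expect_equal(res$X2, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)

  t22 <- matrix(c(12L, 5L, 7L, 16L), 2)
  a <- t22[1, 1]; b <- t22[1, 2]; cc <- t22[2, 1]; d <- t22[2, 2]
  closed <- sum(t22) * (a * d - b * cc)^2 /
    ((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(chiSquared(t22)$X2, closed, tolerance = 1e-12)
  expect_true(is.numeric(chiSquared(t22, fisher = TRUE)$p))
  expect_error(chiSquared(matrix(c(0L, 0L, 3L, 4L), 2, byrow = TRUE)),
               "marginal")
  expect_error(chiSquared(matrix(1:4, 1)), "2x2")
})

test_that("proportion ratios are unit-consistent and reciprocal", {
  expect_equal(proportionRatio(5, 50, 10, 100), 1.0)
  r <- proportionRatio(c(23, 13), c(81, 45), c(8, 5, 1), c(54, 56, 24))
  expect_equal(r * proportionRatio(c(8, 5, 1), c(54, 56, 24),
                                   c(23, 13), c(81, 45)), 1, tolerance = 1e-12)
  expect_warning(rInf <- proportionRatio(5, 10, 0, 10), "infinite")
  expect_equal(rInf, Inf)
  expect_error(proportionRatio(1, 0, 1, 5), "positive")
})

test_that("Kaplan-Meier matches the product-limit formula", {
  # no censoring: empirical survival function
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  # all censored: flat at 1
  kmC <- kmEstimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(kmC$survival == 1))
  # mixed fixture, hand-applied product limit:
  # t=1: 5 at risk, 1 event -> 4/5; t=2: 4 at risk, 1 event (1 censored at 2)
  # -> 4/5 * 3/4 = 3/5; t=3: 2 at risk, 1 event -> 3/5 * 1/2 = 3/10
  km2 <- kmEstimate(c(1, 2, 2, 3, 4), c(1, 1, 0, 1, 0))
  ev <- km2[km2$n_event > 0, ]
  expect_equal(ev$survival, c(4 / 5, 4 / 5 * 3 / 4, 4 / 5 * 3 / 4 * 1 / 2))
  expect_true(all(diff(km2$survival) <= 1e-12))
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("log-rank is symmetric, null-calibrated, and matches permutations", {
  t1 <- c(2, 4, 6, 8, 10, 12, 14, 16); e1 <- c(1, 1, 0, 1, 1, 1, 0, 1)
  t2 <- c(1, 2, 3, 4, 5, 6, 7, 9); e2 <- c(1, 1, 1, 0, 1, 1, 1, 1)
  a <- logRank(t1, e1, t2, e2)
  b <- logRank(t2, e2, t1, e1)
  expect_equal(a$X2, b$X2, tolerance = 1e-9)

  same <- logRank(t1, e1, t1, e1)
  expect_lt(same$X2, 1e-9)
  expect_gt(same$p, 0.99)

  # Monte-Carlo permutation oracle
  times <- c(t1, t2); events <- c(e1, e2)
  set.seed(61)
  nullX2 <- replicate(5000, {
    idx <- sample(16, 8)
    logRank(times[idx], events[idx], times[-idx], events[-idx])$X2
  })
  pPerm <- mean(nullX2 >= a$X2 - 1e-12)
  expect_lt(abs(a$p - pPerm), 3 * sqrt(pPerm * (1 - pPerm) / 5000) + 0.02)
  expect_error(logRank(numeric(), numeric(), t1, e1), "nonempty")
  expect_error(logRank(c(1, 2), c(0, 0), c(3, 4), c(0, 0)), "undefined|events")
})

test_that("KM curve with exponential data integrates to the truncated mean", {
  set.seed(62)
  t <- rexp(4000, rate = 0.2)
  km <- kmEstimate(pmin(t, 20), as.integer(t <= 20))
  # integral of S(t) over [0, horizon] equals E[min(T, horizon)]
  grid <- c(0, km$time[km$time <= 20])
  sv <- c(1, km$survival[km$time <= 20])
  integral <- sum(diff(c(grid, 20)) * sv)
  expect_lt(abs(integral - mean(pmin(t, 20))) / mean(pmin(t, 20)), 0.02)
})
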