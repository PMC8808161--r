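test_that("size factors obey symmetry, scaling, and the direct formula", {
  # identical samples -> all factors 1
  k <- matrix(rep(c(5L, 10L, 20L), 4), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  expect_equal(unname(computeSizeFactors(k)), rep(1, 4))

  # doubling one sample: factors (1/sqrt(2), sqrt(2)) after rescaling
  k2 <- cbind(s1 = c(4L, 8L, 12L), s2 = c(8L, 16L, 24L))
  rownames(k2) <- paste0("g", 1:3)
  expect_equal(unname(computeSizeFactors(k2)), c(1 / sqrt(2), sqrt(2)))

  # random NB matrix vs an independently coded median-of-ratios oracle
  set.seed(9)
  k3 <- matrix(rnbinom(300, mu = 50, size = 5), 50, 6,
               dimnames = list(paste0("g", 1:50), paste0("s", 1:6)))
  oracle <- local({
    geo <- exp(rowMeans(log(k3)))
    use <- geo > 0 & is.finite(geo)
    raw <- apply(k3, 2, function(col) median(col[use] / geo[use]))
    raw / exp(mean(log(raw)))
  })
  expect_equal(computeSizeFactors(k3), oracle, tolerance = 1e-12)

  # scale equivariance: multiplying sample j's counts by c multiplies its
  # factor by c once the geometric-mean-1 rescaling is undone
  k4 <- k3
  k4[, 2] <- k4[, 2] * 3L
  f3 <- computeSizeFactors(k3); f4 <- computeSizeFactors(k4)
  expect_equal(unname((f4 / f3) / exp(mean(log(f4 / f3))))[2] /
                 unname((f4 / f3) / exp(mean(log(f4 / f3))))[1], 3,
               tolerance = 1e-9)

  expect_error(computeSizeFactors(diag(0L, 3)), "no gene")
})

test_that("log2 normalization maps zeros to zero and is scale invariant", {
  k <- matrix(c(0L, 4L, 8L, 2L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  x <- normalizeLog2(k, factors = c(1, 1))
  expect_equal(x["g1", "s1"], 0)
  # doubling a sample's counts and its factor leaves its column unchanged
  k2 <- k; k2[, 2] <- k2[, 2] * 2L
  x2 <- normalizeLog2(k2, factors = c(1, 2))
  expect_equal(x2[, 2], x[, 2])
  # monotone in the count for fixed factor
  expect_true(all(diff(normalizeLog2(matrix(c(0L, 1L, 5L, 50L), 4, 1,
    dimnames = list(paste0("g", 1:4), "s1")), factors = 1)) > 0))
  expect_error(normalizeLog2(k, factors = c(1, 1, 1)), "samples")
})

test_that("severity groups follow the SOFA cut-offs", {
  expect_equal(as.character(assignSeverity(5L)), "High")
  expect_equal(as.character(assignSeverity(2L)), "Intermediate")
  expect_equal(as.character(assignSeverity(0L)), "Low")
  expect_equal(as.character(assignSeverity(c(24L, 4L, 1L))),
               c("High", "Intermediate", "Low"))
  expect_true(is.na(assignSeverity(NA_integer_)))
  expect_error(assignSeverity(25L), "0, 24")
})

test_that("BH adjustment matches the step-up formula and its properties", {
  expect_equal(bhAdjust(0.01), 0.01)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(4)
  p <- runif(50)
  adj <- bhAdjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  # independently coded step-up oracle
  oracle <- local({
    m <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(m / (m:1) * p[o]))[ro]
  })
  expect_equal(adj, oracle, tolerance = 1e-12)
  expect_error(bhAdjust(c(0.1, 1.2)), "0, 1")
})

test_that("NB Wald test is calibrated under the null", {
  set.seed(21)
  n <- 50
  k <- matrix(rnbinom(1500 * 2 * n, mu = 60, size = 1 / 0.15), 1500, 2 * n,
              dimnames = list(sprintf("g%04d", 1:1500),
                              sprintf("s%03d", seq_len(2 * n))))
  det <- nbWaldDE(k, colnames(k)[1:n], colnames(k)[(n + 1):(2 * n)])
  expect_lt(median(abs(det$log2fc)), 0.1)
  expect_gt(ks.test(det$p, "punif")$p.value, 0.001)
})

test_that("NB Wald test recovers a planted two-fold change", {
  set.seed(22)
  n <- 50
  mu <- matrix(80, 300, 2 * n)
  mu[1:5, 1:n] <- 160  # two-fold up in group A, sparse among null genes
  k <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.02), nrow(mu),
              dimnames = list(sprintf("g%03d", 1:300),
                              sprintf("s%03d", seq_len(2 * n))))
  det <- nbWaldDE(k, colnames(k)[1:n], colnames(k)[(n + 1):(2 * n)])
  fc <- 2^det$log2fc[match(sprintf("g%03d", 1:5), det$gene_id)]
  expect_true(all(fc > 1.8 & fc < 2.2))
  expect_true(all(det$adj_p[match(sprintf("g%03d", 1:5), det$gene_id)] < 0.05))
})

test_that("NB Wald test drops all-zero genes and is antisymmetric", {
  set.seed(23)
  k <- matrix(rnbinom(200, mu = 30, size = 5), 20, 10,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  k[3, ] <- 0L
  a <- colnames(k)[1:5]; b <- colnames(k)[6:10]
  det <- nbWaldDE(k, a, b)
  expect_false("g3" %in% det$gene_id)
  expect_identical(attr(det, "dropped"), "g3")
  rev <- nbWaldDE(k, b, a)
  expect_equal(det$log2fc, -rev$log2fc, tolerance = 1e-8)
  expect_equal(det$p, rev$p, tolerance = 1e-8)
  expect_error(nbWaldDE(k, a, a), "disjoint")
  expect_error(nbWaldDE(k, a[1:2], b), "3 samples")
})

test_that("DE filtering is inclusive at thresholds and matches a row scan", {
  det <- makeDETable(paste0("g", 1:5),
                     log2fc = c(log2(1.25), 1, -1, 0.1, 2),
                     adj_p = c(0.05, 0.01, 0.01, 0.01, 0.2))
  # fold exactly 1.25 with adj_p exactly 0.05 is retained
  expect_true("g1" %in% filterDE(det, 1.25, direction = "up"))
  # direction = up excludes all downregulated genes
  expect_false("g3" %in% filterDE(det, 1.25, direction = "up"))
  expect_true("g3" %in% filterDE(det, 1.25, direction = "both"))
  # insignificant adj_p excluded
  expect_false("g5" %in% filterDE(det, 1.25, direction = "up"))
  expect_error(filterDE(det, 0.8), "min_fold")

  set.seed(31)
  big <- makeDETable(sprintf("g%03d", 1:200), log2fc = rnorm(200),
                     adj_p = runif(200))
  got <- filterDE(big, 1.5, 0.1, "both")
  oracle <- big$gene_id[big$adj_p <= 0.1 &
                          (2^big$log2fc >= 1.5 | 2^big$log2fc <= 1 / 1.5)]
  expect_setequal(got, oracle)
})

test_that("per-endotype DE mirrors for two classes and recovers markers", {
  sc <- smallCohort()
  k <- SummarizedExperiment::assay(sc, "counts")
  st <- sampleTable(sc)
  disc <- st$sample_id[st$cohort == "ER_discovery"]
  labels <- stats::setNames(st$endotype[match(disc, st$sample_id)], disc)

  # two-class case: tables are sign-mirrored
  two <- stats::setNames(ifelse(labels %in% c("E1", "E2"), "A", "B"), disc)
  det2 <- perEndotypeDE(k[, disc], two)
  expect_equal(det2$A$log2fc, -det2$B$log2fc, tolerance = 1e-8)

  # planted markers significantly upregulated in their own endotype's table
  det <- perEndotypeDE(k[, disc], labels)
  gt <- groundTruth(sc)
  hit <- unlist(lapply(paste0("E", 1:5), function(e) {
    d <- det[[e]]
    rows <- match(gt$markerGenes[[e]], d$gene_id)
    d$log2fc[rows] > 0 & d$adj_p[rows] <= 0.05
  }))
  expect_gt(mean(hit, na.rm = TRUE), 0.95)
  expect_error(perEndotypeDE(k[, disc], labels[1:4]), "3 samples")
})
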