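test_that("unique marker extraction removes shared genes and caps the sets", {
  detA <- makeDETable(paste0("g", 1:6),
                      log2fc = c(3, 2.5, 2, 1.5, 1.2, -2),
                      adj_p = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.01))
  detB <- makeDETable(paste0("g", 1:6),
                      log2fc = c(-1, 2.2, -1, -1, -1, 3),
                      adj_p = c(0.5, 0.01, 0.5, 0.5, 0.5, 0.01))
  sets <- uniqueUpregulatedMarkers(list(A = detA, B = detB), min_fold = 1.5,
                                   cap = 200)
  # g2 is significantly upregulated in both endotypes: excluded everywhere
  expect_false("g2" %in% unlist(sets))
  # downregulated genes never enter a marker set
  expect_false("g6" %in% sets$A)
  expect_true("g6" %in% sets$B)
  # survivors ranked by descending fold change (g5: 2^1.2 = 2.3 >= 1.5)
  expect_equal(as.character(sets$A), c("g1", "g3", "g4", "g5"))
  expect_length(intersect(sets$A, sets$B), 0)

  capped <- uniqueUpregulatedMarkers(list(A = detA, B = detB), min_fold = 1.5,
                                     cap = 2)
  expect_length(capped$A, 2)
  expect_equal(as.character(capped$A), c("g1", "g3"))
})

test_that("unique markers recover the planted sets on the synthetic cohort", {
  sc <- smallCohort()
  k <- SummarizedExperiment::assay(sc, "counts")
  st <- sampleTable(sc)
  disc <- st$sample_id[st$cohort == "ER_discovery"]
  labels <- stats::setNames(st$endotype[match(disc, st$sample_id)], disc)
  det <- perEndotypeDE(k[, disc], labels)
  sets <- uniqueUpregulatedMarkers(det, cap = 50)
  gt <- groundTruth(sc)
  jac <- vapply(paste0("E", 1:5), function(e)
    jaccard(sets[[e]], gt$markerGenes[[e]]), 0)
  expect_true(all(jac >= 0.7))
  expect_false(anyDuplicated(unlist(sets)) > 0)
})

test_that("a dominant predictor is always selected by the LASSO", {
  set.seed(64)
  n <- 80
  x <- matrix(rnorm(100 * n), 100, n,
              dimnames = list(paste0("g", 1:100), paste0("s", 1:n)))
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  x["g7", ] <- ifelse(y == "pos", 4, -4) + rnorm(n, sd = 0.3)
  model <- lassoSignature(x, stats::setNames(y, colnames(x)),
                          paste0("g", 1:100), cv_folds = 5, seed = 2)
  expect_true("g7" %in% signatureGenes(model))
  expect_gt(model@weights["g7", 1], 0)
  # fixed seed -> identical selection on rerun
  model2 <- lassoSignature(x, stats::setNames(y, colnames(x)),
                           paste0("g", 1:100), cv_folds = 5, seed = 2)
  expect_identical(signatureGenes(model), signatureGenes(model2))
  expect_error(lassoSignature(x, stats::setNames(y, colnames(x)), "absent"),
               "absent")
})

test_that("LASSO selection is consistent for strong logistic predictors", {
  hits <- vapply(1:20, function(s) {
    set.seed(900 + s)
    n <- 200
    x <- matrix(rnorm(100 * n), 100, n,
                dimnames = list(paste0("g", 1:100), paste0("s", 1:n)))
    beta <- rep(0, 100); beta[1:5] <- 1.5
    eta <- drop(t(x) %*% beta)
    y <- factor(ifelse(runif(n) < plogis(eta), "pos", "neg"),
                levels = c("neg", "pos"))
    if (min(table(y)) < 10) return(NA_real_)
    m <- lassoSignature(x, stats::setNames(y, colnames(x)), rownames(x),
                        cv_folds = 10, seed = s)
    sum(paste0("g", 1:5) %in% signatureGenes(m))
  }, 0)
  expect_gte(median(hits, na.rm = TRUE), 4)
})

test_that("stronger penalties never enlarge the signature on a fixed grid", {
  set.seed(66)
  n <- 300
  x <- matrix(rnorm(30 * n), 30, n)
  y <- rbinom(n, 1, plogis(x[1, ] * 1.5 - x[2, ] + 0.5 * x[3, ]))
  grid <- exp(seq(log(0.25), log(0.002), length.out = 12))
  fit <- glmnet::glmnet(t(x), y, family = "binomial", alpha = 1,
                        lambda = grid)
  sizes <- colSums(as.matrix(fit$beta) != 0)
  # penalty decreases along the grid, so the support never shrinks
  expect_true(all(diff(sizes) >= 0))
})

test_that("fold-change reduction keeps the top quartile with inclusive ties", {
  det <- makeDETable(paste0("g", 1:4), log2fc = c(3, 2, 1, 0.5),
                     adj_p = rep(0.01, 4))
  expect_equal(reduceCandidatesByFC(det), "g1")  # ceiling(4 * 0.25) = 1
  ties <- makeDETable(paste0("g", 1:4), log2fc = c(2, 2, 2, 2),
                      adj_p = rep(0.01, 4))
  expect_length(reduceCandidatesByFC(ties), 4)  # all boundary ties kept
  set.seed(6)
  big <- makeDETable(paste0("g", 1:40), log2fc = rnorm(40), adj_p = runif(40, 0, 0.04))
  out <- reduceCandidatesByFC(big)
  expect_true(all(out %in% big$gene_id))
  expect_equal(out, out[order(-abs(big$log2fc[match(out, big$gene_id)]))])
  expect_error(reduceCandidatesByFC(big[0, ]), "empty")
})

test_that("severity-style graded effects transfer to the merged comparison", {
  # graded planted effect: High = full shift, Intermediate = half, Low = none
  set.seed(77)
  n <- 150
  grp <- sample(c("High", "Intermediate", "Low"), n, replace = TRUE)
  x <- matrix(rnorm(40 * n), 40, n,
              dimnames = list(paste0("g", 1:40), paste0("s", 1:n)))
  shift <- c(High = 1.5, Intermediate = 0.75, Low = 0)[grp]
  x[1:8, ] <- x[1:8, ] + rep(shift, each = 8)
  extreme <- grp != "Intermediate"
  model <- lassoSignature(x[, extreme],
                          factor(grp[extreme], levels = c("Low", "High")),
                          rownames(x), cv_folds = 5, seed = 3)
  merged <- stats::setNames(ifelse(grp == "Low", "Low", "HighInt"), colnames(x))
  rep <- evaluateSignatureTransfer(model, x, merged, cv_folds = 5,
                                   repeats = 2, seed = 4)
  expect_gt(rep@auc, 0.8)
  # permuted labels: no transferable signal
  set.seed(5)
  aucNull <- vapply(1:5, function(i) {
    permuted <- stats::setNames(sample(merged), names(merged))
    evaluateSignatureTransfer(model, x, permuted, cv_folds = 5, repeats = 1,
                              seed = i)@auc
  }, 0)
  expect_lt(abs(mean(aucNull) - 0.5), 0.1)
})

test_that("fixed signatures are scored honestly by both learners", {
  sc <- smallCohort()
  expr <- smallExpr()
  st <- sampleTable(sc)
  gt <- groundTruth(sc)
  septic <- st$sample_id[st$cohort != "healthy"]
  died <- stats::setNames(
    factor(ifelse(st$died_in_hospital[match(septic, st$sample_id)],
                  "Died", "Survived"), levels = c("Survived", "Died")),
    septic)
  repRf <- evaluateFixedSignature(gt$mortalityGenes, expr[, septic], died,
                                  learner = "random_forest", cv_folds = 5,
                                  repeats = 1, seed = 8)
  expect_gte(repRf@auc, 0.8)
  expect_equal(nrow(repRf@perFold), 5)
  # random genes carry no signal
  set.seed(9)
  rand <- sample(setdiff(rownames(expr),
                         c(gt$mortalityGenes, gt$severityGenes,
                           unlist(gt$markerGenes))), 30)
  repNull <- evaluateFixedSignature(rand, expr[, septic], died,
                                    learner = "random_forest", cv_folds = 5,
                                    repeats = 2, seed = 10)
  expect_lt(abs(repNull@auc - 0.5), 0.12)
  expect_error(evaluateFixedSignature(character(), expr, died), "empty")
  expect_error(
    evaluateFixedSignature(gt$mortalityGenes, expr[, septic], died,
                           learner = "boosting"),
    "arg")
})
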