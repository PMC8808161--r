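#' Gene-budgeted multinomial LASSO endotype classifier
#'
#' Fits an L1-penalized multinomial logistic regression on the log2
#' expression of the candidate genes and walks the penalty path for the
#' penalty whose union of genes with any nonzero class weight is as close as
#' possible to `gene_budget` without exceeding `gene_budget + 5`; the model
#' is then refit at that penalty. If no path point lands inside the window,
#' the nearest achievable size is returned with a warning.
#'
#' @param expr normalized log2 expression (genes x samples).
#' @param labels per-sample endotype labels (named by sample or in column
#'   order; `NA` dropped); >= 2 classes, each with >= `cv_folds` samples.
#' @param candidates candidate genes, typically the union of the unique
#'   endotype marker sets.
#' @param gene_budget target size of the selected gene union (default 40).
#' @param budget_slack acceptable overshoot above the budget (default 5).
#' @param cv_folds fold count recorded for downstream CV (also the class-size
#'   floor).
#' @param seed stored in the training spec.
#' @return a [SignatureModel] with one weight column per endotype.
#' @export
fitMultinomialLasso <- function(expr, labels, candidates, gene_budget = 40,
                                budget_slack = 5, cv_folds = 5, seed = 1L) {
  .assertMatrix(expr)
  missing <- setdiff(candidates, rownames(expr))
  if (length(missing)) stop("candidate genes absent from expr: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (gene_budget > length(candidates))
    stop("gene_budget exceeds the number of candidate genes")
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  keep <- !is.na(labels)
  y <- factor(labels[keep])
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  if (min(table(y)) < cv_folds)
    stop("every class needs at least cv_folds samples")
  X <- t(expr[candidates, keep, drop = FALSE])

  path <- glmnet::glmnet(X, y, family = "multinomial", alpha = 1,
                         standardize = TRUE, nlambda = 150)
  supportSize <- vapply(seq_along(path$lambda), function(i) {
    nz <- Reduce(`|`, lapply(path$beta, function(b) b[, i] != 0))
    sum(nz)
  }, 0L)
  ok <- supportSize <= gene_budget + budget_slack
  if (any(ok)) {
    cand <- which(ok)
    best <- cand[which.min(abs(supportSize[cand] - gene_budget))]
  } else {
    best <- which.min(abs(supportSize - gene_budget))
    warning("gene budget ", gene_budget, " (+", budget_slack,
            ") unattainable on the penalty grid; nearest size is ",
            supportSize[best])
  }
  lambda <- path$lambda[best]
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 1,
                        standardize = TRUE, lambda = lambda)
  co <- stats::coef(fit)
  beta <- do.call(cbind, lapply(co, function(m) as.matrix(m)[-1, 1]))
  colnames(beta) <- levels(y)
  intercepts <- vapply(co, function(m) as.matrix(m)[1, 1], 0)
  .newSignatureModel(beta, intercepts = intercepts, classes = levels(y),
                     lambda = lambda,
                     training = list(comparison = "multinomial endotype",
                                     gene_budget = gene_budget,
                                     budget_slack = budget_slack,
                                     cv_folds = cv_folds, seed = seed))
}

#' Predict endotype labels and class probabilities
#'
#' Deterministic softmax prediction from a multinomial [SignatureModel];
#' every model gene must be present in `expr`.
#'
#' @param model a [SignatureModel] from [fitMultinomialLasso()].
#' @param expr normalized log2 expression (genes x samples).
#' @return list with `labels` (character, named by sample) and `prob`
#'   (samples x classes matrix; rows sum to 1).
#' @export
predictEndotype <- function(model, expr) {
  stopifnot(methods::is(model, "SignatureModel"))
  missing <- setdiff(model@genes, rownames(expr))
  if (length(missing)) stop("model genes missing from expression matrix: ",
                            paste(missing, collapse = ", "))
  X <- t(expr[model@genes, , drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite expression values")
  eta <- sweep(X %*% model@weights, 2, model@intercepts, "+")
  eta <- eta - apply(eta, 1, max)
  prob <- exp(eta) / rowSums(exp(eta))
  colnames(prob) <- model@classes
  labels <- model@classes[max.col(prob, ties.method = "first")]
  list(labels = stats::setNames(labels, rownames(X)), prob = prob)
}

#' Repeated stratified cross-validation
#'
#' Generic CV engine: all tuning and standardization happen inside the
#' training folds via the supplied trainer. Reports macro one-vs-rest AUC,
#' accuracy, macro sensitivity and macro specificity per fold and aggregated.
#'
#' @param expr normalized log2 expression (genes x samples).
#' @param labels per-sample class labels (named by sample or in column
#'   order; `NA` dropped).
#' @param trainer `function(trainExpr, trainLabels, seed)` returning a model
#'   accepted by `predictFun`.
#' @param predictFun `function(model, testExpr)` returning a samples x
#'   classes probability matrix (or a list with `prob`). Defaults to
#'   [predictEndotype()]'s probabilities.
#' @param folds,repeats,seed cross-validation scheme.
#' @return a [CVReport].
#' @export
crossValidate <- function(expr, labels, trainer, predictFun = NULL,
                          folds = 5, repeats = 5, seed = 1L) {
  .assertMatrix(expr)
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  y <- factor(labels[keep])
  classes <- levels(y)
  if (is.null(predictFun))
    predictFun <- function(model, testExpr) predictEndotype(model, testExpr)$prob
  perFold <- data.frame()
  for (rep in seq_len(repeats)) {
    foldAssign <- stratifiedFolds(y, folds, substreamSeed(seed, "cv-folds", rep))
    for (f in seq_len(folds)) {
      tr <- foldAssign != f
      model <- trainer(expr[, tr, drop = FALSE], y[tr],
                       substreamSeed(seed, "cv-train", rep * 1000L + f))
      prob <- predictFun(model, expr[, !tr, drop = FALSE])
      if (is.list(prob) && !is.null(prob$prob)) prob <- prob$prob
      pred <- colnames(prob)[max.col(prob, ties.method = "first")]
      m <- macroMetrics(y[!tr], pred, prob, classes = classes)
      perFold <- rbind(perFold, data.frame(repeat_ = rep, fold = f,
        auc = m[["auc"]], accuracy = m[["accuracy"]],
        sensitivity = m[["sensitivity"]], specificity = m[["specificity"]]))
    }
  }
  methods::new("CVReport",
    auc = mean(perFold$auc, na.rm = TRUE),
    accuracy = mean(perFold$accuracy),
    sensitivity = mean(perFold$sensitivity, na.rm = TRUE),
    specificity = mean(perFold$specificity, na.rm = TRUE),
    perFold = perFold, folds = as.integer(folds),
    repeats = as.integer(repeats), seed = as.integer(seed))
}

# cross-validated AUC of a 2-gene one-vs-rest logistic rule
.pairCvAuc <- function(x2, pos, foldAssign) {
  prob <- numeric(length(pos))
  for (f in unique(foldAssign)) {
    tr <- foldAssign != f
    fit <- suppressWarnings(stats::glm.fit(
      cbind(1, x2[tr, , drop = FALSE]), pos[tr],
      family = stats::binomial()))
    eta <- drop(cbind(1, x2[!tr, , drop = FALSE]) %*% fit$coefficients)
    prob[!tr] <- eta
  }
  rankAUC(prob, pos)
}

#' Derive discriminative gene pairs from the budgeted classifier genes
#'
#' For every endotype and every unordered pair of genes from the budgeted
#' set, fits a two-feature one-vs-rest logistic regression, estimates its AUC
#' by stratified cross-validation, and retains the pairs with CV AUC at or
#' above `min_auc`. The full-data two-gene weights are returned with each
#' retained pair.
#'
#' @param expr normalized log2 expression (genes x samples).
#' @param labels per-sample endotype labels.
#' @param genes the budgeted gene set (>= 2 genes present in `expr`).
#' @param min_auc retention threshold on the CV AUC (default 0.85).
#' @param cv_folds,seed cross-validation scheme.
#' @return data.frame of class `"PairRuleTable"` with columns `class`,
#'   `gene_a`, `gene_b`, `intercept`, `weight_a`, `weight_b`, `cv_auc`,
#'   sorted by class then descending `cv_auc`.
#' @export
deriveGenePairs <- function(expr, labels, genes, min_auc = 0.85,
                            cv_folds = 5, seed = 1L) {
  .assertMatrix(expr)
  genes <- intersect(genes, rownames(expr))
  if (length(genes) < 2L) stop("need at least 2 budgeted genes present in expr")
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  keep <- !is.na(labels)
  y <- factor(labels[keep])
  X <- t(expr[genes, keep, drop = FALSE])
  pairs <- utils::combn(genes, 2)
  out <- list()
  for (cl in levels(y)) {
    pos <- as.numeric(y == cl)
    foldAssign <- stratifiedFolds(factor(pos), cv_folds,
                                  substreamSeed(seed, "pairs-folds",
                                                match(cl, levels(y))))
    for (j in seq_len(ncol(pairs))) {
      g <- pairs[, j]
      x2 <- X[, g, drop = FALSE]
      auc <- .pairCvAuc(x2, pos, foldAssign)
      if (!is.na(auc) && auc >= min_auc) {
        fit <- suppressWarnings(stats::glm.fit(cbind(1, x2), pos,
                                               family = stats::binomial()))
        out[[length(out) + 1L]] <- data.frame(
          class = cl, gene_a = g[1], gene_b = g[2],
          intercept = fit$coefficients[1],
          weight_a = fit$coefficients[2], weight_b = fit$coefficients[3],
          cv_auc = auc, row.names = NULL)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(class = character(), gene_a = character(), gene_b = character(),
               intercept = numeric(), weight_a = numeric(),
               weight_b = numeric(), cv_auc = numeric())
  res <- res[order(res$class, -res$cv_auc), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("PairRuleTable", "data.frame")
  res
}
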