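#' Unique upregulated marker signatures per endotype
#'
#' From per-endotype DE tables (endotype vs all others), keeps the
#' significantly upregulated genes of each endotype, removes any gene that is
#' significantly upregulated in two or more endotypes, ranks the survivors by
#' descending log2 fold change and truncates at `cap`. The resulting sets are
#' pairwise disjoint by construction; a set may fall short of `cap` when few
#' unique genes exist.
#'
#' @param deTables named list of DE tables from [perEndotypeDE()].
#' @param min_fold,max_adj_p significance filter passed to [filterDE()]
#'   (defaults: fold >= 1.5, adjusted p <= 0.05, upregulated only).
#' @param cap maximum genes per signature (default 200).
#' @param rank_by rank survivors by `"log2fc"` (default) or `"wald_stat"`.
#' @return named list of character vectors (ordered gene sets), with the
#'   per-gene log2 fold changes attached as the `"log2fc"` attribute.
#' @export
uniqueUpregulatedMarkers <- function(deTables, min_fold = 1.5,
                                     max_adj_p = 0.05, cap = 200,
                                     rank_by = c("log2fc", "wald_stat")) {
  rank_by <- match.arg(rank_by)
  up <- lapply(deTables, filterDE, min_fold = min_fold,
               max_adj_p = max_adj_p, direction = "up")
  tab <- table(unlist(up))
  shared <- names(tab)[tab >= 2]
  out <- lapply(names(deTables), function(cl) {
    det <- deTables[[cl]]
    genes <- setdiff(up[[cl]], shared)
    if (!length(genes)) {
      warning("no unique upregulated genes for ", cl)
      return(structure(character(), log2fc = numeric()))
    }
    rows <- det[match(genes, det$gene_id), ]
    ord <- order(-rows[[rank_by]])
    rows <- rows[ord, ][seq_len(min(cap, length(genes))), ]
    structure(rows$gene_id, log2fc = stats::setNames(rows$log2fc, rows$gene_id))
  })
  names(out) <- names(deTables)
  stopifnot(!anyDuplicated(unlist(out)))
  out
}

.newSignatureModel <- function(beta, intercepts, classes, lambda, training) {
  keep <- rowSums(abs(beta)) > 0
  methods::new("SignatureModel",
    genes = rownames(beta)[keep],
    classes = classes,
    weights = beta[keep, , drop = FALSE],
    intercepts = intercepts,
    lambda = lambda,
    training = training)
}

#' L1-penalized logistic gene signature
#'
#' Fits a binomial LASSO on the log2 expression of the candidate genes
#' (standardization is performed inside each cross-validation training fit),
#' selects the penalty by cross-validated deviance with the 1-SE rule, and
#' returns the genes with nonzero weights together with the weights on the
#' original expression scale.
#'
#' @param expr normalized log2 expression (genes x samples).
#' @param labels binary per-sample labels (factor/character/logical), named
#'   by sample or ordered as the columns of `expr`.
#' @param candidates character vector of candidate genes present in `expr`.
#' @param cv_folds folds for penalty selection (both classes must have at
#'   least this many samples).
#' @param seed seed controlling the fold assignment.
#' @param comparison free-text description stored in the training spec.
#' @return a [SignatureModel] with a single weight column giving log-odds of
#'   the second class level.
#' @export
lassoSignature <- function(expr, labels, candidates, cv_folds = 10, seed = 1L,
                           comparison = "binary") {
  .assertMatrix(expr)
  missing <- setdiff(candidates, rownames(expr))
  if (length(missing)) stop("candidate genes absent from expr: ",
                            paste(utils::head(missing, 5), collapse = ", "))
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  y <- factor(labels)
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  if (min(table(y)) < cv_folds)
    stop("both classes need at least cv_folds samples")
  X <- t(expr[candidates, , drop = FALSE])
  constant <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(constant)) {
    warning("removing all-constant candidate genes: ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
  }
  foldid <- stratifiedFolds(y, cv_folds, substreamSeed(seed, "lasso-folds"))
  cv <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                          foldid = foldid, standardize = TRUE,
                          type.measure = "deviance")
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        lambda = cv$lambda.1se, standardize = TRUE)
  co <- as.matrix(stats::coef(fit))
  beta <- co[-1, , drop = FALSE]
  colnames(beta) <- levels(y)[2]
  .newSignatureModel(beta, intercepts = co[1, 1], classes = levels(y),
                     lambda = cv$lambda.1se,
                     training = list(comparison = comparison,
                                     candidates = ncol(X),
                                     cv_folds = cv_folds,
                                     penalty = "lambda.1se", seed = seed))
}

#' Reduce LASSO candidates to the top fold-change quartile
#'
#' Keeps the significant genes whose absolute log2 fold change lies in the
#' top `top_fraction` (ceiling; ties at the boundary are all kept), ordered
#' by descending |log2fc|.
#'
#' @param det a DE table from [nbWaldDE()].
#' @param top_fraction fraction retained (default 0.25).
#' @param max_adj_p significance filter applied first (default 0.05; use
#'   `Inf` to rank all genes).
#' @return character vector of gene ids.
#' @export
reduceCandidatesByFC <- function(det, top_fraction = 0.25, max_adj_p = 0.05) {
  if (!nrow(det)) stop("empty DE table")
  sig <- det[!is.na(det$adj_p) & det$adj_p <= max_adj_p, , drop = FALSE]
  if (!nrow(sig)) return(character())
  afc <- abs(sig$log2fc)
  nKeep <- ceiling(nrow(sig) * top_fraction)
  cutoff <- sort(afc, decreasing = TRUE)[nKeep]
  keep <- sig[afc >= cutoff, , drop = FALSE]
  keep$gene_id[order(-abs(keep$log2fc))]
}

#' Predicted class probabilities of a binomial signature model
#'
#' @param model a two-class [SignatureModel].
#' @param expr normalized log2 expression containing the model genes.
#' @return numeric vector of probabilities of the second class level.
#' @export
predictSignatureProb <- function(model, expr) {
  stopifnot(methods::is(model, "SignatureModel"), length(model@classes) == 2L)
  missing <- setdiff(model@genes, rownames(expr))
  if (length(missing)) stop("model genes absent from expr: ",
                            paste(missing, collapse = ", "))
  eta <- drop(t(expr[model@genes, , drop = FALSE]) %*% model@weights[, 1]) +
    model@intercepts[1]
  stats::plogis(eta)
}

#' Evaluate a severity signature on the merged-group comparison
#'
#' The severity signature is trained on the extreme phenotypes (High vs Low
#' severity); this refits the selected genes (same penalty family, penalty
#' re-selected by CV inside training folds) and cross-validates them on the
#' transferred comparison, e.g. High + Intermediate vs Low.
#'
#' @param model the extreme-phenotype [SignatureModel].
#' @param expr normalized log2 expression.
#' @param labels binary labels of the transferred comparison (named by
#'   sample; `NA` samples are dropped).
#' @param cv_folds,repeats,seed cross-validation scheme.
#' @return a [CVReport].
#' @export
evaluateSignatureTransfer <- function(model, expr, labels, cv_folds = 5,
                                      repeats = 5, seed = 1L) {
  stopifnot(methods::is(model, "SignatureModel"))
  if (!length(model@genes)) stop("model selected no genes")
  evaluateFixedSignature(model@genes, expr, labels, learner = "l1_logistic",
                         cv_folds = cv_folds, repeats = repeats, seed = seed)
}

#' Cross-validated performance of a fixed gene set
#'
#' Evaluates a fixed gene signature (no feature selection inside folds) under
#' an L1-logistic or random-forest learner with repeated stratified
#' cross-validation.
#'
#' @param genes nonempty character vector of signature genes.
#' @param expr normalized log2 expression (genes x samples).
#' @param labels binary per-sample labels (named by sample or in column
#'   order); `NA` samples are dropped.
#' @param learner `"l1_logistic"` or `"random_forest"`.
#' @param cv_folds,repeats,seed cross-validation scheme.
#' @return a [CVReport].
#' @export
evaluateFixedSignature <- function(genes, expr, labels,
                                   learner = c("l1_logistic", "random_forest"),
                                   cv_folds = 5, repeats = 5, seed = 1L) {
  learner <- match.arg(learner)
  if (!length(genes)) stop("gene set is empty")
  missing <- setdiff(genes, rownames(expr))
  if (length(missing)) stop("signature genes absent from expr: ",
                            paste(missing, collapse = ", "))
  if (!is.null(names(labels))) labels <- labels[colnames(expr)]
  keep <- !is.na(labels)
  expr <- expr[, keep, drop = FALSE]
  y <- factor(labels[keep])
  if (nlevels(y) != 2L) stop("labels must have exactly two classes")
  pos <- levels(y)[2]

  trainer <- if (learner == "l1_logistic") {
    function(Xtr, ytr, foldSeed) {
      innerFolds <- max(3L, min(5L, min(table(ytr))))
      foldid <- stratifiedFolds(ytr, innerFolds, foldSeed)
      cv <- glmnet::cv.glmnet(Xtr, ytr, family = "binomial", alpha = 1,
                              foldid = foldid, standardize = TRUE)
      function(Xte) drop(stats::predict(cv, Xte, s = "lambda.1se",
                                        type = "response"))
    }
  } else {
    function(Xtr, ytr, foldSeed) {
      set.seed(foldSeed)
      rf <- randomForest::randomForest(Xtr, ytr, ntree = 500)
      function(Xte) stats::predict(rf, Xte, type = "prob")[, pos]
    }
  }

  X <- t(expr[genes, , drop = FALSE])
  perFold <- data.frame()
  for (rep in seq_len(repeats)) {
    folds <- stratifiedFolds(y, cv_folds,
                             substreamSeed(seed, "fixed-sig-cv", rep))
    for (f in seq_len(cv_folds)) {
      tr <- folds != f
      predictFun <- trainer(X[tr, , drop = FALSE], y[tr],
                            substreamSeed(seed, "fixed-sig-train",
                                          rep * 1000L + f))
      prob <- predictFun(X[!tr, , drop = FALSE])
      pred <- ifelse(prob >= 0.5, pos, levels(y)[1])
      pm <- cbind(1 - prob, prob)
      colnames(pm) <- levels(y)
      m <- macroMetrics(y[!tr], pred, pm, classes = levels(y))
      perFold <- rbind(perFold, data.frame(repeat_ = rep, fold = f,
        auc = rankAUC(prob, y[!tr] == pos), accuracy = m[["accuracy"]],
        sensitivity = m[["sensitivity"]], specificity = m[["specificity"]]))
    }
  }
  methods::new("CVReport",
    auc = mean(perFold$auc, na.rm = TRUE),
    accuracy = mean(perFold$accuracy),
    sensitivity = mean(perFold$sensitivity),
    specificity = mean(perFold$specificity),
    perFold = perFold, folds = as.integer(cv_folds),
    repeats = as.integer(repeats), seed = as.integer(seed))
}
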