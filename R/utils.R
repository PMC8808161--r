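`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic substream seeds: one master seed, named stage offsets, a
# counter within the stage. Kept below 2^31 - 1.
substreamSeed <- function(master, stage, counter = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(master) * 7919 + h * 104729 + counter * 15485863) %% 2147483647)
}

.assertMatrix <- function(x, what = "expression matrix") {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x)))
    stop(what, " must be a matrix with gene rownames and sample colnames")
  invisible(x)
}

# rank-based (Mann-Whitney) AUC of score for the positive class
rankAUC <- function(score, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified fold assignment, deterministic given the seed
stratifiedFolds <- function(labels, folds, seed) {
  labels <- as.character(labels)
  if (min(table(labels)) < folds)
    stop("each class needs at least as many samples as folds")
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

macroMetrics <- function(truth, predicted, prob = NULL, classes = NULL) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(truth))
  sens <- spec <- auc <- rep(NA_real_, length(classes))
  for (i in seq_along(classes)) {
    pos <- truth == classes[i]
    sens[i] <- if (any(pos)) mean(predicted[pos] == classes[i]) else NA_real_
    spec[i] <- if (any(!pos)) mean(predicted[!pos] != classes[i]) else NA_real_
    if (!is.null(prob) && classes[i] %in% colnames(prob))
      auc[i] <- rankAUC(prob[, classes[i]], pos)
  }
  c(auc = mean(auc, na.rm = TRUE),
    accuracy = mean(truth == predicted),
    sensitivity = mean(sens, na.rm = TRUE),
    specificity = mean(spec, na.rm = TRUE))
}

#' Jaccard similarity between two gene sets
#'
#' @param a,b character vectors of gene identifiers.
#' @return `|a intersect b| / |a union b|` (1 for two empty sets).
#' @export
jaccard <- function(a, b) {
  u <- union(a, b)
  if (!length(u)) return(1)
  length(intersect(a, b)) / length(u)
}
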