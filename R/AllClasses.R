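#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData colData<-
NULL

.requiredSampleCols <- c(
  "cohort", "sofa24", "sofa72", "qsofa", "died_in_hospital",
  "survival_time_days", "event", "blood_culture_positive", "age", "sex"
)

.cohortLevels <- c("ER_discovery", "ER_validation", "ICU", "healthy")

#' SepsisCohort: counts plus clinical metadata
#'
#' A thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' gene-by-sample matrix of raw counts in the `"counts"` assay and the
#' per-sample clinical record (cohort, SOFA scores, outcomes, survival,
#' blood culture, demographics, optional endotype label) in `colData`.
#' Simulated cohorts additionally carry the planted ground truth (endotype
#' labels, marker/severity/mortality gene sets, true effect sizes) in
#' `metadata(x)$groundTruth`.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @seealso [simulateCohort()], [groundTruth()]
#' @export
setClass("SepsisCohort", contains = "SummarizedExperiment")

.validSepsisCohort <- function(object) {
  msg <- character()
  if (!"counts" %in% names(assays(object)))
    msg <- c(msg, "assay 'counts' is required")
  else {
    k <- assay(object, "counts")
    if (any(k < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(k != round(k))) msg <- c(msg, "counts must be integral")
    if (anyDuplicated(rownames(object))) msg <- c(msg, "duplicate gene ids")
    if (anyDuplicated(colnames(object))) msg <- c(msg, "duplicate sample ids")
  }
  missing <- setdiff(.requiredSampleCols, colnames(colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("missing colData columns: ", paste(missing, collapse = ", ")))
  if ("cohort" %in% colnames(colData(object)) &&
      !all(colData(object)$cohort %in% .cohortLevels))
    msg <- c(msg, paste0("cohort must be one of: ", paste(.cohortLevels, collapse = ", ")))
  if ("sofa24" %in% colnames(colData(object))) {
    s <- colData(object)$sofa24
    if (any(!is.na(s) & (s < 0 | s > 24))) msg <- c(msg, "sofa24 must lie in [0, 24]")
  }
  if (length(msg)) msg else TRUE
}

setValidity("SepsisCohort", .validSepsisCohort)

#' Consensus clustering result
#'
#' Holds, for each candidate number of clusters k, the consensus co-clustering
#' matrix (fraction of co-sampled resamples in which two samples co-clustered),
#' the final sample labels from clustering `1 - consensus`, a table of cluster
#' validity metrics (mean silhouette, PAC, Calinski-Harabasz, Davies-Bouldin),
#' and the k selected by the mean-rank committee.
#'
#' @slot kRange integer vector of candidate k.
#' @slot consensus named list of symmetric samples-by-samples matrices in
#'   `[0, 1]`, diagonal 1, one per k.
#' @slot labels named list of integer label vectors, one per k.
#' @slot metrics data.frame with columns `k`, `mean_silhouette`, `PAC`,
#'   `calinski_harabasz`, `davies_bouldin`.
#' @slot kSelected selected number of clusters.
#' @slot finalLabels integer labels at `kSelected`, named by sample.
#' @slot seed master seed used for the resampling stream.
#' @seealso [consensusCluster()], [selectK()]
#' @export
setClass("ConsensusResult",
  representation(
    kRange = "integer",
    consensus = "list",
    labels = "list",
    metrics = "data.frame",
    kSelected = "integer",
    finalLabels = "integer",
    seed = "integer"
  )
)

setValidity("ConsensusResult", function(object) {
  msg <- character()
  for (k in as.character(object@kRange)) {
    cm <- object@consensus[[k]]
    if (is.null(cm)) { msg <- c(msg, paste0("missing consensus for k=", k)); next }
    if (!isSymmetric(unname(cm))) msg <- c(msg, paste0("consensus not symmetric at k=", k))
    if (any(cm < 0 | cm > 1, na.rm = TRUE)) msg <- c(msg, "consensus entries outside [0,1]")
    if (any(abs(diag(cm) - 1) > 1e-12)) msg <- c(msg, "consensus diagonal must be 1")
  }
  if (length(object@kSelected) == 1L && !is.na(object@kSelected) &&
      !(object@kSelected %in% object@kRange))
    msg <- c(msg, "kSelected outside kRange")
  if (length(msg)) msg else TRUE
})

#' Penalized regression gene signature
#'
#' A fitted (possibly multinomial) L1-penalized logistic model restricted to a
#' named gene list: per-class weights on the original log2-expression scale,
#' per-class intercepts, and the training specification (comparison, penalty,
#' folds, seed) needed to reproduce the fit.
#'
#' @slot genes character vector of genes with at least one nonzero weight.
#' @slot classes class labels (length 2 for binomial).
#' @slot weights genes x classes numeric matrix (single column for binomial,
#'   giving the log-odds weights of the second class).
#' @slot intercepts per-class intercepts.
#' @slot lambda penalty at which the model was (re)fit.
#' @slot training list describing the training design (comparison, candidate
#'   count, cv folds, seed, penalty rule).
#' @seealso [lassoSignature()], [fitMultinomialLasso()], [predictEndotype()]
#' @export
setClass("SignatureModel",
  representation(
    genes = "character",
    classes = "character",
    weights = "matrix",
    intercepts = "numeric",
    lambda = "numeric",
    training = "list"
  )
)

setValidity("SignatureModel", function(object) {
  msg <- character()
  if (nrow(object@weights) != length(object@genes))
    msg <- c(msg, "weights rows must match genes")
  if (length(object@intercepts) != ncol(object@weights))
    msg <- c(msg, "one intercept per weight column")
  if (length(msg)) msg else TRUE
})

#' Cross-validation performance report
#'
#' Macro one-vs-rest AUC, accuracy, macro sensitivity (recall) and macro
#' specificity, aggregated over folds x repeats of stratified
#' cross-validation, with the per-fold values retained.
#'
#' @slot auc,accuracy,sensitivity,specificity aggregate metrics in `[0, 1]`.
#' @slot perFold data.frame with one row per fold x repeat.
#' @slot folds,repeats,seed the CV scheme.
#' @seealso [crossValidate()]
#' @export
setClass("CVReport",
  representation(
    auc = "numeric",
    accuracy = "numeric",
    sensitivity = "numeric",
    specificity = "numeric",
    perFold = "data.frame",
    folds = "integer",
    repeats = "integer",
    seed = "integer"
  )
)

setValidity("CVReport", function(object) {
  m <- c(object@auc, object@accuracy, object@sensitivity, object@specificity)
  if (any(!is.na(m) & (m < -1e-9 | m > 1 + 1e-9)))
    return("metrics must lie in [0, 1]")
  if (nrow(object@perFold) != object@folds * object@repeats)
    return("perFold must have folds * repeats rows")
  TRUE
})
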