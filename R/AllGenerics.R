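#' Accessors for SepsisEndotypes classes
#'
#' `groundTruth()` returns the planted ground truth of a simulated
#' [SepsisCohort] (or `NULL` for real data); `counts()` the raw count assay;
#' `sampleTable()` the clinical colData as a data.frame. For
#' [ConsensusResult]: `consensusMatrix()`, `clusterLabels()`, `kSelected()`,
#' `finalLabels()` and `clusterMetrics()`. For [SignatureModel]:
#' `signatureGenes()`, `modelWeights()`. For [CVReport]: `cvMetrics()`.
#'
#' @param x an object of the documented class.
#' @param k which number of clusters to extract (defaults to the selected k).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname accessors
#' @export
setGeneric("sampleTable", function(x) standardGeneric("sampleTable"))

#' @rdname accessors
#' @export
setGeneric("consensusMatrix", function(x, k) standardGeneric("consensusMatrix"))

#' @rdname accessors
#' @export
setGeneric("clusterLabels", function(x, k) standardGeneric("clusterLabels"))

#' @rdname accessors
#' @export
setGeneric("kSelected", function(x) standardGeneric("kSelected"))

#' @rdname accessors
#' @export
setGeneric("finalLabels", function(x) standardGeneric("finalLabels"))

#' @rdname accessors
#' @export
setGeneric("clusterMetrics", function(x) standardGeneric("clusterMetrics"))

#' @rdname accessors
#' @export
setGeneric("signatureGenes", function(x) standardGeneric("signatureGenes"))

#' @rdname accessors
#' @export
setGeneric("modelWeights", function(x) standardGeneric("modelWeights"))

#' @rdname accessors
#' @export
setGeneric("cvMetrics", function(x) standardGeneric("cvMetrics"))

#' @rdname accessors
#' @export
setMethod("groundTruth", "SepsisCohort", function(x) metadata(x)$groundTruth)

#' @rdname accessors
#' @export
setMethod("sampleTable", "SepsisCohort", function(x) {
  df <- as.data.frame(colData(x))
  df$sample_id <- colnames(x)
  df[, c("sample_id", setdiff(colnames(df), "sample_id"))]
})

#' @rdname accessors
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@kSelected
  x@consensus[[as.character(k)]]
})

#' @rdname accessors
#' @export
setMethod("clusterLabels", "ConsensusResult", function(x, k) {
  if (missing(k)) k <- x@kSelected
  x@labels[[as.character(k)]]
})

#' @rdname accessors
#' @export
setMethod("kSelected", "ConsensusResult", function(x) x@kSelected)

#' @rdname accessors
#' @export
setMethod("finalLabels", "ConsensusResult", function(x) x@finalLabels)

#' @rdname accessors
#' @export
setMethod("clusterMetrics", "ConsensusResult", function(x) x@metrics)

#' @rdname accessors
#' @export
setMethod("signatureGenes", "SignatureModel", function(x) x@genes)

#' @rdname accessors
#' @export
setMethod("modelWeights", "SignatureModel", function(x) {
  structure(x@weights, intercepts = x@intercepts)
})

#' @rdname accessors
#' @export
setMethod("cvMetrics", "CVReport", function(x) {
  c(auc = x@auc, accuracy = x@accuracy,
    sensitivity = x@sensitivity, specificity = x@specificity)
})

setMethod("show", "SepsisCohort", function(object) {
  callNextMethod()
  tab <- table(colData(object)$cohort)
  cat("cohorts:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (!is.null(groundTruth(object)))
    cat("ground truth: planted (", length(groundTruth(object)$markerGenes),
        "endotype marker sets )\n")
})

setMethod("show", "ConsensusResult", function(object) {
  cat("ConsensusResult over k =", paste(range(object@kRange), collapse = ".."),
      "| selected k =", object@kSelected, "\n")
  print(object@metrics, row.names = FALSE, digits = 3)
})

setMethod("show", "SignatureModel", function(object) {
  cat("SignatureModel:", length(object@genes), "genes,",
      length(object@classes), "classes (",
      paste(object@classes, collapse = ", "), ")\n")
  cat("lambda =", signif(object@lambda, 4), "|",
      object@training$comparison %||% "unspecified comparison", "\n")
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf(
    "CVReport (%d folds x %d repeats): AUC %.3f | accuracy %.3f | sens %.3f | spec %.3f\n",
    object@folds, object@repeats, object@auc, object@accuracy,
    object@sensitivity, object@specificity))
})
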