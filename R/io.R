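#' Read and write GMT gene-set files
#'
#' The GMT format is tab-separated with one gene set per line: name,
#' description, then the member genes.
#'
#' @param path file path.
#' @param sets named list of character vectors of gene ids.
#' @param descriptions optional character vector parallel to `sets`.
#' @return `readGMT` returns a named list of character vectors; `writeGMT`
#'   returns `path` invisibly.
#' @export
readGMT <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("malformed GMT line(s) with < 3 tab-separated fields in ", path)
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  sets
}

#' @rdname readGMT
#' @export
writeGMT <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample counts TSV
#'
#' Expects a header row of sample ids, a first column of gene ids, and
#' nonnegative integer entries.
#'
#' @param path file path.
#' @return integer matrix with gene rownames and sample colnames.
#' @export
readCountsTSV <- function(path) {
  if (!file.exists(path)) stop("counts file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || colnames(df)[1] != "gene_id")
    stop("counts TSV must have a 'gene_id' first column: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in ", path)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers: ", path)
  storage.mode(m) <- "integer"
  m
}

#' @rdname readCountsTSV
#' @param counts integer matrix (genes x samples).
#' @export
writeCountsTSV <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated cohort as plain-text fixture files
#'
#' Writes the counts as TSV (genes in rows, first column `gene_id`, header of
#' sample ids), the clinical metadata as TSV, the planted marker sets as GMT
#' and the remaining ground truth (labels, severity/mortality genes, planted
#' effects, configuration) as JSON, all with deterministic column order.
#'
#' @param cohort a [SepsisCohort].
#' @param directory output directory (created if absent).
#' @return named character vector of the written paths.
#' @seealso [readCohortFixture()]
#' @export
writeCohortFixture <- function(cohort, directory) {
  stopifnot(methods::is(cohort, "SepsisCohort"))
  if (!dir.exists(directory))
    if (!dir.create(directory, recursive = TRUE))
      stop("cannot create fixture directory: ", directory)
  paths <- c(counts = file.path(directory, "counts.tsv"),
             metadata = file.path(directory, "metadata.tsv"),
             markers = file.path(directory, "markers.gmt"),
             truth = file.path(directory, "ground_truth.json"))
  writeCountsTSV(assay(cohort, "counts"), paths["counts"])
  utils::write.table(sampleTable(cohort), paths["metadata"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  gt <- groundTruth(cohort)
  if (!is.null(gt)) {
    writeGMT(gt$markerGenes, paths["markers"],
             descriptions = rep("planted_endotype_markers", length(gt$markerGenes)))
    truth <- list(endotype = as.list(gt$endotype),
                  severityGenes = gt$severityGenes,
                  mortalityGenes = gt$mortalityGenes,
                  trueLog2fc = as.list(gt$trueLog2fc),
                  config = unclass(gt$config))
    jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA)
  } else {
    paths <- paths[c("counts", "metadata")]
  }
  paths
}

#' Read a cohort fixture written by [writeCohortFixture()]
#'
#' @param directory directory containing `counts.tsv` and `metadata.tsv`
#'   (and, for simulated cohorts, `markers.gmt` and `ground_truth.json`).
#' @return a [SepsisCohort].
#' @export
readCohortFixture <- function(directory) {
  counts <- readCountsTSV(file.path(directory, "counts.tsv"))
  meta <- utils::read.delim(file.path(directory, "metadata.tsv"),
                            check.names = FALSE, stringsAsFactors = FALSE)
  if (!identical(meta$sample_id, colnames(counts)))
    stop("metadata sample ids do not match counts columns in ", directory)
  cd <- DataFrame(meta[, setdiff(colnames(meta), "sample_id")],
                  row.names = meta$sample_id)
  md <- list()
  truthPath <- file.path(directory, "ground_truth.json")
  if (file.exists(truthPath)) {
    truth <- jsonlite::read_json(truthPath)
    gt <- list(
      endotype = unlist(truth$endotype) %||% character(),
      markerGenes = readGMT(file.path(directory, "markers.gmt")),
      severityGenes = unlist(truth$severityGenes),
      mortalityGenes = unlist(truth$mortalityGenes),
      trueLog2fc = unlist(truth$trueLog2fc),
      config = truth$config
    )
    md$groundTruth <- gt
  }
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = md)
  methods::new("SepsisCohort", se)
}

#' Write a differential-expression table as TSV
#'
#' Columns: `gene_id, log2fc, se, stat, pvalue, padj`.
#'
#' @param det a DE table from [nbWaldDE()].
#' @param path file path.
#' @export
writeDETable <- function(det, path) {
  out <- data.frame(gene_id = det$gene_id, log2fc = det$log2fc, se = det$se,
                    stat = det$wald_stat, pvalue = det$p, padj = det$adj_p)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
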