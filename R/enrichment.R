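#' @useDynLib SepsisEndotypes, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Single-sample gene-set enrichment scores (GSVA-style)
#'
#' Per gene, a Gaussian-kernel cumulative density estimate across samples
#' (bandwidth = per-gene SD times `n^(-1/5)`) converts expression to
#' sample-level statistics; per sample these are rank-transformed into
#' symmetric rank scores `|p/2 - rank + 1/2|`. For each gene set and sample a
#' weighted Kolmogorov-Smirnov random walk is taken down the sample's gene
#' ranking, stepping up by `|score|^tau` (normalized) at set genes and down
#' by `1/(p - m)` otherwise; the enrichment score is the maximum positive
#' deviation plus the minimum negative deviation of the walk, which is
#' bounded in `[-1, 1]`.
#'
#' @param expr normalized log2 expression (genes x samples, >= 3 samples).
#'   Genes constant across all samples are excluded with a warning.
#' @param geneSets named list of character vectors; genes absent from `expr`
#'   are dropped with a warning, and each set must retain >= 2 genes.
#' @param tau rank-score weight exponent (default 1).
#' @return samples x gene-sets numeric matrix of scores in `[-1, 1]`.
#' @export
gsvaScores <- function(expr, geneSets, tau = 1) {
  .assertMatrix(expr)
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  stopifnot(is.list(geneSets), !is.null(names(geneSets)))
  sds <- apply(expr, 1, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " gene(s) constant across samples")
    expr <- expr[sds > 0, , drop = FALSE]
    sds <- sds[sds > 0]
  }
  n <- ncol(expr); p <- nrow(expr)
  geneSets <- lapply(stats::setNames(names(geneSets), names(geneSets)),
                     function(nm) {
    g <- geneSets[[nm]]
    present <- intersect(g, rownames(expr))
    if (!length(present)) stop("gene set fully absent from expr: ", nm)
    if (length(present) < length(g))
      warning("dropping ", length(g) - length(present),
              " absent gene(s) from set ", nm)
    if (length(present) < 2L) stop("gene set ", nm, " has < 2 genes in expr")
    present
  })

  h <- sds * n^(-1 / 5)
  z <- .kcdfGauss(expr, h)
  dimnames(z) <- dimnames(expr)

  scores <- matrix(NA_real_, n, length(geneSets),
                   dimnames = list(colnames(expr), names(geneSets)))
  setIdx <- lapply(geneSets, function(g) match(g, rownames(expr)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    r <- integer(p); r[ord] <- seq_len(p)       # rank 1 = highest statistic
    symScore <- abs(p / 2 - r + 0.5)
    for (s in seq_along(setIdx)) {
      inSet <- logical(p); inSet[setIdx[[s]]] <- TRUE
      inSetOrd <- inSet[ord]
      w <- symScore[ord]^tau
      stepUp <- ifelse(inSetOrd, w, 0)
      up <- cumsum(stepUp) / sum(stepUp)
      down <- cumsum(!inSetOrd) / (p - length(setIdx[[s]]))
      nu <- up - down
      scores[j, s] <- max(c(nu, 0)) + min(c(nu, 0))
    }
  }
  scores
}

#' Assign endotypes by maximal signature enrichment
#'
#' Labels each sample with the endotype signature attaining the highest
#' enrichment score; exact ties are broken deterministically by signature
#' name order and flagged.
#'
#' @param scores samples x signatures score matrix from [gsvaScores()].
#' @return data.frame with `sample_id`, `label`, `margin` (top minus second
#'   score) and `tie`.
#' @export
classifyByEnrichment <- function(scores) {
  stopifnot(is.matrix(scores), !is.null(colnames(scores)))
  ord <- order(colnames(scores))
  scores <- scores[, ord, drop = FALSE]
  top <- max.col(scores, ties.method = "first")
  sorted <- t(apply(scores, 1, sort, decreasing = TRUE))
  margin <- if (ncol(scores) > 1L) sorted[, 1] - sorted[, 2] else rep(NA_real_, nrow(scores))
  tie <- margin == 0
  data.frame(sample_id = rownames(scores) %||% as.character(seq_len(nrow(scores))),
             label = colnames(scores)[top], margin = margin, tie = tie,
             row.names = NULL)
}

#' Hypergeometric over-representation test
#'
#' Upper-tail probability `P(X >= overlap)` for the overlap of a gene list
#' with a gene set inside a finite universe, plus the enrichment ratio
#' (observed / expected overlap).
#'
#' @param geneList character vector (the query list), subset of `universe`.
#' @param geneSet character vector (the annotated set), subset of `universe`.
#' @param universe character vector of all eligible genes.
#' @param setName label stored in the result row.
#' @return one-row data.frame: `set_name`, `overlap`, `list_size`,
#'   `set_size`, `universe_size`, `enrichment_ratio`, `p`.
#' @export
ora <- function(geneList, geneSet, universe, setName = "set") {
  geneList <- unique(geneList); geneSet <- unique(geneSet)
  universe <- unique(universe)
  outside <- c(setdiff(geneList, universe), setdiff(geneSet, universe))
  if (length(outside))
    stop("ids outside the universe: ", paste(utils::head(outside, 5), collapse = ", "))
  ov <- length(intersect(geneList, geneSet))
  N <- length(universe); m <- length(geneSet); k <- length(geneList)
  p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
  expected <- k * m / N
  data.frame(set_name = setName, overlap = ov, list_size = k, set_size = m,
             universe_size = N,
             enrichment_ratio = if (expected > 0) ov / expected else NA_real_,
             p = p, row.names = NULL)
}

#' Batch over-representation analysis with BH adjustment
#'
#' @param geneList query gene list.
#' @param collection named list of gene sets (e.g. from [readGMT()]).
#' @param universe all eligible genes.
#' @return data.frame of [ora()] rows with an `adj_p` column, sorted by
#'   ascending `adj_p`.
#' @export
oraBatch <- function(geneList, collection, universe) {
  stopifnot(is.list(collection), length(collection) >= 1L)
  if (anyDuplicated(names(collection))) stop("duplicate set names")
  res <- do.call(rbind, lapply(names(collection), function(nm)
    ora(geneList, collection[[nm]], universe, setName = nm)))
  res$adj_p <- bhAdjust(res$p)
  res[order(res$adj_p, res$p), , drop = FALSE]
}
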