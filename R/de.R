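#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed as the median, over genes with a
#' positive geometric mean across samples, of the ratio of the sample's count
#' to that geometric mean, rescaled so the factors have geometric mean 1.
#'
#' @param counts integer matrix (genes x samples) or a [SepsisCohort].
#' @return positive numeric vector named by sample.
#' @export
computeSizeFactors <- function(counts) {
  if (methods::is(counts, "SepsisCohort")) counts <- assay(counts, "counts")
  logGeo <- rowMeans(log(counts))
  use <- is.finite(logGeo)
  if (!any(use))
    stop("no gene is expressed in all samples; size factors undefined")
  geo <- exp(logGeo[use])
  s <- apply(counts[use, , drop = FALSE], 2, function(col)
    stats::median(col / geo))
  s / exp(mean(log(s)))
}

#' Log2 normalized expression
#'
#' `x_ij = log2(K_ij / s_j + pseudocount)`.
#'
#' @param counts integer matrix (genes x samples) or a [SepsisCohort].
#' @param factors per-sample positive size factors; computed with
#'   [computeSizeFactors()] when missing.
#' @param pseudocount added before the log (default 1, so a zero count maps
#'   to 0).
#' @return numeric matrix of the same shape.
#' @export
normalizeLog2 <- function(counts, factors = NULL, pseudocount = 1) {
  if (methods::is(counts, "SepsisCohort")) counts <- assay(counts, "counts")
  if (is.null(factors)) factors <- computeSizeFactors(counts)
  if (length(factors) != ncol(counts))
    stop("length(factors) must equal the number of samples")
  if (any(factors <= 0)) stop("size factors must be positive")
  log2(sweep(counts, 2, factors, "/") + pseudocount)
}

#' SOFA-based severity groups
#'
#' High: 24 h SOFA >= 5; Intermediate: >= 2 and < 5; Low: < 2. Missing SOFA
#' gives `NA` (excluded from severity analyses).
#'
#' @param sofa24 integer vector of 24 h SOFA scores in `[0, 24]`.
#' @return factor with levels `Low`, `Intermediate`, `High`.
#' @export
assignSeverity <- function(sofa24) {
  if (any(!is.na(sofa24) & (sofa24 < 0 | sofa24 > 24)))
    stop("sofa24 must lie in [0, 24]")
  lab <- ifelse(is.na(sofa24), NA_character_,
                ifelse(sofa24 >= 5, "High",
                       ifelse(sofa24 >= 2, "Intermediate", "Low")))
  factor(lab, levels = c("Low", "Intermediate", "High"))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate (wraps
#' `stats::p.adjust(method = "BH")` after validating the input range).
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return adjusted p-values, elementwise `>=` the input and capped at 1.
#' @export
bhAdjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# ML estimate of the NB mean on the log scale with known per-sample offsets
# and fixed dispersion, vectorized over genes via Newton steps on theta =
# log(mu). Score U = sum_j (K_j - m_j) / (1 + phi m_j), m_j = s_j e^theta;
# expected information I = sum_j m_j / (1 + phi m_j).
.nbGroupFit <- function(K, s, phi, meanFloor = 1e-6, iters = 25L) {
  mu <- pmax(rowSums(K) / sum(s), meanFloor)
  theta <- log(mu)
  for (it in seq_len(iters)) {
    m <- exp(theta) %o% s
    denom <- 1 + phi * m
    U <- rowSums((K - m) / denom)
    I <- rowSums(m / denom)
    step <- U / pmax(I, 1e-12)
    step <- pmin(pmax(step, -4), 4)
    theta <- theta + step
    if (max(abs(step)) < 1e-10) break
  }
  theta <- pmax(theta, log(meanFloor))
  m <- exp(theta) %o% s
  info <- rowSums(m / (1 + phi * m))
  list(theta = theta, info = pmax(info, 1e-12))
}

#' Negative-binomial Wald test for two-group differential expression
#'
#' A self-contained two-group NB Wald test: per gene, a shared dispersion is
#' estimated by the method of moments on size-factor-normalized counts
#' (pooled across the two groups, floored at `1e-8`), the per-group NB means
#' are fitted by maximum likelihood with log size factors as offsets, and the
#' Wald statistic `log2fc / se` is referred to the standard normal.
#' Deliberately omits the dispersion shrinkage, outlier replacement and
#' independent filtering of full DE frameworks.
#'
#' @param counts integer matrix (genes x samples) or [SepsisCohort].
#' @param groupA,groupB disjoint character vectors of sample ids (each >= 3).
#' @param sizeFactors optional precomputed factors for all columns of
#'   `counts`; computed on the two groups when missing.
#' @param dispersionFloor,meanFloor numerical floors protecting sparse genes.
#' @return a `data.frame` of class `"DETable"` with columns `gene_id`,
#'   `log2fc` (A over B), `se`, `wald_stat`, `p`, `adj_p`; genes with all-zero
#'   counts in both groups are dropped and listed in `attr(x, "dropped")`.
#' @export
nbWaldDE <- function(counts, groupA, groupB, sizeFactors = NULL,
                     dispersionFloor = 1e-8, meanFloor = 1e-6) {
  if (methods::is(counts, "SepsisCohort")) counts <- assay(counts, "counts")
  .assertMatrix(counts, "counts")
  if (!length(groupA) || !length(groupB)) stop("both groups must be nonempty")
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  if (length(groupA) < 3L || length(groupB) < 3L)
    stop("each group needs at least 3 samples")
  missing <- setdiff(c(groupA, groupB), colnames(counts))
  if (length(missing)) stop("samples absent from counts: ",
                            paste(missing, collapse = ", "))
  sub <- counts[, c(groupA, groupB), drop = FALSE]
  if (is.null(sizeFactors)) {
    s <- computeSizeFactors(sub)
  } else {
    s <- sizeFactors[c(groupA, groupB)]
    if (any(is.na(s))) stop("sizeFactors must cover both groups")
  }
  keep <- rowSums(sub) > 0
  dropped <- rownames(sub)[!keep]
  sub <- sub[keep, , drop = FALSE]
  iA <- seq_along(groupA)
  iB <- length(groupA) + seq_along(groupB)

  # pooled method-of-moments dispersion on normalized counts:
  # Var(K/s) = mu * E[1/s] + phi * mu^2 within each group
  q <- sweep(sub, 2, s, "/")
  momPhi <- function(idx) {
    m <- rowMeans(q[, idx, drop = FALSE])
    v <- apply(q[, idx, drop = FALSE], 1, stats::var)
    (v - m * mean(1 / s[idx])) / pmax(m, meanFloor)^2
  }
  nA <- length(iA); nB <- length(iB)
  phi <- ((nA - 1) * momPhi(iA) + (nB - 1) * momPhi(iB)) / (nA + nB - 2)
  phi <- pmax(phi, dispersionFloor)

  fitA <- .nbGroupFit(sub[, iA, drop = FALSE], s[iA], phi, meanFloor)
  fitB <- .nbGroupFit(sub[, iB, drop = FALSE], s[iB], phi, meanFloor)
  log2fc <- (fitA$theta - fitB$theta) / log(2)
  se <- sqrt(1 / fitA$info + 1 / fitB$info) / log(2)
  stat <- log2fc / se
  p <- 2 * stats::pnorm(-abs(stat))
  det <- data.frame(gene_id = rownames(sub), log2fc = log2fc, se = se,
                    wald_stat = stat, p = p, adj_p = bhAdjust(p),
                    row.names = NULL)
  class(det) <- c("DETable", "data.frame")
  attr(det, "dropped") <- dropped
  det
}

#' Filter a DE table by fold change and adjusted p
#'
#' Thresholds are inclusive: a gene at exactly the fold-change or adjusted-p
#' boundary is retained.
#'
#' @param det a DE table from [nbWaldDE()].
#' @param min_fold minimum fold change (natural scale, >= 1).
#' @param max_adj_p adjusted-p ceiling (default 0.05).
#' @param direction `"up"` (fold >= min_fold), `"down"` (<= 1/min_fold) or
#'   `"both"`.
#' @return character vector of retained gene ids, ordered as in `det`.
#' @export
filterDE <- function(det, min_fold, max_adj_p = 0.05,
                     direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (min_fold < 1) stop("min_fold must be >= 1")
  fc <- 2^det$log2fc
  sig <- !is.na(det$adj_p) & det$adj_p <= max_adj_p
  keep <- switch(direction,
    up = sig & fc >= min_fold,
    down = sig & fc <= 1 / min_fold,
    both = sig & (fc >= min_fold | fc <= 1 / min_fold))
  det$gene_id[keep]
}

#' Per-endotype differential expression (each endotype vs all others)
#'
#' Runs [nbWaldDE()] once per endotype, orienting the fold change as the
#' endotype over the pooled remaining endotypes.
#'
#' @param counts integer matrix (genes x samples) or [SepsisCohort].
#' @param labels per-sample endotype labels named by sample id (samples with
#'   `NA` are ignored); every endotype needs >= 3 samples.
#' @param sizeFactors optional shared size factors.
#' @return named list of DE tables, one per endotype.
#' @export
perEndotypeDE <- function(counts, labels, sizeFactors = NULL) {
  if (methods::is(counts, "SepsisCohort")) counts <- assay(counts, "counts")
  labels <- labels[!is.na(labels)]
  classes <- sort(unique(as.character(labels)))
  sizes <- table(labels)
  if (any(sizes < 3L))
    stop("every endotype needs at least 3 samples; too small: ",
         paste(names(sizes)[sizes < 3L], collapse = ", "))
  if (is.null(sizeFactors))
    sizeFactors <- computeSizeFactors(counts[, names(labels), drop = FALSE])
  out <- lapply(classes, function(cl) {
    a <- names(labels)[labels == cl]
    b <- names(labels)[labels != cl]
    nbWaldDE(counts, a, b, sizeFactors = sizeFactors)
  })
  names(out) <- classes
  out
}
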