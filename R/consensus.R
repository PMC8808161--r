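#' Manhattan distances between samples
#'
#' `d(a, b) = sum_i |x_ia - x_ib|` over the selected feature rows.
#'
#' @param expr numeric matrix (genes x samples).
#' @param features optional character/integer subset of rows (default: all).
#' @return a symmetric `dist`-compatible matrix (samples x samples).
#' @export
manhattanDistances <- function(expr, features = NULL) {
  .assertMatrix(expr)
  if (ncol(expr) < 2L) stop("need at least 2 samples")
  if (!is.null(features)) {
    if (!length(features)) stop("empty feature subset")
    expr <- expr[features, , drop = FALSE]
  }
  as.matrix(stats::dist(t(expr), method = "manhattan"))
}

#' k-medoids partitioning (PAM)
#'
#' Partitioning around medoids on a precomputed distance matrix: greedy BUILD
#' initialization followed by SWAP passes until no single medoid/non-medoid
#' exchange lowers the total distance-to-medoid cost (via `cluster::pam`,
#' which is deterministic for a given input).
#'
#' @param d symmetric distance matrix or `dist` object.
#' @param k number of clusters, `2 <= k <= n` (`k = n` returns every sample
#'   as its own medoid with cost 0).
#' @return list with `labels` (integer, named by sample), `medoids` (sample
#'   ids) and `cost` (total distance of samples to their medoids).
#' @export
pamCluster <- function(d, k) {
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
      stop("distance input must be square and symmetric")
    d <- stats::as.dist(d)
  }
  n <- attr(d, "Size")
  if (k > n) stop("k must not exceed the number of samples")
  if (k < 1L) stop("k must be positive")
  if (k == n) {
    ids <- attr(d, "Labels") %||% as.character(seq_len(n))
    return(list(labels = stats::setNames(seq_len(n), ids), medoids = ids, cost = 0))
  }
  fit <- cluster::pam(d, k = k, diss = TRUE, cluster.only = FALSE)
  labels <- fit$clustering
  dm <- as.matrix(d)
  cost <- sum(vapply(seq_len(n), function(i) dm[i, fit$medoids[labels[i]]], 0))
  list(labels = labels, medoids = fit$medoids, cost = cost)
}

.pac <- function(cm, lower = 0.1, upper = 0.9) {
  v <- cm[upper.tri(cm)]
  mean(v > lower & v < upper)
}

# Calinski-Harabasz and Davies-Bouldin on a samples x features matrix
.chIndex <- function(X, labels) {
  n <- nrow(X); k <- length(unique(labels))
  if (k < 2L || k >= n) return(NA_real_)
  overall <- colMeans(X)
  ssb <- ssw <- 0
  for (cl in unique(labels)) {
    Xi <- X[labels == cl, , drop = FALSE]
    ci <- colMeans(Xi)
    ssb <- ssb + nrow(Xi) * sum((ci - overall)^2)
    ssw <- ssw + sum(sweep(Xi, 2, ci)^2)
  }
  (ssb / (k - 1)) / (ssw / (n - k))
}

.dbIndex <- function(X, labels) {
  cls <- unique(labels); k <- length(cls)
  if (k < 2L) return(NA_real_)
  cent <- t(vapply(cls, function(cl) colMeans(X[labels == cl, , drop = FALSE]),
                   numeric(ncol(X))))
  scat <- vapply(seq_along(cls), function(i) {
    Xi <- X[labels == cls[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(Xi, 2, cent[i, ])^2)))
  }, 0)
  r <- vapply(seq_len(k), function(i) {
    max(vapply(setdiff(seq_len(k), i), function(j) {
      dij <- sqrt(sum((cent[i, ] - cent[j, ])^2))
      if (dij == 0) Inf else (scat[i] + scat[j]) / dij
    }, 0))
  }, 0)
  mean(r)
}

#' Subsampled consensus k-medoids clustering
#'
#' Features are the `nVarGenes` genes with the highest median absolute
#' deviation of normalized log2 expression. For each resample, a random
#' `subsampleFraction` of samples is drawn (once, shared across all k) and
#' partitioned by PAM with Manhattan distance for every k in `kRange`. The
#' consensus entry for a sample pair at a given k is the number of resamples
#' in which they co-clustered divided by the number in which they were
#' co-sampled (diagonal fixed at 1). Final labels per k cut an
#' average-linkage hierarchical tree on `1 - consensus`; cluster validity metrics (PAC on the consensus entries;
#' mean silhouette, Calinski-Harabasz and Davies-Bouldin on a
#' principal-component embedding of the feature matrix) are computed per k
#' and the committee in [selectK()] picks the cluster number.
#'
#' @param expr normalized log2 expression (genes x samples).
#' @param kRange candidate numbers of clusters.
#' @param nResamples number of subsampling iterations (>= 2).
#' @param subsampleFraction fraction of samples per resample, in `(0, 1]`.
#' @param nVarGenes number of most-variable (MAD) genes used as features.
#' @param seed master seed; per-resample seeds are derived by counter.
#' @param pacBounds lower/upper consensus bounds defining "ambiguous" entries
#'   for the PAC statistic.
#' @param nPcs dimensionality of the principal-component embedding of the
#'   feature matrix on which the geometric validity metrics (silhouette,
#'   Calinski-Harabasz, Davies-Bouldin) are evaluated; the clustering itself
#'   always uses the Manhattan distance on the full feature set.
#' @return a [ConsensusResult].
#' @export
consensusCluster <- function(expr, kRange = 2:8, nResamples = 250,
                             subsampleFraction = 0.8, nVarGenes = 2000,
                             seed = 1L, pacBounds = c(0.1, 0.9), nPcs = 10) {
  .assertMatrix(expr)
  if (nResamples < 2L) stop("nResamples must be >= 2")
  if (subsampleFraction <= 0 || subsampleFraction > 1)
    stop("subsampleFraction must lie in (0, 1]")
  kRange <- sort(unique(as.integer(kRange)))
  n <- ncol(expr)
  if (max(kRange) >= n) stop("largest k must be smaller than the sample count")

  madv <- apply(expr, 1, stats::mad)
  features <- names(sort(madv, decreasing = TRUE))[seq_len(min(nVarGenes, nrow(expr)))]
  X <- expr[features, , drop = FALSE]

  m <- max(2L, round(subsampleFraction * n))
  coSample <- matrix(0L, n, n)
  coCluster <- lapply(kRange, function(k) matrix(0L, n, n))
  names(coCluster) <- as.character(kRange)

  for (r in seq_len(nResamples)) {
    set.seed(substreamSeed(seed, "consensus-resample", r))
    idx <- sort(sample.int(n, m))
    coSample[idx, idx] <- coSample[idx, idx] + 1L
    d <- stats::dist(t(X[, idx, drop = FALSE]), method = "manhattan")
    for (k in kRange) {
      lab <- cluster::pam(d, k = k, diss = TRUE, cluster.only = TRUE,
                          pamonce = 5)
      same <- outer(lab, lab, "==")
      ck <- coCluster[[as.character(k)]]
      ck[idx, idx] <- ck[idx, idx] + same
      coCluster[[as.character(k)]] <- ck
    }
  }
  offdiag <- coSample[upper.tri(coSample)]
  if (any(offdiag == 0))
    stop("some sample pairs were never co-sampled; increase nResamples ",
         "or subsampleFraction")

  ids <- colnames(expr)
  # geometric validity metrics are evaluated in a denoised low-dimensional
  # embedding; high-dimensional noise otherwise swamps cluster separation
  pcs <- stats::prcomp(t(X), rank. = min(nPcs, n - 1L, nrow(X)))$x
  pcDist <- stats::dist(pcs)
  consensus <- labels <- list()
  metrics <- data.frame()
  for (k in kRange) {
    cm <- coCluster[[as.character(k)]] / coSample
    diag(cm) <- 1
    dimnames(cm) <- list(ids, ids)
    # final labels: average-linkage tree cut on the consensus dissimilarity.
    # A medoid-based cut is vulnerable to a cost pathology with unequal
    # cluster sizes (splitting a large stable block can undercut separating
    # two small ones); the hierarchical cut is not.
    hc <- stats::hclust(stats::as.dist(1 - cm), method = "average")
    lab <- stats::setNames(as.integer(stats::cutree(hc, k)), ids)
    sil <- mean(cluster::silhouette(lab, pcDist)[, "sil_width"])
    consensus[[as.character(k)]] <- cm
    labels[[as.character(k)]] <- lab
    metrics <- rbind(metrics, data.frame(
      k = k, mean_silhouette = sil,
      PAC = .pac(cm, pacBounds[1], pacBounds[2]),
      calinski_harabasz = .chIndex(pcs, lab),
      davies_bouldin = .dbIndex(pcs, lab)))
  }
  kSel <- if (length(kRange) == 1L) kRange else selectK(metrics)
  methods::new("ConsensusResult",
    kRange = kRange, consensus = consensus, labels = labels,
    metrics = metrics, kSelected = as.integer(kSel),
    finalLabels = labels[[as.character(kSel)]], seed = as.integer(seed))
}

#' Select the number of clusters by a validity-metric committee
#'
#' Each metric ranks the candidate k (higher mean silhouette and
#' Calinski-Harabasz are better; lower PAC and Davies-Bouldin are better);
#' the k with the best (smallest) mean rank wins, ties broken toward the
#' smaller k.
#'
#' @param metrics data.frame with columns `k`, `mean_silhouette`, `PAC`,
#'   `calinski_harabasz`, `davies_bouldin` (as in [clusterMetrics()]).
#' @return the selected integer k.
#' @export
selectK <- function(metrics) {
  need <- c("k", "mean_silhouette", "PAC", "calinski_harabasz", "davies_bouldin")
  if (!all(need %in% colnames(metrics)))
    stop("metrics must contain columns: ", paste(need, collapse = ", "))
  if (nrow(metrics) < 2L) stop("need metrics for at least 2 candidate k")
  ranks <- cbind(
    rank(-metrics$mean_silhouette, ties.method = "average"),
    rank(metrics$PAC, ties.method = "average"),
    rank(-metrics$calinski_harabasz, ties.method = "average"),
    rank(metrics$davies_bouldin, ties.method = "average"))
  meanRank <- rowMeans(ranks)
  best <- which(meanRank == min(meanRank))
  as.integer(min(metrics$k[best]))
}
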