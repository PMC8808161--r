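# Shared fixtures, built once per test run.

# compact cohort: same structure as the default study design, scaled down in
# genes/markers so unit tests stay fast
smallSimConfig <- function(seed = 101L, ...) {
  simConfig(n_genes = 1000L, markers_per_endotype = 50L,
            n_severity_genes = 40L, n_mortality_genes = 30L,
            seed = seed, ...)
}

.fixtureCache <- new.env(parent = emptyenv())

smallCohort <- function() {
  if (is.null(.fixtureCache$small))
    .fixtureCache$small <- simulateCohort(smallSimConfig())
  .fixtureCache$small
}

smallExpr <- function() {
  if (is.null(.fixtureCache$expr))
    .fixtureCache$expr <- normalizeLog2(smallCohort())
  .fixtureCache$expr
}

# expression matrix with c separated classes: class j upregulated in its own
# gene block by `shift`, Gaussian noise elsewhere
blockExpr <- function(nPerClass = 10, nClasses = 3, genesPerBlock = 5,
                      nNoise = 10, shift = 3, sd = 0.5, seed = 42) {
  set.seed(seed)
  n <- nPerClass * nClasses
  p <- genesPerBlock * nClasses + nNoise
  x <- matrix(rnorm(p * n, sd = sd), p, n,
              dimnames = list(sprintf("g%03d", seq_len(p)),
                              sprintf("s%03d", seq_len(n))))
  labels <- rep(paste0("K", seq_len(nClasses)), each = nPerClass)
  for (j in seq_len(nClasses)) {
    rows <- (j - 1) * genesPerBlock + seq_len(genesPerBlock)
    x[rows, labels == paste0("K", j)] <- x[rows, labels == paste0("K", j)] + shift
  }
  list(expr = x, labels = stats::setNames(labels, colnames(x)))
}

# hand-rolled DE table for logic tests
makeDETable <- function(gene_id, log2fc, adj_p, p = adj_p / 2) {
  det <- data.frame(gene_id = gene_id, log2fc = log2fc,
                    se = rep(0.1, length(gene_id)),
                    wald_stat = log2fc / 0.1, p = p, adj_p = adj_p)
  class(det) <- c("DETable", "data.frame")
  det
}
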