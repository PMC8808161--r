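#' Kruskal-Wallis rank-sum test across groups
#'
#' Tie-corrected H statistic with p from the chi-squared approximation on
#' `groups - 1` degrees of freedom (wraps `stats::kruskal.test`).
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @return list with `H`, `df`, `p`.
#' @export
kruskalWallis <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("every group must be nonempty")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' After a Kruskal-Wallis test, compares every pair of groups with the Dunn z
#' statistic: the difference of pooled-rank means divided by
#' `sqrt((N(N+1)/12 - T) * (1/n_a + 1/n_b))` where
#' `T = sum(t^3 - t) / (12 (N - 1))` corrects for ties. Two-sided p-values,
#' optionally BH-adjusted across pairs.
#'
#' @param groups named list of >= 3 numeric vectors.
#' @param p_adjust `"none"` (default) or `"bh"`.
#' @return data.frame with `group_a`, `group_b`, `z`, `p` (and `adj_p`).
#' @export
dunnPosthoc <- function(groups, p_adjust = c("none", "bh")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 3L)
    stop("Dunn's post-hoc needs >= 3 groups; use a rank-sum test for 2")
  if (is.null(names(groups))) names(groups) <- paste0("G", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  N <- length(pooled)
  r <- rank(pooled)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  n <- lengths(groups)
  ties <- table(pooled)
  tieTerm <- sum(ties^3 - ties) / (12 * (N - 1))
  combs <- utils::combn(seq_along(groups), 2)
  z <- vapply(seq_len(ncol(combs)), function(j) {
    a <- combs[1, j]; b <- combs[2, j]
    sigma <- sqrt((N * (N + 1) / 12 - tieTerm) * (1 / n[a] + 1 / n[b]))
    unname((rbar[a] - rbar[b]) / sigma)
  }, 0)
  res <- data.frame(group_a = names(groups)[combs[1, ]],
                    group_b = names(groups)[combs[2, ]],
                    z = z, p = 2 * stats::pnorm(-abs(z)), row.names = NULL)
  if (p_adjust == "bh") res$adj_p <- bhAdjust(res$p)
  res
}

#' Pearson chi-squared test of independence
#'
#' No continuity correction (matching the convention used for the printed
#' clinical tables); Fisher's exact test is available behind `fisher = TRUE`
#' for sparse tables.
#'
#' @param table matrix of nonnegative integer cells (>= 2 rows and columns)
#'   with positive row and column sums.
#' @param fisher use `stats::fisher.test` instead.
#' @return list with `X2`, `df`, `p` (Fisher: `X2`/`df` are `NA`).
#' @export
chiSquared <- function(table, fisher = FALSE) {
  table <- as.matrix(table)
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2x2 table")
  if (any(table < 0) || any(table != round(table)))
    stop("cells must be nonnegative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column marginal")
  if (fisher) {
    ft <- stats::fisher.test(table)
    return(list(X2 = NA_real_, df = NA_real_, p = ft$p.value))
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(X2 = unname(ct$statistic), df = unname(ct$parameter), p = ct$p.value)
}

#' Ratio of pooled positive proportions between two group collections
#'
#' `(sum(positivesA)/sum(totalsA)) / (sum(positivesB)/sum(totalsB))`, e.g.
#' the fold increase of blood-culture positivity in the poor-prognosis
#' endotypes over the remaining endotypes.
#'
#' @param positivesA,totalsA,positivesB,totalsB nonnegative integer vectors.
#' @return the ratio; `Inf` with a warning when group B has no positives.
#' @export
proportionRatio <- function(positivesA, totalsA, positivesB, totalsB) {
  if (sum(totalsA) <= 0 || sum(totalsB) <= 0) stop("totals must be positive")
  pA <- sum(positivesA) / sum(totalsA)
  pB <- sum(positivesB) / sum(totalsB)
  if (pB == 0) {
    warning("no positives in group B; ratio is infinite")
    return(Inf)
  }
  pA / pB
}

#' Kaplan-Meier product-limit estimate
#'
#' @param times nonnegative event/censoring times.
#' @param events binary event indicators (1 = event, 0 = censored).
#' @return data.frame of class `"SurvivalCurve"`: `time` (ascending event
#'   times), `survival`, `at_risk`, `n_event`, `n_censored`; survival starts
#'   at 1 and is nonincreasing.
#' @export
kmEstimate <- function(times, events) {
  if (any(times < 0)) stop("negative times")
  events <- as.integer(events)
  stopifnot(all(events %in% c(0L, 1L)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, survival = fit$surv,
                    at_risk = fit$n.risk, n_event = fit$n.event,
                    n_censored = fit$n.censor, row.names = NULL)
  class(out) <- c("SurvivalCurve", "data.frame")
  out
}

#' Log-rank test between two survival groups
#'
#' Standard (unweighted) log-rank statistic comparing observed and expected
#' events over the shared event times, 1 degree of freedom.
#'
#' @param times1,events1,times2,events2 per-group times and binary event
#'   indicators.
#' @return list with `X2`, `p`.
#' @export
logRank <- function(times1, events1, times2, events2) {
  if (!length(times1) || !length(times2)) stop("both groups must be nonempty")
  if (sum(events1) + sum(events2) == 0)
    stop("no events in either group; log-rank undefined")
  time <- c(times1, times2)
  event <- c(events1, events2)
  group <- rep(c(1L, 2L), c(length(times1), length(times2)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, rho = 0)
  list(X2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
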