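#' Match discovered cluster labels to reference labels
#'
#' Greedy one-to-one assignment of discovered classes to reference classes by
#' decreasing overlap in the confusion matrix, used to compare clustering
#' output with planted ground truth.
#'
#' @param found,truth parallel label vectors.
#' @return named character vector mapping each found class to a reference
#'   class (`NA` for unmatched surplus classes).
#' @export
matchClusters <- function(found, truth) {
  tab <- table(found, truth)
  map <- stats::setNames(rep(NA_character_, nrow(tab)), rownames(tab))
  while (any(tab > -1) && any(is.na(map)) && ncol(tab) > 0) {
    best <- which(tab == max(tab), arr.ind = TRUE)[1, , drop = TRUE]
    if (tab[best[1], best[2]] < 0) break
    map[rownames(tab)[best[1]]] <- colnames(tab)[best[2]]
    tab[best[1], ] <- -1
    tab[, best[2]] <- -1
  }
  map
}

.defaultStages <- function() {
  list(
    severity = list(min_fold = 1.25, max_adj_p = 0.05, cv_folds = 10),
    consensus = list(kRange = 2:8, nResamples = 100, subsampleFraction = 0.8,
                     nVarGenes = 2000),
    markers = list(min_fold = 1.5, max_adj_p = 0.05, cap = 200),
    classifier = list(gene_budget = 40, budget_slack = 5, cv_folds = 5,
                      repeats = 2),
    pairs = list(min_auc = 0.85, cv_folds = 5),
    gsva = list(tau = 1)
  )
}

.mergeStages <- function(user) {
  stages <- .defaultStages()
  for (nm in names(user)) stages[[nm]][names(user[[nm]])] <- user[[nm]]
  stages
}

#' Run the full endotype discovery and transfer pipeline
#'
#' Executes, in order: normalization; severity and mortality differential
#' expression plus LASSO signatures trained on the extreme phenotypes (High
#' vs Low severity; died vs survived) with transfer evaluation on
#' High + Intermediate vs Low; consensus k-medoids endotype discovery on the
#' ER discovery cohort only; unique per-endotype marker signatures; the
#' gene-budgeted multinomial classifier with cross-validation; gene-pair
#' derivation; endotype prediction on the ER validation and ICU cohorts with
#' GSVA-style enrichment confirmation; and clinical statistics by endotype.
#' Validation cohorts never influence clustering, marker selection or penalty
#' tuning. When the cohort carries planted ground truth a recovery report
#' (selected k, ARI, per-endotype marker Jaccard, classifier CV metrics,
#' transfer accuracy) is assembled.
#'
#' @param config either a list with components `simulate` (a [simConfig()])
#'   or `paths` (a fixture directory for [readCohortFixture()]), an optional
#'   `seed` (default: the simulation seed), optional `outDir` for artifact
#'   files, and optional per-stage parameter overrides under `stages`; or the
#'   path of a YAML file holding the same structure.
#' @return a list of class `"PipelineResult"`: the fitted objects
#'   (`consensus`, `markerSets`, `classifier`, `pairs`, `severitySignature`,
#'   `mortalitySignature`, predictions, enrichment scores, clinical
#'   statistics) plus `report`, the recovery report.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- .configFromYAML(config)
  stopifnot(is.list(config))
  if (is.null(config$simulate) == is.null(config$paths))
    stop("config must have exactly one of 'simulate' or 'paths'")
  stages <- .mergeStages(config$stages %||% list())

  cohort <- if (!is.null(config$simulate)) {
    simulateCohort(config$simulate)
  } else {
    readCohortFixture(config$paths)
  }
  seed <- as.integer(config$seed %||% groundTruth(cohort)$config$seed %||% 1L)

  counts <- assay(cohort, "counts")
  meta <- sampleTable(cohort)
  sf <- computeSizeFactors(counts)
  expr <- normalizeLog2(counts, sf)

  ## --- severity & mortality signatures (all septic patients, per design) ---
  septic <- meta$sample_id[meta$cohort != "healthy"]
  sev <- assignSeverity(meta$sofa24[match(septic, meta$sample_id)])
  names(sev) <- septic
  high <- names(sev)[!is.na(sev) & sev == "High"]
  low <- names(sev)[!is.na(sev) & sev == "Low"]
  sevDE <- nbWaldDE(counts, high, low, sizeFactors = sf)
  sevCand <- filterDE(sevDE, min_fold = stages$severity$min_fold,
                      max_adj_p = stages$severity$max_adj_p, direction = "both")
  sevModel <- NULL; sevTransfer <- NULL
  if (length(sevCand) >= 2L) {
    sevModel <- lassoSignature(expr[, c(high, low)],
                               droplevels(sev[c(high, low)]), sevCand,
                               cv_folds = stages$severity$cv_folds,
                               seed = substreamSeed(seed, "severity-lasso"),
                               comparison = "High vs Low severity")
    merged <- ifelse(is.na(sev), NA, ifelse(sev == "Low", "Low", "HighInt"))
    names(merged) <- names(sev)
    if (length(sevModel@genes))
      sevTransfer <- evaluateSignatureTransfer(
        sevModel, expr[, septic], merged[septic],
        cv_folds = 5, repeats = 2,
        seed = substreamSeed(seed, "severity-transfer"))
  }
  died <- stats::setNames(meta$died_in_hospital[match(septic, meta$sample_id)], septic)
  dead <- names(died)[!is.na(died) & died]
  alive <- names(died)[!is.na(died) & !died]
  mortModel <- NULL
  mortDE <- nbWaldDE(counts, dead, alive, sizeFactors = sf)
  mortCand <- filterDE(mortDE, min_fold = stages$severity$min_fold,
                       max_adj_p = stages$severity$max_adj_p, direction = "both")
  if (length(mortCand) >= 2L)
    mortModel <- lassoSignature(expr[, c(dead, alive)],
                                factor(ifelse(died[c(dead, alive)], "Died", "Survived"),
                                       levels = c("Survived", "Died")),
                                mortCand, cv_folds = stages$severity$cv_folds,
                                seed = substreamSeed(seed, "mortality-lasso"),
                                comparison = "Died vs Survived")

  ## --- endotype discovery on the ER discovery cohort only ---
  disc <- meta$sample_id[meta$cohort == "ER_discovery"]
  cr <- consensusCluster(expr[, disc],
                         kRange = stages$consensus$kRange,
                         nResamples = stages$consensus$nResamples,
                         subsampleFraction = stages$consensus$subsampleFraction,
                         nVarGenes = stages$consensus$nVarGenes,
                         seed = substreamSeed(seed, "consensus"))
  discLabels <- stats::setNames(paste0("C", finalLabels(cr)), disc)

  deTables <- perEndotypeDE(counts[, disc], discLabels, sizeFactors = sf[disc])
  markerSets <- uniqueUpregulatedMarkers(deTables,
                                         min_fold = stages$markers$min_fold,
                                         max_adj_p = stages$markers$max_adj_p,
                                         cap = stages$markers$cap)

  candidates <- unlist(markerSets, use.names = FALSE)
  classifier <- fitMultinomialLasso(expr[, disc], discLabels, candidates,
                                    gene_budget = stages$classifier$gene_budget,
                                    budget_slack = stages$classifier$budget_slack,
                                    cv_folds = stages$classifier$cv_folds,
                                    seed = substreamSeed(seed, "multinomial"))
  trainer <- function(trainExpr, trainLabels, s)
    fitMultinomialLasso(trainExpr, trainLabels, candidates,
                        gene_budget = stages$classifier$gene_budget,
                        budget_slack = stages$classifier$budget_slack,
                        cv_folds = stages$classifier$cv_folds, seed = s)
  classifierCV <- crossValidate(expr[, disc], discLabels, trainer,
                                folds = stages$classifier$cv_folds,
                                repeats = stages$classifier$repeats,
                                seed = substreamSeed(seed, "classifier-cv"))
  pairs <- deriveGenePairs(expr[, disc], discLabels, classifier@genes,
                           min_auc = stages$pairs$min_auc,
                           cv_folds = stages$pairs$cv_folds,
                           seed = substreamSeed(seed, "pairs"))

  ## --- transfer to validation cohorts: classifier assigns, GSVA confirms ---
  valid <- meta$sample_id[meta$cohort %in% c("ER_validation", "ICU")]
  predictions <- predictEndotype(classifier, expr[, valid])
  gsva <- gsvaScores(expr[, valid], markerSets, tau = stages$gsva$tau)
  gsvaCalls <- classifyByEnrichment(gsva)
  gsvaAgreement <- mean(gsvaCalls$label == predictions$labels[gsvaCalls$sample_id])

  ## --- clinical statistics by endotype over all septic samples ---
  allLabels <- c(discLabels, predictions$labels)
  clin <- meta[match(names(allLabels), meta$sample_id), ]
  byEnd <- split(seq_len(nrow(clin)), allLabels)
  kwSofa <- kruskalWallis(lapply(byEnd, function(i) clin$sofa24[i]))
  dunnSofa <- if (length(byEnd) >= 3L)
    dunnPosthoc(lapply(byEnd, function(i) clin$sofa24[i])) else NULL
  bcTab <- t(vapply(byEnd, function(i) {
    x <- clin$blood_culture_positive[i]
    c(pos = sum(x, na.rm = TRUE), neg = sum(!x, na.rm = TRUE))
  }, c(pos = 0, neg = 0)))
  chisqBlood <- chiSquared(bcTab)
  mortTab <- t(vapply(byEnd, function(i) {
    x <- clin$died_in_hospital[i]
    c(died = sum(x, na.rm = TRUE), survived = sum(!x, na.rm = TRUE))
  }, c(died = 0, survived = 0)))
  chisqMort <- chiSquared(mortTab)
  # combined-prognosis survival comparison: the two endotypes with the
  # highest mean SOFA vs the rest
  meanSofa <- vapply(byEnd, function(i) mean(clin$sofa24[i], na.rm = TRUE), 0)
  nPoor <- if (length(byEnd) > 2L) 2L else 1L
  worst <- names(sort(meanSofa, decreasing = TRUE))[seq_len(nPoor)]
  inWorst <- allLabels %in% worst
  survOK <- !is.na(clin$survival_time_days)
  kmCurves <- list(
    poor = kmEstimate(clin$survival_time_days[inWorst & survOK],
                      clin$event[inWorst & survOK]),
    fair = kmEstimate(clin$survival_time_days[!inWorst & survOK],
                      clin$event[!inWorst & survOK]))
  lr <- logRank(clin$survival_time_days[inWorst & survOK],
                clin$event[inWorst & survOK],
                clin$survival_time_days[!inWorst & survOK],
                clin$event[!inWorst & survOK])

  ## --- recovery report against planted ground truth ---
  gt <- groundTruth(cohort)
  report <- list(k_selected = kSelected(cr),
                 gsva_classifier_agreement = gsvaAgreement,
                 classifier_cv = as.list(cvMetrics(classifierCV)),
                 n_pairs = nrow(pairs),
                 severity_transfer_cv = if (!is.null(sevTransfer))
                   as.list(cvMetrics(sevTransfer)) else NULL,
                 kw_sofa_p = kwSofa$p, chisq_blood_culture_p = chisqBlood$p,
                 chisq_mortality_p = chisqMort$p, logrank_p = lr$p)
  if (!is.null(gt) && length(gt$endotype)) {
    truthDisc <- gt$endotype[disc]
    report$ari <- mclust::adjustedRandIndex(discLabels, truthDisc)
    map <- matchClusters(discLabels, truthDisc)
    report$cluster_map <- as.list(map)
    jac <- vapply(names(markerSets), function(cl) {
      tr <- map[[cl]]
      if (is.na(tr)) return(NA_real_)
      jaccard(markerSets[[cl]], gt$markerGenes[[tr]])
    }, 0)
    names(jac) <- names(markerSets)
    report$marker_jaccard <- as.list(jac)
    truthValid <- gt$endotype[valid]
    mapped <- unname(map[predictions$labels])
    report$transfer_accuracy <- mean(mapped == truthValid, na.rm = TRUE)
  }

  result <- list(cohort = cohort, sizeFactors = sf,
                 severityDE = sevDE, severitySignature = sevModel,
                 severityTransfer = sevTransfer,
                 mortalityDE = mortDE, mortalitySignature = mortModel,
                 consensus = cr, discoveryLabels = discLabels,
                 markerSets = markerSets, classifier = classifier,
                 classifierCV = classifierCV, pairs = pairs,
                 predictions = predictions, gsva = gsva,
                 gsvaCalls = gsvaCalls,
                 clinical = list(kw_sofa = kwSofa, dunn_sofa = dunnSofa,
                                 blood_culture = chisqBlood,
                                 mortality = chisqMort, km = kmCurves,
                                 log_rank = lr,
                                 combined_poor_prognosis = worst),
                 report = report, seed = seed)
  class(result) <- "PipelineResult"
  if (!is.null(config$outDir)) .writePipelineArtifacts(result, config$outDir)
  result
}

.configFromYAML <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$simulate))
    cfg$simulate <- do.call(simConfig, cfg$simulate)
  cfg
}

.writePipelineArtifacts <- function(result, outDir) {
  if (!dir.exists(outDir) && !dir.create(outDir, recursive = TRUE))
    stop("cannot create output directory: ", outDir)
  cr <- result$consensus
  utils::write.table(
    data.frame(sample_id = names(result$discoveryLabels),
               endotype = unname(result$discoveryLabels)),
    file.path(outDir, "discovery_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(clusterMetrics(cr),
                     file.path(outDir, "cluster_metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- consensusMatrix(cr)
  utils::write.table(data.frame(sample_id = rownames(cm), cm,
                                check.names = FALSE),
                     file.path(outDir, "consensus_matrix.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeGMT(lapply(result$markerSets, as.character),
           file.path(outDir, "endotype_signatures.gmt"),
           descriptions = rep("unique_upregulated_markers",
                              length(result$markerSets)))
  model <- result$classifier
  jsonlite::write_json(
    list(genes = model@genes, classes = model@classes,
         weights = as.data.frame(model@weights),
         intercepts = as.list(model@intercepts), lambda = model@lambda,
         training = model@training),
    file.path(outDir, "classifier.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(result$pairs, file.path(outDir, "gene_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(result$predictions$labels),
               endotype = unname(result$predictions$labels),
               result$predictions$prob, check.names = FALSE),
    file.path(outDir, "predicted_endotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample_id = rownames(result$gsva),
                                result$gsva, check.names = FALSE),
                     file.path(outDir, "gsva_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result$report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outDir)
}

#' @export
print.PipelineResult <- function(x, ...) {
  r <- x$report
  cat("Endotype pipeline result (seed", x$seed, ")\n")
  cat("  selected k:", r$k_selected, "\n")
  if (!is.null(r$ari)) cat("  discovery ARI vs truth:", round(r$ari, 3), "\n")
  cat("  classifier CV accuracy:", round(r$classifier_cv$accuracy, 3),
      "| macro AUC:", round(r$classifier_cv$auc, 3), "\n")
  if (!is.null(r$transfer_accuracy))
    cat("  transfer accuracy (validation + ICU):",
        round(r$transfer_accuracy, 3), "\n")
  cat("  gene pairs retained:", r$n_pairs, "\n")
  invisible(x)
}
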