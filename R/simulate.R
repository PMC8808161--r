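#' Simulation configuration for a synthetic early-sepsis cohort
#'
#' Bundles and validates the parameters of the negative-binomial cohort
#' generator. Defaults emulate the structure of a multi-centre early-sepsis
#' RNA-Seq study: an ER discovery cohort (n = 182), an ER validation cohort
#' (n = 84), an ICU cohort (n = 82) and healthy controls (n = 39), with five
#' latent endotypes each carrying a block of uniquely upregulated marker
#' genes, endotype-dependent 24 h SOFA scores, mortality and blood-culture
#' positivity, plus graded severity and mortality effect genes.
#'
#' @param n_er_discovery,n_er_validation,n_icu,n_healthy cohort sizes.
#' @param n_genes number of genes simulated.
#' @param k_endotypes number of latent endotypes.
#' @param markers_per_endotype uniquely upregulated marker genes planted per
#'   endotype (marker sets are pairwise disjoint).
#' @param marker_log2fc_range range of the uniform distribution the per-marker
#'   log2 fold change is drawn from.
#' @param n_severity_genes,severity_log2fc severity effect genes and their
#'   |log2 fold change|; the effect is graded (High severity = full effect,
#'   Intermediate = half, Low = none), half the genes up-, half downregulated.
#' @param n_mortality_genes,mortality_log2fc analogous effect in patients who
#'   die in hospital.
#' @param baseline_mean_logmu lognormal (meanlog, sdlog) of per-gene baseline
#'   mean expression.
#' @param dispersion range of the per-gene NB dispersion phi
#'   (variance = mean + phi * mean^2).
#' @param libsize_sd sdlog of the lognormal library-size factor.
#' @param endotype_proportions simplex vector of endotype prevalences.
#' @param sofa_model list with per-endotype `mean` and `sd` of the 24 h SOFA
#'   score in ER patients and an `icu_multiplier` applied to the means for
#'   ICU patients; draws are rounded and truncated to `[0, 24]`.
#' @param mortality_rates,blood_culture_rates per-endotype Bernoulli rates.
#' @param seed master seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return a validated list of class `"SimConfig"`.
#' @export
simConfig <- function(n_er_discovery = 182L, n_er_validation = 84L,
                      n_icu = 82L, n_healthy = 39L,
                      n_genes = 8000L, k_endotypes = 5L,
                      markers_per_endotype = 220L,
                      marker_log2fc_range = c(1.0, 2.5),
                      n_severity_genes = 150L, severity_log2fc = 1.0,
                      n_mortality_genes = 100L, mortality_log2fc = 1.0,
                      baseline_mean_logmu = c(4.0, 1.5),
                      dispersion = c(0.05, 0.5),
                      libsize_sd = 0.25,
                      endotype_proportions = c(0.31, 0.17, 0.21, 0.22, 0.09),
                      sofa_model = list(mean = c(2.5, 2.2, 1.4, 1.8, 1.7),
                                        sd = rep(2, 5), icu_multiplier = 3),
                      mortality_rates = c(0.25, 0.15, 0.05, 0.08, 0.04),
                      blood_culture_rates = c(0.284, 0.289, 0.148, 0.089, 0.042),
                      seed = 1L) {
  cfg <- list(
    n_er_discovery = as.integer(n_er_discovery),
    n_er_validation = as.integer(n_er_validation),
    n_icu = as.integer(n_icu), n_healthy = as.integer(n_healthy),
    n_genes = as.integer(n_genes), k_endotypes = as.integer(k_endotypes),
    markers_per_endotype = as.integer(markers_per_endotype),
    marker_log2fc_range = marker_log2fc_range,
    n_severity_genes = as.integer(n_severity_genes),
    severity_log2fc = severity_log2fc,
    n_mortality_genes = as.integer(n_mortality_genes),
    mortality_log2fc = mortality_log2fc,
    baseline_mean_logmu = baseline_mean_logmu,
    dispersion = dispersion, libsize_sd = libsize_sd,
    endotype_proportions = endotype_proportions,
    sofa_model = sofa_model,
    mortality_rates = mortality_rates,
    blood_culture_rates = blood_culture_rates,
    seed = as.integer(seed)
  )
  class(cfg) <- "SimConfig"
  validateSimConfig(cfg)
  cfg
}

validateSimConfig <- function(cfg) {
  k <- cfg$k_endotypes
  if (abs(sum(cfg$endotype_proportions) - 1) > 1e-9)
    stop("endotype_proportions must sum to 1")
  if (cfg$markers_per_endotype * k > cfg$n_genes)
    stop("markers_per_endotype * k_endotypes exceeds n_genes")
  perK <- list(endotype_proportions = cfg$endotype_proportions,
               mortality_rates = cfg$mortality_rates,
               blood_culture_rates = cfg$blood_culture_rates,
               sofa_mean = cfg$sofa_model$mean, sofa_sd = cfg$sofa_model$sd)
  bad <- names(perK)[vapply(perK, length, 1L) != k]
  if (length(bad))
    stop("per-endotype parameter vectors must have length k_endotypes: ",
         paste(bad, collapse = ", "))
  rates <- c(cfg$mortality_rates, cfg$blood_culture_rates, cfg$endotype_proportions)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (cfg$markers_per_endotype * k + cfg$n_severity_genes + cfg$n_mortality_genes >
      cfg$n_genes)
    stop("planted gene sets do not fit disjointly into n_genes")
  if (diff(cfg$dispersion) < 0 || any(cfg$dispersion <= 0))
    stop("dispersion must be a positive increasing range")
  invisible(cfg)
}

.severityScale <- function(sofa24) {
  # graded planted severity effect: High = 1, Intermediate = 1/2, Low = 0
  ifelse(is.na(sofa24), 0, ifelse(sofa24 >= 5, 1, ifelse(sofa24 >= 2, 0.5, 0)))
}

#' Simulate a synthetic sepsis cohort with planted ground truth
#'
#' Draws counts `K_ij ~ NB(mean = s_j * mu_i * 2^beta_ij, dispersion phi_i)`
#' where `s_j` is a lognormal library-size factor, `mu_i` a lognormal baseline
#' and `beta_ij` the planted log2 effect: the marker effect when gene i is a
#' marker of sample j's endotype, the (graded) severity effect when i is a
#' severity gene, and the mortality effect when i is a mortality gene and j
#' dies in hospital. Healthy controls carry no planted effects and no
#' endotype. Clinical covariates (SOFA at 24 h/72 h, qSOFA, mortality, blood
#' culture, 28-day survival, age, sex) are drawn from the endotype-conditional
#' models in the configuration.
#'
#' @param config a [simConfig()] object.
#' @return a [SepsisCohort] whose `metadata(x)$groundTruth` holds the endotype
#'   labels, the per-endotype marker gene sets, the severity and mortality
#'   gene sets and the per-gene planted log2 fold changes.
#' @examples
#' sc <- simulateCohort(simConfig(n_genes = 300, markers_per_endotype = 20,
#'                                n_severity_genes = 10, n_mortality_genes = 10))
#' table(sampleTable(sc)$cohort)
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  validateSimConfig(config)
  set.seed(config$seed)
  k <- config$k_endotypes
  geneIds <- sprintf("G%05d", seq_len(config$n_genes))

  # disjoint planted gene allocation
  pool <- sample(geneIds)
  nMark <- config$markers_per_endotype
  markerGenes <- lapply(seq_len(k), function(e)
    sort(pool[(e - 1) * nMark + seq_len(nMark)]))
  names(markerGenes) <- paste0("E", seq_len(k))
  used <- k * nMark
  severityGenes <- sort(pool[used + seq_len(config$n_severity_genes)])
  used <- used + config$n_severity_genes
  mortalityGenes <- sort(pool[used + seq_len(config$n_mortality_genes)])
  if (anyDuplicated(unlist(markerGenes)))
    stop("marker allocation not disjoint")

  cohort <- c(rep("ER_discovery", config$n_er_discovery),
              rep("ER_validation", config$n_er_validation),
              rep("ICU", config$n_icu),
              rep("healthy", config$n_healthy))
  n <- length(cohort)
  sampleIds <- sprintf("S%04d", seq_len(n))
  septic <- cohort != "healthy"

  endotype <- rep(NA_integer_, n)
  endotype[septic] <- sample.int(k, sum(septic), replace = TRUE,
                                 prob = config$endotype_proportions)

  sofaMean <- ifelse(cohort == "ICU",
                     config$sofa_model$mean[endotype] * config$sofa_model$icu_multiplier,
                     config$sofa_model$mean[endotype])
  sofa24 <- rep(NA_integer_, n)
  sofa24[septic] <- pmin(24L, pmax(0L, as.integer(round(
    stats::rnorm(sum(septic), sofaMean[septic], config$sofa_model$sd[endotype[septic]])))))
  sofa72 <- rep(NA_integer_, n)
  sofa72[septic] <- pmin(24L, pmax(0L, as.integer(round(
    0.8 * sofa24[septic] + stats::rnorm(sum(septic), 0, 1)))))
  qsofa <- rep(NA_integer_, n)
  qsofa[septic] <- pmin(3L, pmax(0L, as.integer(round(
    sofa24[septic] / 4 + stats::rnorm(sum(septic), 0, 0.5)))))

  died <- rep(NA, n)
  died[septic] <- stats::rbinom(sum(septic), 1, config$mortality_rates[endotype[septic]]) == 1
  bcx <- rep(NA, n)
  bcx[septic] <- stats::rbinom(sum(septic), 1, config$blood_culture_rates[endotype[septic]]) == 1

  # 28-day survival: deaths occur uniformly over days 1..28; survivors are
  # censored at hospital discharge, capped at the 28-day horizon
  stay <- pmin(65, pmax(1, round(stats::rgamma(n, shape = 2, scale = 3.75))))
  survTime <- rep(NA_real_, n)
  event <- rep(NA, n)
  survTime[septic] <- ifelse(died[septic],
                             stats::runif(sum(septic), 1, 28),
                             pmin(stay[septic], 28))
  event[septic] <- died[septic]

  age <- numeric(n)
  age[cohort %in% c("ER_discovery", "ER_validation")] <-
    stats::rnorm(sum(cohort %in% c("ER_discovery", "ER_validation")), 56, 13)
  age[cohort == "ICU"] <- stats::rnorm(sum(cohort == "ICU"), 62, 12)
  age[cohort == "healthy"] <- stats::rnorm(sum(cohort == "healthy"), 50, 15)
  age <- round(pmin(96, pmax(19, age)))
  sex <- ifelse(stats::rbinom(n, 1, 0.45) == 1, "F", "M")

  # planted log2 effects
  markerFC <- stats::runif(k * nMark, config$marker_log2fc_range[1],
                           config$marker_log2fc_range[2])
  names(markerFC) <- unlist(markerGenes)
  sevSign <- rep(c(1, -1), length.out = config$n_severity_genes)
  sevFC <- sevSign * config$severity_log2fc
  names(sevFC) <- severityGenes
  mortSign <- rep(c(1, -1), length.out = config$n_mortality_genes)
  mortFC <- mortSign * config$mortality_log2fc
  names(mortFC) <- mortalityGenes

  B <- matrix(0, config$n_genes, n, dimnames = list(geneIds, sampleIds))
  for (e in seq_len(k)) {
    js <- which(!is.na(endotype) & endotype == e)
    if (length(js))
      B[markerGenes[[e]], js] <- markerFC[markerGenes[[e]]]
  }
  sevScale <- .severityScale(sofa24) * as.numeric(septic)
  if (config$n_severity_genes > 0)
    B[severityGenes, ] <- B[severityGenes, ] + outer(sevFC, sevScale)
  diedNum <- as.numeric(!is.na(died) & died)
  if (config$n_mortality_genes > 0)
    B[mortalityGenes, ] <- B[mortalityGenes, ] + outer(mortFC, diedNum)

  mu0 <- stats::rlnorm(config$n_genes, config$baseline_mean_logmu[1],
                       config$baseline_mean_logmu[2])
  phi <- stats::runif(config$n_genes, config$dispersion[1], config$dispersion[2])
  s <- stats::rlnorm(n, 0, config$libsize_sd)
  mu <- outer(mu0, s) * 2^B
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / phi),
                   nrow = config$n_genes, dimnames = dimnames(B))
  storage.mode(counts) <- "integer"

  cd <- DataFrame(
    cohort = cohort, sofa24 = sofa24, sofa72 = sofa72, qsofa = qsofa,
    died_in_hospital = died, survival_time_days = survTime, event = event,
    blood_culture_positive = bcx, age = age, sex = sex,
    endotype = ifelse(is.na(endotype), NA_character_, paste0("E", endotype)),
    row.names = sampleIds
  )
  gt <- list(
    endotype = stats::setNames(as.character(cd$endotype), sampleIds),
    markerGenes = markerGenes,
    severityGenes = severityGenes,
    mortalityGenes = mortalityGenes,
    trueLog2fc = c(markerFC, sevFC, mortFC),
    config = config
  )
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             metadata = list(groundTruth = gt))
  methods::new("SepsisCohort", se)
}
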