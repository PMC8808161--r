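# SepsisEndotypes

Sepsis is notoriously heterogeneous: patients arriving at the emergency room
with suspected infection range from mildly ill to hours away from multi-organ
failure, and clinical scores measured at presentation predict that trajectory
poorly. One productive response has been to stratify early sepsis patients
into **endotypes** — subgroups defined by distinct underlying immune
programs visible in whole-blood gene expression — and to derive compact gene
signatures that anticipate severity and mortality at first clinical
presentation.

`SepsisEndotypes` implements that analysis as a tested, reusable R pipeline
for transcriptomic count data:

* **Endotype discovery** — subsampled consensus clustering with *k*-medoids
  (PAM) on the Manhattan distance of the most-variable genes. For each
  candidate number of clusters *k*, the consensus matrix records how often two
  patients co-cluster when co-sampled; *k* is chosen by a committee of
  cluster-validity metrics (mean silhouette, PAC, Calinski–Harabasz,
  Davies–Bouldin) aggregated by mean rank.
* **Unique endotype signatures** — per-endotype negative-binomial Wald
  differential expression (endotype vs all others) with median-of-ratios
  normalization and Benjamini–Hochberg correction; each signature keeps the
  up to 200 most-upregulated significant genes unique to its endotype.
* **Severity and mortality signatures** — L1-penalized (LASSO) logistic
  regression trained on extreme phenotypes (High vs Low severity by 24 h SOFA:
  High ≥ 5, Intermediate ≥ 2 and < 5, Low < 2; died vs survived), with
  cross-validated penalty selection (1-SE rule), fold-change-reduced variants,
  and transfer evaluation on the merged High + Intermediate vs Low comparison.
* **A gene-budgeted endotype classifier** — multinomial LASSO over the union
  of the unique signatures, with the penalty tuned so the selected gene union
  lands on a 40-gene budget, plus exhaustive derivation of two-gene rules
  (one-vs-rest logistic pairs) that stratify single endotypes.
* **Endotype transfer** — the classifier assigns endotypes in validation and
  ICU cohorts; single-sample gene-set enrichment (a GSVA-style weighted
  Kolmogorov–Smirnov random-walk statistic) confirms the assignments.
* **Clinical statistics** — Kruskal–Wallis with Dunn's post-hoc, chi-squared
  independence tests, pooled proportion ratios, Kaplan–Meier estimation and
  log-rank tests across endotypes, including combined poor- vs
  fair-prognosis comparisons.
* **A synthetic cohort generator** — negative-binomial counts
  (variance = μ + φμ²) with planted endotype marker blocks, graded severity
  and mortality effects, endotype-dependent SOFA scores, mortality,
  blood-culture positivity and 28-day survival, so the whole pipeline is
  testable end-to-end with known ground truth.

The package is Bioconductor-style: cohorts are `SepsisCohort` objects
(extending `SummarizedExperiment`), with S4 classes for consensus results,
signature models and cross-validation reports.

## Worked example

```r
library(SepsisEndotypes)

# a synthetic multi-cohort study: 182 ER discovery + 84 ER validation +
# 82 ICU patients + 39 healthy controls, 8000 genes, 5 planted endotypes
res <- runPipeline(list(simulate = simConfig(seed = 1)))
res
```

which prints (numbers from this exact run):

```
Endotype pipeline result (seed 1 )
  selected k: 5
  discovery ARI vs truth: 1
  classifier CV accuracy: 1 | macro AUC: 1
  transfer accuracy (validation + ICU): 1
  gene pairs retained: 1566
```

Read: the validity-metric committee recovered the planted number of endotypes
(k = 5); the consensus labels match the planted endotype labels exactly
(adjusted Rand index 1); the 40-gene multinomial classifier is perfect under
repeated stratified cross-validation on the discovery cohort and transfers
perfectly to the held-out validation and ICU cohorts; 1566 two-gene rules
reached the 0.85 CV-AUC retention threshold. (Planted effects in the default
generator are strong relative to biological noise on real cohorts — the
vignette discusses what these recoveries do and do not demonstrate.)

Individual stages are exported and composable:

```r
sc    <- simulateCohort(simConfig(seed = 1))
expr  <- normalizeLog2(sc)                                # log2(K/s + 1)
disc  <- colnames(sc)[sc$cohort == "ER_discovery"]
cons  <- consensusCluster(expr[, disc], kRange = 2:8, seed = 7)
kSelected(cons); clusterMetrics(cons)
de    <- perEndotypeDE(sc, setNames(paste0("C", finalLabels(cons)), disc))
sigs  <- uniqueUpregulatedMarkers(de)                     # <= 200 genes each
model <- fitMultinomialLasso(expr[, disc],
                             setNames(paste0("C", finalLabels(cons)), disc),
                             unlist(sigs), gene_budget = 40)
```

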