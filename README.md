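# subtypeAWA

Benchmarking harness for multi-omics clustering algorithms used in
cancer molecular subtyping. Given per-omics feature matrices, a clinical
table and one cluster assignment per candidate method, it computes

* **internal validity indices** — silhouette coefficient (S),
  Calinski–Harabasz index (CH), Dunn's index (D) — on the standardized
  concatenated multi-omics representation, and
* **clinical relevance metrics** — the k-sample log-rank p-value on
  overall survival (LRT) and the count of enriched clinical parameters
  (ECP; Pearson χ² for discrete covariates, Kruskal–Wallis for numeric
  ones),

harmonizes the raw values across methods onto a common 0–10 score scale
(min–max after orienting every metric larger-is-better, with LRT mapped
through −log₁₀ p), and aggregates them into the **accuracy-weighted
average**

    AWA = ((S_S + S_CH + S_D)·w1 + (S_LRT + S_ECP)·w2) / (3·w1 + 2·w2)

with internal weight `w1` and clinical weight `w2` (default 0.5/0.5).
Methods are ranked by AWA, optionally across a sweep of weight settings
and across datasets. The package also ships the standard per-omics
preprocessing rules (copy-number deduplication, methylation β ≥ 0.3
filtering, log₂ + MAD/variance feature filtering, missingness filtering,
sample-mean imputation, unit-variance standardization) and a seeded
synthetic multi-omics generator with known subtype structure,
subtype-dependent survival and controllable covariate enrichment, so the
whole pipeline is testable without external data. Who it is for:
method developers comparing a new integration algorithm against
competitors, and analysts choosing a subtyping method for a cohort.

## Worked example

```r
library(subtypeAWA)

# a K = 3 cohort, 50 samples per subtype, four omics layers, strong
# signal (effect size 5 x noise SD), cluster hazard ratio 3
cfg <- simConfig(K = 3, nPerCluster = rep(50L, 3),
                 omicsSpecs = list(
                   list(kind = "mrna", nFeatures = 100L, effectSize = 5,
                        noiseSd = 1, missingRate = 0.02),
                   list(kind = "methylation", nFeatures = 60L, effectSize = 5,
                        noiseSd = 1, missingRate = 0.02)),
                 hazardMultipliers = c(1, 1.7, 3), seed = 1)
sim <- simulateDataset(cfg)

# evaluate the ground truth against progressively corrupted labellings
truth <- sim$truth$labels
methods <- list(truth,
                perturbLabels(truth, 0.25, seed = 1001),
                perturbLabels(truth, 0.5,  seed = 2001),
                perturbLabels(truth, 1,    seed = 3001))
report <- evaluateMethods(sim$dataset, sim$clinical, methods)
report
```

A run of the bundled acceptance pipeline (same construction, all four
default omics layers, seed 1) prints:

```
AWA ranking (w1 = w2 = 0.5):
  truth             9.732
  perturbed_0.25    6.019
  perturbed_0.5     4.190
  perturbed_1       0.000
```

Reading the numbers: the ground-truth labelling wins every internal
metric and the ECP count (score 10 each) and nearly the log-rank score,
giving AWA 9.73; each additional 25–50% of corrupted labels loses
cluster compactness, survival separation and covariate enrichment, and
the fully random labelling is worst on every metric, pinning its AWA at
0 (scores are min–max normalized across the evaluated methods, so 0 and
10 mean worst/best *within this comparison*, not absolute quality).
`writeReport()` serializes raw metrics, scores, per-covariate
enrichment p-values, AWA, ranking and the weight sweep as JSON;
`writeScoreBoard()` emits the methods-by-metrics table as TSV;
`compareReports()` averages AWA across datasets.

File-based workflows (TSV matrices, YAML run configs) are supported via
`readOmicsMatrix()` / `readClinicalTable()` / `readClusterAssignment()`
/ `readEvalConfig()`, or the thin CLI at `inst/scripts/subtype-awa.R`
with `simulate` / `preprocess` / `evaluate` subcommands.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline from scratch at the given seed — simulates
the benchmark cohort, evaluates the ground-truth labels against three
perturbation levels at equal internal/clinical weights, and writes the
ranked evaluation report (`evaluation_report.json`, `scoreboard.tsv`)
next to the requested output file.

See `vignettes/evaluating-multiomics-subtyping.Rmd` for the model, the
preprocessing conventions, the synthetic generator's assumptions, and
the numerical edge-case policy.
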