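---
title: "Evaluating multi-omics cancer subtyping with the accuracy-weighted average"
author: "subtypeAWA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multi-omics cancer subtyping with the accuracy-weighted average}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subtypeAWA)
```

## The problem

Cancer molecular subtyping partitions tumor samples into groups by their
molecular profiles — copy number, DNA methylation, mRNA and miRNA
expression, and increasingly (phospho)proteomics — rather than by
histology. Many multi-omics clustering algorithms exist, but there is no
gold-standard partition to compare them against, so benchmarking has to
rely on two complementary kinds of evidence:

* **internal validity** — do the clusters look like clusters in the data
  (compact, well separated)?
* **clinical relevance** — do the clusters behave like disease subtypes
  (different survival, different clinical annotations)?

These two views often disagree: a method can produce geometrically
beautiful clusters with no prognostic value, or noisy clusters that
nevertheless separate survival curves. subtypeAWA implements a
harness that computes both families of metrics for any set of candidate
cluster assignments on one dataset, puts them on a common 0–10 score
scale, and aggregates them into a single **accuracy-weighted average
(AWA)** per method so that balanced performers are visible.

## The metrics

Given a sample representation $X$ and an assignment into $k$ clusters of
$n$ samples in total:

* **Silhouette coefficient** $S$: per sample, $s = (b - a)/\max(a, b)$
  where $a$ is the mean Euclidean distance to the sample's own cluster
  and $b$ the smallest mean distance to another cluster; $S$ is the mean
  width, in $[-1, 1]$.
* **Calinski–Harabasz index**
  $CH = \dfrac{\mathrm{tr}(B_k)\,(n-k)}{\mathrm{tr}(W_k)\,(k-1)}$ with
  the between- and within-cluster scatter traces
  $\mathrm{tr}(B_k) = \sum_c n_c\lVert\bar x_c - \bar x\rVert^2$ and
  $\mathrm{tr}(W_k) = \sum_c\sum_{i\in c}\lVert x_i - \bar x_c\rVert^2$.
* **Dunn's index**
  $D = \min_{i\ne j} d(C_i, C_j) \,/\, \max_c \mathrm{diam}(C_c)$, where
  $d(C_i, C_j)$ is single linkage (the minimum pairwise inter-cluster
  distance — the literal reading of "minimum pairwise distance between
  clusters") and the diameter is the maximum intra-cluster distance.
* **LRT**: the p-value of the unstratified $k$-sample log-rank test on
  overall survival across clusters ($\chi^2$ with $k-1$ df); smaller is
  better.
* **ECP**: the number of clinical covariates significantly associated
  with the cluster labels — Pearson $\chi^2$ (no continuity correction)
  for discrete covariates, Kruskal–Wallis for numeric ones, counted at
  level $\alpha$ (default 0.05). The default covariate panel is gender,
  age at diagnosis, pathologic T, M, N, and stage.

The log-rank statistic is delegated to `survival::survdiff()` and the
enrichment tests to `stats::chisq.test()` / `stats::kruskal.test()`; the
test suite independently cross-checks the log-rank path against a
hand-written risk-table accumulation and the internal indices against
`cluster::silhouette()` and brute-force enumeration.

### Which representation do internal metrics see?

Internal indices need one feature space. The default concatenates all
standardized omics layers horizontally (in the fixed order copy number,
methylation, mRNA, miRNA, proteomics, phosphoproteomics), which weights
layers by their feature counts; since every layer is standardized to
unit per-feature variance this is a deliberate, transparent convention
rather than an artifact. The alternative `per_omics` strategy computes
each index per layer and averages, which weights layers equally. The
concatenated form is the default because it evaluates the same joint
space most integration algorithms actually cluster.

## Score harmonization and the AWA

Raw metrics live on incomparable scales, so per dataset and per metric
the methods' values are

1. **oriented** so larger is better — S, CH, D, ECP pass through; the
   log-rank p becomes $-\log_{10}(p)$ with $p$ floored at $10^{-300}$;
2. **min–max rescaled** onto $[0, 10]$: the best method gets 10, the
   worst 0, and an all-tie column gets the neutral 5 for every method.

Min–max rescaling is one of several constructions compatible with a 0–10
score scale (rank-based scoring is another); it was chosen because it
preserves relative magnitudes and admits non-half-integer scores, and it
is isolated in `normalizeToScores()` so an alternative can be swapped in
without touching anything else.

The AWA of one method is then

$$\mathrm{AWA} \;=\; \frac{(S_S + S_{CH} + S_D)\,w_1 + (S_{LRT} + S_{ECP})\,w_2}{3 w_1 + 2 w_2},$$

a weighted mean of the five scores with internal weight $w_1$ and
clinical weight $w_2$ (default $w_1 = w_2 = 0.5$, i.e. internal and
clinical evidence count equally). Useful identities, all enforced by the
test suite to $10^{-12}$: AWA is bounded by the smallest and largest of
the five scores, is invariant to positive rescaling of $(w_1, w_2)$,
collapses to the pure internal (clinical) mean at $w_2 = 0$
($w_1 = 0$), and at equal weights equals $(3\bar I + 2\bar C)/5$ for the
internal average $\bar I$ and clinical average $\bar C$.
`rankAndSweep()` ranks methods by descending AWA — ties broken by
internal average, then method name, so output files are reproducible —
and can tabulate AWA over a list of alternative weight pairs to check
ranking stability.

Because scores are min–max normalized **across methods within one
dataset**, at least two assignments are required, and a method's score
(not its raw metrics) changes when competitors are added or removed.
Cross-dataset aggregation (`compareReports()`) averages AWA values, not
raw metrics.

## Preprocessing rules

`preprocessDataset()` applies per-omics rules common to TCGA-style
studies, with every threshold collected in `preprocessConfig()`:

| step | rule | default |
|---|---|---|
| copy number | drop features whose value vector duplicates an earlier one | — |
| methylation | keep features with mean $\beta \ge$ threshold (inclusive) | 0.3 |
| mRNA/miRNA | $\log_2(x + c)$, drop lowest-MAD fraction, then variance $\le$ cut | $c=1$, 0.5, 0 |
| proteomics | drop features missing in $>$ half the samples, impute feature mean, MAD cut, per-sample median centering | 0.5 |
| all but proteomics | impute missing entries with the **sample** (row) mean, then center/scale each feature to mean 0, unit population variance | — |

Interpretation decisions worth knowing about:

* "features with $\beta$ values $\ge$ 0.3" is read as *mean* beta across
  samples at or above the threshold; "any sample" and "all samples" are
  the other defensible readings, and the mean is the one that behaves
  continuously under noise.
* Imputation by the *sample* mean is taken literally (the row mean
  within one omics layer), not the more conventional feature mean;
  `preprocessProteomics()` uses the feature mean, matching the separate
  rule stated for that data type.
* The MAD filter removes a configurable *fraction* of lowest-MAD
  features (default 0.5) because no absolute cutoff is published;
  resulting feature counts on real cohorts are therefore not
  reproducible by construction and are not a test target.
* Standardization uses the population ($1/n$) variance; zero-variance
  features become all-zero columns with a warning instead of being
  dropped, so feature sets stay aligned across runs.
* The MAD step precedes the variance step; the order is part of the
  contract (a feature with small MAD but large variance — one extreme
  outlier — survives a variance-first pipeline but not this one).

## The synthetic benchmark

`simulateDataset()` generates the world the evaluation framework
assumes: $K$ subtypes with per-omics centroid offsets of magnitude
$\delta$ (the effect size) on a random half of the features, Gaussian
noise of SD $\sigma$, methylation drawn in logit space and squashed into
$[0,1]$ (so beta filtering is exercised), expression exponentiated to a
nonnegative raw scale (so the log transform is exercised), exponential
survival with multiplicative cluster hazards, independent exponential
censoring tuned so $P(\text{censored}) = \mu/(\mu + \lambda_c)$ hits the
target exactly in expectation, and clinical covariates whose association
with the labels is a per-covariate dial in $[0,1]$ (category-tilted
sampling for discrete covariates; a cluster-shifted mean for age).

Defaults describe a plausible desk-scale cohort: $K = 3$ subtypes of 50
samples; four omics layers (60/60/100/40 features); $\delta = \sigma =
1$; 2% missingness; baseline hazard $1/500$ per day (median survival
roughly one year at the top hazard multiplier, a realistic order for
aggressive cancer cohorts); hazard multipliers spread from 1 to 3; 30%
censoring (typical of TCGA overall-survival follow-up); and three of the
six covariates (age, pathologic T, stage) strongly associated with the
subtype. One seed drives all draws through R's RNG in a documented order
(omics layers first, then survival, censoring, covariates), so outputs
are byte-reproducible.

`perturbLabels()` turns the ground truth into progressively worse
"methods" by reassigning a chosen fraction of samples to labels drawn
uniformly over **all** $K$ clusters. Drawing from all clusters rather
than only the *other* ones matters: excluding the own cluster builds
systematic anti-structure (each corrupted cluster becomes a mixture of
the other true clusters), which internal indices and the log-rank test
still detect — a fully "perturbed" assignment would then beat a
half-perturbed one. With uniform redraws, full perturbation is exactly
random labelling, and evaluation quality degrades monotonically in the
flip fraction, which is what a degradation dial is for.

What the generator does **not** emulate: real marginal distributions of
any platform, copy-number segmentation structure, probe-level
methylation correlation, batch effects, informative censoring, or
correlated missingness. A green test therefore establishes that the
*evaluation machinery* is correct and discriminating under a known
ground truth — not that any particular clustering algorithm performs
well on real tumors.

## Numerical conventions

* Samples in singleton clusters contribute silhouette width 0; samples
  whose $a = b = 0$ (coincident points) likewise contribute 0.
* Degenerate denominators (all clusters point masses for CH, all
  singletons for Dunn) return `Inf` with a warning; the orientation step
  replaces the sentinel with the maximum finite value plus one
  distinguishable step so ranking still works.
* Min–max rescaling computes the ratio before scaling by 10 and clamps,
  so the extremes map to exactly 0 and 10 in floating point.
* Missing survival times, missing covariate values, and all-missing
  covariates are dropped per-test (pairwise deletion), never listwise.
* No multiple-testing correction is applied across the six ECP
  covariates by default, mirroring the plain "count of enriched
  parameters" definition; `adjust = "BH"` is available. The uncorrected
  count has a known consequence: with three truly associated covariates
  and three null ones, the probability that no null covariate reaches
  $p < 0.05$ is $0.95^3 \approx 0.857$, so even with perfect power the
  exact count overshoots its target in roughly one run in seven. The
  count is best read as "at least this many covariates are enriched".
* The $\chi^2$ enrichment test warns when any expected cell count is
  below 5; exact tests for sparse tables are out of scope.

## Limitations

* The harness evaluates *assignments*; it does not run clustering
  algorithms, so runtimes (the RT metric) are reported only when the
  caller supplies them with the assignment.
* Scores are relative to the evaluated method set; an AWA of 10 means
  "best among these methods on this dataset", never an absolute quality
  claim.
* Internal metrics use Euclidean distance on the standardized
  representation; correlation-based or kernel distances are not
  implemented.
* The 0–10 score construction is a convention (see above); comparing
  absolute AWA values produced by different score constructions is
  meaningless.
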