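# Clinical relevance metrics: the k-sample log-rank test on overall
# survival across subtypes (LRT, smaller p is better) and the count of
# enriched clinical parameters (ECP) — covariates significantly
# associated with the subtype labels, via Pearson chi-square for discrete
# and Kruskal-Wallis for numeric covariates. Samples missing the quantity
# under test are dropped per-test (pairwise deletion).

#' K-sample log-rank test across subtypes
#'
#' Compares overall survival between the K clusters with the standard
#' unstratified log-rank test (risk-set observed-minus-expected
#' construction, simultaneous handling of tied event times). The p-value
#' comes from the chi-square distribution with `k - 1` degrees of
#' freedom, where `k` is the number of clusters observed after dropping
#' samples with missing survival.
#'
#' @param clinical a [ClinicalTable-class].
#' @param assign a [ClusterAssignment-class] over the same samples.
#' @return Named list with `statistic` (chi-square), `p`, `df` and `n`
#'   (samples used).
#' @export
logrankTest <- function(clinical, assign) {
  ids <- sampleIds(clinical)
  if (!setequal(ids, sampleIds(assign)))
    stop("clinical table and assignment disagree on samples", call. = FALSE)
  time <- clinical@time
  event <- clinical@event
  lab <- clusterLabels(assign)[ids]
  keep <- !is.na(time) & !is.na(event)
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) with missing survival",
                    sum(!keep)), call. = FALSE)
  time <- time[keep]; event <- event[keep]; lab <- lab[keep]
  groups <- sort(unique(lab))
  if (length(groups) < 2L)
    stop("log-rank test needs >= 2 clusters with observed survival",
         call. = FALSE)
  if (sum(event) == 0L) {
    warning("no events observed in any cluster; log-rank p set to 1",
            call. = FALSE)
    return(list(statistic = 0, p = 1, df = length(groups) - 1L,
                n = length(time)))
  }
  fit <- survival::survdiff(survival::Surv(time, event) ~ factor(lab))
  df <- length(groups) - 1L
  list(statistic = unname(fit$chisq),
       p = stats::pchisq(fit$chisq, df = df, lower.tail = FALSE),
       df = df, n = length(time))
}

#' Enrichment test of one clinical covariate against subtype labels
#'
#' Discrete covariates are cross-tabulated clusters x categories and
#' tested with Pearson's chi-square (no continuity correction); numeric
#' covariates with the Kruskal-Wallis rank test across clusters. Missing
#' covariate values are dropped pairwise. Degenerate inputs (a single
#' observed category, constant numeric values) yield p = 1 with a
#' warning; an all-missing covariate yields `NA`.
#'
#' @param values covariate values (character/factor for discrete, numeric
#'   otherwise), one per sample of `assign`, in `sampleIds(assign)` order.
#' @param kind `"discrete"` or `"numeric"`.
#' @param assign a [ClusterAssignment-class].
#' @return p-value in (0, 1\], or `NA` when untestable.
#' @export
covariateEnrichment <- function(values, kind = c("discrete", "numeric"),
                                assign) {
  kind <- match.arg(kind)
  lab <- unname(clusterLabels(assign))
  stopifnot(length(values) == length(lab))
  keep <- !is.na(values)
  if (!any(keep)) {
    warning("covariate is entirely missing; excluded from ECP", call. = FALSE)
    return(NA_real_)
  }
  if (any(!keep))
    warning(sprintf("dropping %d sample(s) with missing covariate value",
                    sum(!keep)), call. = FALSE)
  v <- values[keep]; g <- factor(lab[keep])
  if (kind == "discrete") {
    v <- factor(v)
    if (nlevels(v) < 2L || nlevels(g) < 2L) {
      warning("single observed category; enrichment p set to 1",
              call. = FALSE)
      return(1)
    }
    tab <- table(g, v)
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5))
      warning("chi-square approximation: some expected counts < 5",
              call. = FALSE)
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    return(unname(res$p.value))
  }
  if (length(unique(v)) < 2L || nlevels(droplevels(g)) < 2L) {
    warning("constant numeric covariate; enrichment p set to 1",
            call. = FALSE)
    return(1)
  }
  unname(stats::kruskal.test(v, g)$p.value)
}

#' Count of enriched clinical parameters (ECP)
#'
#' Tests every configured covariate against the subtype labels with
#' [covariateEnrichment()] and counts those with `p < alpha`. No
#' multiple-testing correction is applied by default; set
#' `adjust = "BH"` for Benjamini-Hochberg adjusted p-values. All-missing
#' covariates are excluded from the count and reported as `NA`.
#'
#' @param clinical a [ClinicalTable-class].
#' @param assign a [ClusterAssignment-class] over the same samples.
#' @param alpha enrichment significance level, default 0.05.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return Named list with `ecp` (integer count) and `perCovariateP`
#'   (named p-value vector, after adjustment if requested).
#' @export
ecpCount <- function(clinical, assign, alpha = 0.05,
                     adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(alpha > 0, alpha < 1)
  ids <- sampleIds(clinical)
  if (!setequal(ids, sampleIds(assign)))
    stop("clinical table and assignment disagree on samples", call. = FALSE)
  cov <- covariates(clinical)
  kinds <- covariateKinds(clinical)
  ord <- match(ids, sampleIds(assign))
  lab <- clusterLabels(assign)[ord]
  a2 <- ClusterAssignment(lab, methodName = methodName(assign),
                          k = clusterK(assign))
  p <- vapply(colnames(cov), function(nm)
    covariateEnrichment(cov[[nm]], kinds[[nm]], a2), numeric(1))
  if (adjust == "BH") p <- stats::p.adjust(p, method = "BH")
  list(ecp = sum(p < alpha, na.rm = TRUE), perCovariateP = p)
}

#' Compute both clinical metrics for one assignment
#'
#' @inheritParams ecpCount
#' @return Named list with `lrt` (list: statistic, p, df, n), `ecp`
#'   (count) and `perCovariateP`.
#' @export
clinicalMetrics <- function(clinical, assign, alpha = 0.05,
                            adjust = c("none", "BH")) {
  lrt <- logrankTest(clinical, assign)
  e <- ecpCount(clinical, assign, alpha = alpha, adjust = adjust)
  list(lrt = lrt, ecp = e$ecp, perCovariateP = e$perCovariateP)
}
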