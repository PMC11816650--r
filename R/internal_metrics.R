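# Internal cluster validity indices: silhouette coefficient (S),
# Calinski-Harabasz index (CH) and Dunn's index (D), computed on a
# standardized sample representation with Euclidean distances. All three
# are larger-is-better, invariant to sample permutation and cluster
# relabeling.

#' Build the sample representation internal metrics are computed on
#'
#' The default strategy concatenates all (standardized) omics layers
#' horizontally in the canonical [OMICS_KINDS] order. The alternative
#' `per_omics` strategy is handled by [internalMetrics()], which computes
#' each index per layer and averages.
#'
#' @param dataset a preprocessed [OmicsDataset-class].
#' @return Numeric samples-by-features matrix.
#' @export
buildRepresentation <- function(dataset) {
  mats <- lapply(omicsLayers(dataset), omicsValues)
  ids <- lapply(mats, rownames)
  if (!all(vapply(ids, identical, logical(1), ids[[1L]])))
    stop("omics layers disagree on sample order; run alignAndValidate first",
         call. = FALSE)
  rep <- do.call(cbind, mats)
  if (anyNA(rep))
    stop("representation contains missing values; impute before computing metrics",
         call. = FALSE)
  rep
}

.check_assignment <- function(rep, assign, need_n_gt_k = TRUE) {
  k <- clusterK(assign)
  if (k < 2L)
    stop("internal metrics undefined for a single cluster", call. = FALSE)
  if (!identical(rownames(rep), sampleIds(assign)))
    stop("representation and assignment disagree on samples", call. = FALSE)
  if (need_n_gt_k && nrow(rep) <= k)
    stop("internal metrics need more samples than clusters", call. = FALSE)
  invisible(k)
}

#' Mean silhouette coefficient
#'
#' For each sample, `a` is its mean Euclidean distance to the other
#' members of its own cluster and `b` the smallest mean distance to the
#' members of any other cluster; the per-sample width is
#' `(b - a) / max(a, b)`. Samples in singleton clusters contribute 0 (the
#' width is undefined there; 0 is the common neutral convention). The
#' returned value is the mean width over all samples and lies in
#' \[-1, 1\].
#'
#' @param rep samples-by-features numeric matrix.
#' @param assign a [ClusterAssignment-class] over the same samples.
#' @return Mean silhouette width.
#' @export
silhouetteScore <- function(rep, assign) {
  k <- .check_assignment(rep, assign)
  lab <- unname(clusterLabels(assign))
  d <- as.matrix(stats::dist(rep))
  n <- nrow(rep)
  sizes <- tabulate(lab, k)
  s <- numeric(n)
  # mean distance from each sample to each cluster
  cl_mean <- vapply(seq_len(k), function(c)
    rowSums(d[, lab == c, drop = FALSE]) / sizes[c], numeric(n))
  for (i in seq_len(n)) {
    ci <- lab[i]
    if (sizes[ci] == 1L) { s[i] <- 0; next }
    a <- cl_mean[i, ci] * sizes[ci] / (sizes[ci] - 1L)  # exclude self
    b <- min(cl_mean[i, -ci])
    # coincident points give a = b = 0; the width is 0 by the a = b rule
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' The ratio of between-cluster to within-cluster scatter,
#' `(tr(B_k) * (n - k)) / (tr(W_k) * (k - 1))`, where
#' `tr(B_k) = sum_c n_c * ||mean_c - mean||^2` and
#' `tr(W_k) = sum_c sum_{i in c} ||x_i - mean_c||^2`. When every cluster
#' is a point mass (`tr(W_k) = 0`) the index degenerates; `Inf` is
#' returned with a warning so the scoring layer can still rank.
#'
#' @inheritParams silhouetteScore
#' @return Nonnegative real (possibly `Inf`).
#' @export
calinskiHarabasz <- function(rep, assign) {
  k <- .check_assignment(rep, assign)
  lab <- unname(clusterLabels(assign))
  n <- nrow(rep)
  gmean <- colMeans(rep)
  tr_b <- 0
  tr_w <- 0
  for (c in seq_len(k)) {
    xc <- rep[lab == c, , drop = FALSE]
    cmean <- colMeans(xc)
    tr_b <- tr_b + nrow(xc) * sum((cmean - gmean)^2)
    tr_w <- tr_w + sum(sweep(xc, 2L, cmean, "-")^2)
  }
  if (tr_w == 0) {
    warning("all clusters are point masses; Calinski-Harabasz is infinite",
            call. = FALSE)
    return(Inf)
  }
  (tr_b * (n - k)) / (tr_w * (k - 1))
}

#' Dunn's index
#'
#' The minimum inter-cluster distance divided by the maximum cluster
#' diameter. Inter-cluster distance is single linkage (the minimum
#' pairwise distance between members of the two clusters); a cluster's
#' diameter is its maximum intra-cluster pairwise distance. When every
#' cluster is a singleton the maximum diameter is 0 and `Inf` is returned
#' with a warning.
#'
#' @inheritParams silhouetteScore
#' @return Nonnegative real (possibly `Inf`).
#' @export
dunnIndex <- function(rep, assign) {
  k <- .check_assignment(rep, assign, need_n_gt_k = FALSE)
  lab <- unname(clusterLabels(assign))
  d <- as.matrix(stats::dist(rep))
  inter_min <- Inf
  diam_max <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    inter_min <- min(inter_min, d[lab == i, lab == j])
  }
  for (c in seq_len(k)) {
    dc <- d[lab == c, lab == c]
    if (length(dc) > 1L) diam_max <- max(diam_max, dc)
  }
  if (diam_max == 0) {
    warning("all clusters are singletons; Dunn's index is infinite",
            call. = FALSE)
    return(Inf)
  }
  inter_min / diam_max
}

#' Compute all three internal indices for one assignment
#'
#' @param dataset a preprocessed [OmicsDataset-class].
#' @param assign a [ClusterAssignment-class].
#' @param strategy `"concatenate"` (default) computes S/CH/D once on the
#'   horizontally concatenated representation; `"per_omics"` computes them
#'   on every layer separately and averages the finite values.
#' @return Named numeric vector `c(S =, CH =, D =)`.
#' @export
internalMetrics <- function(dataset, assign,
                            strategy = c("concatenate", "per_omics")) {
  strategy <- match.arg(strategy)
  if (strategy == "concatenate") {
    rep <- buildRepresentation(dataset)
    return(c(S = silhouetteScore(rep, assign),
             CH = calinskiHarabasz(rep, assign),
             D = dunnIndex(rep, assign)))
  }
  per <- vapply(omicsLayers(dataset), function(m) {
    rep <- omicsValues(m)
    c(S = silhouetteScore(rep, assign),
      CH = calinskiHarabasz(rep, assign),
      D = dunnIndex(rep, assign))
  }, numeric(3))
  rowMeans(per)
}
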