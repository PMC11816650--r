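# Fixture builders and independent oracles used across the suite. The
# oracles are deliberately naive (explicit loops, textbook formulas) and
# share no code path with the package implementation.

make_matrix <- function(v, kind = "mrna", ids = NULL, feats = NULL) {
  if (is.null(ids)) ids <- rownames(v)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(v)))
  if (is.null(feats)) feats <- colnames(v)
  if (is.null(feats)) feats <- sprintf("f%d", seq_len(ncol(v)))
  dimnames(v) <- list(ids, feats)
  OmicsMatrix(v, kind)
}

make_assignment <- function(labels, ids = sprintf("s%d", seq_along(labels)),
                            method = "m", k = max(labels)) {
  ClusterAssignment(stats::setNames(as.integer(labels), ids),
                    methodName = method, k = k)
}

make_clinical <- function(time, event, ids = sprintf("s%d", seq_along(time)),
                          covariates = NULL, kinds = NULL) {
  if (is.null(covariates)) covariates <- data.frame(row.names = ids)
  ClinicalTable(ids, time, event, covariates, kinds)
}

# random clustered instance for oracle-equivalence checks: every cluster
# is guaranteed non-empty
random_instance <- function(n, dims, k) {
  lab <- c(seq_len(k), sample.int(k, n - k, replace = TRUE))
  x <- matrix(rnorm(n * dims), n, dims,
              dimnames = list(sprintf("s%d", 1:n), sprintf("f%d", 1:dims)))
  x <- x + lab  # mild separation so indices are well away from degenerate
  list(x = x, assign = make_assignment(lab, ids = rownames(x)))
}

# adjusted Rand index, straight from the contingency-table formula
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  ((sij - expected) / ((sa + sb) / 2 - expected))
}

# Calinski-Harabasz via the total-scatter decomposition tr(T) = tr(W) +
# tr(B): computes tr(T) and tr(W) with explicit per-point loops and
# derives tr(B) by subtraction — a different route than the package's
# direct between-scatter sum
ch_oracle <- function(x, lab) {
  n <- nrow(x)
  k <- length(unique(lab))
  g <- colMeans(x)
  tr_t <- 0
  for (i in seq_len(n)) tr_t <- tr_t + sum((x[i, ] - g)^2)
  tr_w <- 0
  for (c in unique(lab)) {
    xc <- x[lab == c, , drop = FALSE]
    m <- colMeans(xc)
    for (i in seq_len(nrow(xc))) tr_w <- tr_w + sum((xc[i, ] - m)^2)
  }
  ((tr_t - tr_w) * (n - k)) / (tr_w * (k - 1))
}

# Dunn's index by exhaustive enumeration of every point pair
dunn_oracle <- function(x, lab) {
  n <- nrow(x)
  inter <- Inf
  diam <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dij <- sqrt(sum((x[i, ] - x[j, ])^2))
    if (lab[i] == lab[j]) diam <- max(diam, dij)
    else inter <- min(inter, dij)
  }
  inter / diam
}

# k-group log-rank by direct risk-table accumulation over event times:
# hypergeometric observed-minus-expected and covariance summed per
# distinct event time, chi-square via the (k-1)-dimensional quadratic form
logrank_oracle <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  oe <- rep(0, k)
  v <- matrix(0, k, k)
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    nt <- sum(at_risk)
    dt <- sum(event == 1 & time == t)
    nj <- vapply(groups, function(g) sum(at_risk & group == g), numeric(1))
    dj <- vapply(groups, function(g)
      sum(event == 1 & time == t & group == g), numeric(1))
    oe <- oe + dj - dt * nj / nt
    if (nt > 1) {
      for (a in seq_len(k)) for (b in seq_len(k)) {
        va <- if (a == b) nj[a] * (nt - nj[a]) else -nj[a] * nj[b]
        v[a, b] <- v[a, b] + dt * (nt - dt) / (nt - 1) * va / nt^2
      }
    }
  }
  stat <- drop(t(oe[-1]) %*% solve(v[-1, -1, drop = FALSE]) %*% oe[-1])
  list(statistic = stat,
       p = stats::pchisq(stat, df = k - 1, lower.tail = FALSE))
}

# six-covariate clinical spec with every association switched off
null_clinical_spec <- function() {
  kinds <- c(gender = "discrete", age_at_diagnosis = "numeric",
             pathologic_t = "discrete", pathologic_m = "discrete",
             pathologic_n = "discrete", pathologic_stage = "discrete")
  lapply(kinds, function(k) list(kind = k, associationStrength = 0))
}

# small, fast simulation settings reused by several tests
fast_sim_config <- function(seed, effectSize = 3, K = 3L,
                            nPerCluster = rep(50L, K),
                            hazardMultipliers = seq(1, 3, length.out = K),
                            ...) {
  simConfig(K = K, nPerCluster = nPerCluster,
            omicsSpecs = list(
              list(kind = "mrna", nFeatures = 40L, effectSize = effectSize,
                   noiseSd = 1, missingRate = 0.02),
              list(kind = "methylation", nFeatures = 30L,
                   effectSize = effectSize, noiseSd = 1, missingRate = 0)),
            hazardMultipliers = hazardMultipliers, seed = seed, ...)
}
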