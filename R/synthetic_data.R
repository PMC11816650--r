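# Synthetic multi-omics generator: K subtypes with cluster-shifted
# centroids per omics layer, exponential survival with multiplicative
# cluster hazards, and clinical covariates whose association with the
# subtype labels is controlled per covariate. Everything is driven by one
# seed through R's RNG in a fixed draw order (omics layers in the given
# order, then survival, then censoring, then covariates), so a run is
# fully reproducible.

.default_omics_specs <- function() list(
  list(kind = "copy_number", nFeatures = 60L, effectSize = 1, noiseSd = 1,
       missingRate = 0.02),
  list(kind = "methylation", nFeatures = 60L, effectSize = 1, noiseSd = 1,
       missingRate = 0.02),
  list(kind = "mrna", nFeatures = 100L, effectSize = 1, noiseSd = 1,
       missingRate = 0.02),
  list(kind = "mirna", nFeatures = 40L, effectSize = 1, noiseSd = 1,
       missingRate = 0.02))

.default_clinical_spec <- function() list(
  gender           = list(kind = "discrete", associationStrength = 0),
  age_at_diagnosis = list(kind = "numeric",  associationStrength = 0.8),
  pathologic_t     = list(kind = "discrete", associationStrength = 0.8),
  pathologic_m     = list(kind = "discrete", associationStrength = 0),
  pathologic_n     = list(kind = "discrete", associationStrength = 0),
  pathologic_stage = list(kind = "discrete", associationStrength = 0.8))

.covariate_levels <- list(
  gender = c("male", "female"),
  pathologic_t = c("T1", "T2", "T3", "T4"),
  pathologic_m = c("M0", "M1"),
  pathologic_n = c("N0", "N1", "N2"),
  pathologic_stage = c("StageI", "StageII", "StageIII", "StageIV"))

#' Simulation configuration
#'
#' Assembles and validates the settings of [simulateDataset()]. The
#' defaults describe a realistic desk-scale cohort: K = 3 subtypes of 50
#' samples each; four omics layers (copy number, methylation beta, mRNA,
#' miRNA) with unit effect size and unit noise; exponential survival with
#' baseline rate 1/500 per day and cluster hazard multipliers spread from
#' 1 to 3; 30% censoring; and three of the six clinical covariates (age,
#' pathologic T, pathologic stage) strongly associated with the subtype.
#'
#' @param K number of subtypes.
#' @param nPerCluster integer vector of length `K`, samples per subtype.
#' @param omicsSpecs list of per-layer specs, each a list with `kind`,
#'   `nFeatures`, `effectSize` (centroid offset magnitude, in noise-SD
#'   units when `noiseSd = 1`), `noiseSd`, `missingRate`.
#' @param baselineRate exponential baseline hazard (events/day).
#' @param hazardMultipliers positive multiplier per cluster, length `K`.
#' @param censoringRate target fraction of censored samples in \[0, 1).
#' @param clinicalSpec named list per covariate: `kind`
#'   (`"discrete"`/`"numeric"`) and `associationStrength` in \[0, 1\].
#' @param seed integer seed driving every draw.
#' @return Validated configuration list.
#' @export
simConfig <- function(K = 3L,
                      nPerCluster = rep(50L, K),
                      omicsSpecs = .default_omics_specs(),
                      baselineRate = 1 / 500,
                      hazardMultipliers = seq(1, 3, length.out = K),
                      censoringRate = 0.3,
                      clinicalSpec = .default_clinical_spec(),
                      seed = 1L) {
  if (length(nPerCluster) != K || any(nPerCluster < 1))
    stop("invalid field nPerCluster: need K positive counts", call. = FALSE)
  if (length(hazardMultipliers) != K || any(hazardMultipliers <= 0))
    stop("invalid field hazardMultipliers: need K positive values",
         call. = FALSE)
  if (baselineRate <= 0)
    stop("invalid field baselineRate: must be positive", call. = FALSE)
  if (censoringRate < 0 || censoringRate >= 1)
    stop("invalid field censoringRate: must lie in [0, 1)", call. = FALSE)
  for (sp in omicsSpecs) {
    if (!sp$kind %in% OMICS_KINDS)
      stop(sprintf("invalid field omicsSpecs: unknown kind '%s'", sp$kind),
           call. = FALSE)
    if (sp$nFeatures < 2 || sp$effectSize < 0 || sp$noiseSd <= 0 ||
        sp$missingRate < 0 || sp$missingRate >= 1)
      stop(sprintf("invalid field omicsSpecs: bad spec for kind '%s'",
                   sp$kind), call. = FALSE)
  }
  for (nm in names(clinicalSpec)) {
    cs <- clinicalSpec[[nm]]
    if (!cs$kind %in% c("discrete", "numeric") ||
        cs$associationStrength < 0 || cs$associationStrength > 1)
      stop(sprintf("invalid field clinicalSpec: bad spec for '%s'", nm),
           call. = FALSE)
  }
  list(K = as.integer(K), nPerCluster = as.integer(nPerCluster),
       omicsSpecs = omicsSpecs, baselineRate = baselineRate,
       hazardMultipliers = hazardMultipliers,
       censoringRate = censoringRate, clinicalSpec = clinicalSpec,
       seed = as.integer(seed))
}

# one omics layer: cluster centroids with effect-size offsets (random
# sign) on a random half of the features, plus Gaussian noise, mapped to
# the kind's natural scale
.simulate_layer <- function(spec, labels, ids) {
  n <- length(labels)
  p <- spec$nFeatures
  K <- max(labels)
  affected <- sample.int(p, max(1L, round(p / 2)))
  offsets <- matrix(0, K, p)
  offsets[, affected] <- spec$effectSize *
    matrix(sample(c(-1, 1), K * length(affected), replace = TRUE),
           K, length(affected))
  base <- switch(spec$kind,
    mrna = ,
    mirna = stats::runif(p, 2, 8),         # log2 expression level
    methylation = stats::rnorm(p, 0, 1.5),  # logit-scale beta
    stats::rnorm(p, 0, 1))
  latent <- matrix(base, n, p, byrow = TRUE) + offsets[labels, ] +
    matrix(stats::rnorm(n * p, 0, spec$noiseSd), n, p)
  v <- switch(spec$kind,
    mrna = ,
    mirna = pmax(2^latent - 1, 0),          # nonnegative expression
    methylation = stats::plogis(latent),    # squash into [0, 1]
    latent)
  if (spec$missingRate > 0)
    v[matrix(stats::runif(n * p) < spec$missingRate, n, p)] <- NA
  dimnames(v) <- list(ids, sprintf("%s_f%03d", spec$kind, seq_len(p)))
  OmicsMatrix(v, spec$kind)
}

.simulate_covariate <- function(nm, cs, labels, K) {
  s <- cs$associationStrength
  n <- length(labels)
  if (cs$kind == "numeric") {
    shift <- s * 15 * (labels - (K + 1) / 2)
    return(round(stats::rnorm(n, 60 + shift, 10), 1))
  }
  lev <- .covariate_levels[[nm]]
  if (is.null(lev)) lev <- paste0("cat", 1:3)
  ncat <- length(lev)
  out <- character(n)
  for (c in seq_len(K)) {
    pref <- ((c - 1L) %% ncat) + 1L
    pr <- rep((1 - s) / ncat, ncat)
    pr[pref] <- pr[pref] + s
    idx <- labels == c
    out[idx] <- sample(lev, sum(idx), replace = TRUE, prob = pr)
  }
  out
}

#' Simulate a multi-omics dataset with known subtype structure
#'
#' Generates per-omics matrices (cluster-shifted centroids + Gaussian
#' noise, methylation squashed into \[0,1\] through a logistic map,
#' expression exponentiated to a nonnegative raw scale), exponential
#' survival with multiplicative cluster hazards and independent
#' exponential censoring tuned to the target censoring rate, and clinical
#' covariates with cluster-tilted category distributions (discrete) or
#' cluster-shifted means (age).
#'
#' @param cfg a configuration from [simConfig()].
#' @return List with `dataset` ([OmicsDataset-class], raw scale —
#'   run [preprocessDataset()] before computing metrics), `clinical`
#'   ([ClinicalTable-class]), and `truth` (list: `labels` a
#'   [ClusterAssignment-class], `associatedCovariates` the covariate
#'   names with positive association strength).
#' @examples
#' sim <- simulateDataset(simConfig(seed = 7))
#' sim$dataset
#' @export
simulateDataset <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  K <- cfg$K
  labels <- rep(seq_len(K), cfg$nPerCluster)
  n <- length(labels)
  ids <- sprintf("S%04d", seq_len(n))

  mats <- lapply(cfg$omicsSpecs, .simulate_layer, labels = labels, ids = ids)
  dataset <- OmicsDataset(mats, name = sprintf("sim_seed%d", cfg$seed))

  rate <- cfg$baselineRate * cfg$hazardMultipliers[labels]
  t_event <- stats::rexp(n, rate)
  if (cfg$censoringRate > 0) {
    # P(C < T) = mu / (mu + rate) for independent exponentials, so the
    # per-cluster censoring rate mu hits the target exactly in expectation
    mu <- rate * cfg$censoringRate / (1 - cfg$censoringRate)
    t_cens <- stats::rexp(n, mu)
  } else t_cens <- rep(Inf, n)
  time <- round(pmin(t_event, t_cens), 2)
  event <- as.integer(t_event <= t_cens)

  cov <- data.frame(row.names = ids)
  kinds <- character(0)
  for (nm in names(cfg$clinicalSpec)) {
    cs <- cfg$clinicalSpec[[nm]]
    cov[[nm]] <- .simulate_covariate(nm, cs, labels, K)
    kinds[nm] <- cs$kind
  }
  clinical <- ClinicalTable(ids, time, event, cov, kinds)

  assoc <- names(Filter(function(cs) cs$associationStrength > 0,
                        cfg$clinicalSpec))
  truth <- list(
    labels = ClusterAssignment(stats::setNames(labels, ids),
                               methodName = "truth", k = K),
    associatedCovariates = assoc)
  list(dataset = dataset, clinical = clinical, truth = truth)
}

#' Randomly perturb a cluster assignment
#'
#' Reassigns a uniformly chosen fraction of samples, each to a label
#' drawn uniformly over all `K` clusters, emulating a progressively
#' worse subtyping method. `flipFraction = 0` returns the input
#' unchanged; `flipFraction = 1` replaces every label with an i.i.d.
#' uniform draw, so all label information is destroyed up to chance and
#' the adjusted Rand index with the input is ~0.
#'
#' Reassigned samples keep their original label with probability `1/K`,
#' so on average `flipFraction * n * (K - 1) / K` labels differ from the
#' input. Drawing from all clusters (rather than only the other ones) is
#' what makes full perturbation equivalent to random labelling: excluding
#' a sample's own cluster would build systematic anti-structure that
#' internal indices and the log-rank test still detect.
#'
#' @param truth a [ClusterAssignment-class] with `K >= 2`.
#' @param flipFraction fraction of samples to reassign, in \[0, 1\].
#' @param seed integer seed.
#' @param methodName label for the perturbed assignment.
#' @return A [ClusterAssignment-class].
#' @export
perturbLabels <- function(truth, flipFraction, seed = 1L,
                          methodName = sprintf("perturbed_%g", flipFraction)) {
  stopifnot(flipFraction >= 0, flipFraction <= 1)
  lab <- clusterLabels(truth)
  if (flipFraction == 0)
    return(ClusterAssignment(lab, methodName = methodName,
                             k = clusterK(truth)))
  set.seed(seed)
  K <- clusterK(truth)
  n <- length(lab)
  flip <- sample.int(n, round(flipFraction * n))
  lab[flip] <- sample.int(K, length(flip), replace = TRUE)
  ClusterAssignment(lab, methodName = methodName, k = K)
}
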