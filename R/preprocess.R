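# Per-omics preprocessing: copy-number deduplication, methylation beta
# filtering, log transform + MAD/variance feature filtering for
# expression, missingness filtering + median normalization for
# (phospho)proteomics, and sample-mean imputation with per-feature
# standardization. Operators only remove or transform features; the
# sample set and its order are never changed.

#' Preprocessing configuration
#'
#' Bundles the tunable thresholds of the per-omics preprocessing rules.
#'
#' @slot betaThreshold minimum mean methylation beta for a feature to be
#'   kept (inclusive).
#' @slot madQuantile fraction of lowest-MAD features removed from
#'   expression and proteomics layers, in \[0,1\].
#' @slot varianceThreshold features with variance at or below this are
#'   removed from expression layers.
#' @slot missingFractionMax proteomics features missing in strictly more
#'   than this fraction of samples are dropped.
#' @slot logOffset pseudo-count added before the log2 transform.
#'
#' @seealso [preprocessConfig()]
#' @export
setClass("PreprocessConfig",
  representation(betaThreshold = "numeric", madQuantile = "numeric",
                 varianceThreshold = "numeric",
                 missingFractionMax = "numeric", logOffset = "numeric"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (object@betaThreshold < 0 || object@betaThreshold > 1)
    msg <- c(msg, "betaThreshold must lie in [0,1]")
  if (object@madQuantile < 0 || object@madQuantile > 1)
    msg <- c(msg, "madQuantile must lie in [0,1]")
  if (object@varianceThreshold < 0)
    msg <- c(msg, "varianceThreshold must be nonnegative")
  if (object@missingFractionMax < 0 || object@missingFractionMax > 1)
    msg <- c(msg, "missingFractionMax must lie in [0,1]")
  if (object@logOffset <= 0)
    msg <- c(msg, "logOffset must be positive")
  if (length(msg)) msg else TRUE
})

#' Construct a PreprocessConfig
#'
#' @param betaThreshold minimum mean beta, default 0.3.
#' @param madQuantile fraction of lowest-MAD features removed, default 0.5.
#' @param varianceThreshold variance cut (features with variance <= this
#'   are removed), default 0.
#' @param missingFractionMax maximum tolerated missing fraction for
#'   proteomics features, default 0.5.
#' @param logOffset pseudo-count for the log2 transform, default 1.
#' @return A validated [PreprocessConfig-class].
#' @export
preprocessConfig <- function(betaThreshold = 0.3, madQuantile = 0.5,
                             varianceThreshold = 0, missingFractionMax = 0.5,
                             logOffset = 1) {
  new("PreprocessConfig", betaThreshold = betaThreshold,
      madQuantile = madQuantile, varianceThreshold = varianceThreshold,
      missingFractionMax = missingFractionMax, logOffset = logOffset)
}

# median absolute deviation without the Gaussian consistency constant:
# median(|x - median(x)|), NA-tolerant
.raw_mad <- function(x) {
  stats::median(abs(x - stats::median(x, na.rm = TRUE)), na.rm = TRUE)
}

# population (1/n) variance, NA-tolerant
.pop_var <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  mean((x - mean(x))^2)
}

# drop the floor(q * p) features with the lowest MAD; ties broken by input
# order so the result is deterministic
.mad_filter <- function(v, q) {
  p <- ncol(v)
  n_drop <- floor(q * p)
  if (n_drop == 0L) return(v)
  mads <- apply(v, 2L, .raw_mad)
  drop_idx <- order(mads, seq_len(p))[seq_len(n_drop)]
  v[, -drop_idx, drop = FALSE]
}

#' Remove duplicated copy-number features
#'
#' Copy-number segmentations repeat identical value vectors when several
#' regions share one underlying segment. Among features whose columns are
#' identical across all samples (NA positions included), only the first by
#' input order is kept.
#'
#' @param m an [OmicsMatrix-class] of kind `copy_number`.
#' @return The deduplicated [OmicsMatrix-class].
#' @export
dedupCopyNumber <- function(m) {
  stopifnot(omicsKind(m) == "copy_number")
  v <- omicsValues(m)
  dup <- duplicated(t(v))
  OmicsMatrix(v[, !dup, drop = FALSE], omicsKind(m))
}

#' Filter methylation features by mean beta
#'
#' Keeps features whose mean beta across non-missing samples is at or
#' above `betaThreshold` (inclusive boundary). Features with no observed
#' value are dropped with a warning.
#'
#' @param m an [OmicsMatrix-class] of kind `methylation`.
#' @param cfg a [PreprocessConfig-class].
#' @return The filtered [OmicsMatrix-class].
#' @export
filterMethylation <- function(m, cfg = preprocessConfig()) {
  stopifnot(omicsKind(m) == "methylation")
  v <- omicsValues(m)
  means <- colMeans(v, na.rm = TRUE)
  all_na <- apply(v, 2L, function(x) all(is.na(x)))
  if (any(all_na))
    warning(sprintf("dropping %d all-missing methylation feature(s): %s",
                    sum(all_na),
                    paste(colnames(v)[all_na], collapse = ", ")),
            call. = FALSE)
  keep <- !all_na & means >= cfg@betaThreshold
  OmicsMatrix(v[, keep, drop = FALSE], omicsKind(m))
}

#' Preprocess an expression (mRNA/miRNA) layer
#'
#' Applies, in this fixed order: `log2(x + logOffset)`; removal of the
#' lowest-MAD fraction `madQuantile` of features; removal of features
#' whose variance is at or below `varianceThreshold`. Raw values must be
#' nonnegative.
#'
#' @param m an [OmicsMatrix-class] of kind `mrna` or `mirna`.
#' @param cfg a [PreprocessConfig-class].
#' @return The transformed and filtered [OmicsMatrix-class].
#' @export
preprocessExpression <- function(m, cfg = preprocessConfig()) {
  stopifnot(omicsKind(m) %in% c("mrna", "mirna"))
  v <- omicsValues(m)
  bad <- which(!is.na(v) & v < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("negative expression value at (%s, %s)",
                 rownames(v)[bad[1L, 1L]], colnames(v)[bad[1L, 2L]]),
         call. = FALSE)
  v <- log2(v + cfg@logOffset)
  v <- .mad_filter(v, cfg@madQuantile)
  vars <- apply(v, 2L, .pop_var)
  v <- v[, !is.na(vars) & vars > cfg@varianceThreshold, drop = FALSE]
  OmicsMatrix(v, omicsKind(m))
}

#' Preprocess a (phospho)proteomics layer
#'
#' Drops features missing in strictly more than `missingFractionMax` of
#' samples; imputes remaining missing entries with the feature mean;
#' removes the lowest-MAD fraction of features; median-normalizes each
#' sample by subtracting its median.
#'
#' @param m an [OmicsMatrix-class] of kind `proteomics` or
#'   `phosphoproteomics`.
#' @param cfg a [PreprocessConfig-class].
#' @return The filtered and normalized [OmicsMatrix-class].
#' @export
preprocessProteomics <- function(m, cfg = preprocessConfig()) {
  stopifnot(omicsKind(m) %in% c("proteomics", "phosphoproteomics"))
  v <- omicsValues(m)
  miss_frac <- colMeans(is.na(v))
  v <- v[, miss_frac <= cfg@missingFractionMax, drop = FALSE]
  for (j in seq_len(ncol(v))) {
    na <- is.na(v[, j])
    if (any(na)) v[na, j] <- mean(v[, j], na.rm = TRUE)
  }
  v <- .mad_filter(v, cfg@madQuantile)
  v <- sweep(v, 1L, apply(v, 1L, stats::median), "-")
  OmicsMatrix(v, omicsKind(m), standardized = TRUE)
}

#' Impute missing values and standardize features
#'
#' Missing entries are imputed with the mean of the sample's non-missing
#' values within the omics layer; each feature is then centered to mean 0
#' and scaled to unit (population, 1/n) variance. Constant features map to
#' all-zero columns with a warning rather than being dropped.
#'
#' @param m an [OmicsMatrix-class] (any kind, >= 2 samples).
#' @return The standardized [OmicsMatrix-class]; methylation kind is
#'   relabelled unchanged even though values leave \[0,1\] — the result is
#'   returned as a plain matrix wrapper of kind `mrna`-like semantics, so
#'   the beta-range invariant is not re-imposed.
#' @export
imputeAndStandardize <- function(m) {
  v <- omicsValues(m)
  if (nrow(v) < 2L) stop("at least 2 samples required", call. = FALSE)
  all_na <- apply(v, 1L, function(x) all(is.na(x)))
  if (any(all_na))
    stop(sprintf("sample %s has no observed value in omics '%s'",
                 rownames(v)[which(all_na)[1L]], omicsKind(m)),
         call. = FALSE)
  row_means <- rowMeans(v, na.rm = TRUE)
  na <- is.na(v)
  v[na] <- row_means[row(v)[na]]
  mu <- colMeans(v)
  sd_pop <- sqrt(colMeans(sweep(v, 2L, mu, "-")^2))
  const <- sd_pop == 0
  if (any(const))
    warning(sprintf("%d constant feature(s) standardized to zero: %s",
                    sum(const),
                    paste(colnames(v)[const], collapse = ", ")),
            call. = FALSE)
  v <- sweep(v, 2L, mu, "-")
  v[, !const] <- sweep(v[, !const, drop = FALSE], 2L, sd_pop[!const], "/")
  OmicsMatrix(v, omicsKind(m), standardized = TRUE)
}

#' Run the full per-omics preprocessing pipeline on a dataset
#'
#' Dispatches per kind: copy number is deduplicated; methylation is
#' beta-filtered; mRNA/miRNA are log-transformed and MAD/variance
#' filtered; (phospho)proteomics is missingness-filtered, mean-imputed,
#' MAD-filtered and median-normalized. All layers except proteomics are
#' then sample-mean imputed and standardized to per-feature mean 0 /
#' variance 1 (proteomics retains its median normalization).
#'
#' @param dataset an [OmicsDataset-class].
#' @param cfg a [PreprocessConfig-class].
#' @param verbose log per-step feature counts via `message()`.
#' @return The preprocessed [OmicsDataset-class].
#' @export
preprocessDataset <- function(dataset, cfg = preprocessConfig(),
                              verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  mats <- lapply(omicsLayers(dataset), function(m) {
    p0 <- length(featureIds(m))
    out <- switch(omicsKind(m),
      copy_number = imputeAndStandardize(dedupCopyNumber(m)),
      methylation = imputeAndStandardize(filterMethylation(m, cfg)),
      mrna = ,
      mirna = imputeAndStandardize(preprocessExpression(m, cfg)),
      proteomics = ,
      phosphoproteomics = preprocessProteomics(m, cfg))
    say("%s: %d -> %d features", omicsKind(m), p0, length(featureIds(out)))
    out
  })
  OmicsDataset(mats, name = dataset@name)
}
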