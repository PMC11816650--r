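#' @import methods
NULL

#' Recognised omics kinds, in canonical order
#'
#' The fixed ordering used when omics layers are concatenated into a single
#' sample-by-feature representation.
#'
#' @export
OMICS_KINDS <- c("copy_number", "methylation", "mrna", "mirna",
                 "proteomics", "phosphoproteomics")

#' Metric identifiers on the score board, in canonical order
#'
#' `S`, `CH`, `D` are internal cluster validity indices; `LRT` is the
#' log-rank p-value across subtypes and `ECP` the count of enriched
#' clinical parameters.
#'
#' @export
METRIC_IDS <- c("S", "CH", "D", "LRT", "ECP")

#' Default clinical covariate schema
#'
#' The six-covariate set used for clinical enrichment: gender, age at
#' diagnosis, and the pathologic T/M/N/stage annotations. Age is numeric,
#' the rest are discrete.
#'
#' @export
DEFAULT_COVARIATE_SCHEMA <- c(
  gender           = "discrete",
  age_at_diagnosis = "numeric",
  pathologic_t     = "discrete",
  pathologic_m     = "discrete",
  pathologic_n     = "discrete",
  pathologic_stage = "discrete"
)

# ---- OmicsMatrix -----------------------------------------------------------

#' Single-omics feature matrix
#'
#' A samples-by-features real matrix for one omics layer, with missing
#' entries stored as `NA`. Methylation matrices hold beta values and must
#' lie in \[0, 1\] where observed.
#'
#' @slot kind one of [OMICS_KINDS].
#' @slot values numeric matrix, samples as rows, features as columns;
#'   dimnames carry sample and feature identifiers.
#' @slot standardized `TRUE` once the layer has been through
#'   normalization; relaxes the methylation beta-range invariant, which
#'   applies to raw beta values only.
#'
#' @seealso [OmicsMatrix()], [readOmicsMatrix()]
#' @export
setClass("OmicsMatrix",
  representation(kind = "character", values = "matrix",
                 standardized = "logical"),
  prototype(standardized = FALSE))

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% OMICS_KINDS)
    msg <- c(msg, sprintf("kind must be one of: %s",
                          paste(OMICS_KINDS, collapse = ", ")))
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "values must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry sample (row) and feature (column) names")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, sprintf("duplicate sample id: %s",
                            rownames(v)[duplicated(rownames(v))][1L]))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, sprintf("duplicate feature id: %s",
                            colnames(v)[duplicated(colnames(v))][1L]))
  }
  if (identical(object@kind, "methylation") && is.numeric(v) &&
      !isTRUE(object@standardized)) {
    bad <- which(!is.na(v) & (v < 0 | v > 1), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      msg <- c(msg, sprintf(
        "methylation beta value %g outside [0,1] at (%s, %s)",
        v[bad[1L, , drop = FALSE]],
        rownames(v)[bad[1L, 1L]], colnames(v)[bad[1L, 2L]]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix, samples as rows, features as columns, with
#'   dimnames set.
#' @param kind one of [OMICS_KINDS].
#' @param standardized has the layer already been normalized? Raw
#'   methylation input must be `FALSE` so beta values are range-checked.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("f1", "f2", "f3")))
#' OmicsMatrix(m, "mrna")
#' @export
OmicsMatrix <- function(values, kind, standardized = FALSE) {
  storage.mode(values) <- "double"
  new("OmicsMatrix", kind = kind, values = values,
      standardized = standardized)
}

# ---- OmicsDataset ----------------------------------------------------------

#' Multi-omics dataset
#'
#' A named collection of [OmicsMatrix-class] layers sharing one ordered
#' sample set.
#'
#' @slot name dataset label.
#' @slot matrices named list of [OmicsMatrix-class]; names are the omics
#'   kinds.
#'
#' @seealso [OmicsDataset()]
#' @export
setClass("OmicsDataset",
  representation(name = "character", matrices = "list"))

setValidity("OmicsDataset", function(object) {
  msg <- character()
  m <- object@matrices
  if (length(m) < 1L)
    msg <- c(msg, "at least one omics matrix is required")
  if (!all(vapply(m, is, logical(1), "OmicsMatrix")))
    msg <- c(msg, "matrices must all be OmicsMatrix objects")
  else {
    kinds <- vapply(m, function(x) x@kind, character(1))
    if (!identical(unname(names(m)), unname(kinds)))
      msg <- c(msg, "list names must equal each matrix's omics kind")
    if (anyDuplicated(kinds))
      msg <- c(msg, "duplicate omics kind in dataset")
    ids <- lapply(m, function(x) rownames(x@values))
    if (length(m) > 1L &&
        !all(vapply(ids[-1L], identical, logical(1), ids[[1L]])))
      msg <- c(msg, "all omics matrices must share one ordered sample set")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsDataset
#'
#' Layers are stored in the canonical [OMICS_KINDS] order regardless of the
#' order supplied.
#'
#' @param matrices list of [OmicsMatrix-class] objects (named or not; names
#'   are derived from each matrix's kind).
#' @param name dataset label.
#' @return An [OmicsDataset-class].
#' @export
OmicsDataset <- function(matrices, name = "dataset") {
  kinds <- vapply(matrices, function(x) x@kind, character(1))
  ord <- order(match(kinds, OMICS_KINDS))
  matrices <- matrices[ord]
  names(matrices) <- kinds[ord]
  new("OmicsDataset", name = name, matrices = matrices)
}

# ---- ClinicalTable ---------------------------------------------------------

#' Clinical annotation table
#'
#' Overall survival (time in days, event indicator) plus typed clinical
#' covariates per sample. Missing covariate or survival entries are `NA`.
#'
#' @slot sampleIds ordered unique sample identifiers.
#' @slot time nonnegative survival times (days), `NA` allowed.
#' @slot event event indicator, 1 = death observed, 0 = censored, `NA`
#'   allowed.
#' @slot covariates data.frame of covariate values, rownames = sampleIds.
#' @slot covariateKinds named character, `"discrete"` or `"numeric"` per
#'   covariate.
#'
#' @seealso [ClinicalTable()], [readClinicalTable()]
#' @export
setClass("ClinicalTable",
  representation(sampleIds = "character", time = "numeric",
                 event = "integer", covariates = "data.frame",
                 covariateKinds = "character"))

setValidity("ClinicalTable", function(object) {
  msg <- character()
  n <- length(object@sampleIds)
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sample ids")
  if (length(object@time) != n || length(object@event) != n)
    msg <- c(msg, "time and event must have one entry per sample")
  bad_t <- which(!is.na(object@time) & object@time < 0)
  if (length(bad_t))
    msg <- c(msg, sprintf("negative survival time for sample %s",
                          object@sampleIds[bad_t[1L]]))
  bad_e <- which(!is.na(object@event) & !object@event %in% c(0L, 1L))
  if (length(bad_e))
    msg <- c(msg, sprintf("event indicator not in {0,1} for sample %s",
                          object@sampleIds[bad_e[1L]]))
  if (nrow(object@covariates) != n)
    msg <- c(msg, "covariates must have one row per sample")
  if (!setequal(names(object@covariateKinds), colnames(object@covariates)))
    msg <- c(msg, "covariateKinds must name exactly the covariate columns")
  if (!all(object@covariateKinds %in% c("discrete", "numeric")))
    msg <- c(msg, "covariate kinds must be 'discrete' or 'numeric'")
  if (length(msg)) msg else TRUE
})

#' Construct a ClinicalTable
#'
#' @param sampleIds character vector of unique sample ids.
#' @param time survival times in days (`NA` allowed).
#' @param event 0/1 event indicators (`NA` allowed).
#' @param covariates data.frame of covariates, one row per sample.
#' @param covariateKinds named character of `"discrete"`/`"numeric"`;
#'   defaults to [DEFAULT_COVARIATE_SCHEMA] restricted to the supplied
#'   columns.
#' @return A [ClinicalTable-class].
#' @export
ClinicalTable <- function(sampleIds, time, event,
                          covariates = data.frame(row.names = sampleIds),
                          covariateKinds = NULL) {
  if (is.null(covariateKinds)) {
    covariateKinds <- DEFAULT_COVARIATE_SCHEMA[
      intersect(names(DEFAULT_COVARIATE_SCHEMA), colnames(covariates))]
    extra <- setdiff(colnames(covariates), names(covariateKinds))
    if (length(extra)) {
      guessed <- vapply(covariates[extra], is.numeric, logical(1))
      covariateKinds <- c(covariateKinds,
                          stats::setNames(ifelse(guessed, "numeric",
                                                 "discrete"), extra))
    }
  }
  rownames(covariates) <- sampleIds
  new("ClinicalTable", sampleIds = as.character(sampleIds),
      time = as.numeric(time), event = as.integer(event),
      covariates = covariates, covariateKinds = covariateKinds)
}

# ---- ClusterAssignment -----------------------------------------------------

#' Cluster assignment of one subtyping method
#'
#' Maps every sample to an integer subtype label in `1..K`. Every cluster
#' must be non-empty. An optional runtime (seconds) carries the method's
#' reported running-time metric.
#'
#' @slot methodName method label.
#' @slot labels named integer vector, names are sample ids.
#' @slot k number of clusters.
#' @slot runtime wall-clock seconds of the clustering run, `NA` if not
#'   measured.
#'
#' @seealso [ClusterAssignment()], [readClusterAssignment()]
#' @export
setClass("ClusterAssignment",
  representation(methodName = "character", labels = "integer",
                 k = "integer", runtime = "numeric"))

setValidity("ClusterAssignment", function(object) {
  msg <- character()
  lab <- object@labels
  k <- object@k
  if (length(k) != 1L || is.na(k) || k < 1L)
    msg <- c(msg, "K must be a positive integer")
  if (is.null(names(lab)) || anyDuplicated(names(lab)))
    msg <- c(msg, "labels must be named by unique sample ids")
  if (length(k) == 1L && !is.na(k)) {
    if (any(is.na(lab)) || any(lab < 1L | lab > k))
      msg <- c(msg, sprintf("labels must lie in 1..%d", k))
    else {
      empty <- setdiff(seq_len(k), unique(lab))
      if (length(empty))
        msg <- c(msg, sprintf("cluster %d of method '%s' is empty",
                              empty[1L], object@methodName))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClusterAssignment
#'
#' @param labels integer labels named by sample id, values in `1..K`.
#' @param methodName method label.
#' @param k cluster count; defaults to `max(labels)`.
#' @param runtime optional wall-clock seconds.
#' @return A [ClusterAssignment-class].
#' @export
ClusterAssignment <- function(labels, methodName = "method",
                              k = max(labels), runtime = NA_real_) {
  new("ClusterAssignment", methodName = methodName,
      labels = stats::setNames(as.integer(labels), names(labels)),
      k = as.integer(k), runtime = as.numeric(runtime))
}

# ---- ScoreBoard ------------------------------------------------------------

#' Methods-by-metrics score board
#'
#' Raw metric values and their harmonized 0-10 scores for a set of
#' evaluated methods on one dataset. Columns follow [METRIC_IDS]; the `LRT`
#' raw column holds the log-rank p-value (smaller is better), all other
#' raw columns are larger-is-better.
#'
#' @slot raw methods-by-metrics matrix of raw values.
#' @slot scores methods-by-metrics matrix of harmonized scores in \[0,10\].
#' @slot internalAvg per-method mean of the S/CH/D scores.
#' @slot clinicalAvg per-method mean of the LRT/ECP scores.
#'
#' @seealso [buildScoreBoard()]
#' @export
setClass("ScoreBoard",
  representation(raw = "matrix", scores = "matrix",
                 internalAvg = "numeric", clinicalAvg = "numeric"))

setValidity("ScoreBoard", function(object) {
  msg <- character()
  if (!identical(colnames(object@raw), METRIC_IDS) ||
      !identical(colnames(object@scores), METRIC_IDS))
    msg <- c(msg, sprintf("columns must be exactly: %s",
                          paste(METRIC_IDS, collapse = ", ")))
  if (!identical(rownames(object@raw), rownames(object@scores)))
    msg <- c(msg, "raw and scores must list the same methods")
  s <- object@scores
  if (any(!is.na(s) & (s < 0 | s > 10)))
    msg <- c(msg, "harmonized scores must lie in [0, 10]")
  if (length(msg)) msg else TRUE
})

# ---- AWAResult -------------------------------------------------------------

#' Accuracy-weighted average result
#'
#' Per-method AWA values at the configured weights, the induced ranking,
#' reported runtimes, and an optional weight-sweep table.
#'
#' @slot awa named numeric, AWA per method.
#' @slot ranking method names sorted by descending AWA (ties broken by
#'   internal average, then name).
#' @slot runtime named numeric, seconds (`NA` = not measured).
#' @slot weights numeric `c(w1, w2)` used for `awa`.
#' @slot sweep data.frame with columns `w1`, `w2` and one AWA column per
#'   method; zero rows when no sweep was requested.
#'
#' @seealso [rankAndSweep()]
#' @export
setClass("AWAResult",
  representation(awa = "numeric", ranking = "character",
                 runtime = "numeric", weights = "numeric",
                 sweep = "data.frame"))

setValidity("AWAResult", function(object) {
  msg <- character()
  if (!setequal(object@ranking, names(object@awa)) ||
      length(object@ranking) != length(object@awa))
    msg <- c(msg, "ranking must be a permutation of the method names")
  if (length(object@weights) != 2L || any(object@weights < 0) ||
      sum(object@weights) <= 0)
    msg <- c(msg, "weights must be two nonnegative numbers with w1 + w2 > 0")
  if (length(msg)) msg else TRUE
})

# ---- EvaluationReport ------------------------------------------------------

#' End-to-end evaluation report
#'
#' The output of [evaluateMethods()]: configuration echo, raw metrics and
#' harmonized scores, AWA values and ranking, per-covariate enrichment
#' p-values, and accumulated warnings.
#'
#' @slot datasetName dataset label.
#' @slot config list echoing weights, alpha, representation strategy and
#'   other run settings.
#' @slot board a [ScoreBoard-class].
#' @slot result an [AWAResult-class].
#' @slot perCovariateP methods-by-covariates matrix of enrichment p-values.
#' @slot messages character log of warnings raised during the run.
#'
#' @export
setClass("EvaluationReport",
  representation(datasetName = "character", config = "list",
                 board = "ScoreBoard", result = "AWAResult",
                 perCovariateP = "matrix", messages = "character"))
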