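# Accessor generics and show() methods for the core containers.

#' Sample identifiers
#'
#' @param x an OmicsMatrix, OmicsDataset, ClinicalTable or
#'   ClusterAssignment.
#' @return Character vector of ordered sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) rownames(x@values))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "OmicsDataset",
          function(x) rownames(x@matrices[[1L]]@values))

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ClinicalTable", function(x) x@sampleIds)

#' @rdname sampleIds
#' @export
setMethod("sampleIds", "ClusterAssignment", function(x) names(x@labels))

#' Feature identifiers of an omics matrix
#' @param x an OmicsMatrix.
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname featureIds
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) colnames(x@values))

#' Omics kind of a matrix
#' @param x an OmicsMatrix.
#' @export
setGeneric("omicsKind", function(x) standardGeneric("omicsKind"))

#' @rdname omicsKind
#' @export
setMethod("omicsKind", "OmicsMatrix", function(x) x@kind)

#' Underlying samples-by-features value matrix
#' @param x an OmicsMatrix.
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @rdname omicsValues
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)

#' Omics layers of a dataset
#' @param x an OmicsDataset.
#' @return Named list of [OmicsMatrix-class], in canonical kind order.
#' @export
setGeneric("omicsLayers", function(x) standardGeneric("omicsLayers"))

#' @rdname omicsLayers
#' @export
setMethod("omicsLayers", "OmicsDataset", function(x) x@matrices)

#' Survival endpoint accessors
#'
#' `survivalTime()` returns the per-sample follow-up times (days);
#' `survivalEvent()` the 0/1 death indicators.
#'
#' @param x a ClinicalTable.
#' @export
setGeneric("survivalTime", function(x) standardGeneric("survivalTime"))

#' @rdname survivalTime
#' @export
setMethod("survivalTime", "ClinicalTable",
          function(x) stats::setNames(x@time, x@sampleIds))

#' @rdname survivalTime
#' @export
setGeneric("survivalEvent", function(x) standardGeneric("survivalEvent"))

#' @rdname survivalTime
#' @export
setMethod("survivalEvent", "ClinicalTable",
          function(x) stats::setNames(x@event, x@sampleIds))

#' Clinical covariates
#'
#' `covariates()` returns the covariate data.frame (rownames = sample ids);
#' `covariateKinds()` the named `"discrete"`/`"numeric"` type vector.
#'
#' @param x a ClinicalTable.
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname covariates
#' @export
setMethod("covariates", "ClinicalTable", function(x) x@covariates)

#' @rdname covariates
#' @export
setGeneric("covariateKinds", function(x) standardGeneric("covariateKinds"))

#' @rdname covariates
#' @export
setMethod("covariateKinds", "ClinicalTable", function(x) x@covariateKinds)

#' Cluster labels and cluster count
#'
#' @param x a ClusterAssignment.
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterAssignment", function(x) x@labels)

#' @rdname clusterLabels
#' @export
setGeneric("clusterK", function(x) standardGeneric("clusterK"))

#' @rdname clusterLabels
#' @export
setMethod("clusterK", "ClusterAssignment", function(x) x@k)

#' @rdname clusterLabels
#' @export
setGeneric("methodName", function(x) standardGeneric("methodName"))

#' @rdname clusterLabels
#' @export
setMethod("methodName", "ClusterAssignment", function(x) x@methodName)

#' Score-board accessors
#'
#' `rawMetrics()` and `metricScores()` return the methods-by-metrics
#' matrices of raw values and harmonized 0-10 scores;
#' `internalAverage()` / `clinicalAverage()` the per-method component
#' means.
#'
#' @param x a ScoreBoard or EvaluationReport.
#' @export
setGeneric("rawMetrics", function(x) standardGeneric("rawMetrics"))

#' @rdname rawMetrics
#' @export
setMethod("rawMetrics", "ScoreBoard", function(x) x@raw)

#' @rdname rawMetrics
#' @export
setMethod("rawMetrics", "EvaluationReport", function(x) x@board@raw)

#' @rdname rawMetrics
#' @export
setGeneric("metricScores", function(x) standardGeneric("metricScores"))

#' @rdname rawMetrics
#' @export
setMethod("metricScores", "ScoreBoard", function(x) x@scores)

#' @rdname rawMetrics
#' @export
setMethod("metricScores", "EvaluationReport", function(x) x@board@scores)

#' @rdname rawMetrics
#' @export
setGeneric("internalAverage", function(x) standardGeneric("internalAverage"))

#' @rdname rawMetrics
#' @export
setMethod("internalAverage", "ScoreBoard", function(x) x@internalAvg)

#' @rdname rawMetrics
#' @export
setGeneric("clinicalAverage", function(x) standardGeneric("clinicalAverage"))

#' @rdname rawMetrics
#' @export
setMethod("clinicalAverage", "ScoreBoard", function(x) x@clinicalAvg)

#' AWA accessors
#'
#' `awaValues()` returns the per-method AWA index; `awaRanking()` the
#' method names sorted best-first.
#'
#' @param x an AWAResult or EvaluationReport.
#' @export
setGeneric("awaValues", function(x) standardGeneric("awaValues"))

#' @rdname awaValues
#' @export
setMethod("awaValues", "AWAResult", function(x) x@awa)

#' @rdname awaValues
#' @export
setMethod("awaValues", "EvaluationReport", function(x) x@result@awa)

#' @rdname awaValues
#' @export
setGeneric("awaRanking", function(x) standardGeneric("awaRanking"))

#' @rdname awaValues
#' @export
setMethod("awaRanking", "AWAResult", function(x) x@ranking)

#' @rdname awaValues
#' @export
setMethod("awaRanking", "EvaluationReport", function(x) x@result@ranking)

#' @rdname awaValues
#' @export
setGeneric("scoreBoard", function(x) standardGeneric("scoreBoard"))

#' @rdname awaValues
#' @export
setMethod("scoreBoard", "EvaluationReport", function(x) x@board)

# ---- show methods ----------------------------------------------------------

setMethod("show", "OmicsMatrix", function(object) {
  v <- object@values
  cat(sprintf("OmicsMatrix [%s]: %d samples x %d features (%.1f%% missing)\n",
              object@kind, nrow(v), ncol(v), 100 * mean(is.na(v))))
})

setMethod("show", "OmicsDataset", function(object) {
  cat(sprintf("OmicsDataset '%s': %d samples, %d omics layer(s)\n",
              object@name, length(sampleIds(object)),
              length(object@matrices)))
  for (m in object@matrices)
    cat(sprintf("  %-18s %d features\n", m@kind, ncol(m@values)))
})

setMethod("show", "ClinicalTable", function(object) {
  cat(sprintf(
    "ClinicalTable: %d samples, %d events, %d covariate(s): %s\n",
    length(object@sampleIds), sum(object@event == 1L, na.rm = TRUE),
    ncol(object@covariates),
    paste(colnames(object@covariates), collapse = ", ")))
})

setMethod("show", "ClusterAssignment", function(object) {
  cat(sprintf("ClusterAssignment '%s': %d samples in K = %d clusters (%s)\n",
              object@methodName, length(object@labels), object@k,
              paste(tabulate(object@labels, object@k), collapse = "/")))
})

setMethod("show", "ScoreBoard", function(object) {
  cat(sprintf("ScoreBoard: %d method(s) x %d metrics\n",
              nrow(object@raw), ncol(object@raw)))
  print(round(object@scores, 2))
})

setMethod("show", "AWAResult", function(object) {
  cat(sprintf("AWAResult (w1 = %g, w2 = %g):\n",
              object@weights[1L], object@weights[2L]))
  for (m in object@ranking)
    cat(sprintf("  %-20s AWA = %6.3f\n", m, object@awa[m]))
})

setMethod("show", "EvaluationReport", function(object) {
  cat(sprintf("EvaluationReport for '%s'\n", object@datasetName))
  show(object@board)
  show(object@result)
  if (length(object@messages))
    cat(sprintf("%d warning(s) logged\n", length(object@messages)))
})
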