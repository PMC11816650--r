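# End-to-end orchestration: align inputs, preprocess, compute internal
# and clinical metrics per method, harmonize scores, aggregate AWA, rank,
# and emit a reproducible report (JSON, plus a TSV score board).

#' Evaluate a set of subtyping methods on one dataset
#'
#' Runs the full pipeline: sample alignment, per-omics preprocessing
#' (optional, on by default), internal metrics (S, CH, D) on the chosen
#' representation, clinical metrics (log-rank p, ECP), cross-method score
#' harmonization and AWA ranking. Warnings raised by any stage are
#' collected into the report's message log.
#'
#' Score harmonization is cross-method, so at least two assignments are
#' required; raw metrics for one method never depend on which other
#' methods are evaluated.
#'
#' @param dataset an [OmicsDataset-class] (raw scale unless
#'   `preprocess = FALSE`).
#' @param clinical a [ClinicalTable-class].
#' @param assignments list of [ClusterAssignment-class], length >= 2.
#' @param w1,w2 internal/clinical weights of the AWA (default 0.5/0.5).
#' @param alpha enrichment significance level for ECP.
#' @param representation `"concatenate"` or `"per_omics"` (see
#'   [internalMetrics()]).
#' @param preprocess run [preprocessDataset()] first?
#' @param preprocessCfg a [PreprocessConfig-class].
#' @param sweepWeights optional list of `c(w1, w2)` pairs for a weight
#'   sweep.
#' @param adjust multiplicity handling for ECP (`"none"` or `"BH"`).
#' @return An [EvaluationReport-class].
#' @export
evaluateMethods <- function(dataset, clinical, assignments,
                            w1 = 0.5, w2 = 0.5, alpha = 0.05,
                            representation = c("concatenate", "per_omics"),
                            preprocess = TRUE,
                            preprocessCfg = preprocessConfig(),
                            sweepWeights = NULL,
                            adjust = c("none", "BH")) {
  representation <- match.arg(representation)
  adjust <- match.arg(adjust)
  if (is(assignments, "ClusterAssignment")) assignments <- list(assignments)
  if (length(assignments) < 2L)
    stop(paste("cross-method score normalization needs >= 2 methods;",
               "supply at least two assignments"), call. = FALSE)
  msgs <- character()
  collect <- function(expr) withCallingHandlers(expr, warning = function(w) {
    msgs <<- c(msgs, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  aligned <- collect(alignAndValidate(dataset, clinical, assignments))
  ds <- aligned$dataset
  if (preprocess) ds <- collect(preprocessDataset(ds, preprocessCfg))

  methods <- vapply(aligned$assignments, methodName, character(1))
  if (anyDuplicated(methods))
    stop("method names must be unique", call. = FALSE)
  raw <- matrix(NA_real_, length(methods), length(METRIC_IDS),
                dimnames = list(methods, METRIC_IDS))
  cov_names <- colnames(covariates(aligned$clinical))
  perCov <- matrix(NA_real_, length(methods), length(cov_names),
                   dimnames = list(methods, cov_names))
  for (i in seq_along(aligned$assignments)) {
    a <- aligned$assignments[[i]]
    im <- tryCatch(collect(internalMetrics(ds, a, representation)),
                   error = function(e) stop(sprintf(
                     "internal metrics failed for method '%s': %s",
                     methodName(a), conditionMessage(e)), call. = FALSE))
    cm <- tryCatch(collect(clinicalMetrics(aligned$clinical, a,
                                           alpha = alpha, adjust = adjust)),
                   error = function(e) stop(sprintf(
                     "clinical metrics failed for method '%s': %s",
                     methodName(a), conditionMessage(e)), call. = FALSE))
    raw[i, ] <- c(im[["S"]], im[["CH"]], im[["D"]], cm$lrt$p, cm$ecp)
    perCov[i, names(cm$perCovariateP)] <- cm$perCovariateP
  }

  board <- buildScoreBoard(raw)
  runtime <- stats::setNames(
    vapply(aligned$assignments, function(a) a@runtime, numeric(1)), methods)
  result <- rankAndSweep(board, w1 = w1, w2 = w2,
                         sweepWeights = sweepWeights, runtime = runtime)
  new("EvaluationReport", datasetName = dataset@name,
      config = list(w1 = w1, w2 = w2, alpha = alpha,
                    representation = representation,
                    preprocess = preprocess, adjust = adjust,
                    k = vapply(aligned$assignments, clusterK, integer(1)),
                    nSamples = length(sampleIds(ds))),
      board = board, result = result, perCovariateP = perCov,
      messages = msgs)
}

.matrix_to_list <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) as.list(m[i, ]))
  names(out) <- rownames(m)
  out
}

#' Convert an evaluation report to a plain list
#'
#' The list form is what [writeReport()] serializes; it round-trips
#' through JSON losslessly (numbers at full double precision).
#'
#' @param report an [EvaluationReport-class].
#' @return Nested named list.
#' @export
reportToList <- function(report) {
  b <- report@board
  r <- report@result
  list(dataset = report@datasetName,
       config = report@config,
       raw = .matrix_to_list(b@raw),
       scores = .matrix_to_list(b@scores),
       internalAvg = as.list(b@internalAvg),
       clinicalAvg = as.list(b@clinicalAvg),
       awa = as.list(r@awa),
       ranking = as.list(r@ranking),
       runtime = as.list(ifelse(is.na(r@runtime), "not measured",
                                r@runtime)),
       weights = list(w1 = r@weights[1L], w2 = r@weights[2L]),
       sweep = if (nrow(r@sweep)) r@sweep else NULL,
       perCovariateP = .matrix_to_list(report@perCovariateP),
       messages = as.list(report@messages))
}

#' Write an evaluation report as JSON
#'
#' @param report an [EvaluationReport-class].
#' @param path output JSON path.
#' @param timestamp embed the wall-clock time of writing? Off by default
#'   so repeated runs produce byte-identical files.
#' @return `path`, invisibly.
#' @export
writeReport <- function(report, path, timestamp = FALSE) {
  x <- reportToList(report)
  if (timestamp)
    x$generated <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a JSON evaluation report back as a list
#'
#' @param path JSON path written by [writeReport()].
#' @return The report list (see [reportToList()]), timestamp field
#'   removed.
#' @export
readReport <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  x$generated <- NULL
  x
}

#' Write the score board as TSV
#'
#' One row per method: raw metrics, harmonized scores, component
#' averages, AWA and rank.
#'
#' @param report an [EvaluationReport-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeScoreBoard <- function(report, path) {
  b <- report@board
  r <- report@result
  methods <- rownames(b@raw)
  df <- data.frame(method = methods,
                   round(b@raw, 6), round(b@scores, 4),
                   internal_avg = round(b@internalAvg, 4),
                   clinical_avg = round(b@clinicalAvg, 4),
                   awa = round(r@awa[methods], 4),
                   rank = match(methods, r@ranking),
                   check.names = FALSE)
  colnames(df)[2:6] <- paste0("raw_", METRIC_IDS)
  colnames(df)[7:11] <- paste0("score_", METRIC_IDS)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Average AWA across several per-dataset reports
#'
#' Mirrors the cross-cancer aggregation of a benchmark: per-method mean
#' AWA over the supplied reports plus the induced overall ranking.
#' Dataset order does not affect the result.
#'
#' @param reports list of [EvaluationReport-class] sharing one method set.
#' @return data.frame with columns `method`, `meanAWA`, `rank`, and one
#'   AWA column per dataset, ordered best-first.
#' @export
compareReports <- function(reports) {
  if (length(reports) == 0L) stop("no reports supplied", call. = FALSE)
  meth_sets <- lapply(reports, function(r) sort(names(awaValues(r))))
  if (!all(vapply(meth_sets[-1L], identical, logical(1), meth_sets[[1L]]))) {
    all_m <- unique(unlist(meth_sets))
    common <- Reduce(intersect, meth_sets)
    stop(sprintf("reports disagree on method names: %s",
                 paste(setdiff(all_m, common), collapse = ", ")),
         call. = FALSE)
  }
  methods <- meth_sets[[1L]]
  awa_mat <- vapply(reports, function(r) awaValues(r)[methods],
                    numeric(length(methods)))
  awa_mat <- matrix(awa_mat, nrow = length(methods),
                    dimnames = list(methods,
                                    vapply(reports, function(r)
                                      r@datasetName, character(1))))
  mean_awa <- rowMeans(awa_mat)
  ord <- order(-mean_awa, methods)
  out <- data.frame(method = methods, meanAWA = mean_awa,
                    rank = rank(-mean_awa, ties.method = "min"),
                    awa_mat, check.names = FALSE)
  out[ord, , drop = FALSE]
}
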