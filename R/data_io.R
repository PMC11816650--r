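# Reading, writing and cross-validating the three input artifacts:
# per-omics feature matrices, the clinical table, and per-method cluster
# assignments. All files are UTF-8 TSV with a header row; empty cells or
# "NA" (case-insensitive) denote missing values.

.is_missing_token <- function(x) {
  is.na(x) | x == "" | toupper(x) == "NA"
}

.parse_numeric_cells <- function(chr, rows, cols, path) {
  miss <- .is_missing_token(chr)
  out <- suppressWarnings(as.numeric(chr))
  bad <- which(!miss & is.na(out))
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf("non-numeric cell '%s' at (%s, %s) in %s",
                 chr[i], rows[(i - 1L) %% length(rows) + 1L],
                 cols[(i - 1L) %/% length(rows) + 1L], path), call. = FALSE)
  }
  out[miss] <- NA_real_
  out
}

#' Read a single-omics TSV matrix
#'
#' Expects samples as rows: the header row holds feature ids, the first
#' column holds sample ids. Empty cells or `NA` are treated as missing.
#' Methylation matrices are checked to lie in \[0,1\].
#'
#' @param path TSV file path.
#' @param kind one of [OMICS_KINDS].
#' @return A validated [OmicsMatrix-class]; row and column order preserved
#'   from the file.
#' @seealso [writeOmicsMatrix()]
#' @export
readOmicsMatrix <- function(path, kind) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = NULL)
  if (ncol(df) < 2L)
    stop(sprintf("%s: expected sample-id column plus >=1 feature column",
                 path), call. = FALSE)
  samples <- df[[1L]]
  features <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    stop(sprintf("duplicate sample id: %s", samples[duplicated(samples)][1L]),
         call. = FALSE)
  if (anyDuplicated(features))
    stop(sprintf("duplicate feature id: %s",
                 features[duplicated(features)][1L]), call. = FALSE)
  chr <- as.matrix(df[, -1L, drop = FALSE])
  vals <- matrix(.parse_numeric_cells(as.vector(chr), samples, features, path),
                 nrow = length(samples),
                 dimnames = list(samples, features))
  OmicsMatrix(vals, kind)
}

#' Write a single-omics matrix as TSV
#'
#' Inverse of [readOmicsMatrix()]: samples as rows, missing entries written
#' as `NA`, values at full double precision so a read round-trips exactly.
#'
#' @param m an [OmicsMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(m, path) {
  v <- omicsValues(m)
  chr <- matrix(formatC(v, digits = 17, format = "g"), nrow = nrow(v))
  chr[is.na(v)] <- "NA"
  lines <- c(paste(c("sample_id", colnames(v)), collapse = "\t"),
             vapply(seq_len(nrow(v)), function(i)
               paste(c(rownames(v)[i], chr[i, ]), collapse = "\t"),
               character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read the clinical table
#'
#' Expects a TSV with columns `sample_id`, `os_time` (days), `os_event`
#' (1 = death, 0 = censored) and any subset of the covariate schema.
#' Columns outside the schema are ignored with a warning, as are schema
#' covariates absent from the file.
#'
#' @param path TSV file path.
#' @param covariateSchema named character mapping covariate name to
#'   `"discrete"`/`"numeric"`; defaults to [DEFAULT_COVARIATE_SCHEMA].
#' @return A validated [ClinicalTable-class].
#' @export
readClinicalTable <- function(path,
                              covariateSchema = DEFAULT_COVARIATE_SCHEMA) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = NULL)
  req <- c("sample_id", "os_time", "os_event")
  if (!all(req %in% colnames(df)))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(setdiff(req, colnames(df)), collapse = ", ")),
         call. = FALSE)
  ids <- df$sample_id
  time <- .parse_numeric_cells(df$os_time, ids, "os_time", path)
  event <- .parse_numeric_cells(df$os_event, ids, "os_event", path)
  bad_e <- which(!is.na(event) & !event %in% c(0, 1))
  if (length(bad_e))
    stop(sprintf("os_event = %g not in {0,1} for sample %s",
                 event[bad_e[1L]], ids[bad_e[1L]]), call. = FALSE)
  bad_t <- which(!is.na(time) & time < 0)
  if (length(bad_t))
    stop(sprintf("negative os_time for sample %s", ids[bad_t[1L]]),
         call. = FALSE)

  present <- intersect(names(covariateSchema), colnames(df))
  absent <- setdiff(names(covariateSchema), colnames(df))
  unknown <- setdiff(colnames(df), c(req, names(covariateSchema)))
  if (length(absent))
    warning(sprintf("covariate column(s) absent from %s: %s", path,
                    paste(absent, collapse = ", ")), call. = FALSE)
  if (length(unknown))
    warning(sprintf("ignoring unrecognised column(s) in %s: %s", path,
                    paste(unknown, collapse = ", ")), call. = FALSE)

  cov <- data.frame(row.names = ids)
  for (nm in present) {
    raw <- df[[nm]]
    if (covariateSchema[[nm]] == "numeric")
      cov[[nm]] <- .parse_numeric_cells(raw, ids, nm, path)
    else {
      raw[.is_missing_token(raw)] <- NA_character_
      cov[[nm]] <- raw
    }
  }
  ClinicalTable(ids, time, event, cov, covariateSchema[present])
}

#' Write a clinical table as TSV
#'
#' @param clinical a [ClinicalTable-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeClinicalTable <- function(clinical, path) {
  cov <- covariates(clinical)
  fmt <- function(x) {
    out <- if (is.numeric(x)) formatC(x, digits = 17, format = "g")
           else as.character(x)
    out[is.na(x)] <- "NA"
    out
  }
  cols <- c(list(sample_id = sampleIds(clinical),
                 os_time = fmt(clinical@time),
                 os_event = fmt(clinical@event)),
            lapply(cov, fmt))
  names(cols)[-(1:3)] <- colnames(cov)
  lines <- c(paste(names(cols), collapse = "\t"),
             do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a cluster-assignment file
#'
#' Expects a TSV with columns `sample_id` and `label` (integer subtype in
#' `1..K`). `K` defaults to the largest observed label.
#'
#' @param path TSV file path.
#' @param methodName method label; defaults to the file name without
#'   extension.
#' @param k cluster count; `NULL` means `max(label)`.
#' @param runtime optional seconds to attach as the runtime metric.
#' @return A validated [ClusterAssignment-class].
#' @export
readClusterAssignment <- function(path, methodName = NULL, k = NULL,
                                  runtime = NA_real_) {
  if (is.null(methodName))
    methodName <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", na.strings = NULL)
  if (!all(c("sample_id", "label") %in% colnames(df)))
    stop(sprintf("%s: required columns sample_id, label", path),
         call. = FALSE)
  lab <- .parse_numeric_cells(df$label, df$sample_id, "label", path)
  if (any(is.na(lab)) || any(lab != round(lab)))
    stop(sprintf("%s: labels must be integers", path), call. = FALSE)
  ClusterAssignment(stats::setNames(as.integer(lab), df$sample_id),
                    methodName = methodName,
                    k = if (is.null(k)) max(lab) else k,
                    runtime = runtime)
}

#' Write a cluster assignment as TSV
#'
#' @param assign a [ClusterAssignment-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeClusterAssignment <- function(assign, path) {
  lab <- clusterLabels(assign)
  writeLines(c("sample_id\tlabel",
               paste(names(lab), lab, sep = "\t")), path, useBytes = TRUE)
  invisible(path)
}

#' Align omics, clinical and assignment inputs on one sample set
#'
#' Intersects the sample sets of all inputs, reorders every structure to
#' the canonical order (the omics dataset's order restricted to the
#' intersection), and re-checks that no cluster was emptied by the
#' intersection. Dropped samples are reported.
#'
#' The operation is idempotent: applying it to its own output is a no-op.
#'
#' @param dataset an [OmicsDataset-class].
#' @param clinical a [ClinicalTable-class].
#' @param assignments list of [ClusterAssignment-class].
#' @return A list with elements `dataset`, `clinical`, `assignments`
#'   (aligned), and `dropped` (named list of sample ids removed from each
#'   input).
#' @export
alignAndValidate <- function(dataset, clinical, assignments) {
  if (is(assignments, "ClusterAssignment")) assignments <- list(assignments)
  sets <- c(list(omics = sampleIds(dataset), clinical = sampleIds(clinical)),
            stats::setNames(lapply(assignments, sampleIds),
                            vapply(assignments, methodName, character(1))))
  common <- Reduce(intersect, sets)
  if (length(common) == 0L)
    stop("sample-set intersection across inputs is empty", call. = FALSE)
  common <- sets$omics[sets$omics %in% common]  # canonical order
  dropped <- lapply(sets, setdiff, common)
  if (any(lengths(dropped) > 0L))
    message(sprintf("alignAndValidate: dropped %d sample(s): %s",
                    length(unique(unlist(dropped))),
                    paste(unique(unlist(dropped)), collapse = ", ")))

  mats <- lapply(omicsLayers(dataset), function(m)
    OmicsMatrix(omicsValues(m)[common, , drop = FALSE], omicsKind(m),
                standardized = m@standardized))
  ds <- OmicsDataset(mats, name = dataset@name)

  keep <- match(common, sampleIds(clinical))
  cl <- ClinicalTable(common, clinical@time[keep], clinical@event[keep],
                      clinical@covariates[keep, , drop = FALSE],
                      clinical@covariateKinds)

  asg <- lapply(assignments, function(a) {
    lab <- clusterLabels(a)[common]
    empty <- setdiff(seq_len(clusterK(a)), unique(lab))
    if (length(empty))
      stop(sprintf(
        "cluster %d of method '%s' has no samples after alignment",
        empty[1L], methodName(a)), call. = FALSE)
    ClusterAssignment(lab, methodName = methodName(a), k = clusterK(a),
                      runtime = a@runtime)
  })
  list(dataset = ds, clinical = cl, assignments = asg, dropped = dropped)
}

#' Read an evaluation run configuration (YAML)
#'
#' The config lists dataset paths and omics kinds, the clinical table, the
#' assignment files, and run settings (weights `w1`/`w2`, enrichment level
#' `alpha`, representation strategy, seed). Missing settings fall back to
#' the documented defaults.
#'
#' @param path YAML file path.
#' @return A named list with elements `name`, `omics` (list of
#'   `path`/`kind`), `clinical`, `assignments`, `w1`, `w2`, `alpha`,
#'   `representation`, `seed`.
#' @export
readEvalConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(name = "dataset", w1 = 0.5, w2 = 0.5, alpha = 0.05,
                   representation = "concatenate", seed = 1L)
  for (nm in names(defaults))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  for (nm in c("omics", "clinical", "assignments"))
    if (is.null(cfg[[nm]]))
      stop(sprintf("config %s: missing required field '%s'", path, nm),
           call. = FALSE)
  cfg
}
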