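# Cross-method score harmonization and the accuracy-weighted average
# (AWA) index. Raw metric values are oriented so larger is always better
# (the log-rank p-value becomes -log10(p)), min-max rescaled per metric
# across methods onto [0, 10], and aggregated as
#
#   AWA = ((S_S + S_CH + S_D) * w1 + (S_LRT + S_ECP) * w2) / (3 w1 + 2 w2)
#
# with internal weight w1 and clinical weight w2 (default 0.5 / 0.5).

#' Orient raw metric values so larger is better
#'
#' `S`, `CH`, `D` and `ECP` have maximum as optimum and pass through
#' unchanged. `LRT` is a p-value with minimum as optimum and is oriented
#' via `-log10(p)` with `p` floored at 1e-300. `Inf` sentinels (from
#' degenerate CH/Dunn denominators) are replaced by the maximum finite
#' value plus one distinguishable step, so they stay the best value
#' without breaking the min-max rescaling.
#'
#' @param raw numeric vector of raw values, one per method.
#' @param metric one of [METRIC_IDS].
#' @return Oriented numeric vector (larger = better, all finite unless
#'   every input is infinite).
#' @export
orientMetric <- function(raw, metric = METRIC_IDS) {
  metric <- match.arg(metric)
  v <- if (metric == "LRT") -log10(pmax(raw, 1e-300)) else raw
  inf <- is.infinite(v) & v > 0
  if (any(inf)) {
    fin <- v[!inf]
    if (length(fin) == 0L) return(rep(0, length(v)))  # all degenerate: tie
    step <- max(max(fin) - min(fin), 1)
    v[inf] <- max(fin) + step
  }
  v
}

#' Min-max rescale oriented values onto the 0-10 score scale
#'
#' `score = 10 * (v - min) / (max - min)` per metric across methods: the
#' best method scores 10, the worst 0. When all methods tie, every method
#' receives the neutral score 5.
#'
#' @param oriented numeric vector of oriented values (one per method,
#'   larger = better, finite).
#' @return Scores in \[0, 10\].
#' @export
normalizeToScores <- function(oriented) {
  if (length(oriented) < 2L)
    stop("score normalization needs >= 2 methods", call. = FALSE)
  if (any(!is.finite(oriented)))
    stop("non-finite oriented value; orient metrics first", call. = FALSE)
  rng <- range(oriented)
  if (rng[1L] == rng[2L]) return(rep(5, length(oriented)))
  # ratio first, then scale: guarantees the extremes map to exactly 0 and 10
  pmin(pmax(((oriented - rng[1L]) / (rng[2L] - rng[1L])) * 10, 0), 10)
}

#' Accuracy-weighted average of one method's five scores
#'
#' @param scores named numeric with elements `S`, `CH`, `D`, `LRT`, `ECP`,
#'   each in \[0, 10\].
#' @param w1 internal-metric weight (nonnegative).
#' @param w2 clinical-metric weight (nonnegative); `w1 + w2 > 0`.
#' @return The AWA value, a weighted mean of the five scores lying between
#'   their minimum and maximum.
#' @examples
#' computeAWA(c(S = 8, CH = 7, D = 6.25, LRT = 4, ECP = 3))  # 5.65
#' @export
computeAWA <- function(scores, w1 = 0.5, w2 = 0.5) {
  stopifnot(all(METRIC_IDS %in% names(scores)))
  if (w1 < 0 || w2 < 0 || w1 + w2 <= 0)
    stop("weights must be nonnegative with w1 + w2 > 0", call. = FALSE)
  s <- scores[METRIC_IDS]
  ((s[["S"]] + s[["CH"]] + s[["D"]]) * w1 +
     (s[["LRT"]] + s[["ECP"]]) * w2) / (3 * w1 + 2 * w2)
}

#' Build a score board from raw metric values
#'
#' Orients each metric, min-max rescales across methods onto \[0, 10\],
#' and records the internal (S/CH/D) and clinical (LRT/ECP) score
#' averages per method.
#'
#' @param raw methods-by-metrics numeric matrix with columns
#'   [METRIC_IDS]; the `LRT` column holds log-rank p-values.
#' @return A [ScoreBoard-class].
#' @export
buildScoreBoard <- function(raw) {
  if (is.null(rownames(raw)) || nrow(raw) < 2L)
    stop("score board needs >= 2 named methods", call. = FALSE)
  if (!identical(colnames(raw), METRIC_IDS))
    stop(sprintf("raw matrix columns must be exactly: %s",
                 paste(METRIC_IDS, collapse = ", ")), call. = FALSE)
  scores <- raw
  for (m in METRIC_IDS)
    scores[, m] <- normalizeToScores(orientMetric(raw[, m], m))
  new("ScoreBoard", raw = raw, scores = scores,
      internalAvg = rowMeans(scores[, c("S", "CH", "D"), drop = FALSE]),
      clinicalAvg = rowMeans(scores[, c("LRT", "ECP"), drop = FALSE]))
}

#' Rank methods by AWA and sweep the internal/clinical weights
#'
#' Computes each method's AWA at the configured weights, ranks methods by
#' descending AWA (ties broken by internal average, then method name so
#' output files are deterministic), and optionally tabulates AWA over a
#' list of alternative weight pairs.
#'
#' @param board a [ScoreBoard-class].
#' @param w1,w2 weights of the internal and clinical components.
#' @param sweepWeights optional list of `c(w1, w2)` pairs (or a 2-column
#'   matrix) to tabulate; `NULL` for no sweep.
#' @param runtime optional named numeric of per-method runtimes (seconds);
#'   `NA` means not measured.
#' @return An [AWAResult-class].
#' @export
rankAndSweep <- function(board, w1 = 0.5, w2 = 0.5, sweepWeights = NULL,
                         runtime = NULL) {
  methods <- rownames(board@scores)
  if (length(methods) == 0L) stop("empty method list", call. = FALSE)
  awa_at <- function(a, b) vapply(methods, function(m)
    computeAWA(board@scores[m, ], a, b), numeric(1))
  awa <- awa_at(w1, w2)
  ord <- order(-awa, -board@internalAvg[methods], methods)
  sweep_df <- data.frame(w1 = numeric(0), w2 = numeric(0))
  if (!is.null(sweepWeights)) {
    if (is.matrix(sweepWeights))
      sweepWeights <- asplit(sweepWeights, 1L)
    rows <- lapply(sweepWeights, function(w) {
      vals <- awa_at(w[1L], w[2L])
      as.data.frame(c(list(w1 = w[1L], w2 = w[2L]), as.list(vals)))
    })
    sweep_df <- do.call(rbind, rows)
  }
  if (is.null(runtime))
    runtime <- stats::setNames(rep(NA_real_, length(methods)), methods)
  new("AWAResult", awa = awa, ranking = methods[ord],
      runtime = runtime[methods], weights = c(w1, w2), sweep = sweep_df)
}
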