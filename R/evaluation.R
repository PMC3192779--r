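#' @include AllClasses.R
NULL

#' Cross-tabulate predicted against clinical status
#'
#' Positive is the clinically receptor-positive class throughout. The
#' prediction and clinical table must cover the identical sample set; the
#' clinical calls are matched to the prediction's sample order by ID.
#'
#' @param pred A [PredictionResult-class] (or a character vector of
#'   `"positive"`/`"negative"` calls named by sample ID).
#' @param clin A [ClinicalTable-class] with no `"unknown"` entries (or a
#'   named character vector of clinical calls).
#' @return A [ConfusionMatrix-class].
#' @export
confusionMatrix <- function(pred, clin) {
  p <- if (is(pred, "PredictionResult")) status(pred) else pred
  truth <- if (is(clin, "ClinicalTable")) status(clin) else clin
  if (any(truth == "unknown"))
    stop("clinical table contains 'unknown' status; align first")
  if (!setequal(names(p), names(truth)) || length(p) != length(truth))
    stop("prediction and clinical table must cover identical sample sets")
  truth <- truth[names(p)]
  ConfusionMatrix(tp = sum(p == "positive" & truth == "positive"),
                  fp = sum(p == "positive" & truth == "negative"),
                  tn = sum(p == "negative" & truth == "negative"),
                  fn = sum(p == "negative" & truth == "positive"))
}

#' Diagnostic metrics for a confusion matrix
#'
#' Computes percent-scale accuracy, sensitivity, specificity, PPV and NPV
#' under the conventional definitions (sensitivity = tp/(tp+fn) etc.), plus
#' the two-sided Fisher exact p-value. A metric whose denominator is zero is
#' reported as `NA`; the others are still computed.
#'
#' @param cm A [ConfusionMatrix-class].
#' @return An [EvaluationReport-class].
#' @examples
#' evaluationMetrics(ConfusionMatrix(tp = 183, fp = 9, tn = 68, fn = 26))
#' @export
evaluationMetrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  total <- cm@tp + cm@fp + cm@tn + cm@fn
  new("EvaluationReport", confusion = cm,
      accuracy = pct(cm@tp + cm@tn, total),
      sensitivity = pct(cm@tp, cm@tp + cm@fn),
      specificity = pct(cm@tn, cm@tn + cm@fp),
      ppv = pct(cm@tp, cm@tp + cm@fp),
      npv = pct(cm@tn, cm@tn + cm@fn),
      fisher_p = fisherExactTwoSided(cm))
}

#' Two-sided Fisher exact test for a confusion matrix
#'
#' Two-sided p-value for association between predicted and clinical status,
#' computed by summing the hypergeometric probabilities (margins fixed) of
#' every table at most as probable as the observed one — the minimum-
#' likelihood convention of [stats::fisher.test()], to which this delegates.
#'
#' @param cm A [ConfusionMatrix-class].
#' @return p-value in \[0, 1\].
#' @export
fisherExactTwoSided <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  m <- matrix(c(cm@tn, cm@fn, cm@fp, cm@tp), 2, byrow = TRUE)
  stats::fisher.test(m)$p.value
}

#' Cross-dataset t-based confidence interval for a metric
#'
#' Treats the per-dataset values of a metric (percent scale) as replicates
#' and forms the t-interval `mean +/- t_{1-(1-level)/2, n-1} * sd/sqrt(n)`.
#' Bounds are deliberately not clamped to \[0, 100\]; with few datasets the
#' upper bound can exceed 100.
#'
#' @param metric_values Numeric vector of per-dataset percentages, length
#'   at least 2.
#' @param level Confidence level (default 0.95).
#' @return An [IntervalEstimate-class].
#' @examples
#' ciMeanT(c(77.78, 59.09, 76.27))
#' @export
ciMeanT <- function(metric_values, level = 0.95) {
  v <- as.numeric(metric_values)
  if (length(v) < 2L)
    stop("at least 2 per-dataset values are required for an interval")
  n <- length(v)
  m <- mean(v)
  half <- stats::qt(1 - (1 - level) / 2, df = n - 1) * stats::sd(v) / sqrt(n)
  new("IntervalEstimate", mean = m, lower = m - half, upper = m + half,
      level = level, n_datasets = as.integer(n))
}

#' Compare two methods' per-dataset metrics by t-test
#'
#' Two-sided t-test between the metric values of two predictors across the
#' same datasets. Paired by dataset by default (the natural design when the
#' same cohorts are scored under both methods); unpaired is available. Zero
#' variance of the paired differences is flagged as degenerate rather than
#' producing a p-value.
#'
#' @param values_a,values_b Numeric vectors of per-dataset percentages
#'   (equal length when paired; length at least 2 each).
#' @param paired Pair by dataset (default `TRUE`).
#' @return A list with `p_value`, `statistic`, `df`, `paired` and
#'   `degenerate` (`TRUE` with `p_value = NA` when the paired differences
#'   have zero variance).
#' @export
compareMethodsTtest <- function(values_a, values_b, paired = TRUE) {
  a <- as.numeric(values_a)
  b <- as.numeric(values_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("at least 2 values per method are required")
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal-length vectors")
  if (paired && stats::sd(a - b) < .Machine$double.eps * 100)
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_real_,
                paired = TRUE, degenerate = TRUE))
  tt <- stats::t.test(a, b, paired = paired)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       df = unname(tt$parameter), paired = paired, degenerate = FALSE)
}

#' Serialize an evaluation report
#'
#' Flattens an [EvaluationReport-class] into a plain list (suitable for
#' `jsonlite::write_json`) or writes it directly to a JSON file.
#'
#' @param report An [EvaluationReport-class].
#' @param path Optional path; when given, JSON is written there.
#' @return The flat list, invisibly when `path` is given.
#' @export
reportAsList <- function(report, path = NULL) {
  stopifnot(is(report, "EvaluationReport"))
  cm <- report@confusion
  out <- list(
    confusion = list(tp = cm@tp, fp = cm@fp, tn = cm@tn, fn = cm@fn),
    accuracy = report@accuracy, sensitivity = report@sensitivity,
    specificity = report@specificity, ppv = report@ppv, npv = report@npv,
    fisher_p = report@fisher_p)
  if (!is.null(path)) {
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    return(invisible(out))
  }
  out
}
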