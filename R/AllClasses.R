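#' @import methods
#' @importFrom stats cor dnorm kmeans pnorm qt rbinom rnorm sd var
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

VALID_STATUS <- c("positive", "negative", "unknown")
VALID_RECEPTORS <- c("ER", "PR", "ERBB2")

#' ExpressionMatrix: probe-by-sample log-intensity matrix
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' assay, `"exprs"`: log-scale normalized intensities (e.g. fRMA output)
#' with probe-set IDs as rownames and sample IDs as colnames. Validity
#' requires unique, non-empty row and column names and all-finite values;
#' missing values are rejected at construction.
#'
#' @slot platform Character scalar naming the array platform
#'   (e.g. `"HG-U133A"`); `NA` when unknown.
#'
#' @seealso [readExpressionMatrix()], [alignSamples()]
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  representation(platform = "character"),
  prototype(platform = NA_character_)
)

setValidity("ExpressionMatrix", function(object) {
  v <- SummarizedExperiment::assay(object, "exprs")
  msgs <- character()
  if (is.null(rownames(v)) || nrow(v) == 0L)
    msgs <- c(msgs, "probe IDs (rownames) must be present and non-empty")
  if (is.null(colnames(v)) || ncol(v) == 0L)
    msgs <- c(msgs, "sample IDs (colnames) must be present and non-empty")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    msgs <- c(msgs, sprintf("duplicated probe ID(s): %s",
      paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
  if (!is.null(colnames(v)) && anyDuplicated(colnames(v)))
    msgs <- c(msgs, sprintf("duplicated sample ID(s): %s",
      paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  if (!is.numeric(v) || any(!is.finite(v)))
    msgs <- c(msgs, "all expression values must be finite numbers")
  if (length(object@platform) != 1L)
    msgs <- c(msgs, "platform must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values Numeric matrix, probes in rows (rownames = probe IDs),
#'   samples in columns (colnames = sample IDs); log-scale intensities.
#' @param platform Optional platform tag, e.g. `"HG-U133A"`.
#' @return A validated [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
#' ExpressionMatrix(m, platform = "HG-U133A")
#' @export
ExpressionMatrix <- function(values, platform = NA_character_) {
  values <- as.matrix(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  new("ExpressionMatrix", se, platform = as.character(platform))
}

#' ClinicalTable: per-sample binary receptor status
#'
#' Clinical receptor status calls (`positive` / `negative` / `unknown`) for
#' one receptor, with assay provenance. Unknown status is encoded explicitly
#' rather than by absence so per-dataset sample bookkeeping is reproducible.
#'
#' @slot sample_ids Unique sample identifiers.
#' @slot status One of `"positive"`, `"negative"`, `"unknown"` per sample.
#' @slot receptor `"ER"`, `"PR"` or `"ERBB2"`.
#' @slot assay Free-text assay provenance per sample (IHC, FISH, EIA, ...).
#' @export
setClass("ClinicalTable",
  representation(sample_ids = "character", status = "character",
                 receptor = "character", assay = "character")
)

setValidity("ClinicalTable", function(object) {
  msgs <- character()
  if (anyDuplicated(object@sample_ids))
    msgs <- c(msgs, "sample IDs must be unique")
  if (length(object@status) != length(object@sample_ids))
    msgs <- c(msgs, "status must have one entry per sample")
  if (!all(object@status %in% VALID_STATUS))
    msgs <- c(msgs, sprintf("status must be one of: %s",
                            paste(VALID_STATUS, collapse = ", ")))
  if (length(object@receptor) != 1L ||
      !(object@receptor %in% VALID_RECEPTORS))
    msgs <- c(msgs, sprintf("receptor must be one of: %s",
                            paste(VALID_RECEPTORS, collapse = ", ")))
  if (length(object@assay) != length(object@sample_ids))
    msgs <- c(msgs, "assay must have one entry per sample")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ClinicalTable
#'
#' @param sample_ids Character vector of unique sample IDs.
#' @param status Character vector (`positive`/`negative`/`unknown`),
#'   recycled checks not applied: one entry per sample.
#' @param receptor `"ER"`, `"PR"` or `"ERBB2"`.
#' @param assay Assay provenance; recycled to one entry per sample.
#' @return A validated [ClinicalTable-class] object.
#' @export
ClinicalTable <- function(sample_ids, status, receptor, assay = "unspecified") {
  assay <- rep_len(as.character(assay), length(sample_ids))
  new("ClinicalTable", sample_ids = as.character(sample_ids),
      status = as.character(status), receptor = as.character(receptor),
      assay = assay)
}

#' Signature: retained probes with signed correlations
#'
#' A receptor, a Spearman-correlation cutoff, and the probe sets retained at
#' that cutoff together with their signed rho values. Every retained probe
#' satisfies `abs(rho) >= cutoff`.
#'
#' @slot receptor `"ER"`, `"PR"` or `"ERBB2"`.
#' @slot cutoff Correlation cutoff in (0, 1).
#' @slot probe_ids Unique probe-set IDs.
#' @slot rho Signed Spearman correlations, one per probe, in \[-1, 1\].
#' @slot source_tag Free-text provenance of the signature.
#' @export
setClass("Signature",
  representation(receptor = "character", cutoff = "numeric",
                 probe_ids = "character", rho = "numeric",
                 source_tag = "character")
)

setValidity("Signature", function(object) {
  msgs <- character()
  if (length(object@cutoff) != 1L || !is.finite(object@cutoff) ||
      object@cutoff <= 0 || object@cutoff >= 1)
    msgs <- c(msgs, "cutoff must be a single value in (0, 1)")
  if (length(object@probe_ids) == 0L)
    msgs <- c(msgs, "signature must retain at least one probe")
  if (anyDuplicated(object@probe_ids))
    msgs <- c(msgs, "probe IDs must be unique within a signature")
  if (length(object@rho) != length(object@probe_ids))
    msgs <- c(msgs, "rho must have one value per probe")
  if (any(!is.finite(object@rho)) || any(abs(object@rho) > 1))
    msgs <- c(msgs, "rho values must be finite and in [-1, 1]")
  if (length(object@cutoff) == 1L && is.finite(object@cutoff) &&
      any(abs(object@rho) < object@cutoff))
    msgs <- c(msgs, "every |rho| must be >= cutoff")
  if (length(object@receptor) != 1L ||
      !(object@receptor %in% VALID_RECEPTORS))
    msgs <- c(msgs, sprintf("receptor must be one of: %s",
                            paste(VALID_RECEPTORS, collapse = ", ")))
  if (length(msgs)) msgs else TRUE
})

#' Construct a Signature
#'
#' @param receptor `"ER"`, `"PR"` or `"ERBB2"`.
#' @param cutoff Correlation cutoff in (0, 1).
#' @param probe_ids Unique probe-set IDs.
#' @param rho Signed correlations, one per probe; `abs(rho) >= cutoff`.
#' @param source_tag Free-text provenance.
#' @return A validated [Signature-class] object.
#' @export
Signature <- function(receptor, cutoff, probe_ids, rho,
                      source_tag = "derived") {
  new("Signature", receptor = as.character(receptor),
      cutoff = as.numeric(cutoff), probe_ids = as.character(probe_ids),
      rho = as.numeric(rho), source_tag = as.character(source_tag))
}

#' CorrelationTable: per-probe Spearman rho against binary status
#'
#' @slot entries Named numeric vector of rho values (finite, in \[-1, 1\]).
#' @slot n_samples Number of samples the correlations were computed on.
#' @slot excluded_probes Probes with undefined rho (zero rank variance).
#' @export
setClass("CorrelationTable",
  representation(entries = "numeric", n_samples = "integer",
                 excluded_probes = "character")
)

setValidity("CorrelationTable", function(object) {
  msgs <- character()
  if (length(object@entries) &&
      (is.null(names(object@entries)) || anyDuplicated(names(object@entries))))
    msgs <- c(msgs, "entries must be uniquely named by probe ID")
  if (any(!is.finite(object@entries)) || any(abs(object@entries) > 1))
    msgs <- c(msgs, "every rho must be finite and in [-1, 1]")
  if (length(intersect(names(object@entries), object@excluded_probes)))
    msgs <- c(msgs, "entries and excluded_probes must be disjoint")
  if (length(msgs)) msgs else TRUE
})

#' PredictionResult: per-sample binary status calls
#'
#' @slot sample_ids Sample identifiers, in prediction order.
#' @slot predicted `"positive"` or `"negative"` per sample.
#' @slot cluster_centroids 2-row matrix of cluster centers in signature
#'   space (rows `negative`, `positive`); for the single-probe EM baseline
#'   the two component means.
#' @slot orientation_scores Sign-weighted centroid scores used to orient the
#'   clusters (higher = positive).
#' @export
setClass("PredictionResult",
  representation(sample_ids = "character", predicted = "character",
                 cluster_centroids = "matrix", orientation_scores = "numeric")
)

setValidity("PredictionResult", function(object) {
  msgs <- character()
  if (length(object@predicted) != length(object@sample_ids))
    msgs <- c(msgs, "one prediction per sample required")
  if (!all(object@predicted %in% c("positive", "negative")))
    msgs <- c(msgs, "predictions must be 'positive' or 'negative'")
  if (length(object@orientation_scores) != 2L)
    msgs <- c(msgs, "exactly two orientation scores required")
  if (length(msgs)) msgs else TRUE
})

#' MixtureFit: two-component univariate Gaussian mixture
#'
#' Result of fitting a 2-component, unequal-variance Gaussian mixture by EM
#' to the expression values of a single probe set across samples.
#'
#' @slot means Component means (log-intensity units).
#' @slot variances Component variances (floored at `var_floor`).
#' @slot weights Mixing weights in (0, 1), summing to 1.
#' @slot loglik_trace Log-likelihood after each EM iteration
#'   (non-decreasing).
#' @slot n_iterations Number of EM iterations performed.
#' @slot converged Whether the log-likelihood gain fell below tolerance.
#' @slot floored Whether the variance floor was applied.
#' @export
setClass("MixtureFit",
  representation(means = "numeric", variances = "numeric",
                 weights = "numeric", loglik_trace = "numeric",
                 n_iterations = "integer", converged = "logical",
                 floored = "logical")
)

setValidity("MixtureFit", function(object) {
  msgs <- character()
  if (length(object@means) != 2L || length(object@variances) != 2L ||
      length(object@weights) != 2L)
    msgs <- c(msgs, "means, variances and weights must each have length 2")
  if (any(object@weights <= 0) || any(object@weights >= 1) ||
      abs(sum(object@weights) - 1) > 1e-9)
    msgs <- c(msgs, "weights must lie in (0, 1) and sum to 1")
  if (any(object@variances <= 0))
    msgs <- c(msgs, "variances must be positive")
  if (length(object@loglik_trace) > 1L &&
      any(diff(object@loglik_trace) < -1e-6))
    msgs <- c(msgs, "log-likelihood trace must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

#' ConfusionMatrix: 2x2 cross-tabulation of predicted vs clinical status
#'
#' Positive means clinically receptor-positive; predicted positive means
#' called positive by the predictor.
#'
#' @slot tp,fp,tn,fn Non-negative counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "numeric", fp = "numeric",
                 tn = "numeric", fn = "numeric")
)

setValidity("ConfusionMatrix", function(object) {
  cts <- c(object@tp, object@fp, object@tn, object@fn)
  msgs <- character()
  if (length(cts) != 4L || any(!is.finite(cts)) || any(cts < 0) ||
      any(cts != round(cts)))
    msgs <- c(msgs, "tp, fp, tn, fn must be single non-negative integers")
  if (sum(cts) < 1)
    msgs <- c(msgs, "total count must be at least 1")
  if (length(msgs)) msgs else TRUE
})

#' Construct a ConfusionMatrix from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts: true positives, false
#'   positives, true negatives, false negatives.
#' @return A validated [ConfusionMatrix-class] object.
#' @examples
#' ConfusionMatrix(tp = 183, fp = 9, tn = 68, fn = 26)
#' @export
ConfusionMatrix <- function(tp, fp, tn, fn) {
  new("ConfusionMatrix", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn))
}

#' EvaluationReport: diagnostic metrics for a confusion matrix
#'
#' Percent-scale accuracy, sensitivity, specificity, PPV and NPV (each `NA`
#' when its denominator is zero) plus the two-sided Fisher exact p-value.
#'
#' @slot confusion The underlying [ConfusionMatrix-class].
#' @slot accuracy,sensitivity,specificity,ppv,npv Percentages (0-100 scale),
#'   `NA` when undefined.
#' @slot fisher_p Two-sided Fisher exact p-value in \[0, 1\].
#' @export
setClass("EvaluationReport",
  representation(confusion = "ConfusionMatrix", accuracy = "numeric",
                 sensitivity = "numeric", specificity = "numeric",
                 ppv = "numeric", npv = "numeric", fisher_p = "numeric")
)

#' IntervalEstimate: cross-dataset t-based confidence interval
#'
#' Mean of a percent-scale metric across datasets with its t-interval. The
#' bounds are not clamped to \[0, 100\]: with few datasets the upper bound
#' can exceed 100.
#'
#' @slot mean,lower,upper Percent-scale values, `lower <= mean <= upper`.
#' @slot level Confidence level (e.g. 0.95).
#' @slot n_datasets Number of per-dataset values averaged.
#' @export
setClass("IntervalEstimate",
  representation(mean = "numeric", lower = "numeric", upper = "numeric",
                 level = "numeric", n_datasets = "integer")
)

setValidity("IntervalEstimate", function(object) {
  if (object@lower > object@mean + 1e-12 ||
      object@mean > object@upper + 1e-12)
    "must satisfy lower <= mean <= upper" else TRUE
})
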