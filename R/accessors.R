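#' @include AllClasses.R AllGenerics.R
NULL

#' @describeIn ExpressionMatrix Probe-set IDs (rownames).
#' @param x,object An `ExpressionMatrix`.
#' @export
setMethod("probeIds", "ExpressionMatrix", function(x) rownames(x))

#' @describeIn ExpressionMatrix Sample IDs (colnames).
#' @export
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x))

#' @describeIn ExpressionMatrix The probe-by-sample intensity matrix.
#' @export
setMethod("exprValues", "ExpressionMatrix",
          function(x) SummarizedExperiment::assay(x, "exprs"))

#' @describeIn ExpressionMatrix Platform tag.
#' @export
setMethod("platform", "ExpressionMatrix", function(x) x@platform)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (platform: %s)\n",
              nrow(object), ncol(object), object@platform))
})

#' @describeIn ClinicalTable Sample IDs.
#' @param x,object A `ClinicalTable`.
#' @export
setMethod("sampleIds", "ClinicalTable", function(x) x@sample_ids)

#' @describeIn ClinicalTable Receptor of interest.
#' @export
setMethod("receptor", "ClinicalTable", function(x) x@receptor)

#' @describeIn ClinicalTable Status calls, named by sample ID.
#' @export
setMethod("status", "ClinicalTable", function(x) {
  stats::setNames(x@status, x@sample_ids)
})

setMethod("show", "ClinicalTable", function(object) {
  tab <- table(factor(object@status, levels = VALID_STATUS))
  cat(sprintf(
    "ClinicalTable: %s status for %d samples (%d positive, %d negative, %d unknown)\n",
    object@receptor, length(object@sample_ids),
    tab[["positive"]], tab[["negative"]], tab[["unknown"]]))
})

#' Subset a ClinicalTable by sample
#'
#' @param x A [ClinicalTable-class].
#' @param i Sample indices or IDs.
#' @param j,drop,... Ignored.
#' @return A `ClinicalTable` restricted to the selected samples.
#' @export
setMethod("[", "ClinicalTable", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@sample_ids)
  ClinicalTable(x@sample_ids[i], x@status[i], x@receptor, x@assay[i])
})

#' @describeIn Signature Probe-set IDs retained by the signature.
#' @param x,object A `Signature`.
#' @export
setMethod("probeIds", "Signature", function(x) x@probe_ids)

#' @describeIn Signature Signed rho values named by probe ID.
#' @export
setMethod("rho", "Signature",
          function(x) stats::setNames(x@rho, x@probe_ids))

#' @describeIn Signature Receptor of interest.
#' @export
setMethod("receptor", "Signature", function(x) x@receptor)

#' @describeIn Signature Correlation cutoff.
#' @export
setMethod("cutoff", "Signature", function(x) x@cutoff)

setMethod("show", "Signature", function(object) {
  cat(sprintf(
    "Signature: %s, %d probe sets at |rho| >= %.2f (%d positive, %d negative) [%s]\n",
    object@receptor, length(object@probe_ids), object@cutoff,
    sum(object@rho > 0), sum(object@rho < 0), object@source_tag))
})

#' @describeIn CorrelationTable Probes with defined rho.
#' @param x,object A `CorrelationTable`.
#' @export
setMethod("probeIds", "CorrelationTable", function(x) names(x@entries))

#' @describeIn CorrelationTable Named rho values.
#' @export
setMethod("rho", "CorrelationTable", function(x) x@entries)

setMethod("show", "CorrelationTable", function(object) {
  cat(sprintf(
    "CorrelationTable: %d probes over %d samples (%d excluded, zero rank variance)\n",
    length(object@entries), object@n_samples,
    length(object@excluded_probes)))
})

#' @describeIn PredictionResult Sample IDs.
#' @param x,object A `PredictionResult`.
#' @export
setMethod("sampleIds", "PredictionResult", function(x) x@sample_ids)

#' @describeIn PredictionResult Predicted statuses named by sample ID.
#' @export
setMethod("status", "PredictionResult", function(x) {
  stats::setNames(x@predicted, x@sample_ids)
})

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: %d samples (%d positive, %d negative)\n",
              length(object@sample_ids),
              sum(object@predicted == "positive"),
              sum(object@predicted == "negative")))
})

setMethod("show", "MixtureFit", function(object) {
  cat(sprintf(
    "MixtureFit: means %.3f / %.3f, sds %.3f / %.3f, weights %.2f / %.2f\n",
    object@means[1], object@means[2], sqrt(object@variances[1]),
    sqrt(object@variances[2]), object@weights[1], object@weights[2]))
  cat(sprintf("  %d iterations, converged: %s%s\n", object@n_iterations,
              object@converged,
              if (object@floored) " (variance floor applied)" else ""))
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tn, object@fn, object@fp, object@tp), 2, byrow = TRUE,
              dimnames = list(predicted = c("negative", "positive"),
                              clinical = c("negative", "positive")))
  cat("ConfusionMatrix (rows: predicted, columns: clinical)\n")
  print(m)
})

setMethod("show", "EvaluationReport", function(object) {
  show(object@confusion)
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", v)
  cat(sprintf(
    "accuracy %s, sensitivity %s, specificity %s, PPV %s, NPV %s\n",
    fmt(object@accuracy), fmt(object@sensitivity), fmt(object@specificity),
    fmt(object@ppv), fmt(object@npv)))
  cat(sprintf("Fisher exact p (two-sided): %.4g\n", object@fisher_p))
})

setMethod("show", "IntervalEstimate", function(object) {
  cat(sprintf("IntervalEstimate: mean %.2f, %d%% CI [%.2f, %.2f] over %d datasets\n",
              object@mean, round(100 * object@level), object@lower,
              object@upper, object@n_datasets))
})
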