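#' @include AllClasses.R
NULL

#' Probe-set identifiers
#'
#' Accessors for the probe-set identifiers of an object (the rows of an
#' [ExpressionMatrix], the retained probes of a [Signature], or the entries
#' of a [CorrelationTable]).
#'
#' @param x An object with probe-set identifiers.
#' @return Character vector of probe-set IDs.
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))

#' Sample identifiers
#'
#' @param x An object carrying per-sample information.
#' @return Character vector of sample IDs.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Expression values
#'
#' The probe-by-sample matrix of log-scale normalized intensities.
#'
#' @param x An [ExpressionMatrix].
#' @return Numeric matrix (probes in rows, samples in columns).
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Array platform tag
#'
#' @param x An [ExpressionMatrix].
#' @return Character scalar, e.g. `"HG-U133A"` (may be `NA`).
#' @export
setGeneric("platform", function(x) standardGeneric("platform"))

#' Receptor of interest
#'
#' @param x A [ClinicalTable] or [Signature].
#' @return One of `"ER"`, `"PR"`, `"ERBB2"`.
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))

#' Clinical status calls
#'
#' @param x A [ClinicalTable] or [PredictionResult].
#' @return Character vector of statuses, named by sample ID.
#' @export
setGeneric("status", function(x) standardGeneric("status"))

#' Correlation cutoff of a signature
#'
#' @param x A [Signature].
#' @return Numeric scalar in (0, 1).
#' @export
setGeneric("cutoff", function(x) standardGeneric("cutoff"))

#' Signed Spearman correlations
#'
#' @param x A [Signature] or [CorrelationTable].
#' @return Numeric vector of rho values, named by probe ID.
#' @export
setGeneric("rho", function(x) standardGeneric("rho"))
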