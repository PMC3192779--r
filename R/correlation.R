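#' @include AllClasses.R
NULL

# Coerce clinical labels to a 0/1 vector (negative = 0, positive = 1)
# ordered like the expression matrix samples.
.binaryStatus <- function(labels, expr = NULL) {
  if (is(labels, "ClinicalTable")) {
    st <- status(labels)
    if (any(st == "unknown"))
      stop("labels contain 'unknown' status; align the datasets first")
    if (!is.null(expr)) {
      if (!setequal(names(st), sampleIds(expr)))
        stop("expression and clinical samples differ; align the datasets first")
      st <- st[sampleIds(expr)]
    }
    y <- as.numeric(st == "positive")
    names(y) <- names(st)
  } else if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative")))
      stop("status labels must be 'positive' or 'negative'")
    y <- as.numeric(labels == "positive")
  } else {
    y <- as.numeric(labels)
    if (!all(y %in% c(0, 1))) stop("numeric labels must be 0/1")
  }
  y
}

#' Spearman correlation of every probe with binary clinical status
#'
#' For each probe set, computes the Spearman rank correlation (rho) between
#' its expression values and the 0/1 clinical status vector (negative = 0,
#' positive = 1), with ties handled by mid-ranks. Probes with zero rank
#' variance (constant expression) have undefined rho and are reported in
#' `excluded_probes` rather than silently dropped.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param labels A [ClinicalTable-class] aligned with `expr`, or a vector of
#'   `"positive"`/`"negative"` labels (or 0/1) in sample order.
#' @return A [CorrelationTable-class].
#' @examples
#' m <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), 2, 4, byrow = TRUE,
#'   dimnames = list(c("up", "flat"), paste0("s", 1:4)))
#' ct <- spearmanVsStatus(ExpressionMatrix(m), c(0, 0, 1, 1))
#' rho(ct)
#' @export
spearmanVsStatus <- function(expr, labels) {
  stopifnot(is(expr, "ExpressionMatrix"))
  y <- .binaryStatus(labels, expr)
  if (length(y) != ncol(expr))
    stop("one label per sample required")
  if (length(y) < 3L) stop("at least 3 samples required")
  if (length(unique(y)) < 2L)
    stop("both status classes must be present")
  X <- exprValues(expr)
  r <- suppressWarnings(as.vector(stats::cor(t(X), y, method = "spearman")))
  names(r) <- rownames(X)
  excluded <- names(r)[is.na(r)]
  # guard against floating-point |rho| marginally above 1
  r <- pmin(pmax(r[!is.na(r)], -1), 1)
  new("CorrelationTable", entries = r, n_samples = length(y),
      excluded_probes = excluded)
}

#' Select the signature at a correlation cutoff
#'
#' Retains exactly the probes with `abs(rho) >= cutoff`, preserving the
#' signed rho values. Selections are nested across cutoffs: the signature at
#' a higher cutoff is always a subset of the signature at a lower one.
#'
#' @param corr A [CorrelationTable-class].
#' @param cutoff Correlation cutoff in (0, 1).
#' @param receptor `"ER"`, `"PR"` or `"ERBB2"`.
#' @param source_tag Provenance recorded on the signature.
#' @return A [Signature-class].
#' @export
selectSignature <- function(corr, cutoff, receptor, source_tag = "derived") {
  stopifnot(is(corr, "CorrelationTable"))
  if (length(cutoff) != 1L || !is.finite(cutoff) || cutoff <= 0 ||
      cutoff >= 1)
    stop("cutoff must be a single value in (0, 1)")
  keep <- abs(corr@entries) >= cutoff
  if (!any(keep))
    stop(sprintf("no probe reaches |rho| >= %g", cutoff))
  Signature(receptor, cutoff, names(corr@entries)[keep],
            unname(corr@entries[keep]), source_tag)
}

#' Probe with the highest signed Spearman correlation
#'
#' Returns the single probe set maximizing signed rho (not `|rho|`), the
#' natural "best probe" for a positively defined clinical status; ties are
#' broken lexicographically by probe ID.
#'
#' @param corr A [CorrelationTable-class].
#' @return A probe ID (character scalar).
#' @export
bestProbe <- function(corr) {
  stopifnot(is(corr, "CorrelationTable"))
  if (!length(corr@entries)) stop("correlation table is empty")
  ord <- order(-corr@entries, names(corr@entries))
  names(corr@entries)[ord[1L]]
}
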