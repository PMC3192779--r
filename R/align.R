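#' @include AllClasses.R
NULL

#' Align an expression matrix with a clinical table
#'
#' Restricts both objects to the samples they share whose clinical status is
#' known (not `"unknown"`), in the order the samples appear in the
#' expression matrix. Both outputs carry the identical sample ordering, so
#' downstream correlation and evaluation never rely on implicit matching.
#'
#' @param expr An [ExpressionMatrix-class].
#' @param clin A [ClinicalTable-class].
#' @return A list with elements `expression` and `clinical`.
#' @details Errors when the intersection is empty or when only one status
#'   class remains (a binary signature cannot be trained or scored then).
#'   The operation is idempotent.
#' @examples
#' sim <- simulateReceptorData(syntheticConfig(n_samples = 30,
#'   n_background = 5, seed = 1))
#' al <- alignSamples(sim$expression, sim$clinical)
#' ncol(al$expression)
#' @export
alignSamples <- function(expr, clin) {
  stopifnot(is(expr, "ExpressionMatrix"), is(clin, "ClinicalTable"))
  st <- status(clin)
  known <- names(st)[st != "unknown"]
  keep <- sampleIds(expr)[sampleIds(expr) %in% known]
  if (!length(keep))
    stop("no shared samples with known clinical status")
  st <- st[keep]
  for (cls in c("positive", "negative")) {
    if (!any(st == cls))
      stop("no ", cls, " samples after alignment")
  }
  idx <- match(keep, clin@sample_ids)
  list(expression = expr[, keep],
       clinical = ClinicalTable(keep, unname(st), clin@receptor,
                                clin@assay[idx]))
}

#' Remove samples already present in another dataset
#'
#' Cross-dataset deduplication: drops from `secondary` every sample whose ID
#' occurs in `primary_ids` (e.g. tumor profiles contributed to two GEO
#' series by the same center). Matching is by exact sample identifier; an
#' externally determined duplicate list can be passed directly.
#'
#' @param primary_ids Character vector of sample IDs to treat as already
#'   used (or an [ExpressionMatrix-class], in which case its sample IDs are
#'   taken).
#' @param secondary An [ExpressionMatrix-class] to filter.
#' @return `secondary` without the overlapping samples; probe rows
#'   untouched.
#' @export
deduplicateAgainst <- function(primary_ids, secondary) {
  stopifnot(is(secondary, "ExpressionMatrix"))
  if (is(primary_ids, "ExpressionMatrix"))
    primary_ids <- sampleIds(primary_ids)
  keep <- !(sampleIds(secondary) %in% primary_ids)
  if (!any(keep))
    stop("deduplication would remove every sample")
  secondary[, keep]
}
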