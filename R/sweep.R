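#' @include AllClasses.R
NULL

#' Sweep correlation cutoffs and score each candidate signature
#'
#' For each cutoff in an increasing grid: select the probes with
#' `abs(rho) >= cutoff`, call every training sample's status by 2-means
#' clustering in that signature space ([predictStatus()]), and score the
#' calls against the clinical labels. A cutoff retaining no probe is
#' recorded with `n_probes = 0` and `NA` metrics rather than dropped, so
#' the sweep table always has one row per grid point.
#'
#' @param expr An [ExpressionMatrix-class] (training samples).
#' @param clin A [ClinicalTable-class] aligned with `expr`.
#' @param cutoffs Strictly increasing numeric grid in (0, 1). The default
#'   `seq(0.30, 0.60, by = 0.01)` covers the cutoff region usually explored
#'   for receptor signatures.
#' @param seed Integer seed passed to the k-means predictor at every cutoff.
#' @param corr Optional precomputed [CorrelationTable-class] (avoids
#'   recomputing correlations when sweeping repeatedly).
#' @return A data.frame with columns `cutoff`, `n_probes`, `sensitivity`,
#'   `specificity`, `sum_sens_spec`; `n_probes` is non-increasing in
#'   `cutoff`.
#' @export
sweepCutoffs <- function(expr, clin, cutoffs = seq(0.30, 0.60, by = 0.01),
                         seed = 1L, corr = NULL) {
  if (length(cutoffs) < 1L || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoff grid must be strictly increasing")
  if (is.null(corr)) corr <- spearmanVsStatus(expr, clin)
  rec <- if (is(clin, "ClinicalTable")) receptor(clin) else "ER"
  rows <- lapply(cutoffs, function(ct) {
    keep <- abs(corr@entries) >= ct
    if (!any(keep)) {
      return(data.frame(cutoff = ct, n_probes = 0L,
                        sensitivity = NA_real_, specificity = NA_real_,
                        sum_sens_spec = NA_real_))
    }
    sig <- selectSignature(corr, ct, rec, source_tag = "sweep")
    pred <- predictStatus(expr, sig, seed = seed)
    rep <- evaluationMetrics(confusionMatrix(pred, clin))
    data.frame(cutoff = ct, n_probes = length(sig@probe_ids),
               sensitivity = rep@sensitivity,
               specificity = rep@specificity,
               sum_sens_spec = rep@sensitivity + rep@specificity)
  })
  do.call(rbind, rows)
}

#' Choose the cutoff maximizing sensitivity + specificity
#'
#' Returns the cutoff with the largest `sum_sens_spec` on the primary
#' sweep. When the primary sweep is flat — the range of `sum_sens_spec`
#' across usable cutoffs is below `flat_tol` percentage points, so the
#' training set cannot discriminate between signature sizes — a secondary
#' sweep from an additional training set is required and the maximum is
#' taken there instead. Ties are broken toward the larger cutoff (the
#' smaller signature).
#'
#' @param sweep_primary Sweep table from [sweepCutoffs()] on the first
#'   training set.
#' @param sweep_secondary Optional sweep table from a second training set.
#' @param flat_tol Flatness tolerance in percentage points (default 0.5).
#' @return The chosen cutoff (numeric scalar).
#' @export
chooseOptimalCutoff <- function(sweep_primary, sweep_secondary = NULL,
                                flat_tol = 0.5) {
  pick <- function(sw) {
    ok <- sw$n_probes > 0 & is.finite(sw$sum_sens_spec)
    if (!any(ok)) stop("sweep has no usable cutoff")
    sw <- sw[ok, , drop = FALSE]
    best <- sw$sum_sens_spec >= max(sw$sum_sens_spec) - 1e-9
    max(sw$cutoff[best])   # tie -> larger cutoff, smaller signature
  }
  ok <- sweep_primary$n_probes > 0 & is.finite(sweep_primary$sum_sens_spec)
  if (!any(ok)) stop("primary sweep has no usable cutoff")
  sums <- sweep_primary$sum_sens_spec[ok]
  if (max(sums) - min(sums) < flat_tol) {
    if (is.null(sweep_secondary))
      stop("primary sweep is flat (sum of sensitivity and specificity ",
           "constant across cutoffs); a second training set is required ",
           "to choose the cutoff")
    return(pick(sweep_secondary))
  }
  pick(sweep_primary)
}

#' Derive a signature end-to-end from training data
#'
#' The full derivation: Spearman-rank every probe against clinical status,
#' sweep the cutoff grid scoring each candidate signature by k-means status
#' calls, pick the cutoff maximizing sensitivity + specificity (falling back
#' to a second training set when the first sweep is flat), and return the
#' signature at that cutoff.
#'
#' @param expr,clin Aligned training expression matrix and clinical table.
#' @param cutoffs Strictly increasing cutoff grid.
#' @param seed Integer seed for the k-means predictor.
#' @param secondary Optional list with elements `expression` and `clinical`
#'   (a second training set, used only when the first sweep is flat).
#' @param flat_tol Flatness tolerance passed to [chooseOptimalCutoff()].
#' @return A list: `signature` ([Signature-class]), `cutoff`, `sweep`
#'   (primary sweep table), `sweep_secondary` (or `NULL`), and
#'   `correlations` (the primary [CorrelationTable-class]).
#' @export
deriveSignature <- function(expr, clin, cutoffs = seq(0.30, 0.60, by = 0.01),
                            seed = 1L, secondary = NULL, flat_tol = 0.5) {
  corr <- spearmanVsStatus(expr, clin)
  sweep1 <- sweepCutoffs(expr, clin, cutoffs, seed = seed, corr = corr)
  sweep2 <- NULL
  corr2 <- NULL
  ok <- sweep1$n_probes > 0 & is.finite(sweep1$sum_sens_spec)
  flat <- any(ok) &&
    (max(sweep1$sum_sens_spec[ok]) - min(sweep1$sum_sens_spec[ok]) < flat_tol)
  if (flat && !is.null(secondary)) {
    corr2 <- spearmanVsStatus(secondary$expression, secondary$clinical)
    sweep2 <- sweepCutoffs(secondary$expression, secondary$clinical,
                           cutoffs, seed = seed, corr = corr2)
  }
  ct <- chooseOptimalCutoff(sweep1, sweep2, flat_tol = flat_tol)
  # the signature is selected from the sweep that chose the cutoff
  use_corr <- if (flat && !is.null(corr2)) corr2 else corr
  sig <- selectSignature(use_corr, ct, receptor(clin),
                         source_tag = "derived")
  list(signature = sig, cutoff = ct, sweep = sweep1,
       sweep_secondary = sweep2, correlations = corr)
}
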