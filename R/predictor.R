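#' @include AllClasses.R
NULL

#' Call per-sample status by 2-means clustering in signature space
#'
#' Samples are treated as points in the space of the signature's probe sets
#' and partitioned by k-means with k = 2 (Euclidean distance, 25 seeded
#' restarts, lowest within-cluster sum of squares kept). The cluster whose
#' centroid scores higher under the sign-weighted mean
#' `score(c) = mean_j sign(rho_j) * centroid_c[j]` is labelled positive:
#' receptor-positive samples overexpress the positively correlated probes
#' and underexpress the negatively correlated ones. Clustering is always
#' re-run on the dataset at hand (training or validation); only the
#' signature itself is transferred between datasets.
#'
#' @param expr An [ExpressionMatrix-class] containing every signature probe.
#' @param sig A [Signature-class].
#' @param seed Integer seed controlling the k-means restarts.
#' @param nstart Number of random restarts (default 25).
#' @return A [PredictionResult-class].
#' @examples
#' m <- matrix(c(0, 0, 0, 10, 10, 10), 1,
#'   dimnames = list("p1", paste0("s", 1:6)))
#' sig <- Signature("ER", 0.5, "p1", 1)
#' status(predictStatus(ExpressionMatrix(m), sig, seed = 1))
#' @export
predictStatus <- function(expr, sig, seed = 1L, nstart = 25L) {
  stopifnot(is(expr, "ExpressionMatrix"), is(sig, "Signature"))
  missing <- setdiff(sig@probe_ids, probeIds(expr))
  if (length(missing))
    stop("signature probe(s) absent from expression matrix: ",
         paste(missing, collapse = ", "))
  if (ncol(expr) < 2L) stop("at least 2 samples required")
  M <- t(exprValues(expr)[sig@probe_ids, , drop = FALSE])
  set.seed(as.integer(seed))
  km <- tryCatch(
    stats::kmeans(M, centers = 2L, nstart = as.integer(nstart),
                  iter.max = 100L),
    error = function(e) stop("degenerate clustering: ", conditionMessage(e)))
  scores <- as.vector(km$centers %*% sign(sig@rho)) / length(sig@rho)
  if (abs(scores[1L] - scores[2L]) < .Machine$double.eps * 100)
    stop("orientation tie: cluster centroids score identically")
  pos <- which.max(scores)
  predicted <- ifelse(km$cluster == pos, "positive", "negative")
  centroids <- km$centers[order(scores), , drop = FALSE]
  rownames(centroids) <- c("negative", "positive")
  new("PredictionResult", sample_ids = rownames(M),
      predicted = unname(predicted), cluster_centroids = centroids,
      orientation_scores = sort(scores))
}

#' Single-probe status calls via the EM mixture baseline
#'
#' Convenience wrapper so signature-based and single-probe predictors share
#' an interface: fits [fitTwoGaussians()] to the expression values of one
#' probe set and assigns each sample to the higher-mean component via
#' [classifyByMixture()].
#'
#' @param expr An [ExpressionMatrix-class].
#' @param probe_id The probe set to threshold (e.g. `"205225_at"` for ER).
#' @param seed Integer seed for the EM initialization.
#' @return A [PredictionResult-class].
#' @export
predictWithBestProbeEM <- function(expr, probe_id, seed = 1L) {
  stopifnot(is(expr, "ExpressionMatrix"))
  if (length(probe_id) != 1L || !(probe_id %in% probeIds(expr)))
    stop("probe not present in expression matrix: ", probe_id)
  values <- exprValues(expr)[probe_id, ]
  fit <- fitTwoGaussians(values, seed = seed)
  calls <- classifyByMixture(values, fit)
  centroids <- matrix(sort(fit@means), 2, 1,
                      dimnames = list(c("negative", "positive"), probe_id))
  new("PredictionResult", sample_ids = sampleIds(expr),
      predicted = unname(calls), cluster_centroids = centroids,
      orientation_scores = sort(fit@means))
}
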