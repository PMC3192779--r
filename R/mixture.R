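#' @include AllClasses.R
NULL

.mixtureLogLik <- function(x, mu, sigma2, w) {
  # log-sum-exp over the two components, numerically safe in the tails
  l1 <- log(w[1L]) + stats::dnorm(x, mu[1L], sqrt(sigma2[1L]), log = TRUE)
  l2 <- log(w[2L]) + stats::dnorm(x, mu[2L], sqrt(sigma2[2L]), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(exp(l1 - m) + exp(l2 - m)))
}

#' Fit a two-component Gaussian mixture by EM
#'
#' The single-probe baseline model: expression values of a bimodal probe set
#' are modelled as a mixture of two univariate Gaussians with unequal
#' variances (receptor-positive and -negative intensity modes typically have
#' different spreads). Initialization comes from a seeded 2-means split of
#' the values; EM iterates until the log-likelihood gain drops below `tol`
#' or `max_iter` iterations. A variance floor prevents likelihood blow-up on
#' near-degenerate data; when applied it is flagged rather than crashing.
#'
#' @param values Numeric vector of expression values (log scale), at least 4
#'   distinct values.
#' @param seed Integer seed for the 2-means initialization.
#' @param max_iter Maximum EM iterations (default 500).
#' @param tol Log-likelihood convergence tolerance (default 1e-8).
#' @param var_floor Variance floor in squared log-intensity units
#'   (default 1e-4).
#' @return A [MixtureFit-class]; its `loglik_trace` is non-decreasing.
#' @examples
#' set.seed(1)
#' x <- c(rnorm(100, 5), rnorm(100, 9))
#' fitTwoGaussians(x, seed = 1)
#' @export
fitTwoGaussians <- function(values, seed = 1L, max_iter = 500L, tol = 1e-8,
                            var_floor = 1e-4) {
  x <- as.numeric(values)
  if (any(!is.finite(x))) stop("values must be finite")
  if (length(unique(x)) < 4L)
    stop("at least 4 distinct values are required to fit two components")
  n <- length(x)

  set.seed(as.integer(seed))
  km <- stats::kmeans(x, centers = 2L, nstart = 10L)
  mu <- as.vector(km$centers)
  w <- as.vector(table(factor(km$cluster, levels = 1:2))) / n
  w <- pmin(pmax(w, 1 / n), 1 - 1 / n)
  w <- w / sum(w)
  sigma2 <- vapply(1:2, function(k) {
    xs <- x[km$cluster == k]
    if (length(xs) > 1L) stats::var(xs) else var_floor
  }, numeric(1))
  floored <- any(sigma2 < var_floor)
  sigma2 <- pmax(sigma2, var_floor)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # E step: posterior responsibilities of component 1
    l1 <- log(w[1L]) + stats::dnorm(x, mu[1L], sqrt(sigma2[1L]), log = TRUE)
    l2 <- log(w[2L]) + stats::dnorm(x, mu[2L], sqrt(sigma2[2L]), log = TRUE)
    m <- pmax(l1, l2)
    g1 <- exp(l1 - m) / (exp(l1 - m) + exp(l2 - m))
    g <- cbind(g1, 1 - g1)
    # M step
    nk <- colSums(g)
    nk <- pmax(nk, .Machine$double.eps)
    mu <- colSums(g * x) / nk
    sigma2 <- vapply(1:2, function(k) {
      sum(g[, k] * (x - mu[k])^2) / nk[k]
    }, numeric(1))
    if (any(sigma2 < var_floor)) floored <- TRUE
    sigma2 <- pmax(sigma2, var_floor)
    w <- nk / n
    w <- pmin(pmax(w, 1e-12), 1 - 1e-12)
    w <- w / sum(w)
    ll <- .mixtureLogLik(x, mu, sigma2, w)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  new("MixtureFit", means = unname(mu), variances = unname(sigma2),
      weights = unname(w), loglik_trace = trace, n_iterations = iter,
      converged = converged, floored = floored)
}

#' Classify samples under a fitted mixture
#'
#' A sample is called positive when the posterior probability of the
#' higher-mean component is at least 0.5 (a value exactly on the boundary is
#' positive). In the equal-variance case this reduces to a hard intensity
#' threshold at the weighted midpoint of the two means.
#'
#' @param values Numeric vector of expression values (optionally named by
#'   sample ID).
#' @param fit A [MixtureFit-class].
#' @return Character vector of `"positive"`/`"negative"`, named like
#'   `values`.
#' @export
classifyByMixture <- function(values, fit) {
  stopifnot(is(fit, "MixtureFit"))
  x <- as.numeric(values)
  hi <- which.max(fit@means)
  lo <- 3L - hi
  lhi <- log(fit@weights[hi]) +
    stats::dnorm(x, fit@means[hi], sqrt(fit@variances[hi]), log = TRUE)
  llo <- log(fit@weights[lo]) +
    stats::dnorm(x, fit@means[lo], sqrt(fit@variances[lo]), log = TRUE)
  post_hi <- 1 / (1 + exp(llo - lhi))
  out <- ifelse(post_hi >= 0.5, "positive", "negative")
  names(out) <- names(values)
  out
}
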