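# small in-code fixtures shared across test files

tinyExpr <- function(values, probes = NULL, samples = NULL,
                     platform = "test") {
  if (is.null(probes)) probes <- sprintf("p%d", seq_len(nrow(values)))
  if (is.null(samples)) samples <- sprintf("s%d", seq_len(ncol(values)))
  dimnames(values) <- list(probes, samples)
  ExpressionMatrix(values, platform = platform)
}

tinyClin <- function(sample_ids, status, receptor = "ER") {
  ClinicalTable(sample_ids, status, receptor, assay = "test")
}

# independent Spearman oracle: explicit mid-rank construction + the Pearson
# product-moment formula on the ranks
oracleSpearman <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  dx <- rx - mean(rx)
  dy <- ry - mean(ry)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# independent two-sided Fisher oracle: full enumeration of hypergeometric
# probabilities with fixed margins, summing tables at most as probable as
# the observed one
oracleFisher <- function(tn, fn, fp, tp) {
  m <- matrix(c(tn, fn, fp, tp), 2, byrow = TRUE)
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  a <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(a, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

jaccard <- function(a, b) {
  length(intersect(a, b)) / length(union(a, b))
}
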