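#' @include AllClasses.R
NULL

#' Configuration for the synthetic tumor-profile generator
#'
#' Defaults describe a study-like cohort: a few hundred profiled samples, a
#' receptor-positive fraction around 70% (ER-like), a few dozen bimodal
#' marker probes riding on a large background of status-independent probes,
#' a mean shift of 3 log2-units between status classes (well-separated
#' bimodal modes), unit within-class spread, and a 5% chance that the
#' clinical label disagrees with the molecular state (assay discordance).
#'
#' @param n_samples Number of samples.
#' @param prevalence Probability a sample is molecularly positive, in (0,1).
#' @param n_pos_markers,n_neg_markers Marker probes whose high mode tracks
#'   the positive (resp. negative) state; their sum must be at least 1.
#' @param n_background Status-independent probes (may be 0).
#' @param delta Mean shift between status classes, log-intensity units.
#' @param sigma Within-class standard deviation (positive).
#' @param label_noise Probability a clinical label is flipped relative to
#'   the molecular state, in \[0, 0.5).
#' @param baseline Baseline log-intensity.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(n_samples = 250L, prevalence = 0.70,
                            n_pos_markers = 20L, n_neg_markers = 10L,
                            n_background = 2000L, delta = 3, sigma = 1,
                            label_noise = 0.05, baseline = 7, seed = 1L) {
  cfg <- list(n_samples = as.integer(n_samples),
              prevalence = as.numeric(prevalence),
              n_pos_markers = as.integer(n_pos_markers),
              n_neg_markers = as.integer(n_neg_markers),
              n_background = as.integer(n_background),
              delta = as.numeric(delta), sigma = as.numeric(sigma),
              label_noise = as.numeric(label_noise),
              baseline = as.numeric(baseline), seed = as.integer(seed))
  stopifnot(cfg$n_samples >= 2L,
            cfg$prevalence > 0, cfg$prevalence < 1,
            cfg$n_pos_markers >= 0L, cfg$n_neg_markers >= 0L,
            cfg$n_pos_markers + cfg$n_neg_markers >= 1L,
            cfg$n_background >= 0L,
            cfg$sigma > 0,
            cfg$label_noise >= 0, cfg$label_noise < 0.5)
  structure(cfg, class = "SyntheticConfig")
}

#' Generate a synthetic expression dataset with planted ground truth
#'
#' Emulates the structure the receptor-signature pipeline assumes: each
#' sample has a latent binary molecular state drawn with probability
#' `prevalence`; positive-marker probes are `N(baseline + delta * state,
#' sigma^2)`, negative markers `N(baseline + delta * (1 - state), sigma^2)`,
#' background probes `N(baseline, sigma^2)` independent of state; the
#' clinical label equals the molecular state flipped with probability
#' `label_noise`. Probe IDs are synthetic (`SYN_P000001` / `SYN_N000001` /
#' `SYN_B000001`) and never collide with real array probe-set IDs.
#'
#' If a drawn cohort contains only one molecular class, it is regenerated
#' (with a warning) up to 10 times before erroring.
#'
#' @param config A [syntheticConfig()] list.
#' @param receptor Receptor name recorded on the clinical table.
#' @return A list with `expression` ([ExpressionMatrix-class]), `clinical`
#'   ([ClinicalTable-class]), and `truth` — a list holding
#'   `molecular_state` (named 0/1 vector), `signature` (the planted
#'   [Signature-class], rho +1 for positive markers, -1 for negative) and
#'   `config`.
#' @examples
#' sim <- simulateReceptorData(syntheticConfig(n_samples = 40,
#'   n_background = 50, seed = 7))
#' sim$expression
#' @export
simulateReceptorData <- function(config = syntheticConfig(),
                                 receptor = "ER") {
  stopifnot(inherits(config, "SyntheticConfig"))
  n <- config$n_samples
  state <- NULL
  for (attempt in 0:9) {
    set.seed(config$seed + attempt * 7919L)
    cand <- stats::rbinom(n, 1L, config$prevalence)
    if (length(unique(cand)) == 2L) {
      state <- cand
      break
    }
    warning("generated cohort had a single molecular class; regenerating")
  }
  if (is.null(state))
    stop("could not generate both molecular classes in 10 attempts")

  sample_ids <- sprintf("SYNS_%04d", seq_len(n))
  pos_ids <- if (config$n_pos_markers)
    sprintf("SYN_P%06d", seq_len(config$n_pos_markers)) else character()
  neg_ids <- if (config$n_neg_markers)
    sprintf("SYN_N%06d", seq_len(config$n_neg_markers)) else character()
  bg_ids <- if (config$n_background)
    sprintf("SYN_B%06d", seq_len(config$n_background)) else character()

  n_probes <- length(pos_ids) + length(neg_ids) + length(bg_ids)
  mean_mat <- rbind(
    matrix(config$baseline + config$delta * rep(state, each = length(pos_ids)),
           nrow = length(pos_ids), ncol = n),
    matrix(config$baseline + config$delta * rep(1 - state,
                                                each = length(neg_ids)),
           nrow = length(neg_ids), ncol = n),
    matrix(config$baseline, nrow = length(bg_ids), ncol = n))
  values <- mean_mat + stats::rnorm(n_probes * n, sd = config$sigma)
  dimnames(values) <- list(c(pos_ids, neg_ids, bg_ids), sample_ids)

  flip <- stats::rbinom(n, 1L, config$label_noise)
  clinical_state <- ifelse(flip == 1L, 1L - state, state)
  clin <- ClinicalTable(sample_ids,
                        ifelse(clinical_state == 1L, "positive", "negative"),
                        receptor, assay = "synthetic")

  planted <- Signature(receptor, cutoff = 0.5,
                       probe_ids = c(pos_ids, neg_ids),
                       rho = c(rep(1, length(pos_ids)),
                               rep(-1, length(neg_ids))),
                       source_tag = "planted")
  list(expression = ExpressionMatrix(values, platform = "synthetic"),
       clinical = clin,
       truth = list(molecular_state = stats::setNames(state, sample_ids),
                    signature = planted, config = config))
}

#' Analytic operating point of the ideal marker threshold
#'
#' Closed-form expected sensitivity and specificity (percent) of an ideal
#' midpoint threshold on the mean of the planted markers, composed with the
#' clinical label noise. With `k` markers the threshold's per-sample error
#' rate is `Phi(-d/2)` where `d = delta * sqrt(k) / sigma`; a clinically
#' positive sample is molecularly positive with probability depending on
#' `prevalence` and `label_noise` (Bayes), giving for example at
#' `prevalence = 0.5`:
#' `sensitivity = (1 - eps) * Phi(d/2) + eps * (1 - Phi(d/2))`.
#' These values are the oracle against which empirical operating points of
#' the k-means predictor are checked.
#'
#' @param config A [syntheticConfig()] list.
#' @return Named numeric vector `c(sensitivity, specificity)` in percent.
#' @examples
#' expectedOperatingPoint(syntheticConfig(n_pos_markers = 1,
#'   n_neg_markers = 0, delta = 2, sigma = 1, label_noise = 0,
#'   prevalence = 0.5))
#' @export
expectedOperatingPoint <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  k <- config$n_pos_markers + config$n_neg_markers
  d <- config$delta * sqrt(k) / config$sigma
  acc <- stats::pnorm(d / 2)     # P(predicted state = molecular state)
  eps <- config$label_noise
  p <- config$prevalence
  # split joint probabilities over molecular state
  sens <- (p * (1 - eps) * acc + (1 - p) * eps * (1 - acc)) /
    (p * (1 - eps) + (1 - p) * eps)
  spec <- ((1 - p) * (1 - eps) * acc + p * eps * (1 - acc)) /
    ((1 - p) * (1 - eps) + p * eps)
  c(sensitivity = 100 * sens, specificity = 100 * spec)
}
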