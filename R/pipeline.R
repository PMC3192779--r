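#' @include AllClasses.R
NULL

#' Assemble a pipeline run configuration
#'
#' A `RunConfig` ties the stages together: derive a signature on one or two
#' training sets, apply it to validation sets, evaluate, and optionally
#' compare against a single-probe EM baseline. Datasets are given as
#' `list(expression = <path or ExpressionMatrix>, clinical = <path or
#' ClinicalTable>)`.
#'
#' @param receptor `"ER"`, `"PR"` or `"ERBB2"`.
#' @param training A dataset pair, or a list of one or two dataset pairs
#'   (the second is used only when the first sweep is flat).
#' @param validation Named list of dataset pairs (may be empty).
#' @param cutoffs Strictly increasing cutoff grid.
#' @param seed Integer seed used for every stochastic step.
#' @param baseline `"signature"` (no baseline comparison),
#'   `"best_probe_em"` (EM on the training best probe) or
#'   `"published_probe_em"` (EM on `published_probe_id`).
#' @param published_probe_id Probe ID, required for
#'   `"published_probe_em"` (e.g. `"205225_at"` for ER, `"216836_s_at"` for
#'   ERBB2, `"208305_at"` for PR).
#' @param output_dir Run directory; created if needed.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(receptor, training, validation = list(),
                      cutoffs = seq(0.30, 0.60, by = 0.01), seed = 1L,
                      baseline = c("signature", "best_probe_em",
                                   "published_probe_em"),
                      published_probe_id = NULL, output_dir = tempfile("run_")) {
  baseline <- match.arg(baseline)
  if (!is.null(training$expression)) training <- list(training)
  stopifnot(length(training) %in% 1:2)
  if (length(cutoffs) < 1L || is.unsorted(cutoffs, strictly = TRUE))
    stop("cutoff grid must be strictly increasing")
  if (baseline == "published_probe_em" && is.null(published_probe_id))
    stop("baseline 'published_probe_em' requires published_probe_id")
  structure(list(receptor = receptor, training = training,
                 validation = validation, cutoffs = cutoffs,
                 seed = as.integer(seed), baseline = baseline,
                 published_probe_id = published_probe_id,
                 output_dir = output_dir),
            class = "RunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Mirrors [runConfig()]: top-level keys `receptor`, `training` (list of
#' `expression`/`clinical` path pairs), `validation` (named pairs),
#' `cutoff_grid` (`min`, `max`, `step`), `seed`, `baseline`,
#' `published_probe_id`, `output_dir`.
#'
#' @param path Path to the YAML configuration.
#' @return A `"RunConfig"` list.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  g <- y$cutoff_grid
  cutoffs <- if (is.null(g)) seq(0.30, 0.60, by = 0.01) else
    seq(g$min, g$max, by = g$step)
  runConfig(receptor = y$receptor, training = y$training,
            validation = if (is.null(y$validation)) list() else y$validation,
            cutoffs = cutoffs,
            seed = if (is.null(y$seed)) 1L else y$seed,
            baseline = if (is.null(y$baseline)) "signature" else y$baseline,
            published_probe_id = y$published_probe_id,
            output_dir = if (is.null(y$output_dir)) tempfile("run_") else
              y$output_dir)
}

.loadDataset <- function(pair, receptor) {
  expr <- pair$expression
  clin <- pair$clinical
  if (is.character(expr)) expr <- readExpressionMatrix(expr)
  if (is.character(clin)) clin <- readClinicalTable(clin)
  if (!identical(receptor(clin), receptor))
    stop("clinical table receptor (", receptor(clin),
         ") does not match the configured receptor (", receptor, ")")
  alignSamples(expr, clin)
}

.logLines <- function(path, lines) {
  cat(paste0(lines, "\n"), file = path, sep = "", append = TRUE)
}

#' Derive a signature as a pipeline run
#'
#' Runs the derivation on the configured training set(s) and writes, under
#' `output_dir`: `signature.tsv`, the per-cutoff `sweep.tsv` (and
#' `sweep_secondary.tsv` when the flat-sweep fallback fired), and `run.log`
#' recording paths, seed, grid and chosen cutoff. With identical
#' configuration and seed the signature file and sweep tables are
#' byte-identical across runs.
#'
#' @param config A `"RunConfig"` from [runConfig()] or [readRunConfig()].
#' @return Invisibly, the [deriveSignature()] result plus `best_probe` (the
#'   training probe with the highest signed rho).
#' @export
runDerive <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  cat("", file = log_path)
  .logLines(log_path, c(
    sprintf("ReceptorSig %s derive",
            as.character(utils::packageVersion("ReceptorSig"))),
    sprintf("time: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("receptor: %s", config$receptor),
    sprintf("seed: %d", config$seed),
    sprintf("grid: %g..%g (%d cutoffs)", min(config$cutoffs),
            max(config$cutoffs), length(config$cutoffs)),
    sprintf("training sets: %d", length(config$training))))

  primary <- .loadDataset(config$training[[1L]], config$receptor)
  secondary <- if (length(config$training) > 1L)
    .loadDataset(config$training[[2L]], config$receptor) else NULL

  res <- deriveSignature(primary$expression, primary$clinical,
                         cutoffs = config$cutoffs, seed = config$seed,
                         secondary = secondary)
  res$best_probe <- bestProbe(res$correlations)

  writeSignature(res$signature,
                 file.path(config$output_dir, "signature.tsv"))
  utils::write.table(res$sweep, file.path(config$output_dir, "sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$sweep_secondary))
    utils::write.table(res$sweep_secondary,
                       file.path(config$output_dir, "sweep_secondary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  .logLines(log_path, c(
    sprintf("chosen cutoff: %g", res$cutoff),
    sprintf("signature size: %d probes", length(probeIds(res$signature))),
    sprintf("flat-sweep fallback used: %s",
            !is.null(res$sweep_secondary)),
    sprintf("best probe (signed rho): %s", res$best_probe)))
  invisible(res)
}

#' Evaluate a signature across validation datasets
#'
#' For each configured validation dataset: aligns, re-runs the k-means
#' status calls with the given signature, scores against the clinical
#' labels, and writes `report_<dataset>.json`. A `summary.tsv` collects the
#' per-dataset metrics, their cross-dataset t-intervals ([ciMeanT()]), and —
#' when a baseline mode is configured — the paired t-test p-value of
#' signature vs baseline per metric ([compareMethodsTtest()]).
#'
#' @param config A `"RunConfig"`; its `validation` list must be non-empty
#'   and named.
#' @param signature A [Signature-class] (typically from [runDerive()]).
#' @return Invisibly, a list with `reports` (per-dataset
#'   [EvaluationReport-class]s), `baseline_reports` (or `NULL`),
#'   `summary` (data.frame) and `intervals`.
#' @export
runEvaluate <- function(config, signature) {
  stopifnot(inherits(config, "RunConfig"), is(signature, "Signature"))
  if (!length(config$validation))
    stop("no validation datasets configured")
  nms <- names(config$validation)
  if (is.null(nms) || any(!nzchar(nms)))
    stop("validation datasets must be named")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  reports <- list()
  baseline_reports <- if (config$baseline == "signature") NULL else list()
  for (nm in nms) {
    ds <- .loadDataset(config$validation[[nm]], config$receptor)
    pred <- predictStatus(ds$expression, signature, seed = config$seed)
    rep <- evaluationMetrics(confusionMatrix(pred, ds$clinical))
    reports[[nm]] <- rep
    reportAsList(rep, file.path(config$output_dir,
                                sprintf("report_%s.json", nm)))
    if (!is.null(baseline_reports)) {
      probe <- if (config$baseline == "published_probe_em")
        config$published_probe_id else
        bestProbe(spearmanVsStatus(ds$expression, ds$clinical))
      bpred <- predictWithBestProbeEM(ds$expression, probe,
                                      seed = config$seed)
      brep <- evaluationMetrics(confusionMatrix(bpred, ds$clinical))
      baseline_reports[[nm]] <- brep
      reportAsList(brep, file.path(config$output_dir,
                                   sprintf("report_%s_baseline.json", nm)))
    }
  }

  grab <- function(reps, metric)
    vapply(reps, function(r) slot(r, metric), numeric(1))
  summary_rows <- lapply(metric_names, function(metric) {
    v <- grab(reports, metric)
    row <- data.frame(metric = metric,
                      mean = mean(v), lower = NA_real_, upper = NA_real_,
                      n_datasets = length(v), baseline_mean = NA_real_,
                      t_test_p = NA_real_)
    if (length(v) >= 2L && all(is.finite(v))) {
      ci <- ciMeanT(v)
      row$lower <- ci@lower
      row$upper <- ci@upper
    }
    if (!is.null(baseline_reports)) {
      bv <- grab(baseline_reports, metric)
      row$baseline_mean <- mean(bv)
      if (length(v) >= 2L && all(is.finite(v)) && all(is.finite(bv)))
        row$t_test_p <- compareMethodsTtest(v, bv, paired = TRUE)$p_value
    }
    row
  })
  summary_df <- do.call(rbind, summary_rows)
  utils::write.table(summary_df, file.path(config$output_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  intervals <- lapply(stats::setNames(metric_names, metric_names),
    function(metric) {
      v <- grab(reports, metric)
      if (length(v) >= 2L && all(is.finite(v))) ciMeanT(v) else NULL
    })
  invisible(list(reports = reports, baseline_reports = baseline_reports,
                 summary = summary_df, intervals = intervals))
}
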