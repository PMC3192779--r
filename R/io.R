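#' @include AllClasses.R
NULL

#' Read a tab-delimited expression matrix
#'
#' Expects the shape of a GEO series-matrix style export after
#' normalization: a header row of sample IDs, a first column `probe_id`,
#' and one row of log-scale intensities per probe set. Row and column order
#' are preserved from the file.
#'
#' @param path Path to a TSV file.
#' @param platform Optional platform tag stored on the result.
#' @return An [ExpressionMatrix-class].
#' @details A duplicated probe ID, or any blank / non-numeric cell, is a
#'   load error naming the offending probe and sample.
#' @export
readExpressionMatrix <- function(path, platform = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L)
    stop("expression file must have a probe_id column plus sample columns: ",
         path)
  probe_ids <- df[[1L]]
  dup <- unique(probe_ids[duplicated(probe_ids)])
  if (length(dup))
    stop("duplicated probe ID(s) in ", path, ": ",
         paste(dup, collapse = ", "))
  raw <- as.matrix(df[, -1L, drop = FALSE])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                  dimnames = list(probe_ids, colnames(raw))))
  bad <- which(!is.finite(vals) | raw == "", arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-numeric or missing value(s) in ", path, " at: ",
         paste(sprintf("probe '%s' / sample '%s'",
                       probe_ids[bad[, 1L]], colnames(raw)[bad[, 2L]]),
               collapse = "; "))
  }
  ExpressionMatrix(vals, platform = platform)
}

#' Write an expression matrix as TSV
#'
#' @param x An [ExpressionMatrix-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
  df <- data.frame(probe_id = probeIds(x), exprValues(x),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical status table
#'
#' TSV with columns `sample_id`, `status` (positive/negative/unknown),
#' `receptor` and `assay`. All rows must refer to the same receptor.
#'
#' @param path Path to a TSV file.
#' @return A [ClinicalTable-class].
#' @export
readClinicalTable <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "status", "receptor", "assay")
  if (!all(need %in% colnames(df)))
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  rec <- unique(df$receptor)
  if (length(rec) != 1L)
    stop("clinical table mixes receptors: ", paste(rec, collapse = ", "))
  ClinicalTable(df$sample_id, df$status, rec, df$assay)
}

#' Write a clinical status table as TSV
#'
#' @param x A [ClinicalTable-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeClinicalTable <- function(x, path) {
  df <- data.frame(sample_id = x@sample_ids, status = x@status,
                   receptor = x@receptor, assay = x@assay,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature file
#'
#' The signature format is a TSV of `probe_id` and `rho` preceded by a
#' comment header block:
#' \preformatted{
#' # receptor: ER
#' # cutoff: 0.43
#' # source: some provenance text
#' probe_id	rho
#' 205225_at	0.50
#' }
#'
#' @param path Path to a signature TSV.
#' @return A [Signature-class].
#' @export
readSignature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  grab <- function(key) {
    m <- grep(sprintf("^#\\s*%s\\s*:", key), hdr, value = TRUE)
    if (!length(m)) stop("signature header missing '", key, "': ", path)
    sub(sprintf("^#\\s*%s\\s*:\\s*", key), "", m[1L])
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                          header = TRUE, stringsAsFactors = FALSE)
  Signature(receptor = grab("receptor"),
            cutoff = as.numeric(grab("cutoff")),
            probe_ids = as.character(df$probe_id),
            rho = as.numeric(df$rho),
            source_tag = grab("source"))
}

#' Write a signature file
#'
#' @param x A [Signature-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSignature <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# receptor: %s", x@receptor),
               sprintf("# cutoff: %s", format(x@cutoff, digits = 15)),
               sprintf("# source: %s", x@source_tag),
               "probe_id\trho",
               sprintf("%s\t%s", x@probe_ids,
                       format(x@rho, digits = 15, trim = TRUE))), con)
  invisible(path)
}

#' Load a published receptor signature shipped with the package
#'
#' Returns the published 35-probe-set ER, 19-probe-set ERBB2 or
#' 61-probe-set PR signature (coefficients and gene symbols as published;
#' cutoffs 0.43 / 0.35 / 0.38). Only three probe-set IDs are public
#' (`205225_at` for ESR1, `203497_at` for PPARBP, `219197_s_at` for SCUBE2
#' in the PR signature); all other probe IDs in the shipped files are
#' synthetic placeholders derived from the gene symbol, as the file names
#' indicate.
#'
#' @param receptor `"ER"`, `"ERBB2"` or `"PR"`.
#' @return A [Signature-class].
#' @examples
#' publishedSignature("ERBB2")
#' @export
publishedSignature <- function(receptor = c("ER", "ERBB2", "PR")) {
  receptor <- match.arg(receptor)
  path <- system.file("extdata",
                      sprintf("signature_%s_synthetic_probe_ids.tsv",
                              receptor),
                      package = "ReceptorSig", mustWork = TRUE)
  readSignature(path)
}

#' Published per-dataset confusion matrices
#'
#' The published cross-tabulations of predictor calls against clinical
#' status for every receptor/dataset/predictor combination (GEO cohorts
#' GSE3494, GSE2034, GSE7390, GSE2603, GSE20271, GSE20194, GSE16446,
#' GSE9195), as shipped in `inst/extdata`. Rows are keyed by receptor,
#' dataset accession, role (training/validation) and predictor
#' (signature / best_probe).
#'
#' @return A data.frame with columns `receptor`, `dataset`, `role`,
#'   `predictor`, `tn`, `fn`, `fp`, `tp`.
#' @examples
#' head(publishedConfusionTables())
#' @export
publishedConfusionTables <- function() {
  path <- system.file("extdata", "published_confusion_tables.tsv",
                      package = "ReceptorSig", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}
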