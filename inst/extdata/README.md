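# Packaged fixtures

- `signature_{ER,ERBB2,PR}_synthetic_probe_ids.tsv` — the published
  35 / 19 / 61 probe-set receptor signatures (signed Spearman coefficients
  and gene symbols as published; cutoffs 0.43 / 0.35 / 0.38). Only three
  probe-set identifiers are public (`205225_at` ESR1, `203497_at` PPARBP,
  `219197_s_at` SCUBE2-in-PR); every other probe ID in these files is a
  synthetic placeholder of the form `SYN_<SYMBOL>_<k>_at`, as the file
  names indicate. Load with `publishedSignature()`.
- `published_confusion_tables.tsv` — the published per-dataset 2x2
  cross-tabulations of predictor calls against clinical receptor status for
  the GEO cohorts (GSE3494, GSE2034, GSE7390, GSE2603, GSE20271, GSE20194,
  GSE16446, GSE9195). Columns `tn`, `fn`, `fp`, `tp` follow the
  predictor-rows-by-clinical-columns layout. Load with
  `publishedConfusionTables()`.
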