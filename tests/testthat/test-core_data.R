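test_that("expression, clinical and signature files round-trip exactly", {
  m <- matrix(c(1.5, 2.25, -3, 4, 5.125, 6), 3, 2)
  expr <- tinyExpr(m, probes = c("A", "B", "C"), samples = c("s1", "s2"))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeExpressionMatrix(expr, f)
  back <- readExpressionMatrix(f, platform = "test")
  expect_identical(exprValues(back), exprValues(expr))
  expect_identical(probeIds(back), probeIds(expr))
  expect_identical(sampleIds(back), sampleIds(expr))

  clin <- tinyClin(c("s1", "s2", "s3"),
                   c("positive", "negative", "unknown"), "ERBB2")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeClinicalTable(clin, f2)
  back2 <- readClinicalTable(f2)
  expect_identical(status(back2), status(clin))
  expect_identical(receptor(back2), "ERBB2")

  sig <- Signature("PR", 0.38, c("x1", "x2"), c(0.44, -0.39), "roundtrip")
  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeSignature(sig, f3)
  back3 <- readSignature(f3)
  expect_identical(rho(back3), rho(sig))
  expect_identical(cutoff(back3), 0.38)
  expect_identical(receptor(back3), "PR")
})

test_that("malformed expression files fail with informative errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("probe_id\ts1\ts2", "A\t1\t2", "A\t3\t4"), f)
  expect_error(readExpressionMatrix(f), "A")

  writeLines(c("probe_id\ts1\ts2", "A\t1\t", "B\t3\t4"), f)
  expect_error(readExpressionMatrix(f), "probe 'A' / sample 's2'")

  writeLines(c("probe_id\ts1\ts2", "A\t1\tzzz", "B\t3\t4"), f)
  expect_error(readExpressionMatrix(f), "probe 'A' / sample 's2'")
})

test_that("validity catches duplicated IDs and non-finite values", {
  m <- matrix(1:4, 2, 2)
  expect_error(tinyExpr(m, probes = c("A", "A")), "duplicated probe")
  expect_error(tinyExpr(matrix(c(1, NA, 3, 4), 2)), "finite")
  expect_error(ClinicalTable(c("s1", "s1"), c("positive", "negative"), "ER"),
               "unique")
  expect_error(ClinicalTable("s1", "maybe", "ER"), "status")
  expect_error(Signature("ER", 0.5, c("a", "b"), c(0.6, 0.4)),
               "cutoff")
})

test_that("alignment keeps shared known-status samples in expression order", {
  m <- matrix(rnorm(10), 2, 5)
  expr <- tinyExpr(m, samples = c("s1", "s2", "s3", "s4", "s5"))
  clin <- tinyClin(c("s5", "s4", "s3", "s2", "s1"),
                   c("positive", "unknown", "negative", "positive",
                     "negative"))
  al <- alignSamples(expr, clin)
  expect_identical(sampleIds(al$expression), c("s1", "s2", "s3", "s5"))
  expect_identical(sampleIds(al$clinical), sampleIds(al$expression))
  expect_identical(unname(status(al$clinical)),
                   c("negative", "positive", "negative", "positive"))

  # idempotence
  al2 <- alignSamples(al$expression, al$clinical)
  expect_identical(sampleIds(al2$expression), sampleIds(al$expression))
  expect_identical(status(al2$clinical), status(al$clinical))
})

test_that("alignment rejects degenerate sample sets", {
  m <- matrix(rnorm(4), 2, 2)
  expr <- tinyExpr(m, samples = c("s1", "s2"))
  expect_error(alignSamples(expr, tinyClin(c("x1", "x2"),
                                           c("positive", "negative"))),
               "no shared samples")
  expect_error(alignSamples(expr, tinyClin(c("s1", "s2"),
                                           c("positive", "positive"))),
               "no negative samples")
  expect_error(alignSamples(expr, tinyClin(c("s1", "s2"),
                                           c("negative", "negative"))),
               "no positive samples")
})

test_that("cross-dataset deduplication removes exactly the overlap", {
  n_secondary <- 178
  n_overlap <- 34
  ids <- sprintf("MDACC_%03d", seq_len(n_secondary))
  expr <- tinyExpr(matrix(rnorm(2 * n_secondary), 2), samples = ids)
  primary <- c(ids[seq_len(n_overlap)], "OTHER_001")
  kept <- deduplicateAgainst(primary, expr)
  expect_identical(ncol(kept), 144L)
  expect_identical(sort(sampleIds(kept)),
                   sort(setdiff(ids, primary)))
  expect_identical(probeIds(kept), probeIds(expr))

  # no overlap -> unchanged; full overlap -> error
  expect_identical(sampleIds(deduplicateAgainst("ZZZ", expr)), ids)
  expect_error(deduplicateAgainst(ids, expr), "every sample")
})

test_that("published signatures load with the expected sizes and cutoffs", {
  er <- publishedSignature("ER")
  expect_length(probeIds(er), 35)
  expect_identical(cutoff(er), 0.43)
  expect_true(all(rho(er) > 0))
  expect_identical(unname(rho(er)["205225_at"]), 0.50)

  erbb2 <- publishedSignature("ERBB2")
  expect_length(probeIds(erbb2), 19)
  expect_identical(cutoff(erbb2), 0.35)
  expect_identical(sum(rho(erbb2) < 0), 4L)
  expect_identical(unname(rho(erbb2)["203497_at"]), 0.45)

  pr <- publishedSignature("PR")
  expect_length(probeIds(pr), 61)
  expect_identical(cutoff(pr), 0.38)
  expect_identical(sum(rho(pr) < 0), 29L)
  expect_identical(unname(rho(pr)["219197_s_at"]), 0.44)
})
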