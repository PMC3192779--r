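test_that("cross-tabulation counts predicted vs clinical status", {
  ids <- sprintf("s%d", 1:10)
  truth <- setNames(c(rep("positive", 6), rep("negative", 4)), ids)
  cm <- confusionMatrix(truth, tinyClin(ids, truth))
  expect_identical(c(cm@tp, cm@tn, cm@fp, cm@fn), c(6, 4, 0, 0))

  all_pos <- setNames(rep("positive", 8), sprintf("s%d", 1:8))
  truth8 <- setNames(rep(c("positive", "negative"), 4), sprintf("s%d", 1:8))
  cm2 <- confusionMatrix(all_pos, truth8)
  expect_identical(c(cm2@tp, cm2@fp, cm2@tn, cm2@fn), c(4, 4, 0, 0))

  # swapping the roles of prediction and truth transposes the matrix
  a <- setNames(c("positive", "positive", "negative", "negative",
                  "positive"), sprintf("s%d", 1:5))
  b <- setNames(c("positive", "negative", "positive", "negative",
                  "negative"), sprintf("s%d", 1:5))
  ab <- confusionMatrix(a, b)
  ba <- confusionMatrix(b, a)
  expect_identical(c(ab@tp, ab@tn), c(ba@tp, ba@tn))
  expect_identical(ab@fp, ba@fn)
  expect_identical(ab@fn, ba@fp)

  expect_error(confusionMatrix(a, b[c(1:4, 4)]), "identical sample sets")
})

test_that("metrics reproduce the published validation-set values", {
  # GSE2034 ER validation row
  rep1 <- evaluationMetrics(ConfusionMatrix(tp = 183, fp = 9, tn = 68,
                                            fn = 26))
  expect_equal(round(rep1@accuracy, 2), 87.76)
  expect_equal(round(rep1@sensitivity, 2), 87.56)
  expect_equal(round(rep1@specificity, 2), 88.31)
  expect_equal(round(rep1@ppv, 2), 95.31)
  expect_equal(round(rep1@npv, 2), 72.34)

  # GSE2603 ERBB2 training row
  rep2 <- evaluationMetrics(ConfusionMatrix(tp = 7, fp = 4, tn = 75,
                                            fn = 2))
  expect_equal(round(rep2@sensitivity, 2), 77.78)
  expect_equal(round(rep2@specificity, 2), 94.94)
  expect_equal(round(rep2@ppv, 2), 63.64)
  expect_equal(round(rep2@npv, 2), 97.40)

  perfect <- evaluationMetrics(ConfusionMatrix(tp = 5, fp = 0, tn = 5,
                                               fn = 0))
  for (m in c("accuracy", "sensitivity", "specificity", "ppv", "npv"))
    expect_equal(slot(perfect, m), 100)
})

test_that("zero denominators flag the metric without poisoning the rest", {
  rep <- evaluationMetrics(ConfusionMatrix(tp = 5, fp = 3, tn = 0, fn = 0))
  expect_true(is.na(rep@npv))          # no predicted negatives
  expect_equal(rep@specificity, 0)
  expect_equal(rep@sensitivity, 100)
  rep2 <- evaluationMetrics(ConfusionMatrix(tp = 0, fp = 0, tn = 4, fn = 2))
  expect_true(is.na(rep2@ppv))
  expect_equal(rep2@specificity, 100)
  expect_equal(round(rep2@accuracy, 2), 66.67)
})

test_that("two-sided Fisher p agrees with full enumeration", {
  expect_equal(fisherExactTwoSided(ConfusionMatrix(2, 0, 2, 0)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisherExactTwoSided(ConfusionMatrix(10, 10, 10, 10)), 1)

  set.seed(99)
  for (rep in 1:20) {
    cts <- as.vector(stats::rmultinom(1, sample(10:60, 1), rep(0.25, 4)))
    if (sum(cts) < 1) next
    cm <- ConfusionMatrix(cts[1], cts[2], cts[3], cts[4])
    expect_equal(fisherExactTwoSided(cm),
                 oracleFisher(cm@tn, cm@fn, cm@fp, cm@tp),
                 tolerance = 1e-10)
    # transposition and simultaneous row+column swap symmetry
    expect_equal(fisherExactTwoSided(cm),
                 fisherExactTwoSided(ConfusionMatrix(
                   tp = cm@tp, fp = cm@fn, tn = cm@tn, fn = cm@fp)),
                 tolerance = 1e-12)
    expect_equal(fisherExactTwoSided(cm),
                 fisherExactTwoSided(ConfusionMatrix(
                   tp = cm@tn, fp = cm@fn, tn = cm@tp, fn = cm@fp)),
                 tolerance = 1e-12)
  }
})

test_that("cross-dataset t-interval reproduces closed forms", {
  ci <- ciMeanT(c(77.78, 59.09, 76.27))
  expect_equal(round(ci@lower, 2), 45.26)
  expect_equal(round(ci@upper, 2), 96.84)
  expect_identical(ci@n_datasets, 3L)

  # matches t.test's interval on arbitrary data
  set.seed(1)
  v <- rnorm(8, 80, 5)
  ci2 <- ciMeanT(v, level = 0.9)
  ref <- t.test(v, conf.level = 0.9)$conf.int
  expect_equal(c(ci2@lower, ci2@upper), as.vector(ref), tolerance = 1e-12)

  zero <- ciMeanT(c(80, 80, 80))
  expect_equal(zero@lower, 80)
  expect_equal(zero@upper, 80)
  expect_error(ciMeanT(50), "at least 2")
})

test_that("method comparison t-test is paired by dataset", {
  a <- c(70, 75, 80, 85, 90)
  expect_true(compareMethodsTtest(a, a)$degenerate)

  set.seed(2)
  b <- a + 10 + rnorm(5, sd = 0.5)
  paired <- compareMethodsTtest(b, a, paired = TRUE)
  expect_false(paired$degenerate)
  expect_lt(paired$p_value, 0.05)
  expect_equal(paired$p_value,
               t.test(b, a, paired = TRUE)$p.value, tolerance = 1e-12)

  unpaired <- compareMethodsTtest(b, a, paired = FALSE)
  expect_gt(unpaired$p_value, paired$p_value)
})

test_that("reports serialize to JSON and back", {
  rep <- evaluationMetrics(ConfusionMatrix(tp = 61, fp = 13, tn = 54,
                                           fn = 16))
  f <- withr::local_tempfile(fileext = ".json")
  reportAsList(rep, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$accuracy, rep@accuracy, tolerance = 1e-9)
  expect_equal(back$confusion$tp, 61)
  expect_equal(back$fisher_p, rep@fisher_p, tolerance = 1e-12)
})
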