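test_that("probe-status Spearman correlation matches hand-computed values", {
  expr <- tinyExpr(matrix(c(1, 2, 3, 4,
                            4, 3, 2, 1,
                            5, 5, 5, 5), 3, 4, byrow = TRUE),
                   probes = c("up", "down", "flat"))
  ct <- spearmanVsStatus(expr, c(0, 0, 1, 1))
  expect_equal(unname(rho(ct)["up"]), 2 / sqrt(5), tolerance = 1e-12)
  expect_equal(unname(rho(ct)["down"]), -2 / sqrt(5), tolerance = 1e-12)
  expect_identical(ct@excluded_probes, "flat")
  expect_setequal(c(probeIds(ct), ct@excluded_probes), probeIds(expr))
})

test_that("correlations agree with a brute-force mid-rank oracle", {
  set.seed(42)
  for (rep in 1:5) {
    n <- sample(6:15, 1)
    X <- matrix(rnorm(12 * n), 12)
    X[3, ] <- round(X[3, ])          # force ties
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    ct <- spearmanVsStatus(tinyExpr(X), y)
    for (i in seq_len(nrow(X))) {
      if (length(unique(X[i, ])) == 1L) next
      expect_equal(unname(rho(ct)[i]), oracleSpearman(X[i, ], y),
                   tolerance = 1e-12)
    }
    # label-flip antisymmetry
    ct_flip <- spearmanVsStatus(tinyExpr(X), 1 - y)
    expect_equal(unname(rho(ct_flip)), -unname(rho(ct)), tolerance = 1e-12)
  }
})

test_that("signature selection thresholds on |rho| with an inclusive bound", {
  ct <- new("CorrelationTable",
            entries = c(a = 0.50, b = 0.44, c = -0.46, d = 0.20),
            n_samples = 10L, excluded_probes = character())
  expect_setequal(probeIds(selectSignature(ct, 0.45, "ER")), c("a", "c"))
  expect_setequal(probeIds(selectSignature(ct, 0.19, "ER")),
                  c("a", "b", "c", "d"))
  expect_identical(unname(rho(selectSignature(ct, 0.45, "ER"))["c"]), -0.46)
  expect_error(selectSignature(ct, 0.9, "ER"), "0.9")
})

test_that("selections are nested across any increasing cutoff grid", {
  set.seed(7)
  ct <- new("CorrelationTable",
            entries = setNames(runif(50, -1, 1), sprintf("g%02d", 1:50)),
            n_samples = 20L, excluded_probes = character())
  grid <- seq(0.05, 0.60, by = 0.05)
  sigs <- lapply(grid, function(ci) probeIds(selectSignature(ct, ci, "PR")))
  for (i in seq_along(grid)[-1]) {
    expect_true(all(sigs[[i]] %in% sigs[[i - 1]]))
    expect_lte(length(sigs[[i]]), length(sigs[[i - 1]]))
  }
})

test_that("best probe maximizes signed rho with lexicographic tie-break", {
  ct <- new("CorrelationTable", entries = c(a = 0.50, b = 0.45),
            n_samples = 10L, excluded_probes = character())
  expect_identical(bestProbe(ct), "a")
  ct2 <- new("CorrelationTable", entries = c(b = 0.4, a = 0.4, c = -0.9),
             n_samples = 10L, excluded_probes = character())
  expect_identical(bestProbe(ct2), "a")   # |rho| is not used
})

test_that("sweep records one row per cutoff, keeping empty selections", {
  sim <- simulateReceptorData(syntheticConfig(
    n_samples = 60, n_pos_markers = 4, n_neg_markers = 2,
    n_background = 30, delta = 3, label_noise = 0, seed = 11))
  al <- alignSamples(sim$expression, sim$clinical)
  grid <- c(0.30, 0.50, 0.98)   # 0.98 retains nothing
  sw <- sweepCutoffs(al$expression, al$clinical, grid, seed = 1)
  expect_identical(nrow(sw), 3L)
  expect_identical(sw$cutoff, grid)
  expect_true(all(diff(sw$n_probes) <= 0))
  expect_identical(sw$n_probes[3], 0L)
  expect_true(is.na(sw$sum_sens_spec[3]))
  expect_equal(sw$sum_sens_spec[1:2],
               sw$sensitivity[1:2] + sw$specificity[1:2])
  # single-cutoff grid
  expect_identical(nrow(sweepCutoffs(al$expression, al$clinical, 0.5,
                                     seed = 1)), 1L)
})

test_that("optimal cutoff is the argmax, ties broken to the larger cutoff", {
  sw <- data.frame(cutoff = c(0.42, 0.43, 0.44), n_probes = c(50L, 35L, 20L),
                   sensitivity = 0, specificity = 0,
                   sum_sens_spec = c(170.1, 181.3, 175.0))
  expect_identical(chooseOptimalCutoff(sw), 0.43)

  tie <- data.frame(cutoff = c(0.38, 0.39, 0.40), n_probes = c(10L, 7L, 5L),
                    sensitivity = 0, specificity = 0,
                    sum_sens_spec = c(180, 174, 180))
  expect_identical(chooseOptimalCutoff(tie), 0.40)
})

test_that("a flat primary sweep defers to the secondary or errors", {
  flat <- data.frame(cutoff = seq(0.34, 0.39, 0.01), n_probes = 30:25,
                     sensitivity = 0, specificity = 0,
                     sum_sens_spec = rep(172.7, 6))
  expect_error(chooseOptimalCutoff(flat), "second training set")
  peaked <- data.frame(cutoff = seq(0.34, 0.39, 0.01), n_probes = 30:25,
                       sensitivity = 0, specificity = 0,
                       sum_sens_spec = c(150, 153.4, 150, 149, 148, 147))
  expect_equal(chooseOptimalCutoff(flat, peaked), 0.35)
})

test_that("sweep optimum retains exactly the planted markers", {
  # markers at |rho| ~ 0.75, background near 0: every cutoff between the two
  # groups keeps exactly the planted set, and no other cutoff scores higher
  sim <- simulateReceptorData(syntheticConfig(
    n_samples = 120, prevalence = 0.5, n_pos_markers = 5, n_neg_markers = 3,
    n_background = 150, delta = 3, label_noise = 0.1, seed = 5))
  al <- alignSamples(sim$expression, sim$clinical)
  ct <- spearmanVsStatus(al$expression, al$clinical)
  grid <- seq(0.30, 0.60, by = 0.05)
  sw <- sweepCutoffs(al$expression, al$clinical, grid, seed = 1, corr = ct)
  best <- chooseOptimalCutoff(sw, flat_tol = 0)
  got <- probeIds(selectSignature(ct, best, "ER"))
  planted <- probeIds(sim$truth$signature)
  expect_setequal(got, planted)
  # exhaustive check: no grid cutoff beats the chosen one
  ok <- sw$n_probes > 0
  expect_true(all(sw$sum_sens_spec[ok] <=
                  sw$sum_sens_spec[sw$cutoff == best] + 1e-9))
})
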