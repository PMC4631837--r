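test_that("fitted hierarchies expose the layered input dimensionalities", {
  set.seed(51)
  F <- matrix(runif(60 * 10, -1, 1), 60, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  ph <- plantHierarchy(seed = 52)
  ex <- simulateRatings(ph, F, noiseSd = 0, raterBiasSd = 0, seed = 53)
  fit <- fitHierarchy(F, ratingsTable(ex), recoveryFitConfig(54))
  dims <- vapply(layerModels(fit), function(m) length(inputNames(m)),
                 integer(1))
  expect_equal(unname(dims), c(10L, 10L, 10L, 13L, 13L, 13L, 13L, 17L))
  expect_identical(fit@provenance, "fitted")
  # acyclicity is enforced structurally
  expect_true(validObject(fit))
})

test_that("judgment fits are independent of the like-dislike column", {
  set.seed(55)
  F <- matrix(runif(60 * 10, -1, 1), 60, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  ph <- plantHierarchy(seed = 56)
  R <- ratingsTable(simulateRatings(ph, F, noiseSd = 1, raterBiasSd = 0,
                                    seed = 57))
  fit1 <- fitHierarchy(F, R, recoveryFitConfig(58))
  R2 <- R; R2[, "Q"] <- rev(R2[, "Q"])
  fit2 <- fitHierarchy(F, R2, recoveryFitConfig(58))
  for (p in c(paste0("G", 1:3), paste0("T", 1:4))) {
    expect_equal(layerTerms(layerModels(fit1)[[p]]),
                 layerTerms(layerModels(fit2)[[p]]))
  }
  expect_error(fitHierarchy(F, R[, 1:5], recoveryFitConfig(1)),
               "columns")
})

test_that("a noise-free planted hierarchy is recovered through the reduced form", {
  set.seed(61)
  F <- matrix(runif(150 * 10, -1, 1), 150, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  ph <- plantHierarchy(seed = 62)
  ex <- simulateRatings(ph, F, noiseSd = 0, raterBiasSd = 0, seed = 63)
  expect_equal(ratingsTable(ex), predictCascade(ph, F),
               ignore_attr = TRUE, tolerance = 1e-12)
  fit <- fitHierarchy(F, ratingsTable(ex),
                      recoveryFitConfig(64, minGain = 1e-9))
  expect_lt(reducedFormError(ph, fit), 1e-6)
})

test_that("reduced forms compose lower layers and reject non-linear models", {
  h <- tinyHierarchy()
  red <- reducedFormCoefficients(h)
  # Q = 6 f8 + 0.3 G2 + 0.6 T1; G2 = -5 f2 + 1; T1 = 8 f4 + 0.5 G1
  expect_equal(red["Q", "f8"], 6)
  expect_equal(red["Q", "f2"], 0.3 * -5)
  expect_equal(red["Q", "f4"], 0.6 * 8)
  expect_equal(red["Q", "f1"], 0.6 * 0.5 * 10)
  expect_equal(red["Q", "(intercept)"], 2 + 0.3 * 1 + 0.6 * 0.5 * 0)
  expect_error(reducedFormCoefficients(referenceModel()), "linear")
})

test_that("hierarchy evaluation tabulates the metrics per property", {
  set.seed(65)
  F <- matrix(runif(40 * 10, -1, 1), 40, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  ph <- plantHierarchy(seed = 66)
  R <- ratingsTable(simulateRatings(ph, F, noiseSd = 0, raterBiasSd = 0,
                                    seed = 67))
  ev <- evaluateHierarchy(ph, F, R)
  expect_equal(nrow(ev), 8)
  expect_equal(ev$property, c("G1", "G2", "G3", "T1", "T2", "T3", "T4", "Q"))
  expect_true(all(ev$r_squared > 0.999))
  expect_true(all(ev$rmse < 1e-6))
})
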