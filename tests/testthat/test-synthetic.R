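test_that("texture generation is deterministic and honours its parameters", {
  a <- generateTexture("filtered_noise", 64, correlation = 2, seed = 7)
  b <- generateTexture("filtered_noise", 64, correlation = 2, seed = 7)
  expect_identical(pixels(a), pixels(b))
  expect_false(identical(pixels(a),
                         pixels(generateTexture("filtered_noise", 64,
                                                correlation = 2, seed = 8))))
  flat <- generateTexture("grating", 64, amplitude = 0)
  expect_true(all(pixels(flat) == 0.5))
  pw <- generateTexture("color_patchwork", 64, block = 8, seed = 3)
  expect_equal(colorspace(pw), "RGB")
  expect_error(generateTexture("grating", 16), "size")
  expect_error(generateTexture("grating", 64, amplitude = 2), "amplitude")
})

test_that("the simulated experiment produces 100 clipped raw ratings per texture", {
  set.seed(71)
  F <- matrix(runif(5 * 10, -1, 1), 5, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  h <- tinyHierarchy()
  ex <- simulateRatings(h, F, noiseSd = 5, raterBiasSd = 2, seed = 72)
  expect_equal(dim(rawRatings(ex)), c(5L, 8L, 20L, 5L))
  expect_equal(prod(dim(rawRatings(ex))[3:4]), 100)
  expect_true(all(abs(rawRatings(ex)) <= 100))
  expect_equal(ratingsTable(ex),
               apply(rawRatings(ex), c(1, 2), mean), ignore_attr = TRUE)
})

test_that("noise-free ratings equal the cascade, and clipping caps extremes", {
  set.seed(73)
  F <- matrix(runif(4 * 10, -1, 1), 4, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  h0 <- tinyHierarchy()
  ex0 <- simulateRatings(h0, F, noiseSd = 0, raterBiasSd = 0, seed = 74)
  expect_equal(ratingsTable(ex0), predictCascade(h0, F),
               ignore_attr = TRUE, tolerance = 1e-12)
  # plant a warm-cold value beyond the scale: the average saturates at 100
  h150 <- tinyHierarchy(interceptG1 = 150)
  ex150 <- simulateRatings(h150, F * 0, noiseSd = 0, raterBiasSd = 0,
                           seed = 75)
  expect_equal(unname(ratingsTable(ex150)[, "G1"]), rep(100, 4))
})

test_that("averaging concentrates around truth at the expected rate", {
  set.seed(76)
  F <- matrix(runif(40 * 10, -1, 1), 40, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  h <- tinyHierarchy()
  ex <- simulateRatings(h, F, noiseSd = 5, raterBiasSd = 0, seed = 77)
  dev <- ratingsTable(ex) - predictCascade(h, F)
  # sd of the mean of 100 ratings with sigma = 5 is 0.5
  expect_lt(sd(dev), 0.75)
  expect_gt(sd(dev), 0.3)
})

test_that("the benchmark dataset is reproducible and structurally complete", {
  suppressWarnings({
    b1 <- makeBenchmarkDataset(nTextures = 20, seed = 9, size = 64)
    b2 <- makeBenchmarkDataset(nTextures = 20, seed = 9, size = 64)
  })
  expect_identical(b1$ratings, b2$ratings)
  expect_identical(b1$features, b2$features)
  expect_equal(dim(b1$features), c(20L, 109L))
  expect_equal(dim(b1$ratings), c(20L, 8L))
  expect_length(selectedFeatures(b1$selection), 10)
  expect_equal(colnames(b1$selected), paste0("f", 1:10))
  expect_identical(b1$planted@provenance, "planted")
  # retained features are mutually distinguishable by construction
  cc <- cor(b1$selected); diag(cc) <- 0
  expect_lt(max(abs(cc)), 0.95 + 1e-12)
  expect_error(makeBenchmarkDataset(nTextures = 10), "nTextures")
})
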