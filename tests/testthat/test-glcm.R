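test_that("GLCM of simple patterns matches hand enumeration", {
  g <- matrix(3L, 4, 4)  # constant image in bin 3
  P <- computeGLCM(g, distance = 2, angle = 0, levels = 8)
  expect_equal(P[4, 4], 1)
  expect_equal(sum(P), 1)

  # two-level block pattern: all 8 horizontal pairs at d=2 cross the levels
  blk <- matrix(c(0, 0, 1, 1,
                  0, 0, 1, 1,
                  1, 1, 0, 0,
                  1, 1, 0, 0), 4, 4, byrow = TRUE)
  P2 <- computeGLCM(blk, distance = 2, angle = 0, levels = 2,
                    symmetric = TRUE)
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  expect_error(computeGLCM(blk, 10, 0, levels = 2), "no valid pixel pair")
})

test_that("Haralick statistics follow their closed forms and conventions", {
  # single-cell matrix: perfectly predictable constant texture
  P <- matrix(0, 8, 8); P[4, 4] <- 1
  expect_equal(glcmStats(P),
               c(contrast = 0, correlation = 1, energy = 1, homogeneity = 1))
  # antidiagonal two-level matrix, hand-evaluated
  P2 <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(glcmStats(P2),
               c(contrast = 1, correlation = -1, energy = 0.5,
                 homogeneity = 0.5))
  expect_error(glcmStats(matrix(0.5, 2, 2)), "normalized")
})

test_that("fast GLCM agrees exactly with the brute-force pair oracle", {
  set.seed(11)
  for (case in 1:100) {
    gray <- matrix(sample(0:1, 256, replace = TRUE), 16, 16)
    d <- sample(c(1L, 2L, 4L), 1)
    a <- sample(c(0, 45, 90, 135), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    P <- computeGLCM(gray, d, a, levels = 2, symmetric = sym)
    expect_identical(P, bruteGLCM(gray, d, a, 2, sym))
    expect_lt(abs(sum(P) - 1), 1e-9)
    s <- glcmStats(P)
    expect_gt(s["energy"], 0); expect_lte(s["energy"], 1)
    expect_gt(s["homogeneity"], 0); expect_lte(s["homogeneity"], 1)
  }
})

test_that("the default grid yields 16 matrices and 64 ordered features", {
  set.seed(2)
  img <- TextureImage(matrix(runif(64 * 64), 64, 64))
  block <- glcmFeatureBlock(img)
  expect_length(block, 64)
  expect_false(anyDuplicated(names(block)) > 0)
  # ordering: d ascending, then angle, then the fixed statistic order
  expect_equal(names(block)[1:4],
               paste0("glcm.d2.t0.",
                      c("contrast", "correlation", "energy", "homogeneity")))
  expect_equal(names(block)[61:64],
               paste0("glcm.d8.t135.",
                      c("contrast", "correlation", "energy", "homogeneity")))
  # a single-config grid reduces to glcmStats of that configuration
  one <- glcmFeatureBlock(img, distances = 4, angles = 90)
  gray <- toGrayQuantized(img, 8)
  expect_equal(unname(one),
               unname(glcmStats(computeGLCM(gray, 4, 90, levels = 8))))
  # constant image: zero contrast everywhere
  const <- glcmFeatureBlock(TextureImage(matrix(0.4, 64, 64)))
  expect_equal(unname(const[grep("contrast", names(const))]), rep(0, 16))
})
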