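test_that("db4 sub-band signatures reproduce reference transform values", {
  # deterministic rational-valued fixture; expected values computed with an
  # independent reference implementation of the same transform
  # (2-D DWT, db4, half-sample symmetric extension) and frozen
  m <- outer(1:16, 1:16, function(i, j) ((7 * i + 13 * j) %% 29) / 29)
  v <- waveletFeatures(m, levels = 2)
  expected <- c(
    0.224231045375764, 0.259037365366175, 6.20974124139165,
    0.308509684626098, 0.37954905886194, 6.04702284288825,
    0.200465344722203, 0.268940149945539, 5.65640365492545,
    0.162464549818441, 0.215998516214215, 4.96321324088119,
    0.210579482926833, 0.238698104742061, 5.73032736066579,
    0.173720070691192, 0.243899419469308, 4.67834268331857)
  expect_equal(unname(v), expected, tolerance = 1e-12)
})

test_that("the default decomposition yields 36 named features, zero on constants", {
  v <- waveletFeatures(matrix(0.5, 64, 64))
  expect_length(v, 36)
  expect_false(anyDuplicated(names(v)) > 0)
  expect_equal(names(v)[1:3], c("wav.lev1.h.L1", "wav.lev1.h.L2",
                                "wav.lev1.h.ent"))
  expect_true(all(v == 0))
  expect_error(waveletFeatures(matrix(0.5, 8, 8), levels = 4), "too small")
})

test_that("sub-band entropy matches the closed form for sparse coefficient sets", {
  # haar on 2x2 blocks: the level-1 'h' sub-band has one coefficient per block
  one <- matrix(0, 4, 4); one[1, 1:2] <- 1   # a single active block
  v1 <- waveletFeatures(one, levels = 1, wavelet = "haar")
  expect_equal(unname(v1["wav.lev1.h.ent"]), 0)
  two <- matrix(0, 4, 4); two[1, ] <- 1       # two equal-magnitude coefficients
  v2 <- waveletFeatures(two, levels = 1, wavelet = "haar")
  expect_equal(unname(v2["wav.lev1.h.ent"]), 1)
})

test_that("entropy is bounded by log2 of the sub-band size", {
  set.seed(21)
  for (case in 1:10) {
    g <- matrix(runif(32 * 32), 32, 32)
    v <- waveletFeatures(g, levels = 3)
    for (lev in 1:3) {
      n <- (32 / 2^lev + 3)^2  # loose upper bound on coefficients per band
      ents <- v[grep(sprintf("lev%d\\..\\.ent", lev), names(v))]
      expect_true(all(ents >= 0 & ents <= log2(n)))
    }
  }
})

test_that("feature families are stable under wrapped translation of a periodic texture", {
  # 6 integer cycles make the texture wrap-periodic; translating by 16 (a
  # multiple of 2^levels) keeps the decimation grids of all wavelet levels
  # aligned while moving the phase by 1.5 cycles
  base <- pixels(generateTexture("grating", 64, frequency = 6,
                                 orientation = 0, amplitude = 0.8))
  shifted <- base[, c(17:64, 1:16)]
  expect_false(identical(base, shifted))
  fb <- extractFeatures(TextureImage(base))
  fs <- extractFeatures(TextureImage(shifted))
  idx <- grep("glcm\\..*contrast|tamura|wav\\..*L[12]", names(fb))
  relDiff <- abs(fs[idx] - fb[idx]) / pmax(abs(fb[idx]), 0.05)
  expect_lt(max(relDiff), 0.05)
})
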