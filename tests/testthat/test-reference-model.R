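# The audit table below was typed independently of the reference-model
# source, directly from the printed equations, and drives the transcription
# audit at random inputs.
auditEquations <- list(
  G1 = function(f, G, T)
    0.03 * f[1] + 598.16 * f[3] - 234.19 * f[5] - 348.67 * f[7] +
      189.82 * f[9] - 304.29 * f[10] + 22.17,
  G2 = function(f, G, T) -1.31e-13 * f[10] - 1.73,
  G3 = function(f, G, T)
    0.29 * f[1] + 83.14 * f[7] - 53.82 * f[5] - 214.60 * f[9] -
      0.34 * f[1] * f[7] + 216.71 * f[9]^2 + 19.22,
  T1 = function(f, G, T)
    0.03 * f[1] + 119.55 * f[6] - 106.46 * f[7] + 18.21 * f[9] -
      51.51 * f[10] + 0.76 * G[3] + 2.86,
  T2 = function(f, G, T)
    0.09 * f[1] + 691.81 * f[3] - 737.98 * f[4] - 609.32 * f[6] +
      683.64 * f[7] - 66.11 * f[8] + 0.33 * G[3] - 9.60,
  T3 = function(f, G, T)
    1135.64 * f[2] - 1123.31 * f[3] - 582.81 * f[4] + 571.40 * f[7] -
      364.15 * f[8] + 376.91 * f[9] - 14.60,
  T4 = function(f, G, T)
    185.17 * f[2] + 68.26 * f[3] - 215.02 * f[4] - 99.79 * f[8] +
      129.36 * f[9] - 0.15 * G[1] + 24.37,
  Q = function(f, G, T)
    123.09 * f[2] - 144.83 * f[3] - 113.49 * f[8] - 148.05 * f[9] +
      0.64 * T[1] + 0.12 * T[3] + 1.14)

test_that("every transcribed equation matches the audit table at random inputs", {
  h <- referenceModel()
  set.seed(41)
  for (case in 1:5) {
    f <- runif(10, -1, 1); G <- runif(3, -20, 20); T_ <- runif(4, -20, 20)
    predG <- predictCascade(h, f)
    for (p in c("G1", "G2", "G3"))
      expect_equal(unname(predG[1, p]), auditEquations[[p]](f, G, T_),
                   tolerance = 1e-12)
    predT <- predictCascade(h, f, overrides = list(G = G))
    for (p in c("T1", "T2", "T3", "T4"))
      expect_equal(unname(predT[1, p]), auditEquations[[p]](f, G, T_),
                   tolerance = 1e-12)
    predQ <- predictCascade(h, f, overrides = list(G = G, T = T_))
    expect_equal(unname(predQ[1, "Q"]), auditEquations$Q(f, G, T_),
                 tolerance = 1e-12)
  }
})

test_that("zero features expose the printed intercepts and cascade arithmetic", {
  h <- referenceModel()
  out <- predictCascade(h, rep(0, 10))
  expect_equal(unname(out[1, c("G1", "G2", "G3")]), c(22.17, -1.73, 19.22))
  t1 <- 0.76 * 19.22 + 2.86
  expect_equal(unname(out[1, "T1"]), t1)
  expect_equal(unname(out[1, "Q"]), 0.64 * t1 + 0.12 * (-14.60) + 1.14)
  # observed dark-light of zero leaves only the intercept in T1
  ov <- predictCascade(h, rep(0, 10), overrides = list(G = c(0, 0, 0)))
  expect_equal(unname(ov[1, "T1"]), 2.86)
})

test_that("basic complexities of the printed models match their term counts", {
  h <- referenceModel()
  basics <- vapply(layerModels(h),
                   function(m) unname(modelComplexity(m)["basic"]),
                   numeric(1))
  expect_equal(unname(basics), c(6, 1, 6, 6, 7, 6, 6, 6))
  expect_equal(names(basics), c("G1", "G2", "G3", "T1", "T2", "T3", "T4", "Q"))
})

test_that("overriding both layers makes Q independent of the lower equations", {
  h <- referenceModel()
  set.seed(42)
  f <- runif(10, -1, 1)
  G <- c(5, -3, 8); T_ <- c(1, 2, 3, 4)
  q1 <- predictCascade(h, f, overrides = list(G = G, T = T_))[1, "Q"]
  # damaging the affective equations must not change the overridden cascade
  h2 <- h
  h2@affective <- lapply(h2@affective, function(m) { m@intercept <- 999; m })
  q2 <- predictCascade(h2, f, overrides = list(G = G, T = T_))[1, "Q"]
  expect_equal(q1, q2)
  ov <- attr(predictCascade(h, f, overrides = list(G = G, T = T_)),
             "overridden")
  expect_setequal(ov, c(paste0("G", 1:3), paste0("T", 1:4)))
})

test_that("cascade predictions with self-overrides reproduce the pure cascade", {
  h <- referenceModel()
  set.seed(43)
  F <- matrix(runif(30, -1, 1), 3, 10)
  pure <- predictCascade(h, F)
  self <- predictCascade(h, F,
                         overrides = list(G = pure[, paste0("G", 1:3)],
                                          T = pure[, paste0("T", 1:4)]))
  expect_equal(unname(self[, "Q"]), unname(pure[, "Q"]), tolerance = 1e-12)
})

test_that("hierarchy JSON serialization round-trips at full precision", {
  h <- referenceModel()
  path <- withr::local_tempfile(fileext = ".json")
  writeHierarchyJSON(h, path)
  back <- readHierarchyJSON(path)
  expect_equal(back@provenance, "reference")
  for (p in names(layerModels(h))) {
    m1 <- layerModels(h)[[p]]; m2 <- layerModels(back)[[p]]
    expect_identical(m1@terms$coefficient, m2@terms$coefficient)
    expect_identical(m1@intercept, m2@intercept)
    expect_identical(m1@inputNames, m2@inputNames)
  }
  set.seed(44)
  f <- runif(10, -1, 1)
  expect_equal(predictCascade(back, f), predictCascade(h, f))
  # a fitted hierarchy with scaling metadata also survives
  b <- tinyHierarchy()
  b@scaling <- list(min = stats::setNames(runif(10), paste0("f", 1:10)),
                    max = stats::setNames(runif(10) + 2, paste0("f", 1:10)),
                    lo = -1, hi = 1)
  path2 <- withr::local_tempfile(fileext = ".json")
  writeHierarchyJSON(b, path2)
  back2 <- readHierarchyJSON(path2)
  expect_equal(featureScaling(back2)$min, b@scaling$min)
})
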