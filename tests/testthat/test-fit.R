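test_that("the term library enumerates variables, squares, products and transforms", {
  expect_equal(nrow(buildTermLibrary(c("a", "b"), squares = FALSE,
                                     products = FALSE)), 2)
  expect_equal(nrow(buildTermLibrary(c("a", "b"))), 5)  # 2 + 2 + 1
  expect_equal(nrow(buildTermLibrary(paste0("f", 1:10))), 65)  # 10 + 10 + 45
  lib <- buildTermLibrary(c("a", "b"), transforms = c("sin", "log"))
  expect_equal(sum(lib$kind == "unary"), 4)
  expect_error(buildTermLibrary(c("a", "b"), transforms = "cube"),
               "unknown transform")
  expect_error(buildTermLibrary(character()), "non-empty")
})

test_that("a noiseless linear response is recovered exactly", {
  set.seed(1)
  X <- matrix(runif(300, -1, 1), 100, 3,
              dimnames = list(NULL, paste0("x", 1:3)))
  m <- fitLayerModel(X, 2 * X[, 1] - 3, fitConfig(seed = 2))
  expect_equal(nrow(layerTerms(m)), 1)
  expect_equal(layerTerms(m)$input1, "x1")
  expect_equal(layerTerms(m)$coefficient, 2, tolerance = 1e-6)
  expect_equal(intercept(m), -3, tolerance = 1e-6)
  expect_equal(attr(m, "fit")$trainR2, 1, tolerance = 1e-9)
})

test_that("a planted interaction model is recovered from the product library", {
  set.seed(3)
  X <- matrix(runif(300, -1, 1), 100, 3,
              dimnames = list(NULL, paste0("x", 1:3)))
  y <- 1.5 * X[, 1] * X[, 2] + 0.5 * X[, 3]
  m <- fitLayerModel(X, y, fitConfig(seed = 4))
  tt <- layerTerms(m)
  expect_setequal(vapply(seq_len(nrow(tt)), function(i)
    paste(tt$kind[i], tt$input1[i], tt$input2[i]), character(1)),
    c("product x1 x2", "variable x3 NA"))
  expect_equal(sort(tt$coefficient), c(0.5, 1.5), tolerance = 1e-3)
})

test_that("pure-noise responses stay at the intercept-only model", {
  for (s in 1:5) {
    set.seed(s)
    X <- matrix(runif(300, -1, 1), 100, 3,
                dimnames = list(NULL, paste0("x", 1:3)))
    y <- rnorm(100)
    m <- fitLayerModel(X, y, fitConfig(seed = s + 100))
    expect_equal(nrow(layerTerms(m)), 0)
    expect_equal(intercept(m), mean(y), tolerance = 0.2)
  }
})

test_that("evaluation metrics follow their definitions", {
  expect_equal(evaluateModel(c(1, 2, 3), c(1, 2, 3)),
               c(r_squared = 1, pearson_r = 1, rmse = 0))
  obs <- c(1, 2, 3)
  expect_equal(unname(evaluateModel(rep(2, 3), obs)["r_squared"]), 0)
  ev <- evaluateModel(c(1, 2, 4), obs)
  expect_equal(unname(ev["r_squared"]), 1 - 1 / 2)      # SSres 1, SStot 2
  expect_equal(unname(ev["rmse"]), sqrt(1 / 3))
  # hand Pearson: covariance over product of sds
  p <- c(1, 2, 4)
  r <- sum((p - mean(p)) * (obs - mean(obs))) /
    sqrt(sum((p - mean(p))^2) * sum((obs - mean(obs))^2))
  expect_equal(unname(ev["pearson_r"]), r)
  const <- evaluateModel(c(1, 2, 3), c(5, 5, 5))
  expect_true(is.na(const["r_squared"]) && is.na(const["pearson_r"]))
  expect_equal(unname(const["rmse"]), sqrt(mean(c(16, 9, 4))))
  expect_error(evaluateModel(1:3, 1:4), "equal-length")
})

test_that("complexity counts terms and weights the expression tree", {
  h <- referenceModel()
  expect_equal(unname(modelComplexity(layerModels(h)$Q)["basic"]), 6)
  expect_equal(unname(modelComplexity(layerModels(h)$T2)["basic"]), 7)
  empty <- new("LayerModel", target = "y",
               terms = layerTerms(layerModels(h)$Q)[0, ],
               intercept = 1, inputNames = "x")
  expect_equal(unname(modelComplexity(empty)["basic"]), 0)
  # the dark-light model carries the only non-linear terms (product, square)
  cx <- modelComplexity(layerModels(h)$G3)
  expect_gt(cx["enhanced"], modelComplexity(layerModels(h)$G1)["enhanced"])
})

test_that("degenerate fitting inputs are refused", {
  X <- matrix(runif(12), 6, 2, dimnames = list(NULL, c("a", "b")))
  expect_error(fitLayerModel(X, rnorm(6), fitConfig(folds = 5)),
               "2 samples per fold")
  expect_error(fitLayerModel(X, c(1, 2, NA, 4, 5, 6), fitConfig(folds = 2)),
               "finite")
})
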