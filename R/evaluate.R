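#' Goodness-of-fit metrics
#'
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}}, Pearson correlation between predicted
#' and observed, and \eqn{RMSE = \sqrt{mean((obs - pred)^2)}}. For a
#' constant observed vector \eqn{R^2} and r are undefined and reported as
#' \code{NA}; RMSE is still computed.
#'
#' @param predicted,observed equal-length numeric vectors (>= 2 values).
#' @return named numeric vector \code{(r_squared, pearson_r, rmse)}.
#' @examples
#' evaluateModel(c(1, 2, 4), c(1, 2, 3))
#' @export
evaluateModel <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(observed) < 2L)
    stop("'predicted' and 'observed' must be equal-length (>= 2)",
         call. = FALSE)
  rmse <- sqrt(mean((observed - predicted)^2))
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    return(c(r_squared = NA_real_, pearson_r = NA_real_, rmse = rmse))
  r2 <- 1 - sum((observed - predicted)^2) / sst
  r <- if (stats::sd(predicted) == 0) NA_real_ else
    stats::cor(predicted, observed)
  c(r_squared = r2, pearson_r = r, rmse = rmse)
}

#' Model complexity
#'
#' \code{basic} is the number of non-intercept terms, the interpretability
#' measure used to compare the eight property equations. \code{enhanced} is
#' a weighted expression-tree size (weights: variable 1, constant 1, +/- 1,
#' \eqn{\times} 2, unary transform 3, power 2), a declared approximation of
#' symbolic-regression size metrics — useful for reporting, not a quantity
#' with an external reference value.
#'
#' @param m a [LayerModel-class].
#' @return named numeric vector \code{(basic, enhanced)}.
#' @examples
#' modelComplexity(layerModels(referenceModel())$Q)["basic"]
#' @export
modelComplexity <- function(m) {
  stopifnot(is(m, "LayerModel"))
  tt <- m@terms
  basic <- nrow(tt)
  if (!basic) return(c(basic = 0, enhanced = 1))  # bare constant
  exprCost <- vapply(seq_len(basic), function(i) {
    switch(tt$kind[i],
      variable = 1,
      square = 1 + 2,        # variable + power
      product = 1 + 1 + 2,   # two variables + multiply
      unary = 1 + 3)         # variable + transform
  }, numeric(1))
  # each term: coefficient constant + multiply + expression; terms and the
  # intercept are joined by additions
  enhanced <- sum(1 + 2 + exprCost) + basic + 1
  c(basic = basic, enhanced = enhanced)
}

#' Evaluate a hierarchy property-by-property
#'
#' Predicts through the cascade (optionally with observed lower layers, the
#' evaluation mode used for training-set tables in this literature) and
#' tabulates the metrics of [evaluateModel()] together with both complexity
#' measures for each of the eight properties.
#'
#' @param h a [HierarchyModel-class].
#' @param features texture x 10 matrix of scaled features.
#' @param ratings texture x 8 observed ratings matrix (columns G1..Q).
#' @param useObservedLowerLayers when \code{TRUE} (default) the judgment
#'   layer is predicted from observed G and the emotional layer from
#'   observed G and T, mirroring how the models were fitted.
#' @return data.frame with one row per property: \code{property},
#'   \code{r_squared}, \code{basic_complexity}, \code{enhanced_complexity},
#'   \code{pearson_r}, \code{rmse}.
#' @export
evaluateHierarchy <- function(h, features, ratings,
                              useObservedLowerLayers = TRUE) {
  props <- aestheticProperties()$code
  ratings <- as.matrix(ratings)[, props, drop = FALSE]
  overrides <- if (useObservedLowerLayers)
    list(G = ratings[, paste0("G", 1:3), drop = FALSE],
         T = ratings[, paste0("T", 1:4), drop = FALSE]) else NULL
  pred <- predictCascade(h, features, overrides = overrides)
  if (useObservedLowerLayers) {
    # lower layers themselves are still evaluated on their own predictions
    pure <- predictCascade(h, features)
    pred[, paste0("G", 1:3)] <- pure[, paste0("G", 1:3)]
    pred[, paste0("T", 1:4)] <- predictCascade(
      h, features, overrides = list(G = ratings[, paste0("G", 1:3),
                                                drop = FALSE])
    )[, paste0("T", 1:4)]
  }
  mods <- layerModels(h)
  rows <- lapply(props, function(p) {
    met <- evaluateModel(pred[, p], ratings[, p])
    cx <- modelComplexity(mods[[p]])
    data.frame(property = p, r_squared = met["r_squared"],
               basic_complexity = cx["basic"],
               enhanced_complexity = cx["enhanced"],
               pearson_r = met["pearson_r"], rmse = met["rmse"],
               row.names = NULL)
  })
  do.call(rbind, rows)
}
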