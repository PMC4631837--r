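#' Fitting configuration
#'
#' @param folds cross-validation folds (default 5).
#' @param maxTerms maximum number of terms added by forward selection
#'   (default 8).
#' @param minGain minimum improvement in mean CV \eqn{R^2} to accept another
#'   term (default 1e-3).
#' @param squares,products,transforms term-library contents, see
#'   [buildTermLibrary()].
#' @param outlierZ samples with any input or response |z-score| above this
#'   are dropped before fitting (default 3); \code{Inf} disables removal.
#' @param fTest guard term entry with a Bonferroni-corrected partial F-test
#'   (default \code{TRUE}). The guard controls spurious entry under
#'   measurement noise; exact-recovery studies on noise-free data disable it
#'   so that every true term enters regardless of its marginal evidence.
#' @param seed integer seed for the fold assignment.
#' @return named list used by [fitLayerModel()] and [fitHierarchy()].
#' @export
fitConfig <- function(folds = 5L, maxTerms = 8L, minGain = 1e-3,
                      squares = TRUE, products = TRUE,
                      transforms = character(), outlierZ = 3,
                      fTest = TRUE, seed = 1L) {
  folds <- stopifnotScalarCount(folds, "folds", min = 2L)
  maxTerms <- stopifnotScalarCount(maxTerms, "maxTerms", min = 1L)
  list(folds = folds, maxTerms = maxTerms, minGain = minGain,
       squares = squares, products = products, transforms = transforms,
       outlierZ = outlierZ, fTest = isTRUE(fTest), seed = as.integer(seed))
}

# per-fold out-of-sample R^2 for a fixed design (with intercept)
cvR2Folds <- function(D, y, foldId) {
  vapply(sort(unique(foldId)), function(f) {
    tr <- foldId != f; te <- !tr
    Xtr <- cbind(1, D[tr, , drop = FALSE])
    fit <- stats::lm.fit(Xtr, y[tr])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- cbind(1, D[te, , drop = FALSE]) %*% beta
    sst <- sum((y[te] - mean(y[te]))^2)
    if (sst == 0) return(NA_real_)
    1 - sum((y[te] - pred)^2) / sst
  }, numeric(1))
}

trainR2 <- function(D, y) {
  fit <- stats::lm.fit(cbind(1, D), y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(NA_real_)
  1 - sum(fit$residuals^2) / sst
}

#' Fit one aesthetic-property equation
#'
#' Greedy forward selection over the term library: at each step the
#' candidate term that maximizes the mean cross-validated \eqn{R^2} is
#' added; selection stops when the gain falls below \code{minGain} or
#' \code{maxTerms} is reached. When forward steps stall, a swap pass
#' (exchanging one chosen term for one candidate when training \eqn{R^2}
#' improves by \code{minGain}) lets the search leave basins where no single
#' addition helps, without growing the model. Because the best of many candidates
#' capitalizes on CV noise, acceptance is additionally guarded by an
#' F-to-enter test: the winner's partial F-statistic on the training fit
#' must be significant at a Bonferroni-corrected level (0.05 divided by the
#' library size), which keeps pure-noise responses at the intercept-only
#' model while leaving genuine terms (whose F-statistics are orders of
#' magnitude above the threshold) untouched. A backward pruning pass then removes terms
#' whose removal costs less than \code{minGain} of training \eqn{R^2}
#' (forward steps on correlated texture features can pick proxy terms en
#' route to the final fit; pruning restores the minimal support). Final
#' coefficients are ordinary least squares on all (outlier-filtered)
#' samples. Candidate columns that are non-finite for the data at hand
#' (out-of-domain transforms) are excluded; a rank-deficient final design
#' drops the offending term with a warning.
#'
#' @param X numeric sample x input matrix with named columns.
#' @param y numeric response (the averaged ratings of one property).
#' @param cfg list from [fitConfig()].
#' @param target property code stored in the model (default \code{"y"}).
#' @return a [LayerModel-class] with attribute \code{"fit"} (a list with
#'   \code{cvR2}, \code{trainR2}, \code{nSamples}).
#' @export
fitLayerModel <- function(X, y, cfg = fitConfig(), target = "y") {
  if (!is.matrix(X)) X <- as.matrix(X)
  if (is.null(colnames(X)))
    colnames(X) <- sprintf("x%d", seq_len(ncol(X)))
  if (length(y) != nrow(X))
    stop("'X' and 'y' must have matching lengths", call. = FALSE)
  if (any(!is.finite(y))) stop("'y' must be finite", call. = FALSE)
  if (nrow(X) < 2L * cfg$folds)
    stop("need at least 2 samples per fold", call. = FALSE)

  # z-score outlier removal over inputs and response
  if (is.finite(cfg$outlierZ)) {
    Z <- cbind(X, y)
    zs <- scale(Z)
    zs[, attr(zs, "scaled:scale") == 0] <- 0
    keep <- apply(abs(zs) <= cfg$outlierZ, 1L, all)
    if (sum(keep) >= 2L * cfg$folds && any(!keep)) {
      X <- X[keep, , drop = FALSE]; y <- y[keep]
    }
  }
  n <- nrow(X)

  lib <- buildTermLibrary(colnames(X), squares = cfg$squares,
                          products = cfg$products,
                          transforms = cfg$transforms)
  cand <- termDesign(lib, X)
  finiteCol <- apply(is.finite(cand), 2L, all)
  lib <- lib[finiteCol, , drop = FALSE]
  cand <- cand[, finiteCol, drop = FALSE]
  if (nrow(lib) && cfg$maxTerms >= n)
    stop("refusing to fit more terms than samples", call. = FALSE)

  foldId <- withSeed(cfg$seed, sample(rep_len(seq_len(cfg$folds), n)))

  chosen <- integer(0)
  bestVec <- cvR2Folds(matrix(numeric(), n, 0L), y, foldId)  # intercept-only
  # A candidate must clear two hurdles: its mean CV-R^2 gain must reach
  # minGain, and its partial F-test on the training fit must be significant
  # at a Bonferroni-corrected level (0.05 / library size). The CV gain alone
  # is not a safe acceptance signal — the best of many candidates
  # capitalizes on CV noise under a pure-noise response — while the
  # F-to-enter guard controls the family-wise rate of spurious terms.
  alphaEnter <- 0.05 / max(1L, nrow(lib))
  tss <- sum((y - mean(y))^2)
  partialP <- function(chosen, j) {
    rss0 <- sum(stats::lm.fit(cbind(1, cand[, chosen, drop = FALSE]),
                              y)$residuals^2)
    fit1 <- stats::lm.fit(cbind(1, cand[, c(chosen, j), drop = FALSE]), y)
    rss1 <- sum(fit1$residuals^2)
    df2 <- n - length(chosen) - 2L
    if (df2 < 1L) return(1)
    if (rss1 <= 1e-12 * tss)  # (near-)perfect fit: accept only a real drop
      return(if (rss0 - rss1 > 1e-12 * tss) 0 else 1)
    stats::pf((rss0 - rss1) / (rss1 / df2), 1, df2, lower.tail = FALSE)
  }
  forwardPass <- function(chosen, bestVec) {
    repeat {
      if (length(chosen) >= cfg$maxTerms) break
      remaining <- setdiff(seq_len(nrow(lib)), chosen)
      if (!length(remaining)) break
      cvs <- lapply(remaining, function(j)
        cvR2Folds(cand[, c(chosen, j), drop = FALSE], y, foldId))
      gains <- vapply(cvs, function(v) mean(v - bestVec, na.rm = TRUE),
                      numeric(1))
      ok <- which(is.finite(gains) & gains >= cfg$minGain)
      ok <- ok[order(-gains[ok])]
      iBest <- NA_integer_
      for (i in ok) {  # best CV gain whose F-to-enter also passes
        if (!cfg$fTest || partialP(chosen, remaining[i]) <= alphaEnter) {
          iBest <- i; break
        }
      }
      if (is.na(iBest)) break
      bestVec <- cvs[[iBest]]
      chosen <- c(chosen, remaining[iBest])
    }
    list(chosen = chosen, bestVec = bestVec)
  }
  # greedy forward steps can settle in a basin where no single addition
  # helps; a swap pass (exchange one chosen term for one candidate when
  # training R^2 improves) escapes it without growing the model, then
  # forward selection resumes
  swapPass <- function(chosen) {
    repeat {
      if (!length(chosen)) return(chosen)
      cur <- trainR2(cand[, chosen, drop = FALSE], y)
      bestGain <- cfg$minGain; bestSwap <- NULL
      for (i in seq_along(chosen)) {
        for (j in setdiff(seq_len(nrow(lib)), chosen)) {
          r2 <- trainR2(cand[, c(chosen[-i], j), drop = FALSE], y)
          if (is.finite(r2) && r2 - cur >= bestGain) {
            bestGain <- r2 - cur; bestSwap <- c(i, j)
          }
        }
      }
      if (is.null(bestSwap)) return(chosen)
      chosen[bestSwap[1]] <- bestSwap[2]
    }
  }
  st <- forwardPass(chosen, bestVec)
  for (pass in 1:5) {
    swapped <- swapPass(st$chosen)
    if (identical(swapped, st$chosen)) break
    st <- forwardPass(swapped,
                      cvR2Folds(cand[, swapped, drop = FALSE], y, foldId))
  }
  chosen <- st$chosen
  bestVec <- st$bestVec

  # backward pruning on training R^2
  if (length(chosen) > 1L) {
    full <- trainR2(cand[, chosen, drop = FALSE], y)
    repeat {
      drop1 <- vapply(seq_along(chosen), function(i)
        trainR2(cand[, chosen[-i], drop = FALSE], y), numeric(1))
      worst <- which.max(drop1)
      if (full - drop1[worst] < cfg$minGain && length(chosen) > 1L) {
        chosen <- chosen[-worst]
        full <- drop1[worst]
      } else break
    }
  }

  terms <- lib[chosen, , drop = FALSE]
  D <- cand[, chosen, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, D), y)
  if (any(is.na(fit$coefficients))) {
    bad <- which(is.na(fit$coefficients)) - 1L   # skip intercept slot
    warning("dropping rank-deficient term(s): ",
            paste(colnames(D)[bad], collapse = ", "))
    chosen <- chosen[-bad]
    terms <- lib[chosen, , drop = FALSE]
    D <- cand[, chosen, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, D), y)
  }
  coefs <- fit$coefficients
  terms$coefficient <- if (nrow(terms)) unname(coefs[-1L]) else numeric(0)
  model <- new("LayerModel", target = target, terms = terms,
               intercept = unname(coefs[1L]), inputNames = colnames(X))
  attr(model, "fit") <- list(cvR2 = mean(bestVec, na.rm = TRUE),
                             trainR2 = trainR2(D, y), nSamples = n)
  model
}

#' Fit the full three-layer hierarchy
#'
#' Fits the three affective models on the selected features, the four
#' judgment models on features plus the \emph{observed} affective ratings,
#' and the like-dislike model on features plus observed affective and
#' judgment ratings — observed lower-layer values are used during training
#' (as in the original study), predictions only at prediction time. The
#' judgment fits never see the Q column and the affective fits see features
#' only.
#'
#' @param features numeric texture x 10 matrix of scaled selected features;
#'   unnamed columns are labelled \code{f1...f10}.
#' @param ratings numeric texture x 8 matrix with columns G1..G3, T1..T4, Q
#'   (the averaged semantic-differential ratings).
#' @param cfg list from [fitConfig()].
#' @param scaling optional feature-scaling metadata stored in the model.
#' @return a [HierarchyModel-class] with provenance \code{"fitted"}.
#' @export
fitHierarchy <- function(features, ratings, cfg = fitConfig(),
                         scaling = list()) {
  if (!is.matrix(features)) features <- as.matrix(features)
  if (is.null(colnames(features)))
    colnames(features) <- paste0("f", seq_len(ncol(features)))
  props <- aestheticProperties()$code
  if (!all(props %in% colnames(ratings)))
    stop("ratings must have columns ", paste(props, collapse = ", "),
         call. = FALSE)
  if (nrow(features) != nrow(ratings))
    stop("features and ratings must describe the same textures",
         call. = FALSE)
  ratings <- ratings[, props, drop = FALSE]

  gObs <- ratings[, paste0("G", 1:3), drop = FALSE]
  tObs <- ratings[, paste0("T", 1:4), drop = FALSE]
  XG <- features
  XT <- cbind(features, gObs)
  XQ <- cbind(features, gObs, tObs)

  aff <- lapply(paste0("G", 1:3), function(p)
    fitLayerModel(XG, ratings[, p], cfg, target = p))
  jud <- lapply(paste0("T", 1:4), function(p)
    fitLayerModel(XT, ratings[, p], cfg, target = p))
  emo <- list(fitLayerModel(XQ, ratings[, "Q"], cfg, target = "Q"))
  new("HierarchyModel", affective = aff, judgment = jud, emotional = emo,
      scaling = scaling, provenance = "fitted")
}
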