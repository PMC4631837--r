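# Parametric texture generation and simulation of the semantic-differential
# rating experiment. These stand in for a non-redistributable photographic
# stimulus set: they give controllable coarseness, contrast, orientation and
# colour, not photorealism.

#' Generate a parametric texture
#'
#' Four kinds are available: \describe{
#'   \item{grating}{\code{0.5 + amplitude/2 * sin(2*pi*frequency*
#'     (x*cos(theta) + y*sin(theta)))} with x, y in cycles per image;
#'     amplitude 0 gives a constant image.}
#'   \item{checkerboard}{alternating blocks of side \code{block} at
#'     intensities \code{0.5 +/- amplitude/2}.}
#'   \item{filtered_noise}{seeded white noise convolved with a separable
#'     Gaussian kernel of standard deviation \code{correlation} pixels, then
#'     rescaled to \eqn{[0, 1]}.}
#'   \item{color_patchwork}{an RGB image of \code{block}-sized tiles, each
#'     tile coloured by a draw from the HSV \code{palette} (a list of
#'     \code{c(h, s, v)} triplets on \eqn{[0, 1]}).}
#' }
#' Generation is deterministic given \code{seed}.
#'
#' @param kind one of \code{"grating"}, \code{"checkerboard"},
#'   \code{"filtered_noise"}, \code{"color_patchwork"}.
#' @param size image side in pixels (>= 32; default 128, the package's
#'   test-scale default — pass 480 for study-scale stimuli).
#' @param frequency grating frequency, cycles per image (default 8).
#' @param orientation grating orientation in degrees (default 0).
#' @param amplitude contrast amplitude on \eqn{[0, 1]} (default 1).
#' @param block block side in pixels for checkerboard/patchwork (default 16).
#' @param correlation Gaussian correlation length in pixels for filtered
#'   noise (default 3).
#' @param palette list of HSV triplets for the patchwork.
#' @param seed integer seed (used by the stochastic kinds).
#' @return a [TextureImage-class].
#' @examples
#' img <- generateTexture("grating", frequency = 12, orientation = 45)
#' @export
generateTexture <- function(kind = c("grating", "checkerboard",
                                     "filtered_noise", "color_patchwork"),
                            size = 128L, frequency = 8, orientation = 0,
                            amplitude = 1, block = 16L, correlation = 3,
                            palette = NULL, seed = 1L) {
  kind <- match.arg(kind)
  size <- stopifnotScalarCount(size, "size", min = 32L)
  if (amplitude < 0 || amplitude > 1)
    stop("'amplitude' must lie in [0, 1]", call. = FALSE)
  px <- switch(kind,
    grating = {
      th <- orientation * pi / 180
      xy <- (seq_len(size) - 0.5) / size
      phase <- outer(xy * sin(th), xy * cos(th), "+")
      0.5 + amplitude / 2 * sin(2 * pi * frequency * phase)
    },
    checkerboard = {
      block <- stopifnotScalarCount(block, "block", min = 1L)
      idx <- floor((seq_len(size) - 1L) / block)
      par <- outer(idx, idx, "+") %% 2L
      0.5 - amplitude / 2 + amplitude * par
    },
    filtered_noise = {
      if (correlation <= 0) stop("'correlation' must be > 0", call. = FALSE)
      z <- withSeed(seed, matrix(stats::rnorm(size^2), size, size))
      half <- max(1L, ceiling(3 * correlation))
      kern <- stats::dnorm(seq(-half, half), sd = correlation)
      kern <- kern / sum(kern)
      sm <- apply(z, 2L, function(col) blurPad(col, kern))
      sm <- t(apply(sm, 1L, function(row) blurPad(row, kern)))
      rng <- range(sm)
      if (diff(rng) == 0) matrix(0.5, size, size) else
        (sm - rng[1]) / diff(rng)
    },
    color_patchwork = {
      block <- stopifnotScalarCount(block, "block", min = 1L)
      if (is.null(palette))
        palette <- list(c(0.00, 0.8, 0.9), c(0.12, 0.7, 0.8),
                        c(0.33, 0.6, 0.7), c(0.60, 0.8, 0.9),
                        c(0.80, 0.5, 0.6))
      nTiles <- ceiling(size / block)
      pick <- withSeed(seed,
        matrix(sample.int(length(palette), nTiles^2, replace = TRUE),
               nTiles, nTiles))
      arr <- array(0, c(size, size, 3L))
      tileOf <- floor((seq_len(size) - 1L) / block) + 1L
      for (i in seq_len(nTiles)) {
        for (j in seq_len(nTiles)) {
          hsv <- palette[[pick[i, j]]]
          rgb <- grDevices::col2rgb(
            grDevices::hsv(hsv[1], hsv[2], hsv[3])) / 255
          rr <- which(tileOf == i); cc <- which(tileOf == j)
          for (ch in 1:3) arr[rr, cc, ch] <- rgb[ch]
        }
      }
      arr
    })
  px <- pmin(pmax(px, 0), 1)
  TextureImage(px, if (kind == "color_patchwork") "RGB" else "GRAY")
}

# 1-D convolution with edge-replication padding (internal)
blurPad <- function(x, kern) {
  half <- (length(kern) - 1L) / 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  stats::convolve(xp, rev(kern), type = "filter")
}

#' Plant a random sparse hierarchy
#'
#' Draws a sparse linear three-layer hierarchy for simulation studies:
#' each affective model gets \code{affectiveTerms} feature terms, each
#' judgment/emotional model \code{upperFeatureTerms} feature terms plus
#' \code{nLowerTerms} lower-layer terms. Feature-coefficient magnitudes are
#' uniform on \code{coefRange} with random signs, lower-layer magnitudes on
#' \code{lowerCoefRange}; intercepts uniform on \code{interceptRange}.
#'
#' The default structure is chosen so recovery from data is well-posed:
#' because an affective property is itself a function of the features, a
#' lower-layer term can in principle be replaced by its feature expansion.
#' With 5-feature affective models and at most 8 terms per fitted equation,
#' any such substitution needs more terms than the fitter may use, so the
#' planted support is the only representation reachable — a structural
#' identifiability guarantee rather than a statistical one. The magnitude
#' defaults keep cascade values on features in \eqn{[-1, 1]} mostly inside
#' the \eqn{[-100, 100]} rating range, so clipping stays rare.
#'
#' @param nFeatures number of feature inputs (default 10).
#' @param affectiveTerms feature terms per affective model (default 5).
#' @param upperFeatureTerms feature terms per judgment/emotional model
#'   (default 3).
#' @param nLowerTerms lower-layer terms per judgment/emotional model
#'   (default 2).
#' @param coefRange magnitude range of feature coefficients (default
#'   \code{c(8, 20)}).
#' @param lowerCoefRange magnitude range of lower-layer coefficients
#'   (default \code{c(0.2, 0.6)}).
#' @param interceptRange intercept range (default \code{c(-10, 10)}).
#' @param seed integer seed.
#' @return a [HierarchyModel-class] with provenance \code{"planted"}.
#' @export
plantHierarchy <- function(nFeatures = 10L, affectiveTerms = 5L,
                           upperFeatureTerms = 3L,
                           nLowerTerms = 2L, coefRange = c(8, 20),
                           lowerCoefRange = c(0.2, 0.6),
                           interceptRange = c(-10, 10), seed = 1L) {
  nFeatures <- stopifnotScalarCount(nFeatures, "nFeatures", min = 2L)
  f <- paste0("f", seq_len(nFeatures))
  gN <- paste0("G", 1:3); tN <- paste0("T", 1:4)
  draw <- function(vars, n, range) {
    v <- sample(vars, min(n, length(vars)))
    makeTerms("variable", v,
              coefficient = sample(c(-1, 1), length(v), replace = TRUE) *
                stats::runif(length(v), range[1], range[2]))
  }
  withSeed(seed, {
    mk <- function(target, inputs, lowerVars = NULL) {
      nf <- if (is.null(lowerVars)) affectiveTerms else upperFeatureTerms
      terms <- draw(f, nf, coefRange)
      if (!is.null(lowerVars))
        terms <- rbind(terms, draw(lowerVars, nLowerTerms, lowerCoefRange))
      new("LayerModel", target = target, terms = terms,
          intercept = stats::runif(1, interceptRange[1], interceptRange[2]),
          inputNames = inputs)
    }
    aff <- lapply(gN, mk, inputs = f)
    jud <- lapply(tN, mk, inputs = c(f, gN), lowerVars = gN)
    emo <- list(mk("Q", c(f, gN, tN), lowerVars = c(gN, tN)))
    new("HierarchyModel", affective = aff, judgment = jud, emotional = emo,
        scaling = list(), provenance = "planted")
  })
}

#' Simulate a semantic-differential rating experiment
#'
#' True property values come from the planted cascade; every raw rating is
#' true value + rater bias + repetition noise, clipped to the rating range;
#' the per-texture table averages all \code{nRaters * nReps} raw ratings
#' (100 under the default design).
#'
#' @param h a [HierarchyModel-class] (typically planted).
#' @param features texture x feature matrix on the hierarchy's scale.
#' @param nRaters number of raters (default 20).
#' @param nReps repetitions per rater (default 5).
#' @param noiseSd per-rating Gaussian noise sd, one value or one per layer
#'   \code{c(affective, judgment, emotional)} (default 5).
#' @param raterBiasSd sd of the per-rater, per-property additive bias
#'   (default 2).
#' @param clip rating range (default \code{c(-100, 100)}).
#' @param seed integer seed.
#' @return a [SimulatedExperiment-class].
#' @export
simulateRatings <- function(h, features, nRaters = 20L, nReps = 5L,
                            noiseSd = 5, raterBiasSd = 2,
                            clip = c(-100, 100), seed = 1L) {
  stopifnot(is(h, "HierarchyModel"))
  nRaters <- stopifnotScalarCount(nRaters, "nRaters", min = 1L)
  nReps <- stopifnotScalarCount(nReps, "nReps", min = 1L)
  if (any(noiseSd < 0) || raterBiasSd < 0)
    stop("noise standard deviations must be >= 0", call. = FALSE)
  true <- predictCascade(h, features)
  nTex <- nrow(true); props <- colnames(true)
  sdProp <- if (length(noiseSd) == 3L) rep(noiseSd, c(3L, 4L, 1L))
            else rep_len(noiseSd, 8L)
  raw <- withSeed(seed, {
    bias <- matrix(stats::rnorm(nRaters * 8L, 0, raterBiasSd), nRaters, 8L)
    a <- array(0, c(nTex, 8L, nRaters, nReps))
    for (r in seq_len(nRaters)) {
      for (p in seq_len(8L)) {
        eps <- matrix(stats::rnorm(nTex * nReps, 0, sdProp[p]), nTex, nReps)
        a[, p, r, ] <- true[, p] + bias[r, p] + eps
      }
    }
    a
  })
  raw <- pmin(pmax(raw, clip[1]), clip[2])
  ratings <- apply(raw, c(1L, 2L), mean)
  dimnames(ratings) <- list(rownames(features), props)
  new("SimulatedExperiment", raw = raw, ratings = ratings,
      trueValues = true,
      design = list(nRaters = nRaters, nReps = nReps, clip = clip,
                    noiseSd = sdProp, raterBiasSd = raterBiasSd,
                    seed = seed))
}

#' Generate an end-to-end synthetic benchmark
#'
#' Draws texture specifications spanning all four kinds, extracts the full
#' feature bank, scales it to \eqn{[-1, 1]}, ranks features by Laplacian
#' Score and keeps the top \code{nSelect}, plants a sparse hierarchy on the
#' selected features and simulates the rating experiment — returning every
#' intermediate plus the ground truth, so recovery of the planted
#' coefficients can be tested.
#'
#' The retained set walks down the Laplacian-Score ranking but skips
#' features whose absolute correlation with an already-kept feature exceeds
#' \code{maxAbsCor}: the feature bank contains near-duplicates (e.g.
#' co-occurrence contrasts at adjacent distances correlate above 0.99), and
#' a hierarchy planted on one of two nearly collinear columns is not
#' identifiable from data. The redundancy filter is exactly the role
#' unsupervised selection plays in this pipeline, applied with an explicit
#' threshold.
#'
#' @param nTextures number of textures (>= 20; 151 reproduces the scale of
#'   a full perception study).
#' @param seed integer seed driving every random choice.
#' @param size image side in pixels (default 128).
#' @param nSelect number of features to retain (default 10).
#' @param noiseSd,raterBiasSd,nRaters,nReps passed to [simulateRatings()].
#' @param k kNN size for the affinity graph (default 5).
#' @param maxAbsCor redundancy threshold for the retained set (default
#'   0.95).
#' @return list with elements \code{images}, \code{features} (raw bank),
#'   \code{scaled} (with scaling attribute), \code{selection}
#'   ([SelectionResult-class]), \code{selected} (texture x nSelect matrix,
#'   columns renamed f1...fn), \code{planted} ([HierarchyModel-class]),
#'   \code{experiment} ([SimulatedExperiment-class]) and \code{ratings}.
#' @export
makeBenchmarkDataset <- function(nTextures = 30L, seed = 1L, size = 128L,
                                 nSelect = 10L, noiseSd = 5,
                                 raterBiasSd = 2, nRaters = 20L, nReps = 5L,
                                 k = 5L, maxAbsCor = 0.95) {
  nTextures <- stopifnotScalarCount(nTextures, "nTextures", min = 20L)
  kinds <- c("grating", "checkerboard", "filtered_noise", "color_patchwork")
  specs <- withSeed(seed, lapply(seq_len(nTextures), function(i) {
    list(kind = kinds[((i - 1L) %% 4L) + 1L],
         frequency = stats::runif(1, 2, 24),
         orientation = stats::runif(1, 0, 180),
         amplitude = stats::runif(1, 0.3, 1),
         block = sample(c(2L, 4L, 8L, 16L, 32L), 1L),
         correlation = stats::runif(1, 0.8, 8),
         seed = seed + i)
  }))
  images <- lapply(specs, function(s)
    generateTexture(s$kind, size = size, frequency = s$frequency,
                    orientation = s$orientation, amplitude = s$amplitude,
                    block = s$block, correlation = s$correlation,
                    seed = s$seed))
  names(images) <- sprintf("tex%03d", seq_len(nTextures))
  X <- extractFeatureMatrix(images)
  Xs <- scaleFeatures(X)
  g <- buildAffinityGraph(Xs, k = k)
  scores <- laplacianScores(Xs, g)
  ranked <- selectFeatures(scores, mode = "top_k", value = nSelect)
  # walk the full ranking, skipping features nearly collinear with kept ones
  keep <- integer(0)
  for (j in featureRanking(ranked)) {
    if (stats::sd(Xs[, j]) == 0) next
    if (length(keep) &&
        max(abs(stats::cor(Xs[, j], Xs[, keep, drop = FALSE]))) > maxAbsCor)
      next
    keep <- c(keep, j)
    if (length(keep) == nSelect) break
  }
  if (length(keep) < nSelect)
    stop("fewer than ", nSelect, " mutually distinguishable features; ",
         "raise maxAbsCor or enlarge the texture set", call. = FALSE)
  sel <- new("SelectionResult", scores = scores,
             ranking = featureRanking(ranked),
             selected = colnames(Xs)[keep],
             params = list(mode = "top_k", value = nSelect,
                           higherIsBetter = TRUE, maxAbsCor = maxAbsCor))
  selX <- Xs[, selectedFeatures(sel), drop = FALSE]
  colnames(selX) <- paste0("f", seq_len(ncol(selX)))
  planted <- plantHierarchy(nFeatures = nSelect, seed = seed + 1L)
  exper <- simulateRatings(planted, selX, nRaters = nRaters, nReps = nReps,
                           noiseSd = noiseSd, raterBiasSd = raterBiasSd,
                           seed = seed + 2L)
  list(images = images, features = X, scaled = Xs, selection = sel,
       selected = selX, planted = planted, experiment = exper,
       ratings = ratingsTable(exper))
}
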