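#' Default feature-extraction configuration
#'
#' Returns the configuration of the four-family feature bank: 6 HSV colour
#' statistics, a 4-distance x 4-orientation GLCM grid (64 features), the
#' three Tamura descriptors, and 4-level wavelet signatures (36 features) —
#' 109 features in total.
#'
#' @param glcmDistances,glcmAngles,glcmLevels,glcmSymmetric GLCM grid.
#' @param tamuraKMax,tamuraBins,tamuraThreshold Tamura parameters.
#' @param waveletLevels,wavelet,waveletBoundary wavelet parameters.
#' @return a named list understood by [extractFeatures()].
#' @export
featureConfig <- function(glcmDistances = c(2L, 4L, 6L, 8L),
                          glcmAngles = c(0, 45, 90, 135),
                          glcmLevels = 8L, glcmSymmetric = TRUE,
                          tamuraKMax = 5L, tamuraBins = 16L,
                          tamuraThreshold = 0.1,
                          waveletLevels = 4L, wavelet = "db4",
                          waveletBoundary = "symmetric") {
  list(glcmDistances = glcmDistances, glcmAngles = glcmAngles,
       glcmLevels = glcmLevels, glcmSymmetric = glcmSymmetric,
       tamuraKMax = tamuraKMax, tamuraBins = tamuraBins,
       tamuraThreshold = tamuraThreshold,
       waveletLevels = waveletLevels, wavelet = wavelet,
       waveletBoundary = waveletBoundary)
}

#' Extract the full texture feature vector
#'
#' Concatenates the four feature families in the fixed order colour (6),
#' GLCM (64 with the default grid), Tamura (3), wavelet (9 per level;
#' 36 by default), for 109 features under the default configuration. Any
#' non-finite value aborts with the offending feature named — failed
#' sub-features never silently propagate NaN. The image must be at least
#' 32 x 32.
#'
#' @param img a [TextureImage-class].
#' @param config list from [featureConfig()].
#' @return named numeric vector with a \code{"families"} attribute tagging
#'   each entry as \code{color}, \code{glcm}, \code{tamura} or
#'   \code{wavelet}.
#' @examples
#' img <- TextureImage(matrix(runif(64 * 64), 64, 64))
#' length(extractFeatures(img))
#' @export
extractFeatures <- function(img, config = featureConfig()) {
  stopifnot(is(img, "TextureImage"))
  d <- dim(img@pixels)
  if (d[1] < 32L || d[2] < 32L)
    stop("feature extraction requires images of at least 32 x 32 pixels",
         call. = FALSE)
  gray <- grayIntensity(img)
  col6 <- hsvStats(img)
  glcm <- glcmFeatureBlock(img, distances = config$glcmDistances,
                           angles = config$glcmAngles,
                           levels = config$glcmLevels,
                           symmetric = config$glcmSymmetric)
  tam <- c(tamura.coarseness = tamuraCoarseness(gray, config$tamuraKMax),
           tamura.contrast = tamuraContrast(gray),
           tamura.directionality = tamuraDirectionality(
             gray, config$tamuraBins, config$tamuraThreshold))
  wav <- waveletFeatures(gray, levels = config$waveletLevels,
                         wavelet = config$wavelet,
                         boundary = config$waveletBoundary)
  out <- c(col6, glcm, tam, wav)
  if (any(!is.finite(out)))
    stop("non-finite feature value(s): ",
         paste(names(out)[!is.finite(out)], collapse = ", "), call. = FALSE)
  attr(out, "families") <- rep(c("color", "glcm", "tamura", "wavelet"),
                               c(length(col6), length(glcm), length(tam),
                                 length(wav)))
  out
}

#' Extract a textures x features matrix
#'
#' @param images list of [TextureImage-class] objects (names become row
#'   names) or a directory of PNG/TIFF/JPEG files.
#' @param config list from [featureConfig()].
#' @return numeric matrix, one row per texture, columns the stable feature
#'   names.
#' @export
extractFeatureMatrix <- function(images, config = featureConfig()) {
  if (is.character(images)) {
    if (!dir.exists(images))
      stop("image directory not found: ", images, call. = FALSE)
    files <- list.files(images, "\\.(png|tiff?|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files))
      stop("no images found under ", images, call. = FALSE)
    nm <- tools::file_path_sans_ext(basename(files))
    images <- lapply(files, readTextureImage)
    names(images) <- nm
  }
  if (!length(images)) stop("no images supplied", call. = FALSE)
  rows <- lapply(images, extractFeatures, config = config)
  X <- do.call(rbind, lapply(rows, as.vector))
  colnames(X) <- names(rows[[1]])
  rownames(X) <- if (!is.null(names(images))) names(images) else
    sprintf("texture%03d", seq_along(images))
  X
}

#' Min-max feature scaling
#'
#' Maps each feature column linearly onto \code{[lo, hi]} (default
#' \eqn{[-1, 1]}). Constant columns map to the interval midpoint. The
#' scaling parameters are attached so the identical transform can be applied
#' to new textures with [applyFeatureScaling()].
#'
#' @param X numeric feature matrix with at least 2 rows.
#' @param lo,hi target interval.
#' @return the scaled matrix with attribute \code{"scaling"} (a list with
#'   \code{min}, \code{max}, \code{lo}, \code{hi}).
#' @export
scaleFeatures <- function(X, lo = -1, hi = 1) {
  if (!is.matrix(X) || nrow(X) < 2L)
    stop("'X' must be a matrix with at least 2 rows", call. = FALSE)
  sc <- list(min = apply(X, 2L, min), max = apply(X, 2L, max),
             lo = lo, hi = hi)
  out <- applyFeatureScaling(X, sc)
  attr(out, "scaling") <- sc
  out
}

#' @rdname scaleFeatures
#' @param scaling a scaling parameter list as produced by [scaleFeatures()].
#' @export
applyFeatureScaling <- function(X, scaling) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  rng <- scaling$max - scaling$min
  mid <- (scaling$lo + scaling$hi) / 2
  out <- X
  for (j in seq_len(ncol(X))) {
    out[, j] <- if (rng[j] == 0) mid else
      scaling$lo + (X[, j] - scaling$min[j]) / rng[j] *
        (scaling$hi - scaling$lo)
  }
  out
}

#' Read/write feature matrices as CSV
#'
#' The on-disk format is one row per texture: first column \code{texture}
#' (the identifier), remaining columns the stable feature names.
#'
#' @param X feature matrix with row names.
#' @param path CSV path.
#' @return \code{writeFeatureCSV}: the path, invisibly;
#'   \code{readFeatureCSV}: the feature matrix.
#' @export
writeFeatureCSV <- function(X, path) {
  df <- data.frame(texture = rownames(X), X, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  X <- as.matrix(df[, -1L, drop = FALSE])
  rownames(X) <- df[[1L]]
  X
}
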