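#' Create a TextureImage from a pixel array
#'
#' @param pixels numeric matrix (grayscale) or height x width x 3 array (RGB),
#'   values on \eqn{[0, 1]}.
#' @param colorspace \code{"RGB"} or \code{"GRAY"}; inferred from the array
#'   dimensions when omitted.
#' @return A [TextureImage-class] object.
#' @examples
#' img <- TextureImage(matrix(runif(64 * 64), 64, 64))
#' colorspace(img)
#' @export
TextureImage <- function(pixels, colorspace = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, dim = dim(pixels))
  if (!is.array(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix or array", call. = FALSE)
  if (is.null(colorspace))
    colorspace <- if (length(dim(pixels)) == 3L) "RGB" else "GRAY"
  new("TextureImage", pixels = pixels, colorspace = colorspace)
}

#' Read a texture image from PNG, TIFF or JPEG
#'
#' 8- or 16-bit images are converted to doubles on \eqn{[0, 1]}. Single-channel
#' files become \code{GRAY} images, 3- or 4-channel files become \code{RGB}
#' (an alpha channel, if present, is dropped). JPEG input requires the
#' \pkg{EBImage} package.
#'
#' @param path file path; format is chosen by extension.
#' @return A [TextureImage-class].
#' @seealso [writeTextureImage()]
#' @export
readTextureImage <- function(path) {
  if (!file.exists(path))
    stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = tiff::readTIFF(path),
    jpg = , jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG input requires the EBImage package", call. = FALSE)
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      # EBImage stores x (columns) in the first dimension; transpose to rows
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop("unsupported image format: ", ext, call. = FALSE))
  px <- pmin(pmax(px, 0), 1)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] >= 3L) {
      TextureImage(px[, , 1:3, drop = FALSE], "RGB")
    } else {
      TextureImage(px[, , 1L], "GRAY")
    }
  } else {
    TextureImage(px, "GRAY")
  }
}

#' Write a TextureImage to a PNG file
#'
#' @param img a [TextureImage-class].
#' @param path output path (PNG).
#' @return \code{path}, invisibly.
#' @export
writeTextureImage <- function(img, path) {
  stopifnot(is(img, "TextureImage"))
  png::writePNG(img@pixels, target = path)
  invisible(path)
}

#' Grayscale intensity of a texture image
#'
#' RGB pixels are reduced by the standard luma weighting
#' \eqn{0.299 R + 0.587 G + 0.114 B}; grayscale images pass through.
#'
#' @param img a [TextureImage-class].
#' @return numeric matrix of intensities on \eqn{[0, 1]}.
#' @export
grayIntensity <- function(img) {
  stopifnot(is(img, "TextureImage"))
  px <- img@pixels
  if (img@colorspace == "GRAY") return(px[, , drop = TRUE])
  0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
}

#' Quantize an image to discrete gray levels
#'
#' Uniform quantization of \eqn{[0, 1]} into \code{levels} equal bins; the
#' closed upper edge (intensity exactly 1) is assigned to the top bin. RGB
#' images are first reduced with [grayIntensity()].
#'
#' @param img a [TextureImage-class] or a numeric intensity matrix on
#'   \eqn{[0, 1]}.
#' @param levels number of gray levels (>= 2).
#' @return integer matrix of bin indices in \code{0:(levels - 1)}.
#' @examples
#' toGrayQuantized(TextureImage(matrix(c(0, .49, .51, 1), 2, 2)), 2)
#' @export
toGrayQuantized <- function(img, levels = 8L) {
  levels <- stopifnotScalarCount(levels, "levels", min = 2L)
  g <- if (is(img, "TextureImage")) grayIntensity(img) else img
  if (!is.matrix(g) || anyNA(g) || min(g) < 0 || max(g) > 1)
    stop("intensities must form a matrix with values in [0, 1]", call. = FALSE)
  q <- floor(g * levels)
  q[q == levels] <- levels - 1L
  storage.mode(q) <- "integer"
  q
}
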