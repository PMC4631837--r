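#' HSV colour statistics
#'
#' Converts the image to HSV (hue expressed as angle/360 so all three
#' channels live on \eqn{[0, 1]}) and returns the channel means and
#' population standard deviations, the six colour descriptors of the feature
#' bank. Grayscale images are promoted by replicating the channel, so their
#' saturation is identically zero.
#'
#' @param img a [TextureImage-class].
#' @return named numeric vector
#'   \code{(color.hue.mean, color.sat.mean, color.val.mean,
#'   color.hue.sd, color.sat.sd, color.val.sd)}.
#' @examples
#' red <- TextureImage(array(rep(c(1, 0, 0), each = 64 * 64), c(64, 64, 3)))
#' hsvStats(red)[c("color.hue.mean", "color.sat.mean", "color.val.mean")]
#' @export
hsvStats <- function(img) {
  stopifnot(is(img, "TextureImage"))
  px <- img@pixels
  if (img@colorspace == "GRAY") {
    v <- as.vector(px)
    hsv <- rbind(h = 0, s = 0, v = v)
  } else {
    hsv <- grDevices::rgb2hsv(
      r = as.vector(px[, , 1]), g = as.vector(px[, , 2]),
      b = as.vector(px[, , 3]), maxColorValue = 1)
  }
  popSd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- c(mean(hsv["h", ]), mean(hsv["s", ]), mean(hsv["v", ]),
           popSd(hsv["h", ]), popSd(hsv["s", ]), popSd(hsv["v", ]))
  names(out) <- c("color.hue.mean", "color.sat.mean", "color.val.mean",
                  "color.hue.sd", "color.sat.sd", "color.val.sd")
  out
}
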