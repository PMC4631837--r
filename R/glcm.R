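#' Gray-level co-occurrence matrix
#'
#' Counts co-occurrences of quantized gray levels at pixel offset
#' \code{(distance, angle)} and normalizes to a joint probability matrix.
#' Angles are measured counter-clockwise from the +column axis with row
#' indices growing downwards, so the offsets \code{(drow, dcol)} are
#' 0° = \code{(0, d)}, 45° = \code{(-d, d)}, 90° = \code{(-d, 0)},
#' 135° = \code{(-d, -d)}. When \code{symmetric}, transpose counts are added
#' before normalization (each pair counted in both directions).
#'
#' @param gray integer matrix of bin indices from [toGrayQuantized()].
#' @param distance offset length in pixels (>= 1).
#' @param angle one of 0, 45, 90, 135 (degrees).
#' @param levels number of gray levels; defaults to \code{max(gray) + 1}.
#' @param symmetric logical, default \code{TRUE}.
#' @return \code{levels x levels} matrix of joint probabilities summing to 1.
#' @examples
#' g <- toGrayQuantized(TextureImage(matrix(0.6, 4, 4)), 8)
#' computeGLCM(g, distance = 2, angle = 0)[5, 5]
#' @export
computeGLCM <- function(gray, distance, angle, levels = NULL,
                        symmetric = TRUE) {
  distance <- stopifnotScalarCount(distance, "distance", min = 1L)
  if (!angle %in% c(0, 45, 90, 135))
    stop("'angle' must be one of 0, 45, 90, 135", call. = FALSE)
  if (!is.matrix(gray)) stop("'gray' must be a matrix", call. = FALSE)
  if (is.null(levels)) levels <- max(gray) + 1L
  levels <- stopifnotScalarCount(levels, "levels", min = 2L)
  if (min(gray) < 0 || max(gray) >= levels)
    stop("gray indices must lie in [0, levels - 1]", call. = FALSE)

  off <- switch(as.character(angle),
    "0"   = c(0L, distance),
    "45"  = c(-distance, distance),
    "90"  = c(-distance, 0L),
    "135" = c(-distance, -distance))
  nr <- nrow(gray); nc <- ncol(gray)
  rows <- seq_len(nr); cols <- seq_len(nc)
  rows <- rows[rows + off[1] >= 1L & rows + off[1] <= nr]
  cols <- cols[cols + off[2] >= 1L & cols + off[2] <= nc]
  if (!length(rows) || !length(cols))
    stop("no valid pixel pair at offset (d = ", distance, ", theta = ",
         angle, ")", call. = FALSE)

  from <- gray[rows, cols, drop = FALSE]
  to <- gray[rows + off[1], cols + off[2], drop = FALSE]
  counts <- matrix(0, levels, levels)
  idx <- from + levels * to + 1L  # column-major cell index (i = from, j = to)
  tab <- tabulate(idx, nbins = levels * levels)
  counts[] <- tab
  if (symmetric) counts <- counts + t(counts)
  P <- counts / sum(counts)
  stopifnot(abs(sum(P) - 1) < 1e-9)
  P
}

#' Haralick statistics of a GLCM
#'
#' Computes the four co-occurrence statistics used in the feature bank:
#' contrast \eqn{\sum (i-j)^2 p_{ij}}, correlation
#' \eqn{\sum (i-\mu_i)(j-\mu_j) p_{ij} / (\sigma_i \sigma_j)}, energy
#' \eqn{\sum p_{ij}^2} and homogeneity \eqn{\sum p_{ij} / (1 + |i-j|)}.
#' For a constant texture both marginal standard deviations vanish;
#' correlation is then defined as 1 (a constant texture is perfectly
#' predictable from itself), avoiding NaN propagation.
#'
#' @param P normalized GLCM from [computeGLCM()].
#' @return named numeric vector
#'   \code{(contrast, correlation, energy, homogeneity)}.
#' @export
glcmStats <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("'P' must be a square matrix", call. = FALSE)
  if (any(P < 0) || abs(sum(P) - 1) > 1e-9)
    stop("'P' must be a normalized co-occurrence matrix", call. = FALSE)
  n <- nrow(P)
  i <- matrix(seq_len(n) - 1, n, n)        # row index = first gray level
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + abs(i - j)))
  pi_ <- rowSums(P); pj_ <- colSums(P)
  lev <- seq_len(n) - 1
  mi <- sum(lev * pi_); mj <- sum(lev * pj_)
  si <- sqrt(sum((lev - mi)^2 * pi_)); sj <- sqrt(sum((lev - mj)^2 * pj_))
  correlation <- if (si * sj == 0) 1 else
    sum((i - mi) * (j - mj) * P) / (si * sj)
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity)
}

#' GLCM feature block over a distance/orientation grid
#'
#' Evaluates [glcmStats()] for every combination of the distance and angle
#' grids (defaults d in \{2, 4, 6, 8\} crossed with angles
#' \{0°, 45°, 90°, 135°\}: 16 matrices, 64 features). Features are ordered by
#' distance, then angle, then the fixed statistic order
#' contrast/correlation/energy/homogeneity, with names like
#' \code{glcm.d8.t45.contrast}.
#'
#' @param img a [TextureImage-class] or a quantized integer matrix.
#' @param distances integer vector of offset lengths.
#' @param angles subset of \code{c(0, 45, 90, 135)}.
#' @param levels gray levels for quantization (default 8).
#' @param symmetric passed to [computeGLCM()].
#' @return named numeric vector of \code{4 * length(distances) *
#'   length(angles)} features.
#' @export
glcmFeatureBlock <- function(img, distances = c(2L, 4L, 6L, 8L),
                             angles = c(0, 45, 90, 135), levels = 8L,
                             symmetric = TRUE) {
  gray <- if (is(img, "TextureImage")) toGrayQuantized(img, levels)
          else img
  stats <- c("contrast", "correlation", "energy", "homogeneity")
  out <- numeric(0)
  for (d in sort(distances)) {
    for (a in sort(angles)) {
      s <- glcmStats(computeGLCM(gray, d, a, levels = levels,
                                 symmetric = symmetric))
      names(s) <- sprintf("glcm.d%d.t%d.%s", d, a, stats)
      out <- c(out, s)
    }
  }
  out
}
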