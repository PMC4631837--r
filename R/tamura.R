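# Tamura perceptual texture descriptors: coarseness, contrast, directionality.
# Intensities are expected on [0, 1]; defaults follow the classical
# formulations, with every parameter exposed.

# summed-area table with a zero row/column prepended, so the sum of
# gray[a..b, c..d] is C[b+1, d+1] - C[a, d+1] - C[b+1, c] + C[a, c]
cumsum2 <- function(g) {
  C <- matrix(0, nrow(g) + 1L, ncol(g) + 1L)
  C[-1L, -1L] <- apply(apply(g, 2L, cumsum), 1L, cumsum) |> t()
  C
}

#' Tamura coarseness
#'
#' Implements the Sbest procedure: neighbourhood averages \eqn{A_k} over
#' \eqn{2^k \times 2^k} windows, horizontal and vertical differences between
#' window averages separated by \eqn{2^{k-1}}, a per-pixel best scale
#' \eqn{2^{k^*}} maximizing the larger difference (ties and the all-zero case
#' resolved toward the smallest k), and the mean of \eqn{2^{k^*}} over the
#' valid interior. Scales whose neighbour windows do not fit anywhere in the
#' image are dropped from the comparison; the valid interior is the set of
#' pixels where the finest scale (k = 1) is defined.
#'
#' @param gray numeric intensity matrix on \eqn{[0, 1]}.
#' @param kMax largest window exponent considered (default 5, i.e. 32-pixel
#'   windows). The image side must be at least \code{2^kMax}.
#' @return scalar coarseness in \code{[2, 2^kMax]}.
#' @export
tamuraCoarseness <- function(gray, kMax = 5L) {
  kMax <- stopifnotScalarCount(kMax, "kMax", min = 1L)
  if (!is.matrix(gray)) stop("'gray' must be a matrix", call. = FALSE)
  n <- nrow(gray); m <- ncol(gray)
  if (min(n, m) < 2^kMax)
    stop("image too small for kMax = ", kMax,
         " (need side >= ", 2^kMax, "); lower kMax", call. = FALSE)
  # scales usable somewhere in the image: need side >= 2^(k+1)
  kEff <- min(kMax, floor(log2(min(n, m))) - 1L)
  if (kEff < 1L)
    stop("image too small for coarseness (need side >= 4)", call. = FALSE)

  C <- cumsum2(gray)
  bestVal <- matrix(-1, n, m)
  bestK <- matrix(NA_integer_, n, m)
  for (k in seq_len(kEff)) {
    h <- 2^(k - 1L); w2 <- 2^(2L * k)
    rs <- (h + 1L):(n - h + 1L)
    cs <- (h + 1L):(m - h + 1L)
    A <- matrix(NA_real_, n, m)
    A[rs, cs] <- (C[rs + h, cs + h] - C[rs - h, cs + h] -
                  C[rs + h, cs - h] + C[rs - h, cs - h]) / w2
    rr <- (2L * h + 1L):(n - 2L * h + 1L)
    cc <- (2L * h + 1L):(m - 2L * h + 1L)
    Eh <- abs(A[rr, cc + h, drop = FALSE] - A[rr, cc - h, drop = FALSE])
    Ev <- abs(A[rr + h, cc, drop = FALSE] - A[rr - h, cc, drop = FALSE])
    E <- pmax(Eh, Ev)
    sub <- bestVal[rr, cc, drop = FALSE]
    take <- E > sub                       # strict: ties keep the smaller k
    sub[take] <- E[take]
    bestVal[rr, cc] <- sub
    subK <- bestK[rr, cc, drop = FALSE]
    subK[take] <- k
    if (k == 1L) subK[is.na(subK)] <- 1L  # all-zero differences: finest scale
    bestK[rr, cc] <- subK
  }
  mean(2^bestK[!is.na(bestK)])
}

#' Tamura contrast
#'
#' \eqn{F_{con} = \sigma / \alpha_4^{1/4}} with kurtosis
#' \eqn{\alpha_4 = \mu_4 / \sigma^4}, using population moments. Defined as 0
#' for a constant image.
#'
#' @param gray numeric intensity matrix.
#' @return nonnegative scalar.
#' @export
tamuraContrast <- function(gray) {
  if (!is.matrix(gray)) stop("'gray' must be a matrix", call. = FALSE)
  x <- as.vector(gray)
  s2 <- mean((x - mean(x))^2)
  if (s2 == 0) return(0)
  mu4 <- mean((x - mean(x))^4)
  alpha4 <- mu4 / s2^2
  sqrt(s2) / alpha4^0.25
}

#' Tamura directionality
#'
#' Prewitt 3x3 derivatives give a gradient magnitude
#' \eqn{|\Delta G| = (|\Delta_H| + |\Delta_V|)/2} and an orientation
#' \eqn{\phi = \mathrm{atan2}(\Delta_V, \Delta_H)} folded into \eqn{[0, \pi)}.
#' Orientations of pixels with \eqn{|\Delta G| \ge t} are histogrammed into
#' \code{nBins} bins; sharpness of the histogram's peaks is summarized as
#' \deqn{F_{dir} = 1 - n_{bins} \sum_p \sum_{\phi \in w_p}
#'   H_D(\phi) (\phi - \phi_p)^2 / (\pi^2/4),}
#' where peaks are circular local maxima above the histogram mean, windows
#' \eqn{w_p} extend to the adjacent valleys, and angle differences are
#' wrapped to \eqn{(-\pi/2, \pi/2]}. The value is clipped to \eqn{[0, 1]} and
#' defined as 0 when no pixel passes the gradient threshold.
#'
#' @param gray numeric intensity matrix on \eqn{[0, 1]} (side >= 3).
#' @param nBins number of orientation bins (default 16).
#' @param threshold gradient-magnitude threshold (default 0.1).
#' @return scalar in \eqn{[0, 1]}; 1 means a single dominant orientation.
#' @export
tamuraDirectionality <- function(gray, nBins = 16L, threshold = 0.1) {
  nBins <- stopifnotScalarCount(nBins, "nBins", min = 2L)
  if (!is.matrix(gray) || min(dim(gray)) < 3L)
    stop("'gray' must be a matrix with side >= 3", call. = FALSE)
  n <- nrow(gray); m <- ncol(gray)
  ri <- 2:(n - 1L); ci <- 2:(m - 1L)
  # Prewitt: column differences (right - left) and row differences
  dH <- (gray[ri - 1L, ci + 1L] + gray[ri, ci + 1L] + gray[ri + 1L, ci + 1L]) -
        (gray[ri - 1L, ci - 1L] + gray[ri, ci - 1L] + gray[ri + 1L, ci - 1L])
  dV <- (gray[ri + 1L, ci - 1L] + gray[ri + 1L, ci] + gray[ri + 1L, ci + 1L]) -
        (gray[ri - 1L, ci - 1L] + gray[ri - 1L, ci] + gray[ri - 1L, ci + 1L])
  mag <- (abs(dH) + abs(dV)) / 2
  keep <- mag >= threshold
  if (!any(keep)) return(0)
  phi <- atan2(dV[keep], dH[keep]) %% pi
  bin <- pmin(floor(phi / pi * nBins) + 1L, nBins)
  H <- tabulate(bin, nBins)
  H <- H / sum(H)

  centers <- (seq_len(nBins) - 0.5) * pi / nBins
  idx <- function(i) ((i - 1L) %% nBins) + 1L   # circular indexing
  mu <- mean(H)
  penalty <- 0
  for (p in seq_len(nBins)) {
    l <- H[idx(p - 1L)]; r <- H[idx(p + 1L)]
    if (!(H[p] > mu && H[p] > l && H[p] >= r)) next
    # window: walk to the adjacent valleys on each side
    wl <- p
    while (idx(wl - 1L) != p && H[idx(wl - 1L)] <= H[idx(wl)]) wl <- wl - 1L
    wr <- p
    while (idx(wr + 1L) != p && H[idx(wr + 1L)] <= H[idx(wr)]) wr <- wr + 1L
    for (b in wl:wr) {
      bb <- idx(b)
      d <- centers[bb] - centers[p]
      d <- ((d + pi / 2) %% pi) - pi / 2        # wrap to (-pi/2, pi/2]
      penalty <- penalty + H[bb] * d^2
    }
  }
  fdir <- 1 - nBins * penalty / (pi^2 / 4)
  min(max(fdir, 0), 1)
}
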