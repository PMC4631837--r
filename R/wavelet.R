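# 2-D discrete wavelet transform (separable, decimated) and the sub-band
# energy/entropy signatures. Filters are the standard Daubechies
# decomposition pairs; boundary handling is half-sample symmetric extension,
# the common choice in the energy-signature literature.

# orthonormal Daubechies decomposition low-pass filters (db1, db2, db4)
daubechiesFilters <- function(name) {
  lo <- switch(name,
    haar = , db1 = c(0.7071067811865476, 0.7071067811865476),
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    db4 = c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    stop("unsupported wavelet: ", name, call. = FALSE))
  L <- length(lo)
  # quadrature mirror: hi[k] = (-1)^k * lo[L - 1 - k] (0-based)
  hi <- rev(lo) * (-1)^(seq_len(L) - 1L)
  list(lo = lo, hi = hi)
}

# one analysis step along the columns of x (i.e. filtering each column),
# returning the decimated approximation and detail matrices
dwtStepCols <- function(x, lo, hi, boundary = "symmetric") {
  L <- length(lo); N <- nrow(x)
  if (N < L) stop("signal too short for the wavelet filter", call. = FALSE)
  ext <- switch(boundary,
    symmetric = rbind(x[(L - 1L):1L, , drop = FALSE], x,
                      x[N:(N - L + 2L), , drop = FALSE]),
    periodic = rbind(x[(N - L + 2L):N, , drop = FALSE], x,
                     x[1L:(L - 1L), , drop = FALSE]),
    stop("unsupported boundary mode: ", boundary, call. = FALSE))
  nv <- nrow(ext) - L + 1L
  take <- seq(2L, nv, by = 2L)
  conv1 <- function(f) {
    fr <- rev(f)
    out <- matrix(0, nv, ncol(x))
    for (s in seq_len(L)) # true convolution, vectorized over columns
      out <- out + fr[s] * ext[(s):(s + nv - 1L), , drop = FALSE]
    out[take, , drop = FALSE]
  }
  list(a = conv1(lo), d = conv1(hi))
}

# single-level 2-D DWT: returns LL plus the three detail sub-bands.
# "h" holds horizontal image structure (low-pass along rows of the image,
# high-pass across them), "v" vertical structure, "d" diagonal.
dwt2 <- function(x, lo, hi, boundary = "symmetric") {
  colStep <- dwtStepCols(x, lo, hi, boundary)
  rowA <- dwtStepCols(t(colStep$a), lo, hi, boundary)
  rowD <- dwtStepCols(t(colStep$d), lo, hi, boundary)
  list(ll = t(rowA$a),
       h = t(rowD$a),   # detail across rows, smooth along columns
       v = t(rowA$d),
       d = t(rowD$d))
}

#' Wavelet sub-band energy and entropy signatures
#'
#' Decomposes the image with a decimated 2-D discrete wavelet transform to
#' \code{levels} levels and, for each of the \code{3 * levels} high-frequency
#' sub-bands (horizontal/vertical/diagonal detail per level) with
#' coefficients \eqn{w_1 \ldots w_N}, computes the per-coefficient norms
#' \eqn{L^1 = N^{-1} \sum |w_i|}, \eqn{L^2 = (N^{-1} \sum w_i^2)^{1/2}} and
#' the Shannon entropy \eqn{-\sum q_i \log_2 q_i} of the normalized
#' coefficient energies \eqn{q_i = w_i^2 / \sum w^2} (0 for an all-zero
#' sub-band). Features are ordered by level, then sub-band (H, V, D), then
#' measure (L1, L2, entropy), named like \code{wav.lev1.h.L2}.
#'
#' @param gray numeric intensity matrix; both sides must be at least
#'   \code{2^levels}.
#' @param levels decomposition depth (default 4, giving 36 features).
#' @param wavelet \code{"db4"} (default), \code{"db2"} or \code{"haar"}.
#' @param boundary \code{"symmetric"} (default) or \code{"periodic"}.
#' @return named numeric vector of \code{9 * levels} features.
#' @export
waveletFeatures <- function(gray, levels = 4L, wavelet = "db4",
                            boundary = "symmetric") {
  levels <- stopifnotScalarCount(levels, "levels", min = 1L)
  if (!is.matrix(gray)) stop("'gray' must be a matrix", call. = FALSE)
  if (min(dim(gray)) < 2^levels)
    stop("image too small for ", levels, " decomposition levels",
         call. = FALSE)
  f <- daubechiesFilters(wavelet)
  out <- numeric(0)
  cur <- gray
  for (lev in seq_len(levels)) {
    dec <- dwt2(cur, f$lo, f$hi, boundary)
    # flush roundoff-level detail (a constant region has exactly zero detail
    # analytically; floating arithmetic leaves ~1e-16 residue)
    tol <- 1e-12 * max(1, max(abs(cur)))
    for (band in c("h", "v", "d")) {
      w <- as.vector(dec[[band]])
      w[abs(w) < tol] <- 0
      l1 <- mean(abs(w))
      l2 <- sqrt(mean(w^2))
      tot <- sum(w^2)
      ent <- if (tot == 0) 0 else {
        q <- w^2 / tot
        q <- q[q > 0]
        -sum(q * log2(q))
      }
      v <- c(l1, l2, ent)
      names(v) <- sprintf("wav.lev%d.%s.%s", lev, band, c("L1", "L2", "ent"))
      out <- c(out, v)
    }
    cur <- dec$ll
  }
  out
}
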