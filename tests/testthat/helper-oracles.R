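# independent oracles used across tests; deliberately naive implementations

# brute-force GLCM: double loop over every pixel and the literal offset
bruteGLCM <- function(gray, d, angle, levels, symmetric = TRUE) {
  off <- switch(as.character(angle),
    "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0), "135" = c(-d, -d))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(gray))) {
    for (c in seq_len(ncol(gray))) {
      r2 <- r + off[1]; c2 <- c + off[2]
      if (r2 >= 1 && r2 <= nrow(gray) && c2 >= 1 && c2 <= ncol(gray)) {
        i <- gray[r, c] + 1L; j <- gray[r2, c2] + 1L
        counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  if (symmetric) counts <- counts + t(counts)
  counts / sum(counts)
}

# dense matrix-arithmetic Laplacian Score
denseLS <- function(X, graph) {
  S <- graph@S
  D <- diag(rowSums(S))
  L <- D - S
  one <- rep(1, nrow(X))
  vapply(seq_len(ncol(X)), function(r) {
    f <- X[, r]
    ft <- f - as.numeric(t(f) %*% D %*% one) /
      as.numeric(t(one) %*% D %*% one) * one
    as.numeric(t(ft) %*% L %*% ft) / as.numeric(t(ft) %*% D %*% ft)
  }, numeric(1))
}

# hand RGB -> HSV for a single pixel (hue on [0,1])
handHSV <- function(r, g, b) {
  mx <- max(r, g, b); mn <- min(r, g, b); d <- mx - mn
  v <- mx
  s <- if (mx == 0) 0 else d / mx
  h <- if (d == 0) 0
  else if (mx == r) (((g - b) / d) %% 6) / 6
  else if (mx == g) ((b - r) / d + 2) / 6
  else ((r - g) / d + 4) / 6
  c(h = h, s = s, v = v)
}

# tiny fully-specified linear hierarchy for simulation contracts
tinyHierarchy <- function(interceptG1 = 0) {
  f <- paste0("f", 1:10)
  lin <- function(target, inputs, vars, coefs, intercept) {
    terms <- data.frame(kind = "variable", input1 = vars,
                        input2 = NA_character_, transform = "identity",
                        coefficient = coefs, stringsAsFactors = FALSE)
    if (!length(vars)) terms <- terms[0, ]
    new("LayerModel", target = target, terms = terms,
        intercept = intercept, inputNames = inputs)
  }
  jIn <- c(f, paste0("G", 1:3)); eIn <- c(jIn, paste0("T", 1:4))
  new("HierarchyModel",
      affective = list(lin("G1", f, "f1", 10, interceptG1),
                       lin("G2", f, "f2", -5, 1),
                       lin("G3", f, "f3", 20, -2)),
      judgment = list(lin("T1", jIn, c("f4", "G1"), c(8, 0.5), 0),
                      lin("T2", jIn, "f5", 12, 3),
                      lin("T3", jIn, c("f6", "G3"), c(-7, 0.4), 1),
                      lin("T4", jIn, "f7", 9, -1)),
      emotional = list(lin("Q", eIn, c("f8", "G2", "T1"),
                           c(6, 0.3, 0.6), 2)),
      scaling = list(), provenance = "planted")
}

# reduced-form relative discrepancy between two linear hierarchies
reducedFormError <- function(h1, h2) {
  A <- reducedFormCoefficients(h1)
  B <- reducedFormCoefficients(h2)
  max(vapply(rownames(A), function(p)
    max(abs(B[p, ] - A[p, ])) / max(abs(A[p, ])), numeric(1)))
}

# recovery-study fit configuration: linear library (the planted truth is
# linear), headroom above the planted model sizes, entry guard off so every
# true term can enter on noise-free data
recoveryFitConfig <- function(seed, minGain = 1e-3) {
  fitConfig(squares = FALSE, products = FALSE, maxTerms = 12L,
            fTest = FALSE, minGain = minGain, seed = seed)
}
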