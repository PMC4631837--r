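#' Build the kNN heat-kernel affinity graph
#'
#' Connects each sample to its \code{k} nearest Euclidean neighbours
#' (distance ties at the k-th neighbour are all included, so exactly
#' duplicated samples stay mutually connected), symmetrises the edge set by
#' union, and weights edges with the heat kernel
#' \eqn{S_{ij} = \exp(-\|x_i - x_j\|^2 / t)}. Features should be pre-scaled
#' (see [scaleFeatures()]) so distances are commensurate.
#'
#' @param X numeric sample x feature matrix with at least \code{k + 1} rows.
#' @param k neighbourhood size (default 5).
#' @param t kernel bandwidth; defaults to the mean squared distance over the
#'   graph's edges (a self-tuning choice).
#' @return an [AffinityGraph-class].
#' @export
buildAffinityGraph <- function(X, k = 5L, t = NULL) {
  if (!is.matrix(X)) X <- as.matrix(X)
  n <- nrow(X)
  k <- stopifnotScalarCount(k, "k", min = 1L)
  if (k >= n)
    stop("'k' must be smaller than the number of samples", call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    d <- D2[i, ]; d[i] <- Inf
    kth <- sort(d, partial = k)[k]
    adj[i, d <= kth] <- TRUE
  }
  adj <- adj | t(adj)                      # union symmetrisation
  diag(adj) <- FALSE
  if (is.null(t)) {
    ed <- D2[adj]
    t <- mean(ed)
    if (!is.finite(t) || t <= 0) t <- 1    # all-duplicate degenerate case
  }
  S <- matrix(0, n, n)
  S[adj] <- exp(-D2[adj] / t)
  deg <- rowSums(S)
  if (any(deg == 0))
    warning("affinity graph has isolated samples (zero degree)")
  new("AffinityGraph", S = S, degree = deg, laplacian = diag(deg) - S,
      params = list(k = k, t = t))
}

#' Laplacian Scores of feature columns
#'
#' For each feature column \eqn{f_r}, removes the degree-weighted mean,
#' \eqn{\tilde f_r = f_r - (f_r^T D \mathbf{1} / \mathbf{1}^T D \mathbf{1})
#' \mathbf{1}}, and scores
#' \eqn{L_r = \tilde f_r^T L \tilde f_r / \tilde f_r^T D \tilde f_r}, the
#' ratio of the graph-Laplacian to the degree-weighted quadratic form. A
#' constant feature has a vanishing denominator and receives the sentinel
#' \code{NA} with a warning; [selectFeatures()] always ranks sentinels last.
#'
#' @param X sample x feature matrix (same samples as the graph).
#' @param graph an [AffinityGraph-class] from [buildAffinityGraph()].
#' @return named numeric vector of scores, one per feature column.
#' @export
laplacianScores <- function(X, graph) {
  stopifnot(is(graph, "AffinityGraph"))
  if (!is.matrix(X)) X <- as.matrix(X)
  if (nrow(X) != nrow(graph@S))
    stop("'X' and the graph must describe the same samples", call. = FALSE)
  d <- graph@degree
  L <- graph@laplacian
  sumD <- sum(d)
  scores <- vapply(seq_len(ncol(X)), function(r) {
    f <- X[, r]
    ft <- f - sum(f * d) / sumD
    den <- sum(ft * d * ft)
    if (den <= .Machine$double.eps * max(1, sum(f^2))) return(NA_real_)
    as.numeric(ft %*% L %*% ft) / den
  }, numeric(1))
  if (anyNA(scores))
    warning("constant feature(s) received the sentinel score NA: ",
            paste(colnames(X)[is.na(scores)], collapse = ", "))
  names(scores) <- colnames(X)
  scores
}

#' Rank features and retain a working subset
#'
#' Features are ranked by Laplacian score. The importance direction is a
#' documented configuration: by default a higher score is more important.
#' (The original Laplacian-Score formulation treats small scores as locality
#' preserving; empirical feature tables in this domain list the retained
#' features with the largest scores first, which is the default here —
#' set \code{higherIsBetter = FALSE} for the opposite convention.)
#' Ties, and the \code{NA} sentinel of constant features (always last), are
#' broken by original feature order.
#'
#' @param scores named numeric vector from [laplacianScores()].
#' @param mode \code{"top_k"} (keep the \code{value} best-ranked features,
#'   default 10) or \code{"threshold"} (keep scores passing \code{value},
#'   i.e. \code{>= value} when higher is better, \code{<= value} otherwise).
#' @param value the k or the threshold.
#' @param higherIsBetter logical, default \code{TRUE}.
#' @return a [SelectionResult-class].
#' @examples
#' selectFeatures(c(a = .9, b = .5, c = .7), mode = "top_k", value = 2)
#' @export
selectFeatures <- function(scores, mode = c("top_k", "threshold"),
                           value = 10, higherIsBetter = TRUE) {
  mode <- match.arg(mode)
  if (is.null(names(scores)))
    names(scores) <- sprintf("feature%03d", seq_along(scores))
  key <- if (higherIsBetter) -scores else scores
  ranking <- order(key, seq_along(scores), na.last = TRUE)
  if (mode == "top_k") {
    value <- stopifnotScalarCount(value, "value", min = 1L)
    if (value > length(scores))
      stop("cannot select ", value, " of ", length(scores), " features",
           call. = FALSE)
    keep <- ranking[seq_len(value)]
  } else {
    ok <- if (higherIsBetter) !is.na(scores) & scores >= value
          else !is.na(scores) & scores <= value
    keep <- ranking[ok[ranking]]
  }
  new("SelectionResult", scores = scores, ranking = as.integer(ranking),
      selected = names(scores)[keep],
      params = list(mode = mode, value = value,
                    higherIsBetter = higherIsBetter))
}

#' Write a selection report
#'
#' One row per feature: name, Laplacian score, rank and whether it was
#' retained. Companion [writeSelectionJSON()] stores the retained names as a
#' manifest consumed by the modelling stage.
#'
#' @param sel a [SelectionResult-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSelectionCSV <- function(sel, path) {
  stopifnot(is(sel, "SelectionResult"))
  nm <- names(sel@scores)
  rank <- match(seq_along(nm), sel@ranking)
  df <- data.frame(name = nm, score = unname(sel@scores), rank = rank,
                   kept = nm %in% sel@selected)
  utils::write.csv(df[order(df$rank), ], path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSelectionCSV
#' @export
writeSelectionJSON <- function(sel, path) {
  stopifnot(is(sel, "SelectionResult"))
  jsonlite::write_json(
    list(selected = sel@selected, mode = sel@params$mode,
         value = sel@params$value,
         higherIsBetter = sel@params$higherIsBetter),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
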