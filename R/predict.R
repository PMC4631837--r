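# cascade prediction through the three layers

# evaluate one LayerModel on a data matrix whose columns cover inputNames
predictLayer <- function(model, data) {
  stopifnot(is(model, "LayerModel"))
  miss <- setdiff(unique(c(model@terms$input1,
                           model@terms$input2[model@terms$kind == "product"])),
                  colnames(data))
  if (length(miss))
    stop("missing model input(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  D <- termDesign(model@terms, data)
  base <- if (ncol(D)) as.vector(D %*% model@terms$coefficient)
          else rep(0, nrow(data))
  base + model@intercept
}

#' Predict all eight aesthetic properties through the cascade
#'
#' The affective properties G1..G3 are predicted from the ten features; the
#' judgment properties T1..T4 from the features plus the (overridden or
#' predicted) affective values; like-dislike Q from features plus both lower
#' layers. Observed lower-layer values — e.g. interview data — can be
#' substituted for the predictions via \code{overrides}.
#'
#' @param h a [HierarchyModel-class].
#' @param features numeric vector of 10 scaled features (names
#'   \code{f1...f10}; unnamed vectors are taken in that order) or a matrix
#'   with one row per texture.
#' @param overrides optional named list with entries \code{G} (length-3) and
#'   /or \code{T} (length-4), each a vector or a matrix matching
#'   \code{features}; an override replaces the layer's predictions both in
#'   the output and as input to the layers above.
#' @return matrix with one row per texture and columns G1..G3, T1..T4, Q,
#'   with attribute \code{"overridden"} naming substituted properties.
#' @examples
#' predictCascade(referenceModel(), rep(0, 10))
#' @export
predictCascade <- function(h, features, overrides = NULL) {
  stopifnot(is(h, "HierarchyModel"))
  if (is.null(dim(features)))
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  nf <- length(h@affective[[1]]@inputNames)
  if (ncol(features) != nf)
    stop("expected ", nf, " features, got ", ncol(features), call. = FALSE)
  if (is.null(colnames(features)))
    colnames(features) <- h@affective[[1]]@inputNames

  asLayerMat <- function(x, p, what) {
    if (is.null(x)) return(NULL)
    if (is.null(dim(x))) x <- matrix(x, nrow = nrow(features), ncol = p,
                                     byrow = nrow(features) > 1L && length(x) == p)
    if (!all(dim(x) == c(nrow(features), p)))
      stop("override for ", what, " must supply ", p,
           " values per texture", call. = FALSE)
    x
  }
  ovG <- asLayerMat(overrides$G, 3L, "G")
  ovT <- asLayerMat(overrides$T, 4L, "T")

  G <- if (is.null(ovG))
    vapply(h@affective, predictLayer, numeric(nrow(features)),
           data = features) |> matrix(nrow = nrow(features)) else ovG
  colnames(G) <- paste0("G", 1:3)
  dataGT <- cbind(features, G)
  T_ <- if (is.null(ovT))
    vapply(h@judgment, predictLayer, numeric(nrow(features)),
           data = dataGT) |> matrix(nrow = nrow(features)) else ovT
  colnames(T_) <- paste0("T", 1:4)
  Q <- predictLayer(h@emotional[[1]], cbind(dataGT, T_))

  out <- cbind(G, T_, Q = Q)
  attr(out, "overridden") <- c(if (!is.null(ovG)) paste0("G", 1:3),
                               if (!is.null(ovT)) paste0("T", 1:4))
  out
}
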