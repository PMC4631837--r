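#' @import methods
NULL

#' TextureImage: a raster texture with a colour-space tag
#'
#' Container for a single texture stimulus. Pixels are stored as a numeric
#' array on \eqn{[0, 1]}: either \code{height x width} (colorspace
#' \code{"GRAY"}) or \code{height x width x 3} (colorspace \code{"RGB"}).
#' Feature extraction requires both sides to be at least 32 pixels; smaller
#' images can be constructed (they are convenient for unit arithmetic) but
#' are rejected by [extractFeatures()].
#'
#' @slot pixels numeric array, values on \eqn{[0, 1]}.
#' @slot colorspace either \code{"RGB"} or \code{"GRAY"}.
#'
#' @seealso [TextureImage()], [readTextureImage()], [extractFeatures()]
#' @export
setClass("TextureImage",
  representation(pixels = "array", colorspace = "character"))

setValidity("TextureImage", function(object) {
  msgs <- character()
  nd <- length(dim(object@pixels))
  if (!(object@colorspace %in% c("RGB", "GRAY")))
    msgs <- c(msgs, "colorspace must be 'RGB' or 'GRAY'")
  if (object@colorspace == "RGB" && !(nd == 3L && dim(object@pixels)[3] == 3L))
    msgs <- c(msgs, "RGB images need a height x width x 3 pixel array")
  if (object@colorspace == "GRAY" && nd != 2L)
    msgs <- c(msgs, "GRAY images need a height x width pixel array")
  if (anyNA(object@pixels) || !all(is.finite(object@pixels)))
    msgs <- c(msgs, "pixel values must be finite")
  else if (min(object@pixels) < 0 || max(object@pixels) > 1)
    msgs <- c(msgs, "pixel values must lie in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' AffinityGraph: kNN heat-kernel graph for the Laplacian Score
#'
#' Symmetric nonnegative weight matrix \eqn{S} on union-symmetrised
#' k-nearest-neighbour edges with heat-kernel weights
#' \eqn{S_{ij} = \exp(-\|x_i - x_j\|^2 / t)}, its degree vector
#' \eqn{D_{ii} = \sum_j S_{ij}} and graph Laplacian \eqn{L = D - S}.
#'
#' @slot S symmetric n x n weight matrix.
#' @slot degree numeric vector of row sums of \code{S}.
#' @slot laplacian the matrix \code{diag(degree) - S}.
#' @slot params list with the \code{k} and bandwidth \code{t} used.
#'
#' @seealso [buildAffinityGraph()], [laplacianScores()]
#' @export
setClass("AffinityGraph",
  representation(S = "matrix", degree = "numeric", laplacian = "matrix",
                 params = "list"))

setValidity("AffinityGraph", function(object) {
  msgs <- character()
  if (nrow(object@S) != ncol(object@S))
    msgs <- c(msgs, "S must be square")
  else {
    if (max(abs(object@S - t(object@S))) > 1e-10)
      msgs <- c(msgs, "S must be symmetric")
    if (any(object@S < 0)) msgs <- c(msgs, "S must be nonnegative")
    if (length(object@degree) != nrow(object@S))
      msgs <- c(msgs, "degree length must match S")
  }
  if (length(msgs)) msgs else TRUE
})

#' SelectionResult: Laplacian-Score ranking and retained subset
#'
#' @slot scores named numeric vector of per-feature Laplacian scores
#'   (\code{NA} marks the constant-feature sentinel, always ranked last).
#' @slot ranking integer permutation of \code{seq_along(scores)}, most
#'   important feature first.
#' @slot selected character vector of retained feature names, in rank order.
#' @slot params list: selection \code{mode}, its \code{value}, and
#'   \code{higherIsBetter}.
#'
#' @seealso [laplacianScores()], [selectFeatures()]
#' @export
setClass("SelectionResult",
  representation(scores = "numeric", ranking = "integer",
                 selected = "character", params = "list"))

setValidity("SelectionResult", function(object) {
  msgs <- character()
  if (!identical(sort(object@ranking), seq_along(object@scores)))
    msgs <- c(msgs, "ranking must be a permutation of the feature indices")
  if (length(object@selected) > length(object@scores))
    msgs <- c(msgs, "cannot select more features than scored")
  if (length(msgs)) msgs else TRUE
})

#' LayerModel: one fitted (or transcribed) aesthetic-property equation
#'
#' A single property model is an intercept plus a list of weighted terms over
#' the allowed inputs of its layer. Terms are rows of a data.frame with
#' columns \code{kind} (\code{"variable"}, \code{"square"}, \code{"product"},
#' \code{"unary"}), \code{input1}, \code{input2} (only for products),
#' \code{transform} (function tag, \code{"identity"} unless \code{kind ==
#' "unary"}) and \code{coefficient}.
#'
#' @slot target property code, e.g. \code{"G1"} or \code{"Q"}.
#' @slot terms data.frame of terms as described above (0 rows for an
#'   intercept-only model).
#' @slot intercept numeric scalar.
#' @slot inputNames ordered character vector of inputs the model may use.
#'
#' @seealso [referenceModel()], [fitLayerModel()], [modelComplexity()]
#' @export
setClass("LayerModel",
  representation(target = "character", terms = "data.frame",
                 intercept = "numeric", inputNames = "character"))

setValidity("LayerModel", function(object) {
  msgs <- character()
  tt <- object@terms
  need <- c("kind", "input1", "input2", "transform", "coefficient")
  if (!all(need %in% names(tt)))
    return(paste("terms must have columns:", paste(need, collapse = ", ")))
  if (nrow(tt)) {
    if (!all(tt$kind %in% c("variable", "square", "product", "unary")))
      msgs <- c(msgs, "unknown term kind")
    used <- c(tt$input1, tt$input2[tt$kind == "product"])
    if (!all(used %in% object@inputNames))
      msgs <- c(msgs, "term inputs must be among inputNames")
    if (any(tt$kind == "product" & (is.na(tt$input2) | tt$input2 == "")))
      msgs <- c(msgs, "product terms need two inputs")
    if (!all(is.finite(tt$coefficient)))
      msgs <- c(msgs, "coefficients must be finite")
  }
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msgs <- c(msgs, "intercept must be a finite scalar")
  if (length(msgs)) msgs else TRUE
})

#' HierarchyModel: the three-layer feed-forward perception model
#'
#' The affective layer (warm-cold, rough-smooth, dark-light) is modelled from
#' the 10 selected texture features; the judgment layer
#' (disordered-harmonious, inelegant-elegant, simple-complex,
#' artificial-natural) from features plus the 3 affective properties (13
#' inputs); the emotional layer (like-dislike) from features plus all lower
#' properties (17 inputs). Judgment models never reference T or Q and
#' affective models reference features only, which the validity method
#' enforces.
#'
#' @slot affective list of 3 [LayerModel-class] (targets G1, G2, G3).
#' @slot judgment list of 4 [LayerModel-class] (targets T1..T4).
#' @slot emotional list of 1 [LayerModel-class] (target Q).
#' @slot scaling feature-scaling metadata (list with per-feature \code{min},
#'   \code{max} and target interval \code{lo}, \code{hi}), or an empty list
#'   when inputs are assumed already scaled.
#' @slot provenance \code{"reference"}, \code{"fitted"} or \code{"planted"}.
#'
#' @seealso [referenceModel()], [fitHierarchy()], [predictCascade()]
#' @export
setClass("HierarchyModel",
  representation(affective = "list", judgment = "list", emotional = "list",
                 scaling = "list", provenance = "character"))

setValidity("HierarchyModel", function(object) {
  msgs <- character()
  if (length(object@affective) != 3L) msgs <- c(msgs, "need 3 affective models")
  if (length(object@judgment) != 4L) msgs <- c(msgs, "need 4 judgment models")
  if (length(object@emotional) != 1L) msgs <- c(msgs, "need 1 emotional model")
  all8 <- c(object@affective, object@judgment, object@emotional)
  if (!all(vapply(all8, is, logical(1), class2 = "LayerModel")))
    return("all layer entries must be LayerModel objects")
  gNames <- paste0("G", 1:3); tNames <- paste0("T", 1:4)
  for (m in object@affective)
    if (any(c(gNames, tNames, "Q") %in% m@inputNames))
      msgs <- c(msgs, "affective models may use features only")
  for (m in object@judgment)
    if (any(c(tNames, "Q") %in% m@inputNames))
      msgs <- c(msgs, "judgment models may not use T or Q")
  if (length(msgs)) msgs else TRUE
})

#' SimulatedExperiment: a simulated semantic-differential rating study
#'
#' Raw per-rater, per-repetition ratings on the continuous \eqn{[-100, 100]}
#' antonym scales, together with the per-texture averages used for modelling.
#'
#' @slot raw 4-D numeric array \code{texture x property x rater x repetition},
#'   already clipped to the rating range.
#' @slot ratings matrix \code{texture x property} of averaged ratings.
#' @slot trueValues matrix of noise-free planted cascade values (pre-clip).
#' @slot design list: \code{nRaters}, \code{nReps}, \code{clip} range, noise
#'   standard deviations and the seed.
#'
#' @seealso [simulateRatings()], [makeBenchmarkDataset()]
#' @export
setClass("SimulatedExperiment",
  representation(raw = "array", ratings = "matrix", trueValues = "matrix",
                 design = "list"))

setValidity("SimulatedExperiment", function(object) {
  d <- dim(object@raw)
  if (length(d) != 4L) return("raw must be a 4-D array")
  if (!identical(d[1:2], dim(object@ratings)))
    return("ratings must be texture x property")
  clip <- object@design$clip
  if (!is.null(clip) && (min(object@raw) < clip[1] || max(object@raw) > clip[2]))
    return("raw ratings must respect the clip range")
  TRUE
})
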