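#' Accessor generics
#'
#' Small accessor family for the package's S4 classes: \code{pixels} and
#' \code{colorspace} for [TextureImage-class]; \code{lsScores},
#' \code{featureRanking} and \code{selectedFeatures} for
#' [SelectionResult-class]; \code{layerTerms}, \code{intercept} and
#' \code{inputNames} for [LayerModel-class]; \code{layerModels} and
#' \code{featureScaling} for [HierarchyModel-class]; \code{ratingsTable} and
#' \code{rawRatings} for [SimulatedExperiment-class].
#'
#' @param x an object of the relevant class.
#' @param ... unused.
#' @return The slot contents (see each class's documentation).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x, ...) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("colorspace", function(x, ...) standardGeneric("colorspace"))
#' @rdname accessors
#' @export
setGeneric("lsScores", function(x, ...) standardGeneric("lsScores"))
#' @rdname accessors
#' @export
setGeneric("featureRanking", function(x, ...) standardGeneric("featureRanking"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x, ...) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("layerTerms", function(x, ...) standardGeneric("layerTerms"))
#' @rdname accessors
#' @export
setGeneric("intercept", function(x, ...) standardGeneric("intercept"))
#' @rdname accessors
#' @export
setGeneric("inputNames", function(x, ...) standardGeneric("inputNames"))
#' @rdname accessors
#' @export
setGeneric("layerModels", function(x, ...) standardGeneric("layerModels"))
#' @rdname accessors
#' @export
setGeneric("featureScaling", function(x, ...) standardGeneric("featureScaling"))
#' @rdname accessors
#' @export
setGeneric("ratingsTable", function(x, ...) standardGeneric("ratingsTable"))
#' @rdname accessors
#' @export
setGeneric("rawRatings", function(x, ...) standardGeneric("rawRatings"))

#' @rdname accessors
#' @export
setMethod("pixels", "TextureImage", function(x, ...) x@pixels)
#' @rdname accessors
#' @export
setMethod("colorspace", "TextureImage", function(x, ...) x@colorspace)
#' @rdname accessors
#' @export
setMethod("lsScores", "SelectionResult", function(x, ...) x@scores)
#' @rdname accessors
#' @export
setMethod("featureRanking", "SelectionResult", function(x, ...) x@ranking)
#' @rdname accessors
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x, ...) x@selected)
#' @rdname accessors
#' @export
setMethod("layerTerms", "LayerModel", function(x, ...) x@terms)
#' @rdname accessors
#' @export
setMethod("intercept", "LayerModel", function(x, ...) x@intercept)
#' @rdname accessors
#' @export
setMethod("inputNames", "LayerModel", function(x, ...) x@inputNames)
#' @rdname accessors
#' @export
setMethod("layerModels", "HierarchyModel", function(x, ...) {
  mods <- c(x@affective, x@judgment, x@emotional)
  names(mods) <- vapply(mods, function(m) m@target, character(1))
  mods
})
#' @rdname accessors
#' @export
setMethod("featureScaling", "HierarchyModel", function(x, ...) x@scaling)
#' @rdname accessors
#' @export
setMethod("ratingsTable", "SimulatedExperiment", function(x, ...) x@ratings)
#' @rdname accessors
#' @export
setMethod("rawRatings", "SimulatedExperiment", function(x, ...) x@raw)

setMethod("show", "TextureImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("TextureImage %dx%d [%s], intensity range [%.3f, %.3f]\n",
              d[1], d[2], object@colorspace,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "AffinityGraph", function(object) {
  cat(sprintf("AffinityGraph on %d samples (k = %s, t = %.4g), %d edges\n",
              nrow(object@S), object@params$k, object@params$t,
              sum(object@S[upper.tri(object@S)] > 0)))
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: %d features scored, %d selected (%s)\n",
              length(object@scores), length(object@selected),
              object@params$mode))
  top <- utils::head(object@selected, 5L)
  if (length(top)) cat("  top:", paste(top, collapse = ", "), "\n")
})

setMethod("show", "LayerModel", function(object) {
  cat(sprintf("LayerModel for %s: %d term(s) + intercept %.4g\n",
              object@target, nrow(object@terms), object@intercept))
})

setMethod("show", "HierarchyModel", function(object) {
  cat(sprintf("HierarchyModel (%s): 3 affective + 4 judgment + 1 emotional\n",
              object@provenance))
  for (m in layerModels(object))
    cat(sprintf("  %-3s %d term(s)\n", m@target, nrow(m@terms)))
})

setMethod("show", "SimulatedExperiment", function(object) {
  d <- dim(object@raw)
  cat(sprintf(
    "SimulatedExperiment: %d textures x %d properties, %d raters x %d reps\n",
    d[1], d[2], d[3], d[4]))
})
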