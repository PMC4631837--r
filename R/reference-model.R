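#' The published reference hierarchy
#'
#' Returns the eight aesthetic-property equations with coefficients
#' transcribed verbatim from the published study, assembled as a
#' [HierarchyModel-class] with provenance \code{"reference"}. Inputs
#' \code{f1...f10} are the Laplacian-Score-selected features scaled to
#' \eqn{[-1, 1]} (see [referenceFeatureNames()] for what each f maps to in
#' the feature bank); the rough-smooth slope of \code{-1.31e-13} is kept
#' exactly as printed, which makes that property effectively constant at its
#' intercept. The dark-light model is the only non-linear one (one product
#' and one squared term).
#'
#' @return a [HierarchyModel-class].
#' @examples
#' h <- referenceModel()
#' vapply(layerModels(h), function(m) nrow(layerTerms(m)), integer(1))
#' @export
referenceModel <- function() {
  f <- paste0("f", 1:10)
  affIn <- f
  judIn <- c(f, paste0("G", 1:3))
  emoIn <- c(f, paste0("G", 1:3), paste0("T", 1:4))

  lm1 <- function(target, inputs, vars, coefs, intercept, extra = NULL) {
    terms <- makeTerms("variable", vars, coefficient = coefs)
    if (!is.null(extra)) terms <- rbind(terms, extra)
    new("LayerModel", target = target, terms = terms, intercept = intercept,
        inputNames = inputs)
  }

  g1 <- lm1("G1", affIn, c("f1", "f3", "f5", "f7", "f9", "f10"),
            c(0.03, 598.16, -234.19, -348.67, 189.82, -304.29), 22.17)
  g2 <- lm1("G2", affIn, "f10", -1.31e-13, -1.73)
  g3extra <- rbind(
    makeTerms("product", "f1", "f7", coefficient = -0.34),
    makeTerms("square", "f9", coefficient = 216.71))
  g3 <- lm1("G3", affIn, c("f1", "f7", "f5", "f9"),
            c(0.29, 83.14, -53.82, -214.60), 19.22, extra = g3extra)

  t1 <- lm1("T1", judIn, c("f1", "f6", "f7", "f9", "f10", "G3"),
            c(0.03, 119.55, -106.46, 18.21, -51.51, 0.76), 2.86)
  t2 <- lm1("T2", judIn, c("f1", "f3", "f4", "f6", "f7", "f8", "G3"),
            c(0.09, 691.81, -737.98, -609.32, 683.64, -66.11, 0.33), -9.60)
  t3 <- lm1("T3", judIn, c("f2", "f3", "f4", "f7", "f8", "f9"),
            c(1135.64, -1123.31, -582.81, 571.40, -364.15, 376.91), -14.60)
  t4 <- lm1("T4", judIn, c("f2", "f3", "f4", "f8", "f9", "G1"),
            c(185.17, 68.26, -215.02, -99.79, 129.36, -0.15), 24.37)

  q <- lm1("Q", emoIn, c("f2", "f3", "f8", "f9", "T1", "T3"),
           c(123.09, -144.83, -113.49, -148.05, 0.64, 0.12), 1.14)

  new("HierarchyModel", affective = list(g1, g2, g3),
      judgment = list(t1, t2, t3, t4), emotional = list(q),
      scaling = list(), provenance = "reference")
}

#' Feature-bank names behind the reference model's f1...f10
#'
#' The ten retained features, in rank order: mean saturation; GLCM contrast
#' at (d=8, 45°), (d=6, 45°), (d=8, 135°), (d=8, 90°), (d=4, 45°); Tamura
#' coarseness and directionality; and the level-1 horizontal and vertical
#' wavelet L2 norms.
#'
#' @return named character vector mapping \code{f1...f10} to stable feature
#'   names of [extractFeatures()].
#' @export
referenceFeatureNames <- function() {
  c(f1 = "color.sat.mean",
    f2 = "glcm.d8.t45.contrast",
    f3 = "glcm.d6.t45.contrast",
    f4 = "glcm.d8.t135.contrast",
    f5 = "glcm.d8.t90.contrast",
    f6 = "glcm.d4.t45.contrast",
    f7 = "tamura.coarseness",
    f8 = "tamura.directionality",
    f9 = "wav.lev1.h.L2",
    f10 = "wav.lev1.v.L2")
}
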