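#' Feature-space reduced form of a linear hierarchy
#'
#' Composes the three layers of a purely linear hierarchy into, for each of
#' the eight properties, an affine function of the features alone:
#' judgment-layer references to affective properties are replaced by the
#' affective equations, and emotional-layer references by both. The reduced
#' form is the natural object for comparing two hierarchies: a layered
#' linear model is identified only up to substitution of a lower-layer
#' property by its own feature expansion (the data cannot distinguish
#' \eqn{\gamma G} from \eqn{\gamma} times G's equation), while the induced
#' feature-space map is unique.
#'
#' @param h a [HierarchyModel-class] whose models contain only plain
#'   \code{variable} terms (fitted or planted linear hierarchies; an error
#'   is raised otherwise).
#' @return numeric matrix with one row per property (G1..Q) and one column
#'   per feature plus \code{"(intercept)"}.
#' @examples
#' ph <- plantHierarchy(seed = 3)
#' reducedFormCoefficients(ph)["Q", ]
#' @export
reducedFormCoefficients <- function(h) {
  stopifnot(is(h, "HierarchyModel"))
  mods <- layerModels(h)
  if (!all(vapply(mods, function(m) all(m@terms$kind == "variable"),
                  logical(1))))
    stop("reduced form is defined for purely linear hierarchies only",
         call. = FALSE)
  feat <- mods[[1]]@inputNames
  nF <- length(feat)
  red <- matrix(0, length(mods), nF + 1L,
                dimnames = list(names(mods), c(feat, "(intercept)")))
  for (p in names(mods)) {
    m <- mods[[p]]
    vec <- stats::setNames(numeric(nF + 1L), colnames(red))
    vec["(intercept)"] <- m@intercept
    for (i in seq_len(nrow(m@terms))) {
      v <- m@terms$input1[i]; coef <- m@terms$coefficient[i]
      if (v %in% feat) {
        vec[v] <- vec[v] + coef
      } else {
        # lower-layer reference: add coef * its (already reduced) row
        vec <- vec + coef * red[v, ]
      }
    }
    red[p, ] <- vec
  }
  red
}
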