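#' Save and load hierarchy models as JSON
#'
#' The file stores, per property model, the target, the term list (kind,
#' inputs, transform, coefficient), the intercept and the allowed inputs,
#' plus the hierarchy's scaling metadata and provenance. Numbers are written
#' at full precision so a save/load round trip is lossless.
#'
#' @param h a [HierarchyModel-class].
#' @param path JSON file path.
#' @return \code{writeHierarchyJSON}: the path, invisibly;
#'   \code{readHierarchyJSON}: a [HierarchyModel-class].
#' @export
writeHierarchyJSON <- function(h, path) {
  stopifnot(is(h, "HierarchyModel"))
  ser <- function(m) list(
    target = m@target,
    terms = m@terms,
    intercept = m@intercept,
    inputNames = m@inputNames)
  scaling <- h@scaling
  if (length(scaling)) {  # keep feature names: named lists serialize as objects
    scaling$min <- as.list(scaling$min)
    scaling$max <- as.list(scaling$max)
  }
  payload <- list(
    provenance = h@provenance,
    scaling = scaling,
    affective = lapply(h@affective, ser),
    judgment = lapply(h@judgment, ser),
    emotional = lapply(h@emotional, ser))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname writeHierarchyJSON
#' @export
readHierarchyJSON <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  des <- function(x) {
    tt <- if (length(x$terms)) as.data.frame(x$terms) else emptyTerms()
    if (nrow(tt)) {
      if (!"input2" %in% names(tt)) tt$input2 <- NA_character_
      tt$input2 <- as.character(tt$input2)
      tt$input2[tt$kind != "product"] <- NA_character_
      tt$kind <- as.character(tt$kind)
      tt$input1 <- as.character(tt$input1)
      tt$transform <- as.character(tt$transform)
      tt$coefficient <- as.numeric(tt$coefficient)
    }
    tt <- tt[, c("kind", "input1", "input2", "transform", "coefficient")]
    new("LayerModel", target = as.character(x$target), terms = tt,
        intercept = as.numeric(x$intercept),
        inputNames = as.character(unlist(x$inputNames)))
  }
  sc <- if (length(p$scaling)) {
    s <- p$scaling
    list(min = unlist(s$min), max = unlist(s$max), lo = s$lo, hi = s$hi)
  } else list()
  deserLayer <- function(lst) {
    # jsonlite may simplify a list of records into a data.frame
    if (is.data.frame(lst)) lst <- split(lst, seq_len(nrow(lst)))
    lapply(lst, des)
  }
  new("HierarchyModel",
      affective = deserLayer(p$affective),
      judgment = deserLayer(p$judgment),
      emotional = deserLayer(p$emotional),
      scaling = sc, provenance = p$provenance)
}
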