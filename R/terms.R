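# term library: candidate basis functions over a set of named inputs, and
# their evaluation into design-matrix columns

unaryFuns <- list(identity = identity, square = function(x) x^2,
                  sqrt = sqrt, log = log, exp = exp,
                  sin = sin, cos = cos, tan = tan)

emptyTerms <- function() {
  data.frame(kind = character(), input1 = character(), input2 = character(),
             transform = character(), coefficient = numeric(),
             stringsAsFactors = FALSE)
}

makeTerms <- function(kind, input1, input2 = NA_character_,
                      transform = "identity", coefficient = NA_real_) {
  data.frame(kind = kind, input1 = input1, input2 = input2,
             transform = transform, coefficient = coefficient,
             stringsAsFactors = FALSE)
}

# human-readable label of a term, used in reports and JSON
termLabel <- function(term) {
  switch(term$kind,
    variable = term$input1,
    square = paste0(term$input1, "^2"),
    product = paste0(term$input1, "*", term$input2),
    unary = paste0(term$transform, "(", term$input1, ")"))
}

#' Candidate term library for layer-model fitting
#'
#' Enumerates the basis functions the fitter may combine linearly: every
#' plain variable, optionally every square and every pairwise product, and
#' the requested unary transforms of each variable. The order is
#' deterministic (variables, squares, products by index pairs, transforms);
#' duplicates (e.g. a \code{"square"} transform when squares are already
#' present) are removed.
#'
#' @param inputNames character vector of allowed inputs.
#' @param squares include squared terms (default TRUE).
#' @param products include pairwise products (default TRUE).
#' @param transforms character subset of
#'   \code{c("sqrt", "log", "exp", "sin", "cos", "tan")}; empty by default.
#' @return a data.frame of terms (columns \code{kind}, \code{input1},
#'   \code{input2}, \code{transform}, \code{coefficient}).
#' @examples
#' nrow(buildTermLibrary(paste0("f", 1:10)))  # 10 + 10 + 45
#' @export
buildTermLibrary <- function(inputNames, squares = TRUE, products = TRUE,
                             transforms = character()) {
  if (!length(inputNames)) stop("'inputNames' must be non-empty", call. = FALSE)
  if (anyDuplicated(inputNames))
    stop("'inputNames' must be unique", call. = FALSE)
  bad <- setdiff(transforms, setdiff(names(unaryFuns), c("identity", "square")))
  if (length(bad))
    stop("unknown transform(s): ", paste(bad, collapse = ", "), call. = FALSE)
  lib <- makeTerms("variable", inputNames)
  if (squares) lib <- rbind(lib, makeTerms("square", inputNames))
  if (products && length(inputNames) > 1L) {
    pairs <- utils::combn(inputNames, 2L)
    lib <- rbind(lib, makeTerms("product", pairs[1L, ], pairs[2L, ]))
  }
  for (tr in transforms)
    lib <- rbind(lib, makeTerms("unary", inputNames, transform = tr))
  lib
}

# evaluate one term on a data matrix (columns named by input); returns the
# design column, possibly non-finite where the transform leaves its domain
evalTermColumn <- function(term, X) {
  x1 <- X[, term$input1]
  switch(term$kind,
    variable = x1,
    square = x1^2,
    product = x1 * X[, term$input2],
    unary = unaryFuns[[term$transform]](x1),
    stop("unknown term kind: ", term$kind, call. = FALSE))
}

# design matrix (no intercept column) for a set of terms
termDesign <- function(terms, X) {
  if (!nrow(terms)) return(matrix(numeric(), nrow(X), 0L))
  cols <- vapply(seq_len(nrow(terms)),
                 function(i) evalTermColumn(terms[i, ], X),
                 numeric(nrow(X)))
  cols <- matrix(cols, nrow = nrow(X))
  colnames(cols) <- vapply(seq_len(nrow(terms)),
                           function(i) termLabel(terms[i, ]), character(1))
  cols
}
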