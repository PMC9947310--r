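#' Parse a chemical formula string
#'
#' Parses formulas such as `"C6H12O6"` into a named vector of element counts.
#' Element symbols are one upper-case letter optionally followed by one
#' lower-case letter; counts default to 1 and may be non-negative integers.
#'
#' @param formula character vector of formula strings (`NA` allowed).
#' @return A list (one element per input) of named numeric vectors
#'   (element -> count), or `NULL` for `NA`/empty input.
#' @examples
#' parseFormula("C6H12O6")
#' @export
parseFormula <- function(formula) {
  parse1 <- function(f) {
    if (is.na(f) || !nzchar(f)) return(NULL)
    m <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    toks <- regmatches(f, list(m))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f))
      stop("cannot parse chemical formula: '", f, "'", call. = FALSE)
    el <- sub("[0-9]*$", "", toks)
    n <- suppressWarnings(as.numeric(sub("^[A-Za-z]+", "", toks)))
    n[is.na(n)] <- 1
    agg <- tapply(n, el, sum)[unique(el)]
    stats::setNames(as.numeric(agg), unique(el))
  }
  lapply(as.character(formula), parse1)
}

#' Count one element in formula strings
#'
#' @param formula character vector of formulas.
#' @param element element symbol, default `"C"`.
#' @return Numeric vector of counts; `NA` where the formula is absent.
#' @export
elementCount <- function(formula, element = "C") {
  vapply(parseFormula(formula), function(p) {
    if (is.null(p)) return(NA_real_)
    if (element %in% names(p)) unname(p[[element]]) else 0
  }, numeric(1))
}

#' Carbon counts of a model's metabolites
#'
#' @param model a [MetabolicModel-class].
#' @return Named numeric vector, metabolite id -> number of carbon atoms
#'   (`NA` when the metabolite carries no formula).
#' @export
metCarbons <- function(model) {
  stats::setNames(elementCount(model@mets$formula, "C"), model@mets$id)
}
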