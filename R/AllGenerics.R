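#' @import methods
#' @importFrom Matrix Matrix sparseMatrix t colSums rowSums
NULL

#' Accessor generics for sydicos objects
#'
#' Standard accessors for the central S4 containers: metabolite and reaction
#' tables, gene table, stoichiometric matrix, flux bounds, objective reaction,
#' and the components of a flux distribution.
#'
#' @param x,object an object of the appropriate sydicos class.
#' @param value replacement value.
#' @param ... further arguments passed to methods.
#' @return The accessed component; see the method documentation of each class.
#' @name sydicos-generics
NULL

#' @rdname sydicos-generics
#' @export
setGeneric("metabolites", function(x, ...) standardGeneric("metabolites"))

#' @rdname sydicos-generics
#' @export
setGeneric("reactions", function(x, ...) standardGeneric("reactions"))

#' @rdname sydicos-generics
#' @export
setGeneric("modelGenes", function(x, ...) standardGeneric("modelGenes"))

#' @rdname sydicos-generics
#' @export
setGeneric("objectiveReaction", function(x) standardGeneric("objectiveReaction"))

#' @rdname sydicos-generics
#' @export
setGeneric("objectiveReaction<-", function(x, value) standardGeneric("objectiveReaction<-"))

#' @rdname sydicos-generics
#' @export
setGeneric("stoichiometricMatrix", function(x, ...) standardGeneric("stoichiometricMatrix"))

#' @rdname sydicos-generics
#' @export
setGeneric("bounds", function(x, ...) standardGeneric("bounds"))

#' @rdname sydicos-generics
#' @export
setGeneric("fluxes", function(x) standardGeneric("fluxes"))

#' @rdname sydicos-generics
#' @export
setGeneric("objectiveValue", function(x) standardGeneric("objectiveValue"))

#' @rdname sydicos-generics
#' @export
setGeneric("solverStatus", function(x) standardGeneric("solverStatus"))
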