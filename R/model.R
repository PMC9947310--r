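#' Construct a MetabolicModel
#'
#' Builds a validated [MetabolicModel-class] from metabolite, reaction and
#' gene tables plus a stoichiometric matrix or a list of stoichiometries.
#'
#' Missing optional columns are filled with defaults: `name` (= id),
#' `formula`/`gpr`/`subsystem`/`pathway` (`NA`/empty), bounds
#' (`[-1000, 1000]` for reactions declared reversible via a negative lower
#' bound, `[0, 1000]` otherwise -- the standard big-M convention) and
#' `is_exchange` (auto-detected: reactions touching exactly one metabolite).
#'
#' @param mets data.frame of metabolites (column `id` required; optional
#'   `name`, `compartment`, `formula`).
#' @param rxns data.frame of reactions (column `id` required; optional
#'   `name`, `lower_bound`, `upper_bound`, `gpr`, `subsystem`,
#'   `is_exchange`).
#' @param S stoichiometric matrix (metabolites x reactions), any matrix type
#'   coercible to a sparse [Matrix::Matrix()]; alternatively a named list
#'   reaction id -> named coefficient vector (negative = consumed).
#' @param genes data.frame of genes (columns `id`, optional `name`,
#'   `pathway`); defaults to the genes referenced by the GPR rules.
#' @param objective id of the objective (biomass) reaction, or `character(0)`.
#' @param compartments compartment ids; defaults to those used by `mets`.
#' @return A [MetabolicModel-class].
#' @examples
#' m <- MetabolicModel(
#'   mets = data.frame(id = c("A", "B"), compartment = "c"),
#'   rxns = data.frame(id = c("R1", "EX_B"), lower_bound = c(0, 0),
#'                     upper_bound = c(10, 10)),
#'   S = list(R1 = c(A = -1, B = 1), EX_B = c(B = -1)),
#'   objective = character(0))
#' nReactions(m)
#' @export
MetabolicModel <- function(mets, rxns, S, genes = NULL,
                           objective = character(0), compartments = NULL) {
  mets <- as.data.frame(mets, stringsAsFactors = FALSE)
  rxns <- as.data.frame(rxns, stringsAsFactors = FALSE)
  if (is.null(mets$name)) mets$name <- mets$id
  if (is.null(mets$compartment)) mets$compartment <- rep("", nrow(mets))
  if (is.null(mets$formula)) mets$formula <- rep(NA_character_, nrow(mets))
  mets <- mets[c("id", "name", "compartment", "formula")]

  if (is.null(rxns$name)) rxns$name <- rxns$id
  if (is.null(rxns$lower_bound)) rxns$lower_bound <- rep(0, nrow(rxns))
  if (is.null(rxns$upper_bound)) rxns$upper_bound <- rep(1000, nrow(rxns))
  if (is.null(rxns$gpr)) rxns$gpr <- rep("", nrow(rxns))
  rxns$gpr[is.na(rxns$gpr)] <- ""
  if (is.null(rxns$subsystem)) rxns$subsystem <- rep("", nrow(rxns))
  rxns$subsystem[is.na(rxns$subsystem)] <- ""

  if (is.list(S) && !is(S, "Matrix") && !is.matrix(S)) {
    stopifnot(!is.null(names(S)))
    S <- S[rxns$id]
    i <- unlist(lapply(S, function(x) match(names(x), mets$id)))
    j <- rep(seq_along(S), lengths(S))
    x <- unlist(S, use.names = FALSE)
    if (anyNA(i)) {
      bad <- unique(unlist(lapply(S, names)))
      bad <- setdiff(bad, mets$id)
      stop("stoichiometry references unknown metabolite(s): ",
           paste(bad, collapse = ", "))
    }
    S <- Matrix::sparseMatrix(i = i, j = j, x = x,
                              dims = c(nrow(mets), nrow(rxns)))
  }
  S <- methods::as(methods::as(Matrix::Matrix(S, sparse = TRUE), "generalMatrix"),
                   "CsparseMatrix")
  dimnames(S) <- list(mets$id, rxns$id)

  if (is.null(rxns$is_exchange))
    rxns$is_exchange <- Matrix::colSums(S != 0) == 1
  rxns <- rxns[c("id", "name", "lower_bound", "upper_bound", "gpr",
                 "subsystem", "is_exchange")]

  if (is.null(genes)) {
    ids <- unique(unlist(lapply(rxns$gpr, gprGenes)))
    genes <- data.frame(id = ids %||% character(0), stringsAsFactors = FALSE)
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (is.null(genes$id)) genes$id <- character(0)
  if (is.null(genes$name)) genes$name <- genes$id
  if (is.null(genes$pathway)) genes$pathway <- rep("", nrow(genes))
  genes <- genes[c("id", "name", "pathway")]

  if (is.null(compartments))
    compartments <- unique(mets$compartment[nzchar(mets$compartment)])

  methods::new("MetabolicModel", mets = mets, rxns = rxns, S = S,
               genes = genes, objective = as.character(objective),
               compartments = as.character(compartments))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname sydicos-generics
#' @export
setMethod("metabolites", "MetabolicModel", function(x, ...) x@mets)

#' @rdname sydicos-generics
#' @export
setMethod("reactions", "MetabolicModel", function(x, ...) x@rxns)

#' @rdname sydicos-generics
#' @export
setMethod("modelGenes", "MetabolicModel", function(x, ...) x@genes)

#' @rdname sydicos-generics
#' @export
setMethod("objectiveReaction", "MetabolicModel", function(x) x@objective)

#' @rdname sydicos-generics
#' @export
setMethod("objectiveReaction<-", "MetabolicModel", function(x, value) {
  value <- as.character(value)
  if (length(value) && !value %in% x@rxns$id)
    stop("objective reaction not in model: ", value)
  x@objective <- value
  x
})

#' @describeIn MetabolicModel the stoichiometric matrix as a sparse
#'   `dgCMatrix` (rows = metabolites in table order, columns = reactions in
#'   table order); entry (i, j) is the signed coefficient of metabolite i in
#'   reaction j.
#' @param x,object a `MetabolicModel`.
#' @param ... unused.
#' @export
setMethod("stoichiometricMatrix", "MetabolicModel", function(x, ...) x@S)

#' @describeIn MetabolicModel flux bounds as a data.frame
#'   (`reaction`, `lower`, `upper`).
#' @export
setMethod("bounds", "MetabolicModel", function(x, ...) {
  data.frame(reaction = x@rxns$id, lower = x@rxns$lower_bound,
             upper = x@rxns$upper_bound, stringsAsFactors = FALSE)
})

#' Number of reactions / metabolites
#' @param model a [MetabolicModel-class].
#' @return Integer count.
#' @export
nReactions <- function(model) nrow(model@rxns)

#' @rdname nReactions
#' @export
nMetabolites <- function(model) nrow(model@mets)

setMethod("show", "MetabolicModel", function(object) {
  cat("MetabolicModel with", nrow(object@mets), "metabolites,",
      nrow(object@rxns), "reactions,", nrow(object@genes), "genes\n")
  cat("  compartments:", paste(object@compartments, collapse = ", "), "\n")
  cat("  exchange reactions:", sum(object@rxns$is_exchange), "\n")
  cat("  objective:",
      if (length(object@objective)) object@objective else "<unset>", "\n")
})

setMethod("show", "FluxDistribution", function(object) {
  cat("FluxDistribution:", object@status)
  if (object@status == "optimal")
    cat(", objective =", format(object@objective_value, digits = 8),
        "over", length(object@fluxes), "reactions")
  cat("\n")
})

#' @rdname sydicos-generics
#' @export
setMethod("fluxes", "FluxDistribution", function(x) x@fluxes)

#' @rdname sydicos-generics
#' @export
setMethod("objectiveValue", "FluxDistribution", function(x) x@objective_value)

#' @rdname sydicos-generics
#' @export
setMethod("solverStatus", "FluxDistribution", function(x) x@status)

setMethod("show", "DietSpec", function(object) {
  cat("DietSpec '", object@name, "': ", nrow(object@entries),
      " components, intake ", object@intake, " g/day, total ",
      round(sum(object@entries$percent_w_w), 2), "% w/w\n", sep = "")
})

setMethod("show", "ExpressionProfile", function(object) {
  cat("ExpressionProfile '", object@condition, "': ", length(object@values),
      " genes (", object@unit, ")\n", sep = "")
})

setMethod("show", "SwapPlan", function(object) {
  cat("SwapPlan '", object@name, "': base=", object@base@name,
      ", reference=", object@reference@name, ", swap={",
      paste(object@swap_classes, collapse = ","), "}",
      if (!is.null(object@keep_sugars))
        paste0(", keep sugars={", paste(object@keep_sugars, collapse = ","), "}"),
      "\n", sep = "")
})

setMethod("show", "DistanceMatrix", function(object) {
  cat("DistanceMatrix over", length(object@labels), "distributions",
      if (object@normalized) "(normalized to max = 1)", "\n")
  print(round(object@values, 4))
})

#' Validate a metabolic model
#'
#' Checks all semantic invariants and reports violations without throwing:
#' unique identifiers, `lower_bound <= upper_bound`, resolvable GPR genes,
#' exchange reactions touching exactly one metabolite, objective present,
#' formula/parseability, and empty reactions.
#'
#' @param model a [MetabolicModel-class].
#' @return data.frame with columns `entity`, `rule`, `message`; zero rows
#'   for a well-formed model. The input model is never modified.
#' @export
validateModel <- function(model) {
  v <- list()
  add <- function(entity, rule, message)
    v[[length(v) + 1]] <<- data.frame(entity = entity, rule = rule,
                                      message = message,
                                      stringsAsFactors = FALSE)
  r <- model@rxns
  m <- model@mets
  g <- model@genes
  for (dup in unique(m$id[duplicated(m$id)]))
    add(dup, "unique_metabolite_id", paste("duplicate metabolite id", dup))
  for (dup in unique(r$id[duplicated(r$id)]))
    add(dup, "unique_reaction_id", paste("duplicate reaction id", dup))
  for (dup in unique(g$id[duplicated(g$id)]))
    add(dup, "unique_gene_id", paste("duplicate gene id", dup))
  bad <- r$id[r$lower_bound > r$upper_bound]
  for (id in bad)
    add(id, "bound_order", paste("lower_bound > upper_bound in", id))
  nnz <- Matrix::colSums(model@S != 0)
  for (id in r$id[r$is_exchange & nnz != 1])
    add(id, "exchange_arity",
        paste("exchange reaction", id, "must have exactly one metabolite"))
  for (id in r$id[nnz == 0 & !r$is_exchange])
    add(id, "empty_reaction", paste("reaction", id, "has no stoichiometry"))
  for (i in seq_len(nrow(r))) {
    genes_i <- tryCatch(gprGenes(r$gpr[i]), error = function(e) NA)
    if (length(genes_i) == 1 && is.na(genes_i[1])) {
      add(r$id[i], "gpr_parse", paste("unparseable GPR in", r$id[i]))
      next
    }
    missing <- setdiff(genes_i, g$id)
    for (gid in missing)
      add(r$id[i], "gpr_gene",
          paste("GPR of", r$id[i], "cites unknown gene", gid))
  }
  if (length(model@objective) && !model@objective %in% r$id)
    add(model@objective, "objective_exists",
        paste("objective reaction", model@objective, "not in model"))
  for (i in seq_len(nrow(m))) {
    ok <- tryCatch({ parseFormula(m$formula[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok)
      add(m$id[i], "formula_parse",
          paste("unparseable formula for", m$id[i]))
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(entity = character(0), rule = character(0),
                  message = character(0), stringsAsFactors = FALSE)
}

#' Set flux bounds on selected reactions
#'
#' @param model a [MetabolicModel-class].
#' @param reaction reaction ids.
#' @param lower,upper replacement bounds (recycled; `NA` = keep current).
#' @return The modified model (input untouched).
#' @export
setBounds <- function(model, reaction, lower = NA, upper = NA) {
  idx <- match(reaction, model@rxns$id)
  if (anyNA(idx))
    stop("unknown reaction(s): ", paste(reaction[is.na(idx)], collapse = ", "))
  lower <- rep_len(lower, length(idx))
  upper <- rep_len(upper, length(idx))
  keep_l <- is.na(lower)
  keep_u <- is.na(upper)
  model@rxns$lower_bound[idx[!keep_l]] <- lower[!keep_l]
  model@rxns$upper_bound[idx[!keep_u]] <- upper[!keep_u]
  model
}

#' Subset a model to a set of reactions
#'
#' Keeps the given reactions, the metabolites they touch and the genes their
#' GPR rules reference; the objective is kept when retained.
#'
#' @param model a [MetabolicModel-class].
#' @param keep reaction ids to keep.
#' @return A new [MetabolicModel-class].
#' @export
subsetReactions <- function(model, keep) {
  idx <- match(keep, model@rxns$id)
  if (anyNA(idx))
    stop("unknown reaction(s): ", paste(keep[is.na(idx)], collapse = ", "))
  rxns <- model@rxns[idx, , drop = FALSE]
  S <- model@S[, idx, drop = FALSE]
  mkeep <- Matrix::rowSums(S != 0) > 0
  S <- S[mkeep, , drop = FALSE]
  mets <- model@mets[mkeep, , drop = FALSE]
  gids <- unique(unlist(lapply(rxns$gpr, gprGenes)))
  genes <- model@genes[model@genes$id %in% gids, , drop = FALSE]
  obj <- model@objective
  if (length(obj) && !obj %in% rxns$id) obj <- character(0)
  rownames(rxns) <- rownames(mets) <- rownames(genes) <- NULL
  dimnames(S) <- list(mets$id, rxns$id)
  methods::new("MetabolicModel", mets = mets, rxns = rxns, S = S,
               genes = genes, objective = obj,
               compartments = model@compartments)
}

#' Remove reactions from a model
#'
#' @param model a [MetabolicModel-class].
#' @param drop reaction ids to remove.
#' @return A new [MetabolicModel-class] without `drop`; metabolites left
#'   unused are removed as well.
#' @export
removeReactions <- function(model, drop) {
  subsetReactions(model, setdiff(model@rxns$id, drop))
}

#' Map each exchanged metabolite to its exchange reaction
#'
#' @param model a [MetabolicModel-class].
#' @return Named character vector: metabolite id -> exchange reaction id.
#' @export
exchangeMap <- function(model) {
  ex <- which(model@rxns$is_exchange)
  mets <- vapply(ex, function(j) {
    i <- which(model@S[, j] != 0)
    model@mets$id[i[1]]
  }, character(1))
  stats::setNames(model@rxns$id[ex], mets)
}

# Orientation of an exchange reaction: +1 if positive flux exports the
# metabolite (coefficient -1, the usual convention), -1 if positive flux
# imports it.
exchangeOrientation <- function(model, rxn_id) {
  j <- match(rxn_id, model@rxns$id)
  vapply(j, function(jj) {
    x <- model@S[, jj]
    i <- which(x != 0)[1]
    if (x[i] < 0) 1 else -1
  }, numeric(1))
}
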