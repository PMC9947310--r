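setClassUnion("characterOrNULL", c("character", "NULL"))

#' MetabolicModel: a constraint-based metabolic network
#'
#' S4 container for a genome-scale (or toy) metabolic model: metabolite and
#' reaction tables, a sparse stoichiometric matrix, a gene table, the biomass
#' objective and the compartment list.
#'
#' Slots hold plain data frames so that semantically broken models (e.g.
#' `lower_bound > upper_bound`) remain representable; [validateModel()]
#' reports such violations without throwing. The class validity only enforces
#' structural integrity (matching dimensions and identifiers).
#'
#' Conventions: flux units are mmol/mouse/day; reversibility is encoded
#' solely by a negative lower bound; an exchange reaction has exactly one
#' metabolite and is written in the export direction (positive flux =
#' secretion, negative flux = uptake) unless its single coefficient is
#' positive, in which case positive flux is uptake.
#'
#' @slot mets data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (chemical formula string, `NA` when unknown).
#' @slot rxns data.frame with columns `id`, `name`, `lower_bound`,
#'   `upper_bound`, `gpr` (gene-protein-reaction boolean rule, `""` for
#'   orphan reactions), `subsystem`, `is_exchange`.
#' @slot S sparse [`Matrix::dgCMatrix-class`] (metabolites x reactions),
#'   dimnames set to the metabolite and reaction ids.
#' @slot genes data.frame with columns `id`, `name`, `pathway` (free-text
#'   pathway tag used by the synthetic expression generator; may be `""`).
#' @slot objective id of the biomass/objective reaction (length 0 when unset).
#' @slot compartments character vector of compartment ids.
#'
#' @seealso [MetabolicModel()], [validateModel()], [readModel()], [fba()]
#' @export
setClass("MetabolicModel",
  slots = c(
    mets = "data.frame",
    rxns = "data.frame",
    S = "Matrix",
    genes = "data.frame",
    objective = "character",
    compartments = "character"
  )
)

setValidity("MetabolicModel", function(object) {
  msg <- character(0)
  met_cols <- c("id", "name", "compartment", "formula")
  rxn_cols <- c("id", "name", "lower_bound", "upper_bound", "gpr",
                "subsystem", "is_exchange")
  if (!all(met_cols %in% names(object@mets)))
    msg <- c(msg, paste("mets must have columns:", paste(met_cols, collapse = ", ")))
  if (!all(rxn_cols %in% names(object@rxns)))
    msg <- c(msg, paste("rxns must have columns:", paste(rxn_cols, collapse = ", ")))
  if (!all(c("id", "name") %in% names(object@genes)))
    msg <- c(msg, "genes must have columns: id, name")
  if (length(msg)) return(msg)
  if (nrow(object@S) != nrow(object@mets) || ncol(object@S) != nrow(object@rxns))
    msg <- c(msg, "S dimensions must be (n metabolites) x (n reactions)")
  else {
    rn <- rownames(object@S)
    cn <- colnames(object@S)
    if (!identical(if (is.null(rn)) character(0) else rn, object@mets$id))
      msg <- c(msg, "rownames(S) must equal mets$id")
    if (!identical(if (is.null(cn)) character(0) else cn, object@rxns$id))
      msg <- c(msg, "colnames(S) must equal rxns$id")
  }
  if (length(object@objective) > 1)
    msg <- c(msg, "objective must be a single reaction id (or empty)")
  if (length(msg)) msg else TRUE
})

#' FluxDistribution: the result of a flux balance analysis solve
#'
#' @slot fluxes named numeric vector of reaction fluxes (mmol/mouse/day);
#'   empty when the solve did not reach an optimum.
#' @slot objective_value flux through the objective reaction at the optimum
#'   (`NA` otherwise).
#' @slot status one of `"optimal"`, `"infeasible"`, `"unbounded"`.
#' @seealso [fba()], [pfba()], [fluxDistance()]
#' @export
setClass("FluxDistribution",
  slots = c(
    fluxes = "numeric",
    objective_value = "numeric",
    status = "character"
  )
)

setValidity("FluxDistribution", function(object) {
  msg <- character(0)
  if (length(object@status) != 1 ||
      !object@status %in% c("optimal", "infeasible", "unbounded"))
    msg <- c(msg, "status must be one of optimal, infeasible, unbounded")
  if (length(object@status) == 1 && object@status != "optimal" &&
      length(object@fluxes) > 0)
    msg <- c(msg, "non-optimal distributions must carry no fluxes")
  if (length(object@fluxes) > 0 && is.null(names(object@fluxes)))
    msg <- c(msg, "fluxes must be named by reaction id")
  if (length(msg)) msg else TRUE
})

#' DietSpec: a diet composition table
#'
#' Per-nutrient diet composition used to derive exchange-reaction uptake
#' bounds. `percent_w_w` is the nutrient's share of total diet mass (% w/w),
#' `intake` the grams of food consumed per mouse per day.
#'
#' @slot name diet label.
#' @slot intake grams of food per mouse per day (default fixture value 3).
#' @slot entries data.frame with columns `metabolite`, `percent_w_w`,
#'   `class` (one of carbohydrate, lipid, amino_acid, other),
#'   `mw` (molecular weight, g/mol), `carbons` (carbon atoms per molecule).
#' @seealso [dietSpec()], [dietBounds()], [swapDiet()]
#' @export
setClass("DietSpec",
  slots = c(name = "character", intake = "numeric", entries = "data.frame")
)

setValidity("DietSpec", function(object) {
  msg <- character(0)
  cols <- c("metabolite", "percent_w_w", "class", "mw", "carbons")
  if (!all(cols %in% names(object@entries)))
    return(paste("entries must have columns:", paste(cols, collapse = ", ")))
  e <- object@entries
  if (length(object@intake) != 1 || !is.finite(object@intake) || object@intake < 0)
    msg <- c(msg, "intake must be a single non-negative number")
  if (anyDuplicated(e$metabolite))
    msg <- c(msg, "duplicate metabolite entries in diet")
  if (any(e$percent_w_w < 0)) msg <- c(msg, "percent_w_w must be >= 0")
  if (sum(e$percent_w_w) > 100 + 1e-9)
    msg <- c(msg, "total percent_w_w exceeds 100")
  if (any(e$mw <= 0)) msg <- c(msg, "molecular weights must be > 0")
  bad <- setdiff(unique(e$class), c("carbohydrate", "lipid", "amino_acid", "other"))
  if (length(bad))
    msg <- c(msg, paste("unknown component class:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' ExpressionProfile: mean gene expression for one condition
#'
#' @slot condition condition label (e.g. `"T"`, `"PT"`).
#' @slot values named numeric vector, gene id -> mean expression across
#'   biological replicates; all values must be non-negative.
#' @slot unit expression unit, typically `"FPKM"` or `"TPM"`.
#' @seealso [expressionProfile()], [efluxBounds()], [classifyExpression()]
#' @export
setClass("ExpressionProfile",
  slots = c(condition = "character", values = "numeric", unit = "character")
)

setValidity("ExpressionProfile", function(object) {
  msg <- character(0)
  if (length(object@values) > 0 && is.null(names(object@values)))
    msg <- c(msg, "values must be named by gene id")
  if (any(object@values < 0)) msg <- c(msg, "expression values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SwapPlan: one SyDiCoS diet manipulation
#'
#' Describes a Systematic Diet Composition Swap: starting from `base`, the
#' \% w/w of every metabolite whose component class is listed in
#' `swap_classes` is replaced by its value in `reference`; optionally the
#' carbohydrate entries are then restricted to the ids in `keep_sugars`
#' (all other sugars set to zero).
#'
#' @slot name plan label.
#' @slot base base [DietSpec-class] (its intake is retained).
#' @slot reference reference [DietSpec-class] supplying swapped values.
#' @slot swap_classes subset of `c("carbohydrate", "lipid", "amino_acid")`
#'   (may be empty).
#' @slot keep_sugars `NULL` for no sugar restriction, otherwise the
#'   carbohydrate metabolite ids to retain (may be `character(0)`: drop all).
#' @seealso [swapPlan()], [swapDiet()], [runSydicos()]
#' @export
setClass("SwapPlan",
  slots = c(
    name = "character",
    base = "DietSpec",
    reference = "DietSpec",
    swap_classes = "character",
    keep_sugars = "characterOrNULL"
  )
)

setValidity("SwapPlan", function(object) {
  bad <- setdiff(object@swap_classes, c("carbohydrate", "lipid", "amino_acid"))
  if (length(bad))
    return(paste("swap_classes may only contain carbohydrate, lipid,",
                 "amino_acid; got:", paste(bad, collapse = ", ")))
  TRUE
})

#' DistanceMatrix: pairwise flux-vector distances
#'
#' @slot labels labels of the compared flux distributions.
#' @slot values symmetric non-negative matrix of Euclidean distances.
#' @slot normalized whether values were divided by the maximum entry.
#' @seealso [distanceMatrix()]
#' @export
setClass("DistanceMatrix",
  slots = c(labels = "character", values = "matrix", normalized = "logical")
)

setValidity("DistanceMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (length(object@labels) != nrow(v)) msg <- c(msg, "labels length mismatch")
  if (any(abs(diag(v)) > 1e-12)) msg <- c(msg, "diagonal must be zero")
  if (any(v < -1e-12)) msg <- c(msg, "distances must be non-negative")
  if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "values must be symmetric")
  if (length(msg)) msg else TRUE
})
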