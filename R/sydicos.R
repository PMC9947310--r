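#' Construct a SwapPlan
#'
#' @param name plan label.
#' @param base base [DietSpec-class].
#' @param reference reference [DietSpec-class] supplying the swapped values.
#' @param swap_classes subset of
#'   `c("carbohydrate", "lipid", "amino_acid")`; empty = no swap.
#' @param keep_sugars `NULL` for no sugar restriction, otherwise the
#'   carbohydrate metabolite ids to keep.
#' @return A [SwapPlan-class].
#' @export
swapPlan <- function(name, base, reference, swap_classes = character(0),
                     keep_sugars = NULL) {
  methods::new("SwapPlan", name = name, base = base, reference = reference,
               swap_classes = as.character(swap_classes),
               keep_sugars = keep_sugars)
}

#' Swap diet component classes between two diets
#'
#' Builds the effective diet of a plan: every metabolite whose component
#' class is in `swap_classes` takes its \% w/w from the reference diet
#' (zero when absent there); metabolites of a swapped class present only in
#' the reference diet are added; all other entries and the base intake are
#' kept. Applies the plan's sugar restriction afterwards, if any.
#'
#' @param plan a [SwapPlan-class].
#' @return The effective [DietSpec-class].
#' @export
swapDiet <- function(plan) {
  base <- plan@base@entries
  ref <- plan@reference@entries
  shared <- intersect(base$metabolite, ref$metabolite)
  mismatch <- shared[base$class[match(shared, base$metabolite)] !=
                       ref$class[match(shared, ref$metabolite)]]
  if (length(mismatch))
    stop("component class mismatch between diets for: ",
         paste(mismatch, collapse = ", "))
  e <- base
  sw <- e$class %in% plan@swap_classes
  ridx <- match(e$metabolite, ref$metabolite)
  e$percent_w_w[sw] <- ifelse(is.na(ridx[sw]), 0,
                              ref$percent_w_w[ridx[sw]])
  extra <- ref[ref$class %in% plan@swap_classes &
                 !ref$metabolite %in% base$metabolite, , drop = FALSE]
  e <- rbind(e, extra)
  rownames(e) <- NULL
  out <- dietSpec(paste0(plan@base@name, "_swap[",
                         paste(plan@swap_classes, collapse = ","), "](",
                         plan@reference@name, ")"),
                  e, intake = plan@base@intake)
  if (!is.null(plan@keep_sugars))
    out <- restrictSugars(out, plan@keep_sugars)
  out
}

#' Restrict a diet's sugars to a chosen subset
#'
#' Sets the \% w/w of every carbohydrate entry not in `keep` to zero; kept
#' sugars and all non-carbohydrate entries are unchanged.
#'
#' @param diet a [DietSpec-class].
#' @param keep carbohydrate metabolite ids to retain (may be empty: all
#'   sugars removed).
#' @return A new [DietSpec-class].
#' @export
restrictSugars <- function(diet, keep) {
  e <- diet@entries
  carb <- e$metabolite[e$class == "carbohydrate"]
  bad <- setdiff(keep, carb)
  if (length(bad))
    stop("keep set contains non-carbohydrate entries: ",
         paste(bad, collapse = ", "))
  drop <- e$class == "carbohydrate" & !e$metabolite %in% keep
  e$percent_w_w[drop] <- 0
  dietSpec(paste0(diet@name, "_sugars[", paste(keep, collapse = ","), "]"),
           e, intake = diet@intake)
}

#' Run a SyDiCoS batch
#'
#' For every (model, plan) pair: build the plan's effective diet, derive its
#' uptake bounds, stack them (with optional gas-exchange bounds) on top of
#' the model's existing (expression-constrained) bounds, and solve with
#' [pfba()]. Failures are recorded per cell and the batch continues.
#'
#' @param models named list of [MetabolicModel-class] objects (typically
#'   expression-constrained context-specific models).
#' @param plans named list of [SwapPlan-class] objects.
#' @param gas_layers optional list of bound maps (e.g. from [gasBounds()])
#'   applied to every cell after the diet layer.
#' @param options [solverOptions()].
#' @return list of class `SydicosResult` with elements
#'   `distributions` (named list, keys `"<model>|<plan>"`),
#'   `status` (data.frame model/plan/status/objective) and
#'   `diets` (effective [DietSpec-class] per plan).
#' @export
runSydicos <- function(models, plans, gas_layers = list(),
                       options = solverOptions()) {
  if (is.null(names(models))) names(models) <- paste0("m", seq_along(models))
  if (is.null(names(plans)))
    names(plans) <- vapply(plans, function(p) p@name, character(1))
  diets <- lapply(plans, swapDiet)
  dist <- list()
  status <- list()
  for (mn in names(models)) {
    for (pn in names(plans)) {
      key <- paste(mn, pn, sep = "|")
      cell <- tryCatch({
        layers <- c(list(dietBounds(diets[[pn]], models[[mn]])), gas_layers)
        m <- applyConstraints(models[[mn]], layers)
        pfba(m, options)
      }, error = function(e)
        methods::new("FluxDistribution", fluxes = numeric(0),
                     objective_value = NA_real_, status = "infeasible"))
      dist[[key]] <- cell
      status[[key]] <- data.frame(model = mn, plan = pn,
                                  status = cell@status,
                                  objective = cell@objective_value,
                                  stringsAsFactors = FALSE)
    }
  }
  structure(list(distributions = dist,
                 status = do.call(rbind, c(status,
                                           list(make.row.names = FALSE))),
                 diets = diets),
            class = "SydicosResult")
}

#' Euclidean distance between two flux distributions
#'
#' `sqrt(sum_j (a_j - b_j)^2)` over the (id-sorted) intersection of
#' reaction ids; warns when the reaction sets differ.
#'
#' @param a,b optimal [FluxDistribution-class] objects.
#' @return Non-negative scalar.
#' @export
fluxDistance <- function(a, b) {
  if (a@status != "optimal" || b@status != "optimal")
    stop("flux distance requires two optimal distributions")
  common <- sort(intersect(names(a@fluxes), names(b@fluxes)))
  if (length(common) < length(a@fluxes) || length(common) < length(b@fluxes))
    warning("flux distributions cover different reaction sets; ",
            "using their intersection (", length(common), " reactions)")
  sqrt(sum((a@fluxes[common] - b@fluxes[common])^2))
}

#' Pairwise distance matrix of flux distributions
#'
#' @param distributions named list of at least two optimal
#'   [FluxDistribution-class] objects.
#' @param normalize divide all entries by the maximum distance (default
#'   `TRUE`, matching the "relative to the maximum" presentation).
#' @return A [DistanceMatrix-class].
#' @export
distanceMatrix <- function(distributions, normalize = TRUE) {
  n <- length(distributions)
  if (n < 2) stop("need at least two distributions")
  labels <- names(distributions) %||% paste0("d", seq_len(n))
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- fluxDistance(distributions[[i]], distributions[[j]])
    v[i, j] <- v[j, i] <- d
  }
  if (normalize && max(v) > 0) v <- v / max(v)
  methods::new("DistanceMatrix", labels = labels, values = v,
               normalized = normalize && max(v) > 0)
}

#' Per-reaction flux ratios between two conditions
#'
#' `|a_j| / |b_j|` where the denominator carries flux; reactions carried
#' only in `a` are coded `"new"`, reactions carried in neither are coded
#' `"off"` (epsilon-based, avoiding infinities in reports).
#'
#' @param a,b optimal [FluxDistribution-class] objects.
#' @param epsilon smallest flux magnitude considered nonzero
#'   (default 1e-6).
#' @return data.frame with columns `reaction`, `ratio` (NA when coded) and
#'   `code` (`"ratio"`, `"new"`, `"off"`).
#' @export
fluxRatio <- function(a, b, epsilon = 1e-6) {
  common <- sort(intersect(names(a@fluxes), names(b@fluxes)))
  av <- abs(a@fluxes[common])
  bv <- abs(b@fluxes[common])
  code <- ifelse(bv > epsilon, "ratio",
                 ifelse(av > epsilon, "new", "off"))
  data.frame(reaction = common,
             ratio = ifelse(code == "ratio", av / bv, NA_real_),
             code = code, stringsAsFactors = FALSE, row.names = NULL)
}

#' Carbon influx/efflux accounting of a flux distribution
#'
#' Splits the exchange fluxes of an optimal distribution into uptake
#' (influx) and secretion (efflux) and weights each by the metabolite's
#' carbon count: the per-metabolite and total `C_moles` taken up or
#' produced across the model's pseudo-boundary (mmol C/day).
#'
#' @param d an optimal [FluxDistribution-class].
#' @param model the [MetabolicModel-class] the distribution came from.
#' @param carbons named metabolite -> carbon count map (default derived
#'   from the model formulas via [metCarbons()]).
#' @return list with `perMetabolite` (data.frame `metabolite`, `flux`
#'   -- uptake positive for influx rows --, `carbon_flux`, `direction`),
#'   `totalInflux`, `totalEfflux` (mmol C/day).
#' @export
effluxInfluxSummary <- function(d, model, carbons = metCarbons(model)) {
  if (d@status != "optimal")
    stop("summary requires an optimal distribution")
  emap <- exchangeMap(model)
  rows <- list()
  for (mid in names(emap)) {
    rid <- emap[[mid]]
    v <- d@fluxes[[rid]]
    if (is.null(v) || abs(v) < 1e-12) next
    export <- v * exchangeOrientation(model, rid) > 0
    flux <- abs(v)
    cc <- carbons[[mid]]
    if (is.null(cc) || is.na(cc))
      stop("carbon count missing for exchanged metabolite: ", mid)
    rows[[mid]] <- data.frame(
      metabolite = mid, flux = flux, carbon_flux = flux * cc,
      direction = if (export) "efflux" else "influx",
      stringsAsFactors = FALSE)
  }
  per <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
    else data.frame(metabolite = character(0), flux = numeric(0),
                    carbon_flux = numeric(0), direction = character(0),
                    stringsAsFactors = FALSE)
  list(perMetabolite = per,
       totalInflux = sum(per$carbon_flux[per$direction == "influx"]),
       totalEfflux = sum(per$carbon_flux[per$direction == "efflux"]))
}

#' Per-subsystem reaction ratios between two conditions
#'
#' Restricts to subsystems with at least one reaction carrying flux
#' (`|v| > flux_epsilon` in either condition) and reports, per subsystem,
#' the fraction of those carried reactions with higher absolute flux in
#' `a` than in `b` (beyond `flux_epsilon`). A ratio of 1 means every
#' carried reaction of the subsystem runs higher in `a`.
#'
#' @param a,b optimal [FluxDistribution-class] objects.
#' @param model the shared [MetabolicModel-class].
#' @param flux_epsilon carried-flux threshold (default 1e-6 mmol/day).
#' @return data.frame with columns `subsystem`, `n_reactions_with_flux`,
#'   `n_higher_in_a`, `reaction_ratio`.
#' @export
subsystemReactionRatio <- function(a, b, model, flux_epsilon = 1e-6) {
  common <- intersect(names(a@fluxes), names(b@fluxes))
  idx <- match(common, model@rxns$id)
  ss <- model@rxns$subsystem[idx]
  av <- abs(a@fluxes[common])
  bv <- abs(b@fluxes[common])
  carried <- av > flux_epsilon | bv > flux_epsilon
  keep <- ss[carried]
  out <- lapply(sort(unique(keep)), function(s) {
    sel <- carried & ss == s
    n <- sum(sel)
    nh <- sum(av[sel] > bv[sel] + flux_epsilon)
    data.frame(subsystem = s, n_reactions_with_flux = n,
               n_higher_in_a = nh, reaction_ratio = nh / n,
               stringsAsFactors = FALSE)
  })
  if (!length(out))
    return(data.frame(subsystem = character(0),
                      n_reactions_with_flux = integer(0),
                      n_higher_in_a = integer(0),
                      reaction_ratio = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Biomass-connected differential subnetwork
#'
#' Builds the reaction-metabolite bipartite graph of the reactions (from
#' the given subsystems) whose flux differs between two conditions beyond
#' `flux_epsilon`, excluding currency metabolites from connectivity, and
#' returns the connected component containing the biomass reaction as a
#' sub-model.
#'
#' @param a,b optimal [FluxDistribution-class] objects.
#' @param model the shared [MetabolicModel-class].
#' @param subsystems subsystem names passing the upstream filter (e.g.
#'   reaction ratio equal to 1 in either direction); default: all.
#' @param biomass_id biomass reaction id (default the model objective).
#' @param flux_epsilon differential-flux threshold (default 1e-6).
#' @param currency_mets metabolite base names (compartment suffix
#'   stripped) excluded from connectivity; defaults to water, protons,
#'   ATP/ADP, NAD(H), CO2 and phosphate.
#' @return A [MetabolicModel-class] sub-model (possibly empty, with a
#'   warning when the biomass reaction connects to no differential
#'   reaction).
#' @export
differentialSubnetwork <- function(a, b, model, subsystems = NULL,
                                   biomass_id = objectiveReaction(model),
                                   flux_epsilon = 1e-6,
                                   currency_mets = c("h2o", "h", "atp",
                                                     "adp", "nad", "nadh",
                                                     "co2", "pi")) {
  if (!length(biomass_id) || !biomass_id %in% model@rxns$id)
    stop("biomass reaction not found in model")
  common <- intersect(names(a@fluxes), names(b@fluxes))
  idx <- match(common, model@rxns$id)
  diffr <- common[abs(a@fluxes[common] - b@fluxes[common]) > flux_epsilon]
  if (!is.null(subsystems)) {
    ss <- model@rxns$subsystem[match(diffr, model@rxns$id)]
    diffr <- diffr[ss %in% subsystems]
  }
  if (!length(diffr)) return(subsetReactions(model, character(0)))
  nodes_r <- unique(c(diffr, biomass_id))
  base_id <- sub("_[a-z]+$", "", model@mets$id)
  keep_met <- !(tolower(base_id) %in% tolower(currency_mets))
  edges <- character(0)
  for (rid in nodes_r) {
    j <- match(rid, model@rxns$id)
    i <- which(model@S[, j] != 0 & keep_met)
    for (mi in i) edges <- c(edges, paste0("R:", rid), paste0("M:", model@mets$id[mi]))
  }
  if (!length(edges)) {
    warning("biomass reaction shares no non-currency metabolite with the ",
            "differential set; returning an empty subnetwork")
    return(subsetReactions(model, character(0)))
  }
  g <- igraph::make_graph(edges, directed = FALSE)
  g <- igraph::add_vertices(g, length(setdiff(paste0("R:", nodes_r),
                                              igraph::V(g)$name)),
                            name = setdiff(paste0("R:", nodes_r),
                                           igraph::V(g)$name))
  comp <- igraph::components(g)
  bio_v <- paste0("R:", biomass_id)
  target <- comp$membership[bio_v]
  members <- names(comp$membership)[comp$membership == target]
  rxn_keep <- sub("^R:", "", members[startsWith(members, "R:")])
  rxn_keep <- intersect(model@rxns$id, rxn_keep)
  if (identical(rxn_keep, biomass_id) && !biomass_id %in% diffr) {
    warning("biomass reaction is not connected to any differential ",
            "reaction; returning an empty subnetwork")
    return(subsetReactions(model, character(0)))
  }
  subsetReactions(model, sort(rxn_keep))
}
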