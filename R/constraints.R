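#' Construct a DietSpec
#'
#' @param name diet label.
#' @param entries data.frame with columns `metabolite`, `percent_w_w`,
#'   `class`, `mw`, `carbons`.
#' @param intake grams of food consumed per mouse per day; the default of
#'   3 g/day is the standard mouse intake used throughout.
#' @return A [DietSpec-class].
#' @export
dietSpec <- function(name, entries, intake = 3) {
  methods::new("DietSpec", name = name, intake = intake,
               entries = as.data.frame(entries, stringsAsFactors = FALSE))
}

#' Construct an ExpressionProfile
#'
#' @param condition condition label.
#' @param values named numeric vector gene -> mean expression across
#'   biological replicates.
#' @param unit expression unit (default `"FPKM"`).
#' @return An [ExpressionProfile-class].
#' @export
expressionProfile <- function(condition, values, unit = "FPKM") {
  methods::new("ExpressionProfile", condition = condition,
               values = values, unit = unit)
}

#' Gas exchange measurement
#'
#' Respiratory gas measurement used to force a minimum O2 consumption or
#' CO2 production flux, converted as `b = density * volume / mw * 1000`
#' (mmol/mouse/day).
#'
#' @param gas `"O2"` or `"CO2"`.
#' @param density gas density, g/L.
#' @param volume exchanged gas volume, L per mouse per day.
#' @param mw molecular weight, g/mol (defaults: 31.998 for O2, 44.009 for
#'   CO2).
#' @return list of class `GasExchangeSpec`.
#' @export
gasExchangeSpec <- function(gas = c("O2", "CO2"), density, volume,
                            mw = NULL) {
  gas <- match.arg(gas)
  mw <- mw %||% if (gas == "O2") 31.998 else 44.009
  stopifnot(density > 0, volume >= 0, mw > 0)
  structure(list(gas = gas, density = density, volume = volume, mw = mw),
            class = "GasExchangeSpec")
}

emptyBoundMap <- function() {
  data.frame(reaction = character(0), lower = numeric(0), upper = numeric(0),
             stringsAsFactors = FALSE)
}

#' Diet-derived uptake bounds
#'
#' Converts a diet composition into maximum uptake rates for the matching
#' exchange reactions: `b = (percent_w_w / 100) * intake / mw * 1000`
#' mmol/mouse/day. The bound caps the uptake direction of the exchange
#' reaction (the model may always take less, down to zero); the secretion
#' direction is left untouched.
#'
#' @param diet a [DietSpec-class].
#' @param model a [MetabolicModel-class] (used to orient each exchange).
#' @param exchange_map named vector metabolite -> exchange reaction id
#'   (default [exchangeMap()] of the model).
#' @return A bound map: data.frame (`reaction`, `lower`, `upper`) where `NA`
#'   means "leave the existing bound"; the `units` attribute is
#'   `"mmol/mouse/day"`.
#' @examples
#' diets <- makeSyntheticDiets()
#' toy <- makeToyHepaticModel()
#' head(dietBounds(diets$cd, toy))
#' @export
dietBounds <- function(diet, model, exchange_map = exchangeMap(model)) {
  e <- diet@entries
  missing <- setdiff(e$metabolite, names(exchange_map))
  if (length(missing))
    stop("no exchange reaction for diet metabolite(s): ",
         paste(sort(missing), collapse = ", "))
  b <- (e$percent_w_w / 100) * diet@intake / e$mw * 1000
  rids <- unname(exchange_map[e$metabolite])
  orient <- exchangeOrientation(model, rids)
  # export-oriented exchange (+flux = secretion): uptake = -flux, so the
  # uptake cap b becomes lower = -b; secretion side untouched (NA).
  # import-oriented: uptake = +flux, cap becomes upper = b.
  out <- data.frame(reaction = rids,
                    lower = ifelse(orient > 0, -b, NA_real_),
                    upper = ifelse(orient > 0, NA_real_, b),
                    stringsAsFactors = FALSE)
  attr(out, "units") <- "mmol/mouse/day"
  out
}

#' Split pooled diet components into individual metabolites
#'
#' Divides a pooled entry's \% w/w equally among its member metabolites
#' (e.g. a "saturated fatty acids" pool split equally between palmitate,
#' stearate, myristate and laurate). Members inherit the pool's component
#' class; the pool entry is removed.
#'
#' @param diet a [DietSpec-class].
#' @param split_rules named list: pool metabolite id -> data.frame with
#'   columns `metabolite`, `mw`, `carbons` describing the members.
#' @return A new [DietSpec-class].
#' @export
splitPooledComponents <- function(diet, split_rules) {
  e <- diet@entries
  for (pool in names(split_rules)) {
    i <- match(pool, e$metabolite)
    if (is.na(i)) stop("pool entry not in diet: ", pool)
    members <- split_rules[[pool]]
    if (!NROW(members)) stop("empty member list for pool: ", pool)
    stopifnot(all(c("metabolite", "mw", "carbons") %in% names(members)))
    share <- e$percent_w_w[i] / nrow(members)
    add <- data.frame(metabolite = members$metabolite,
                      percent_w_w = share,
                      class = e$class[i],
                      mw = members$mw,
                      carbons = members$carbons,
                      stringsAsFactors = FALSE)
    e <- rbind(e[-i, , drop = FALSE], add)
  }
  rownames(e) <- NULL
  dietSpec(diet@name, e, intake = diet@intake)
}

#' Gas-exchange flux bound
#'
#' Converts a gas measurement to `b = density * volume / mw * 1000`
#' mmol/mouse/day and imposes it as the minimum rate of the mapped exchange
#' reaction in the stated direction (O2 consumption or CO2 production).
#'
#' @param spec a [gasExchangeSpec()].
#' @param model a [MetabolicModel-class].
#' @param reaction exchange reaction id to constrain.
#' @param direction `"uptake"` (gas must be consumed at >= b) or
#'   `"production"` (gas must be produced at >= b); defaults to `"uptake"`
#'   for O2 and `"production"` for CO2.
#' @return A bound map as in [dietBounds()] (one row; `NA` = leave
#'   existing), with attribute `units = "mmol/mouse/day"`.
#' @export
gasBounds <- function(spec, model, reaction,
                      direction = if (spec$gas == "O2") "uptake" else "production") {
  direction <- match.arg(direction, c("uptake", "production"))
  b <- spec$density * spec$volume / spec$mw * 1000
  if (b == 0) {
    out <- data.frame(reaction = reaction, lower = NA_real_,
                      upper = NA_real_, stringsAsFactors = FALSE)
    attr(out, "units") <- "mmol/mouse/day"
    return(out)
  }
  orient <- exchangeOrientation(model, reaction)
  # export-oriented (+1): production = positive flux, uptake = negative
  if (direction == "production") {
    out <- if (orient > 0)
      data.frame(reaction = reaction, lower = b, upper = NA_real_)
    else data.frame(reaction = reaction, lower = NA_real_, upper = -b)
  } else {
    out <- if (orient > 0)
      data.frame(reaction = reaction, lower = NA_real_, upper = -b)
    else data.frame(reaction = reaction, lower = b, upper = NA_real_)
  }
  attr(out, "units") <- "mmol/mouse/day"
  out
}

#' Carbon-weighted flux total
#'
#' `C_moles = sum_j C_j * v_j`: the total flux of carbon atoms carried by a
#' set of per-metabolite fluxes or bounds (mmol C/day). Used for the
#' diet-available carbon total as well as solved uptake/secretion totals.
#'
#' @param values named numeric vector metabolite -> flux or bound
#'   (mmol/day).
#' @param carbons named numeric vector metabolite -> carbon atoms per
#'   molecule; must cover every metabolite with a nonzero value.
#' @return Total carbon flux (mmol C/day).
#' @examples
#' carbonFlux(c(glc_e = 2), c(glc_e = 6))  # 12
#' @export
carbonFlux <- function(values, carbons) {
  if (!length(values)) return(0)
  nz <- names(values)[values != 0]
  missing <- nz[!nz %in% names(carbons) | is.na(carbons[nz])]
  if (length(missing))
    stop("carbon count missing for metabolite(s): ",
         paste(sort(unique(missing)), collapse = ", "))
  sum(values * ifelse(is.na(carbons[names(values)]), 0,
                      carbons[names(values)]))
}

#' Carbon total available from a diet
#'
#' @param diet a [DietSpec-class].
#' @return `C_moles` of the diet: sum over entries of carbons times the
#'   uptake bound from [dietBounds()] arithmetic (mmol C/day).
#' @export
dietCarbonFlux <- function(diet) {
  e <- diet@entries
  b <- (e$percent_w_w / 100) * diet@intake / e$mw * 1000
  carbonFlux(stats::setNames(b, e$metabolite),
             stats::setNames(e$carbons, e$metabolite))
}

#' Expression-derived reaction bounds (adapted E-flux)
#'
#' Evaluates each reaction's GPR rule on the mean expression values: a
#' single gene contributes its mean expression, OR-related genes are summed
#' (isozymes add capacity) and AND-related genes take the minimum (complex
#' subunits limit capacity). Unmeasured genes contribute `missing`
#' (default 0, making reactions whose only catalyst is unmeasured blocked).
#' The resulting value `b` becomes the upper bound; reversible reactions
#' additionally receive `-b` as the lower bound. Orphan reactions (no GPR)
#' and exchange reactions are never constrained and are absent from the
#' returned map.
#'
#' @param model a [MetabolicModel-class].
#' @param expr an [ExpressionProfile-class].
#' @param missing value substituted for unmeasured genes (default 0).
#' @return A bound map as in [dietBounds()] (`NA` = leave existing bound);
#'   units are the expression units per day.
#' @export
efluxBounds <- function(model, expr, missing = 0) {
  r <- model@rxns
  out <- emptyBoundMap()
  for (j in seq_len(nrow(r))) {
    if (r$is_exchange[j] || !nzchar(r$gpr[j])) next
    tree <- tryCatch(parseGpr(r$gpr[j]), error = function(e)
      stop("malformed GPR in reaction '", r$id[j], "': ",
           conditionMessage(e)))
    b <- gprEval(tree, expr@values, missing = missing)
    reversible <- r$lower_bound[j] < 0
    out <- rbind(out, data.frame(
      reaction = r$id[j],
      lower = if (reversible) -b else 0,
      upper = b, stringsAsFactors = FALSE))
  }
  attr(out, "units") <- paste0(expr@unit, "/day")
  out
}

#' Classify expression levels
#'
#' Bins FPKM-scale expression values: `high` (>= 50), `medium`
#' (10 <= v < 50), `low` (1 <= v < 10), `none` (< 1).
#'
#' @param value numeric vector of non-negative expression values.
#' @return Character vector of classes.
#' @export
classifyExpression <- function(value) {
  if (any(value < 0)) stop("expression values must be non-negative")
  ifelse(value >= 50, "high",
         ifelse(value >= 10, "medium",
                ifelse(value >= 1, "low", "none")))
}

#' Apply layered bound maps to a model
#'
#' Applies bound maps in order; later layers override earlier ones per
#' reaction and side. Resulting bounds are intersected with the model's
#' structural reversibility: a reaction that is irreversible in the input
#' model (`lower_bound >= 0`) never receives a negative lower bound. The
#' input model is not modified.
#'
#' @param model a [MetabolicModel-class].
#' @param layers list of bound maps (data.frames `reaction`, `lower`,
#'   `upper`; `NA` = keep).
#' @return A new [MetabolicModel-class].
#' @export
applyConstraints <- function(model, layers) {
  if (!length(layers)) return(model)
  irrev <- model@rxns$lower_bound >= 0
  out <- model
  origin <- stats::setNames(rep("model", nrow(out@rxns)), out@rxns$id)
  for (k in seq_along(layers)) {
    bm <- layers[[k]]
    if (!NROW(bm)) next
    idx <- match(bm$reaction, out@rxns$id)
    if (anyNA(idx))
      stop("bound map references unknown reaction(s): ",
           paste(bm$reaction[is.na(idx)], collapse = ", "))
    lower <- bm$lower
    clamp <- irrev[idx] & !is.na(lower) & lower < 0
    lower[clamp] <- 0
    sel_l <- !is.na(lower)
    sel_u <- !is.na(bm$upper)
    out@rxns$lower_bound[idx[sel_l]] <- lower[sel_l]
    out@rxns$upper_bound[idx[sel_u]] <- bm$upper[sel_u]
    origin[idx[sel_l | sel_u]] <- paste0("layer", k)
  }
  bad <- which(out@rxns$lower_bound > out@rxns$upper_bound + 1e-12)
  if (length(bad))
    stop("conflicting bounds (lower > upper) after applying layers for: ",
         paste(paste0(out@rxns$id[bad], " (", origin[bad], ")"),
               collapse = ", "))
  out
}

#' Expression-gated model extraction
#'
#' A simplified, deterministic context-specific extraction (NOT the
#' published task-driven MILP algorithms such as tINIT): reactions whose
#' GPR genes are all unexpressed (expression class `"none"`, i.e. < 1) are
#' candidates for removal. Candidates are visited in lexicographic id order
#' and each is removed only if afterwards every task still passes and the
#' biomass optimum stays positive; otherwise it is kept.
#'
#' @param model a [MetabolicModel-class] that passes `tasks`.
#' @param expr an [ExpressionProfile-class].
#' @param tasks list of [metabolicTask()] objects.
#' @param min_biomass smallest biomass optimum still considered feasible
#'   (default 1e-6).
#' @return list with `model` and `report` (`removed`, `reinstated`).
#' @export
expressionGateExtraction <- function(model, expr, tasks = list(),
                                     min_biomass = 1e-6) {
  base_tasks <- checkTasks(model, tasks)
  if (any(base_tasks == "fail"))
    stop("input model fails task(s): ",
         paste(names(base_tasks)[base_tasks == "fail"], collapse = ", "))
  base_sol <- fba(model)
  if (base_sol@status != "optimal" || base_sol@objective_value < min_biomass)
    stop("input model has no feasible biomass production")

  r <- model@rxns
  candidate <- vapply(seq_len(nrow(r)), function(j) {
    if (r$is_exchange[j] || !nzchar(r$gpr[j])) return(FALSE)
    g <- gprGenes(r$gpr[j])
    vals <- ifelse(is.na(expr@values[g]), 0, expr@values[g])
    all(classifyExpression(vals) == "none")
  }, logical(1))
  cand_ids <- sort(r$id[candidate])

  cur <- model
  removed <- character(0)
  reinstated <- character(0)
  for (rid in cand_ids) {
    trial <- removeReactions(cur, rid)
    sol <- fba(trial)
    ok <- sol@status == "optimal" && sol@objective_value >= min_biomass
    if (ok && length(tasks)) {
      tr <- checkTasks(trial, tasks)
      ok <- all(tr == "pass")
    }
    if (ok) { cur <- trial; removed <- c(removed, rid) }
    else reinstated <- c(reinstated, rid)
  }
  list(model = cur, report = list(removed = removed,
                                  reinstated = reinstated))
}

#' Read / write diet tables
#'
#' TSV with columns `metabolite`, `percent_w_w`, `class`, `mw`, `carbons`;
#' the diet name and intake travel in a JSON side-car (`<path>.json`) with
#' fields `name` and `intake`.
#'
#' @param path TSV path.
#' @param diet a [DietSpec-class] (for writing).
#' @return [DietSpec-class] (read) or `path` invisibly (write).
#' @export
readDiet <- function(path) {
  e <- readTsv(path)
  meta_path <- paste0(path, ".json")
  name <- sub("\\.tsv$", "", basename(path))
  intake <- 3
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (!is.null(meta$name)) name <- meta$name
    if (!is.null(meta$intake)) intake <- as.numeric(meta$intake)
  }
  dietSpec(name, e, intake = intake)
}

#' @rdname readDiet
#' @export
writeDiet <- function(diet, path) {
  writeTsv(diet@entries, path)
  jsonlite::write_json(list(name = diet@name, intake = diet@intake),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read expression profiles from a gene-by-condition TSV
#'
#' First column `gene`, remaining columns one condition each.
#'
#' @param path TSV path.
#' @param unit expression unit label (default `"FPKM"`).
#' @return Named list of [ExpressionProfile-class], one per condition.
#' @export
readExpression <- function(path, unit = "FPKM") {
  df <- readTsv(path)
  stopifnot(names(df)[1] == "gene")
  conds <- names(df)[-1]
  out <- lapply(conds, function(cc)
    expressionProfile(cc, stats::setNames(df[[cc]], df$gene), unit = unit))
  stats::setNames(out, conds)
}

#' @rdname readExpression
#' @param profiles named list of [ExpressionProfile-class] sharing a gene
#'   set.
#' @export
writeExpression <- function(profiles, path) {
  genes <- sort(unique(unlist(lapply(profiles, function(p) names(p@values)))))
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (p in profiles) {
    v <- p@values[genes]
    v[is.na(v)] <- 0
    df[[p@condition]] <- unname(v)
  }
  writeTsv(df, path)
  invisible(path)
}
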