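#' Map metabolite identifiers onto a common namespace
#'
#' Renames metabolites according to a mapping table (e.g. model-native ids
#' to KEGG ids). Metabolites in the same compartment that collide onto one
#' target id are merged and all reactions re-pointed; the same target id in
#' different compartments is never merged (such ids are qualified with the
#' compartment suffix to stay unique). When a merge puts a metabolite on
#' both sides of a reaction its coefficients are summed; if the sum is zero
#' the metabolite is dropped from that reaction and the event flagged.
#'
#' @param model a [MetabolicModel-class].
#' @param mapping data.frame with columns `source_namespace`, `source_id`,
#'   `target_id`; `(source_namespace, source_id)` must be unique.
#' @param namespace which source namespace applies to this model's ids
#'   (default: use every row).
#' @return list with `model` (mapped) and `report` (list with `mapped`,
#'   `unmapped`, `merged`, `cancelled` -- reaction/metabolite pairs whose
#'   coefficients cancelled to zero).
#' @export
mapMetaboliteIds <- function(model, mapping, namespace = NULL) {
  stopifnot(all(c("source_namespace", "source_id", "target_id") %in%
                  names(mapping)))
  if (!is.null(namespace))
    mapping <- mapping[mapping$source_namespace %in% namespace, , drop = FALSE]
  if (anyDuplicated(mapping[c("source_namespace", "source_id")]))
    stop("mapping table has duplicate (source_namespace, source_id) rows")
  tgt <- stats::setNames(mapping$target_id, mapping$source_id)

  mets <- model@mets
  hit <- mets$id %in% names(tgt)
  new_id <- ifelse(hit, unname(tgt[mets$id]), mets$id)
  # merge key: target id + compartment
  key <- paste(new_id, mets$compartment, sep = "@@")
  first <- !duplicated(key)
  group <- match(key, key[first])

  S_old <- model@S
  n_new <- sum(first)
  P <- Matrix::sparseMatrix(i = group, j = seq_along(group), x = 1,
                            dims = c(n_new, nrow(mets)))
  S_new <- P %*% S_old

  mets_new <- mets[first, , drop = FALSE]
  mets_new$id <- new_id[first]
  rownames(mets_new) <- NULL
  # the same target id in different compartments is never merged; qualify
  # such ids with the compartment suffix to keep identifiers unique
  clash <- mets_new$id %in% mets_new$id[duplicated(mets_new$id)]
  mets_new$id[clash] <- paste(mets_new$id[clash], mets_new$compartment[clash],
                              sep = "_")

  # flag stoichiometry cancellations: entries that became zero although some
  # merged source row was nonzero
  cancelled <- data.frame(reaction = character(0), metabolite = character(0),
                          stringsAsFactors = FALSE)
  merged_groups <- which(tabulate(group) > 1)
  for (gidx in merged_groups) {
    rows <- which(group == gidx)
    had <- Matrix::colSums(S_old[rows, , drop = FALSE] != 0) > 0
    now <- S_new[gidx, ] != 0
    gone <- which(had & !now)
    if (length(gone))
      cancelled <- rbind(cancelled, data.frame(
        reaction = model@rxns$id[gone],
        metabolite = mets_new$id[gidx], stringsAsFactors = FALSE))
  }

  S_new <- Matrix::drop0(S_new)
  dimnames(S_new) <- list(mets_new$id, model@rxns$id)
  out <- methods::new("MetabolicModel", mets = mets_new, rxns = model@rxns,
                      S = methods::as(S_new, "CsparseMatrix"),
                      genes = model@genes,
                      objective = model@objective,
                      compartments = model@compartments)
  report <- list(
    mapped = sort(unique(mets$id[hit])),
    unmapped = sort(unique(mets$id[!hit])),
    merged = mets_new$id[merged_groups],
    cancelled = cancelled)
  list(model = out, report = report)
}

#' Merge several metabolic models
#'
#' Takes the union of metabolites, reactions and genes. Models must already
#' share a metabolite namespace (run [mapMetaboliteIds()] first). The first
#' occurrence of a metabolite/reaction/gene id wins; a metabolite whose
#' formula conflicts between models keeps the first formula and is flagged.
#' Reaction provenance (which source models contributed each reaction id) is
#' recorded in the report.
#'
#' @param models list of [MetabolicModel-class] objects; names are used as
#'   provenance labels (defaults to `model1`, `model2`, ...).
#' @return list with `model` and `report` (list with `provenance` data.frame
#'   and `formula_conflicts`).
#' @export
mergeModels <- function(models) {
  stopifnot(length(models) >= 1)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    names(models) <- paste0("model", seq_along(models))

  mets <- list(); rxns <- list(); genes <- list(); stoich <- list()
  prov <- list()
  conflicts <- character(0)
  met_formula <- character(0)
  for (nm in names(models)) {
    m <- models[[nm]]
    for (i in seq_len(nrow(m@mets))) {
      id <- m@mets$id[i]
      if (is.null(mets[[id]])) {
        mets[[id]] <- m@mets[i, , drop = FALSE]
        met_formula[id] <- m@mets$formula[i]
      } else {
        f <- m@mets$formula[i]
        if (!is.na(f) && !is.na(met_formula[id]) && f != met_formula[id])
          conflicts <- c(conflicts, id)
      }
    }
    for (j in seq_len(nrow(m@rxns))) {
      id <- m@rxns$id[j]
      prov[[id]] <- c(prov[[id]], nm)
      if (is.null(rxns[[id]])) {
        rxns[[id]] <- m@rxns[j, , drop = FALSE]
        x <- m@S[, j]
        stoich[[id]] <- stats::setNames(x[x != 0],
                                        m@mets$id[which(x != 0)])
      }
    }
    for (i in seq_len(nrow(m@genes))) {
      id <- m@genes$id[i]
      if (is.null(genes[[id]])) genes[[id]] <- m@genes[i, , drop = FALSE]
    }
  }
  mets_df <- do.call(rbind, mets); rownames(mets_df) <- NULL
  rxns_df <- do.call(rbind, rxns); rownames(rxns_df) <- NULL
  genes_df <- if (length(genes)) {
    g <- do.call(rbind, genes); rownames(g) <- NULL; g
  } else NULL
  obj <- unique(unlist(lapply(models, function(m) m@objective)))
  obj <- if (length(obj)) obj[1] else character(0)
  comp <- unique(unlist(lapply(models, function(m) m@compartments)))
  out <- MetabolicModel(mets = mets_df, rxns = rxns_df, S = stoich,
                        genes = genes_df, objective = obj,
                        compartments = comp)
  report <- list(
    provenance = data.frame(
      reaction = names(prov),
      sources = vapply(prov, paste, character(1), collapse = ","),
      stringsAsFactors = FALSE, row.names = NULL),
    formula_conflicts = sort(unique(conflicts)))
  list(model = out, report = report)
}

# Canonical duplicate-detection key for one reaction column: terms sorted by
# metabolite id; for reversible reactions the orientation whose substrate
# side is lexicographically smallest is used, so reverse-written duplicates
# of reversible reactions collapse onto one key.
reactionKey <- function(model, j) {
  x <- model@S[, j]
  nz <- which(x != 0)
  ids <- model@mets$id[nz]
  o <- order(ids)
  ids <- ids[o]
  coef <- x[nz][o]
  fmt <- function(cf) {
    num <- vapply(cf, function(x)
      format(x, digits = 12, trim = TRUE, scientific = FALSE), character(1))
    paste(paste0(num, "*", ids), collapse = "|")
  }
  fwd <- fmt(coef)
  if (model@rxns$lower_bound[j] < 0) {
    rev <- fmt(-coef)
    if (rev < fwd) return(list(key = rev, flipped = TRUE))
  }
  list(key = fwd, flipped = FALSE)
}

#' Remove duplicate reactions
#'
#' Reactions with identical canonicalised stoichiometry (sorted terms;
#' reverse-written duplicates of reversible reactions count as duplicates)
#' are collapsed onto the first occurrence. GPR rules of merged duplicates
#' are joined with OR (either enzyme suffices) and the widest bounds are
#' retained; for a reverse-oriented duplicate the bounds are flipped before
#' widening. Reactions with the same metabolites but different coefficients
#' are kept apart. The operation is idempotent.
#'
#' @param model a [MetabolicModel-class].
#' @return list with `model` and `report` (data.frame `kept`/`removed`).
#' @export
removeDuplicates <- function(model) {
  n <- nrow(model@rxns)
  keys <- character(n); flipped <- logical(n)
  for (j in seq_len(n)) {
    k <- reactionKey(model, j)
    keys[j] <- k$key; flipped[j] <- k$flipped
  }
  first <- !duplicated(keys)
  removed <- data.frame(kept = character(0), removed = character(0),
                        stringsAsFactors = FALSE)
  rxns <- model@rxns
  for (j in which(!first)) {
    i <- which(keys == keys[j])[1]
    # orient duplicate j like representative i before widening bounds
    lb_j <- rxns$lower_bound[j]; ub_j <- rxns$upper_bound[j]
    if (flipped[j] != flipped[i]) { tmp <- lb_j; lb_j <- -ub_j; ub_j <- -tmp }
    rxns$lower_bound[i] <- min(rxns$lower_bound[i], lb_j)
    rxns$upper_bound[i] <- max(rxns$upper_bound[i], ub_j)
    gi <- rxns$gpr[i]; gj <- rxns$gpr[j]
    if (nzchar(gj) && !identical(gi, gj))
      rxns$gpr[i] <- if (nzchar(gi)) paste0("(", gi, ") or (", gj, ")") else gj
    removed <- rbind(removed, data.frame(kept = rxns$id[i],
                                         removed = rxns$id[j],
                                         stringsAsFactors = FALSE))
  }
  model@rxns <- rxns
  out <- subsetReactions(model, rxns$id[first])
  list(model = out, report = removed)
}

#' Elemental balance of reactions
#'
#' For each (or one) reaction, computes the net imbalance of each element:
#' `sum over products of coeff * count - sum over substrates of coeff *
#' count`. Exchange reactions are skipped with status `"exchange"` (they are
#' imbalanced by construction: they cross the pseudo-boundary). A reaction
#' touching any formula-less metabolite is reported `"undetermined"`, never
#' `"balanced"`.
#'
#' @param model a [MetabolicModel-class].
#' @param reaction reaction ids to assess (default: all).
#' @param elements element symbols to balance (default C, N, O, S, P --
#'   hydrogen is deliberately excluded, as proton bookkeeping is untracked).
#' @return data.frame with columns `reaction`, `status` (one of `balanced`,
#'   `imbalanced`, `undetermined`, `exchange`) and one numeric column per
#'   element holding the net imbalance (`NA` when undetermined).
#' @export
elementalBalance <- function(model, reaction = NULL,
                             elements = c("C", "N", "O", "S", "P")) {
  ids <- reaction %||% model@rxns$id
  j_idx <- match(ids, model@rxns$id)
  if (anyNA(j_idx))
    stop("unknown reaction(s): ", paste(ids[is.na(j_idx)], collapse = ", "))
  parsed <- parseFormula(model@mets$formula)
  counts <- vapply(elements, function(e)
    vapply(parsed, function(p) {
      if (is.null(p)) NA_real_
      else if (e %in% names(p)) unname(p[[e]]) else 0
    }, numeric(1)), numeric(nrow(model@mets)))
  counts <- matrix(counts, nrow = nrow(model@mets),
                   dimnames = list(model@mets$id, elements))
  out <- data.frame(reaction = ids, status = NA_character_,
                    stringsAsFactors = FALSE)
  for (e in elements) out[[e]] <- NA_real_
  for (k in seq_along(j_idx)) {
    j <- j_idx[k]
    if (model@rxns$is_exchange[j]) { out$status[k] <- "exchange"; next }
    x <- model@S[, j]
    nz <- which(x != 0)
    if (!length(nz)) {
      out$status[k] <- "balanced"
      out[k, elements] <- 0
      next
    }
    cnt <- counts[nz, , drop = FALSE]
    if (anyNA(cnt)) { out$status[k] <- "undetermined"; next }
    imb <- as.vector(x[nz] %*% cnt)
    out[k, elements] <- imb
    out$status[k] <- if (all(abs(imb) < 1e-9)) "balanced" else "imbalanced"
  }
  out
}

#' Check metabolic task feasibility
#'
#' A task passes iff the steady-state LP is feasible when only the task's
#' allowed inputs are open for uptake (every other exchange closed in both
#' directions) and each required output is imposed as a minimum production
#' flux. Exchange reactions missing for a task metabolite are added
#' temporarily. Pure feasibility -- no objective is optimised.
#'
#' @param model a [MetabolicModel-class].
#' @param tasks list of [metabolicTask()] objects.
#' @return Named character vector task id -> `"pass"`/`"fail"`; failed
#'   tasks referencing unknown metabolites carry the reason as an attribute
#'   `"reasons"`.
#' @export
checkTasks <- function(model, tasks) {
  if (!length(tasks)) return(stats::setNames(character(0), character(0)))
  res <- character(length(tasks))
  reasons <- stats::setNames(rep(NA_character_, length(tasks)),
                             vapply(tasks, `[[`, character(1), "id"))
  for (k in seq_along(tasks)) {
    t <- tasks[[k]]
    mets_needed <- c(t$inputs$metabolite, t$outputs$metabolite)
    unknown <- setdiff(mets_needed, model@mets$id)
    if (length(unknown)) {
      res[k] <- "fail"
      reasons[k] <- paste("unknown metabolite:",
                          paste(unknown, collapse = ", "))
      next
    }
    m <- model
    # close every exchange
    ex <- m@rxns$id[m@rxns$is_exchange]
    m <- setBounds(m, ex, lower = 0, upper = 0)
    emap <- exchangeMap(m)
    # temporary exchanges for task metabolites lacking one
    need <- setdiff(mets_needed, names(emap))
    for (mid in need) {
      m <- addExchange(m, mid, lb = 0, ub = 0)
    }
    emap <- exchangeMap(m)
    orient <- stats::setNames(exchangeOrientation(m, emap), names(emap))
    # open inputs: uptake up to max_uptake
    for (i in seq_len(NROW(t$inputs))) {
      mid <- t$inputs$metabolite[i]
      rid <- emap[[mid]]
      b <- t$inputs$max_uptake[i]
      if (orient[[mid]] > 0) m <- setBounds(m, rid, lower = -b, upper = 0)
      else m <- setBounds(m, rid, lower = 0, upper = b)
    }
    # require outputs: production of at least min_production
    for (i in seq_len(NROW(t$outputs))) {
      mid <- t$outputs$metabolite[i]
      rid <- emap[[mid]]
      b <- t$outputs$min_production[i]
      if (orient[[mid]] > 0) m <- setBounds(m, rid, lower = b, upper = 1000)
      else m <- setBounds(m, rid, lower = -1000, upper = -b)
    }
    p <- list(S = as.matrix(m@S), lb = m@rxns$lower_bound,
              ub = m@rxns$upper_bound)
    sol <- solveLP(rep(0, ncol(p$S)), Aeq = p$S, beq = rep(0, nrow(p$S)),
                   lb = p$lb, ub = p$ub)
    res[k] <- if (sol$status == "optimal") "pass" else "fail"
  }
  out <- stats::setNames(res, names(reasons))
  attr(out, "reasons") <- reasons[!is.na(reasons)]
  out
}

# append a simple export-oriented exchange reaction for `met`
addExchange <- function(model, met, lb = 0, ub = 0) {
  rid <- paste0("EX_", met, "_task")
  while (rid %in% model@rxns$id) rid <- paste0(rid, "_")
  rxns <- rbind(model@rxns, data.frame(
    id = rid, name = rid, lower_bound = lb, upper_bound = ub, gpr = "",
    subsystem = "Exchange", is_exchange = TRUE, stringsAsFactors = FALSE))
  S <- cbind(model@S, Matrix::sparseMatrix(
    i = match(met, model@mets$id), j = 1, x = -1,
    dims = c(nrow(model@mets), 1)))
  dimnames(S) <- list(model@mets$id, rxns$id)
  methods::new("MetabolicModel", mets = model@mets, rxns = rxns,
               S = methods::as(S, "CsparseMatrix"), genes = model@genes,
               objective = model@objective, compartments = model@compartments)
}

#' Define a metabolic task
#'
#' @param id task label.
#' @param inputs data.frame with columns `metabolite`, `max_uptake`
#'   (non-negative flux, mmol/mouse/day).
#' @param outputs data.frame with columns `metabolite`, `min_production`.
#' @return list of class `MetabolicTask`.
#' @export
metabolicTask <- function(id, inputs = NULL, outputs = NULL) {
  empty_in <- data.frame(metabolite = character(0), max_uptake = numeric(0),
                         stringsAsFactors = FALSE)
  empty_out <- data.frame(metabolite = character(0),
                          min_production = numeric(0),
                          stringsAsFactors = FALSE)
  inputs <- inputs %||% empty_in
  outputs <- outputs %||% empty_out
  stopifnot(all(c("metabolite", "max_uptake") %in% names(inputs)),
            all(c("metabolite", "min_production") %in% names(outputs)),
            all(inputs$max_uptake >= 0), all(outputs$min_production >= 0))
  structure(list(id = id, inputs = inputs, outputs = outputs),
            class = "MetabolicTask")
}

#' Read metabolic tasks from TSV
#'
#' One row per task metabolite: columns `task`, `role` (`input`/`output`),
#' `metabolite`, `flux` (max uptake for inputs, min production for outputs).
#'
#' @param path TSV file path.
#' @return list of [metabolicTask()] objects.
#' @export
readTasks <- function(path) {
  df <- readTsv(path)
  stopifnot(all(c("task", "role", "metabolite", "flux") %in% names(df)))
  lapply(split(df, df$task), function(d) {
    metabolicTask(
      id = d$task[1],
      inputs = data.frame(metabolite = d$metabolite[d$role == "input"],
                          max_uptake = d$flux[d$role == "input"],
                          stringsAsFactors = FALSE),
      outputs = data.frame(metabolite = d$metabolite[d$role == "output"],
                           min_production = d$flux[d$role == "output"],
                           stringsAsFactors = FALSE))
  })
}

#' Prune elementally imbalanced reactions while preserving function
#'
#' Iterates over the imbalanced reactions in lexicographic id order and
#' tentatively removes each one. A removal is kept only when the optimal
#' biomass flux stays at or above `(1 - biomass_tolerance)` times the
#' reference optimum and every task that passed on the input model still
#' passes; otherwise the reaction is reinstated and flagged for manual
#' curation.
#'
#' @param model a [MetabolicModel-class] with a feasible biomass optimum.
#' @param tasks list of [metabolicTask()] objects (may be empty).
#' @param biomass_tolerance maximal tolerated relative drop of the biomass
#'   optimum (default 1e-6: the optimum must not be reduced).
#' @param elements elements assessed, as in [elementalBalance()].
#' @return list with `model` (pruned) and `report` (a `CurationReport`
#'   list: `imbalanced`, `pruned`, `retained_flagged`).
#' @export
pruneImbalanced <- function(model, tasks = list(), biomass_tolerance = 1e-6,
                            elements = c("C", "N", "O", "S", "P")) {
  ref_sol <- fba(model)
  if (ref_sol@status != "optimal")
    stop("starting model has no feasible biomass optimum (status: ",
         ref_sol@status, ")")
  ref <- ref_sol@objective_value
  ref_tasks <- checkTasks(model, tasks)
  passing <- names(ref_tasks)[ref_tasks == "pass"]

  bal <- elementalBalance(model, elements = elements)
  imbalanced <- sort(bal$reaction[bal$status == "imbalanced"])
  pruned <- character(0)
  retained <- character(0)
  cur <- model
  for (rid in imbalanced) {
    cand <- removeReactions(cur, rid)
    sol <- fba(cand)
    ok <- sol@status == "optimal" &&
      sol@objective_value >= (1 - biomass_tolerance) * ref
    if (ok && length(passing)) {
      tr <- checkTasks(cand, tasks)
      ok <- all(tr[passing] == "pass")
    }
    if (ok) { cur <- cand; pruned <- c(pruned, rid) }
    else retained <- c(retained, rid)
  }
  list(model = cur,
       report = list(imbalanced = bal[bal$status == "imbalanced", ,
                                      drop = FALSE],
                     pruned = pruned, retained_flagged = retained))
}

#' Detect stoichiometrically inconsistent metabolites
#'
#' A model is stoichiometrically consistent when strictly positive molecular
#' masses exist that conserve mass in every internal reaction. Solves the
#' LP: maximise `sum z` subject to `t(S_internal) m = 0`, `0 <= z <= 1`,
#' `z <= m`, `m >= 0`; metabolites whose `z` falls below `1 - 1e-6` at the
#' optimum cannot carry a positive mass and are reported inconsistent.
#' Exchange reactions are excluded (they are mass-imbalanced by design).
#'
#' @param model a [MetabolicModel-class].
#' @return Character vector of inconsistent metabolite ids (empty when the
#'   internal network is consistent).
#' @export
stoichiometricConsistency <- function(model) {
  internal <- which(!model@rxns$is_exchange)
  if (!length(internal)) return(character(0))
  S <- as.matrix(model@S[, internal, drop = FALSE])
  nm <- nrow(S)
  # variables: m (nm), z (nm)
  Aeq <- cbind(t(S), matrix(0, ncol(S), nm))
  beq <- rep(0, ncol(S))
  Ale <- cbind(-diag(nm), diag(nm))  # z - m <= 0
  ble <- rep(0, nm)
  cc <- c(rep(0, nm), rep(1, nm))
  res <- solveLP(cc, Aeq = Aeq, beq = beq, Ale = Ale, ble = ble,
                 lb = rep(0, 2 * nm), ub = c(rep(1e4, nm), rep(1, nm)),
                 maximize = TRUE)
  if (res$status != "optimal")
    stop("stoichiometric consistency LP did not solve: ", res$status)
  z <- res$x[nm + seq_len(nm)]
  model@mets$id[z < 1 - 1e-6]
}
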