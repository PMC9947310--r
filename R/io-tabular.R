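# Tabular model dialect: four TSV files sharing a path prefix,
#   <prefix>_metabolites.tsv  id, name, compartment, formula
#   <prefix>_reactions.tsv    id, name, equation, lower_bound, upper_bound,
#                             gpr, subsystem, is_exchange
#   <prefix>_genes.tsv        id, name, pathway
#   <prefix>_model.tsv        key/value: objective, compartments (comma-sep)
# Reaction equations use metabolite ids with "=>" (irreversible) or "<=>"
# (reversible) arrows, e.g. "1 glc_c => 1 g6p_c"; the bounds columns are
# authoritative, the arrow is cosmetic on read.

formatEquation <- function(model, j) {
  x <- model@S[, j]
  i <- which(x != 0)
  lhs <- i[x[i] < 0]
  rhs <- i[x[i] > 0]
  fmt <- function(ii, sgn) {
    if (!length(ii)) return("")
    paste(paste(format(abs(x[ii]), trim = TRUE, digits = 12),
                model@mets$id[ii]), collapse = " + ")
  }
  arrow <- if (model@rxns$lower_bound[j] < 0) "<=>" else "=>"
  paste(fmt(lhs), arrow, fmt(rhs))
}

parseEquation <- function(eq, rxn_id) {
  arrow <- if (grepl("<=>", eq, fixed = TRUE)) "<=>" else "=>"
  sides <- strsplit(eq, arrow, fixed = TRUE)[[1]]
  if (length(sides) > 2)
    stop("format error in reaction '", rxn_id, "': multiple arrows")
  if (length(sides) == 1) sides <- c(sides, "")
  parseSide <- function(s, sign) {
    s <- trimws(s)
    if (!nzchar(s)) return(numeric(0))
    terms <- strsplit(s, "+", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (t in terms) {
      t <- trimws(t)
      if (!nzchar(t)) next
      m <- regmatches(t, regexec("^([0-9.eE+-]+[0-9.]|[0-9.])?\\s*(\\S+)$", t))[[1]]
      if (length(m) != 3 || !nzchar(m[3]))
        stop("format error in reaction '", rxn_id, "': cannot parse term '",
             t, "'")
      coef <- if (nzchar(m[2])) as.numeric(m[2]) else 1
      if (is.na(coef))
        stop("format error in reaction '", rxn_id,
             "': bad coefficient in term '", t, "'")
      out[m[3]] <- (if (m[3] %in% names(out)) out[m[3]] else 0) + sign * coef
    }
    out
  }
  lhs <- parseSide(sides[1], -1)
  rhs <- parseSide(sides[2], +1)
  st <- lhs
  for (nm in names(rhs)) st[nm] <- (if (nm %in% names(st)) st[nm] else 0) + rhs[nm]
  list(stoich = st[st != 0], reversible = arrow == "<=>")
}

readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                    comment.char = "", check.names = TRUE)
}

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

readModelTabular <- function(prefix) {
  mets <- readTsv(paste0(prefix, "_metabolites.tsv"))
  rxns <- readTsv(paste0(prefix, "_reactions.tsv"))
  genes_path <- paste0(prefix, "_genes.tsv")
  genes <- if (file.exists(genes_path)) readTsv(genes_path) else NULL
  meta_path <- paste0(prefix, "_model.tsv")
  objective <- character(0)
  compartments <- NULL
  if (file.exists(meta_path)) {
    meta <- readTsv(meta_path)
    kv <- stats::setNames(as.character(meta$value), meta$key)
    if (!is.na(kv["objective"]) && nzchar(kv["objective"]))
      objective <- unname(kv["objective"])
    if (!is.na(kv["compartments"]))
      compartments <- trimws(strsplit(kv["compartments"], ",")[[1]])
  }
  if (is.null(rxns$equation))
    stop("format error: reactions table lacks an 'equation' column")
  parsed <- lapply(seq_len(nrow(rxns)),
                   function(i) parseEquation(rxns$equation[i], rxns$id[i]))
  stoich <- stats::setNames(lapply(parsed, `[[`, "stoich"), rxns$id)
  unknown <- setdiff(unique(unlist(lapply(stoich, names))), mets$id)
  if (length(unknown))
    stop("validation error: reactions reference unknown metabolite(s): ",
         paste(sort(unknown), collapse = ", "))
  rev <- vapply(parsed, `[[`, logical(1), "reversible")
  if (is.null(rxns$lower_bound)) rxns$lower_bound <- ifelse(rev, -1000, 0)
  if (is.null(rxns$upper_bound)) rxns$upper_bound <- 1000
  rxns$lower_bound[is.na(rxns$lower_bound)] <- ifelse(rev, -1000, 0)[is.na(rxns$lower_bound)]
  rxns$upper_bound[is.na(rxns$upper_bound)] <- 1000
  rxns$equation <- NULL
  if (!is.null(rxns$is_exchange)) rxns$is_exchange <- as.logical(rxns$is_exchange)
  MetabolicModel(mets = mets, rxns = rxns, S = stoich, genes = genes,
                 objective = objective, compartments = compartments)
}

writeModelTabular <- function(model, prefix) {
  writeTsv(model@mets, paste0(prefix, "_metabolites.tsv"))
  r <- model@rxns
  eq <- vapply(seq_len(nrow(r)), function(j) formatEquation(model, j),
               character(1))
  out <- data.frame(id = r$id, name = r$name, equation = eq,
                    lower_bound = r$lower_bound, upper_bound = r$upper_bound,
                    gpr = r$gpr, subsystem = r$subsystem,
                    is_exchange = r$is_exchange, stringsAsFactors = FALSE)
  writeTsv(out, paste0(prefix, "_reactions.tsv"))
  writeTsv(model@genes, paste0(prefix, "_genes.tsv"))
  meta <- data.frame(
    key = c("objective", "compartments"),
    value = c(if (length(model@objective)) model@objective else "",
              paste(model@compartments, collapse = ",")),
    stringsAsFactors = FALSE)
  writeTsv(meta, paste0(prefix, "_model.tsv"))
  invisible(prefix)
}

#' Read a metabolic model
#'
#' @param path for `format = "tabular"`, the path prefix of the TSV file set
#'   (see the package vignette for the schema); for `format = "sbml"`, an
#'   SBML Level 3 file with the fbc version 2 extension.
#' @param format `"tabular"` or `"sbml"` (default guessed from `path`:
#'   `.xml`/`.sbml` means SBML).
#' @return A [MetabolicModel-class]. Dangling references raise a validation
#'   error listing the offending ids; unparseable content raises a format
#'   error naming the element.
#' @seealso [writeModel()]
#' @export
readModel <- function(path, format = c("auto", "tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path)) "sbml" else "tabular"
  if (format == "sbml") readModelSbml(path) else readModelTabular(path)
}

#' Write a metabolic model
#'
#' @param model a [MetabolicModel-class].
#' @param path output path (prefix for tabular, file path for SBML).
#' @param format `"tabular"` or `"sbml"` (default guessed as in
#'   [readModel()]).
#' @return `path`, invisibly.
#' @export
writeModel <- function(model, path, format = c("auto", "tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(xml|sbml)$", path)) "sbml" else "tabular"
  if (format == "sbml") writeModelSbml(model, path)
  else writeModelTabular(model, path)
}
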