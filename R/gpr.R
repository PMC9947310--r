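# Gene-protein-reaction rule handling.
#
# Grammar: parenthesised infix boolean expressions over bare gene-id tokens,
# operators "and"/"or" (case-insensitive). "" is the orphan (no-gene) rule.

gprTokenize <- function(rule) {
  rule <- gsub("([()])", " \\1 ", rule)
  toks <- strsplit(trimws(rule), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene-protein-reaction rule
#'
#' Parses a GPR boolean rule (e.g. `"(g1 and g2) or g3"`) into a nested list
#' tree with nodes `list(op = "and"|"or", children = list(...))` and leaves
#' `list(op = "gene", gene = <id>)`. Operator names are case-insensitive;
#' `or` binds looser than `and` (standard SBML-FBC practice).
#'
#' @param rule a single GPR string; `""`/`NA` (orphan) returns `NULL`.
#' @return Parse tree, or `NULL` for an orphan rule.
#' @export
parseGpr <- function(rule) {
  if (length(rule) != 1) stop("parseGpr expects a single rule")
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gprTokenize(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  fail <- function(what) stop("malformed GPR rule '", rule, "': ", what,
                              call. = FALSE)

  parse_or <- function() {
    kids <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      kids <- c(kids, list(parse_and()))
    }
    if (length(kids) == 1) kids[[1]] else list(op = "or", children = kids)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      kids <- c(kids, list(parse_atom()))
    }
    if (length(kids) == 1) kids[[1]] else list(op = "and", children = kids)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) fail("unexpected end of rule")
    if (t == "(") {
      take()
      node <- parse_or()
      if (is.na(peek()) || take() != ")") fail("missing closing parenthesis")
      return(node)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) fail(paste("unexpected token", t))
    list(op = "gene", gene = take())
  }

  tree <- parse_or()
  if (pos <= length(toks)) fail(paste("trailing tokens from", toks[pos]))
  tree
}

#' Genes referenced by a GPR rule
#'
#' @param rule a single GPR string.
#' @return Character vector of gene ids (empty for orphan rules).
#' @export
gprGenes <- function(rule) {
  tree <- parseGpr(rule)
  walk <- function(node) {
    if (is.null(node)) return(character(0))
    if (node$op == "gene") return(node$gene)
    unlist(lapply(node$children, walk))
  }
  unique(walk(tree))
}

# Evaluate a GPR tree under the adapted E-flux semantics: leaf = mean
# expression of the gene (missing gene -> `missing`), OR = sum of children,
# AND = min of children.
gprEval <- function(tree, values, missing = 0) {
  if (is.null(tree)) return(NA_real_)
  rec <- function(node) {
    if (node$op == "gene") {
      v <- values[node$gene]
      return(if (is.na(v)) missing else unname(v))
    }
    kids <- vapply(node$children, rec, numeric(1))
    if (node$op == "or") sum(kids) else min(kids)
  }
  rec(tree)
}
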