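# Shared fixtures and independent oracles for the test suite.

toyFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeToyHepaticModel()
    cache
  }
})

dietFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- makeSyntheticDiets()
    cache
  }
})

# gas-exchange bound layers for the toy model
gasLayers <- function(model) {
  gas <- makeSyntheticGas()
  emap <- exchangeMap(model)
  list(gasBounds(gas$o2, model, emap[["o2_e"]]),
       gasBounds(gas$co2, model, emap[["co2_e"]]))
}

# a tiny linear chain model: E_in (ub 10) -> A -> biomass
chainModel <- function(ub_in = 10) {
  MetabolicModel(
    mets = data.frame(id = c("E", "A"), compartment = "c",
                      formula = c("C2H4O2", "C2H4O2")),
    rxns = data.frame(id = c("EX_E", "T1", "BIO"),
                      lower_bound = c(-ub_in, 0, 0),
                      upper_bound = c(0, 1000, 1000)),
    S = list(EX_E = c(E = -1), T1 = c(E = -1, A = 1), BIO = c(A = -1)),
    objective = "BIO")
}

# wrap a named flux vector as an optimal FluxDistribution
makeFD <- function(v, objective = 0) {
  methods::new("FluxDistribution", fluxes = v, objective_value = objective,
               status = "optimal")
}

# --- independent LP oracle -------------------------------------------------
# Solves max/min cc'x s.t. Aeq x = beq, lb <= x <= ub using pracma::linprog
# on the shifted problem, with boot::simplex as a second, independently
# implemented fallback. Never calls the package's own solver.
oracleLP <- function(cc, Aeq, beq, lb, ub, maximize = TRUE) {
  n <- length(cc)
  shift_beq <- as.numeric(beq) - as.vector(Aeq %*% lb)
  res <- tryCatch({
    r <- pracma::linprog(cc, Aeq = Aeq, beq = shift_beq, ub = ub - lb,
                         maxiter = 2000, maximize = maximize)
    if (r$errno != 1) NULL
    else list(objective = unname(r$fval + sum(cc * lb)))
  }, error = function(e) NULL, warning = function(w) NULL)
  if (!is.null(res)) return(res)
  # boot::simplex: optimise a'x s.t. A1 x <= b1, A3 x = b3, x >= 0
  A1 <- diag(n)
  r <- tryCatch(boot::simplex(a = cc, A1 = A1, b1 = ub - lb, A3 = Aeq,
                              b3 = shift_beq, maxi = maximize),
                error = function(e) NULL)
  if (is.null(r) || r$solved != 1) return(NULL)
  list(objective = unname(r$value + sum(cc * lb)))
}

# random small metabolic network with bounded fluxes (always has v = 0
# feasible, objective bounded by finite bounds)
randomNetwork <- function(n_rxn = NULL, n_met = NULL) {
  n_rxn <- n_rxn %||% sample(4:12, 1)
  n_met <- n_met %||% sample(2:5, 1)
  S <- matrix(sample(c(-2, -1, 0, 0, 1, 2), n_met * n_rxn, replace = TRUE),
              n_met, n_rxn)
  # make sure every reaction touches a metabolite
  for (j in which(colSums(S != 0) == 0)) S[sample(n_met, 1), j] <- 1
  lb <- ifelse(stats::runif(n_rxn) < 0.5, -10, 0)
  ub <- rep(10, n_rxn)
  rxns <- data.frame(id = sprintf("R%02d", seq_len(n_rxn)),
                     lower_bound = lb, upper_bound = ub,
                     is_exchange = FALSE)
  mets <- data.frame(id = sprintf("M%02d", seq_len(n_met)),
                     compartment = "c", formula = NA_character_)
  dimnames(S) <- list(mets$id, rxns$id)
  MetabolicModel(mets = mets, rxns = rxns, S = S,
                 objective = sample(rxns$id, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- independent GPR evaluator oracle --------------------------------------
# Direct string-rewriting evaluation of a GPR expression: substitutes each
# gene token by its value, "or" by "+", "and" by min(...) via recursive
# splitting on the outermost operator. Independent of parseGpr/gprEval.
oracleGpr <- function(rule, values, missing = 0) {
  rule <- trimws(rule)
  # strip one redundant outer parenthesis pair
  repeat {
    if (!startsWith(rule, "(")) break
    depth <- 0; wraps <- TRUE
    chars <- strsplit(rule, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1
      if (chars[i] == ")") depth <- depth - 1
      if (depth == 0 && i < length(chars)) { wraps <- FALSE; break }
    }
    if (!wraps) break
    rule <- trimws(substr(rule, 2, nchar(rule) - 1))
  }
  splitTop <- function(rule, op) {
    toks <- character(0); depth <- 0; cur <- ""
    words <- strsplit(gsub("([()])", " \\1 ", rule), "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    parts <- list(); buf <- character(0)
    for (wd in words) {
      if (wd == "(") depth <- depth + 1
      if (wd == ")") depth <- depth - 1
      if (depth == 0 && tolower(wd) == op) {
        parts <- c(parts, list(buf)); buf <- character(0)
      } else buf <- c(buf, wd)
    }
    parts <- c(parts, list(buf))
    if (length(parts) == 1) NULL else
      vapply(parts, paste, character(1), collapse = " ")
  }
  ors <- splitTop(rule, "or")
  if (!is.null(ors))
    return(sum(vapply(ors, oracleGpr, numeric(1), values = values,
                      missing = missing)))
  ands <- splitTop(rule, "and")
  if (!is.null(ands))
    return(min(vapply(ands, oracleGpr, numeric(1), values = values,
                      missing = missing)))
  v <- values[rule]
  if (is.na(v)) missing else unname(v)
}

# random GPR rule over a gene pool
randomGpr <- function(genes, depth = 0) {
  if (depth > 2 || stats::runif(1) < 0.4) return(sample(genes, 1))
  op <- sample(c("and", "or"), 1)
  k <- sample(2:3, 1)
  kids <- vapply(seq_len(k), function(i) randomGpr(genes, depth + 1),
                 character(1))
  paste0("(", paste(kids, collapse = paste0(" ", op, " ")), ")")
}
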