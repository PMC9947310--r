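# Deterministic, seeded generators: a toy hepatic metabolic network, fixed
# control-diet (CD-like) / western-style-diet (WD-like) compositions,
# tumor/peritumoral-like expression profiles and flaw-injected fixtures.
# The toy network is carbon/nitrogen/oxygen-balanced by construction (small
# integer-ish compositions; phosphate moieties and protons are implicit,
# so S and P never appear and H is not balance-checked).

toyMetTable <- function() {
  m <- function(id, name, comp, formula)
    data.frame(id = id, name = name, compartment = comp, formula = formula,
               stringsAsFactors = FALSE)
  rbind(
    m("glc_e", "glucose", "e", "C6H12O6"),
    m("fru_e", "fructose", "e", "C6H12O6"),
    m("fa_e", "palmitate", "e", "C16H32O2"),
    m("ala_e", "alanine", "e", "C3H7NO2"),
    m("o2_e", "oxygen", "e", "O2"),
    m("co2_e", "carbon dioxide", "e", "CO2"),
    m("h2o_e", "water", "e", "H2O"),
    m("glyc_e", "glycerol", "e", "C3H8O3"),
    m("succ_e", "succinate", "e", "C4H6O4"),
    m("biom_e", "biomass", "e", "C69H136N2O24"),
    m("glc_c", "glucose", "c", "C6H12O6"),
    m("fru_c", "fructose", "c", "C6H12O6"),
    m("fa_c", "palmitate", "c", "C16H32O2"),
    m("ala_c", "alanine", "c", "C3H7NO2"),
    m("o2_c", "oxygen", "c", "O2"),
    m("co2_c", "carbon dioxide", "c", "CO2"),
    m("h2o_c", "water", "c", "H2O"),
    m("glyc_c", "glycerol", "c", "C3H8O3"),
    m("g6p_c", "glucose 6-phosphate", "c", "C6H12O6"),
    m("fbp_c", "fructose 1,6-bisphosphate", "c", "C6H12O6"),
    m("gap_c", "glyceraldehyde 3-phosphate", "c", "C3H6O3"),
    m("dhap_c", "dihydroxyacetone phosphate", "c", "C3H6O3"),
    m("f1p_c", "fructose 1-phosphate", "c", "C6H12O6"),
    m("ga_c", "glyceraldehyde", "c", "C3H6O3"),
    m("pg3_c", "3-phosphoglycerate", "c", "C3H6O4"),
    m("pyr_c", "pyruvate", "c", "C3H4O3"),
    m("ser_c", "serine", "c", "C3H7NO3"),
    m("g3p_c", "glycerol 3-phosphate", "c", "C3H8O3"),
    m("facoa_c", "fatty acyl-CoA", "c", "C16H32O2"),
    m("tag_c", "triacylglycerol", "c", "C51H98O6"),
    m("succ_c", "succinate", "c", "C4H6O4"),
    m("pyr_m", "pyruvate", "m", "C3H4O3"),
    m("accoa_m", "acetyl-CoA", "m", "C2H4O2"),
    m("oaa_m", "oxaloacetate", "m", "C4H4O5"),
    m("cit_m", "citrate", "m", "C6H8O7"),
    m("akg_m", "alpha-ketoglutarate", "m", "C5H6O5"),
    m("succ_m", "succinate", "m", "C4H6O4"),
    m("facoa_m", "fatty acyl-CoA", "m", "C16H32O2"),
    m("o2_m", "oxygen", "m", "O2"),
    m("co2_m", "carbon dioxide", "m", "CO2"),
    m("h2o_m", "water", "m", "H2O"))
}

toyRxnTable <- function() {
  r <- function(id, eq, lb, ub, gpr, subsystem)
    data.frame(id = id, equation = eq, lower_bound = lb, upper_bound = ub,
               gpr = gpr, subsystem = subsystem, stringsAsFactors = FALSE)
  rbind(
    # pseudo-boundary exchanges (positive flux = secretion)
    r("EX_glc", "1 glc_e =>", -1000, 1000, "", "Exchange"),
    r("EX_fru", "1 fru_e =>", -1000, 1000, "", "Exchange"),
    r("EX_fa", "1 fa_e =>", -1000, 1000, "", "Exchange"),
    r("EX_ala", "1 ala_e =>", -1000, 1000, "", "Exchange"),
    r("EX_o2", "1 o2_e =>", -1000, 0, "", "Exchange"),
    r("EX_co2", "1 co2_e =>", 0, 1000, "", "Exchange"),
    r("EX_h2o", "1 h2o_e =>", -1000, 1000, "", "Exchange"),
    r("EX_glyc", "1 glyc_e =>", 0, 1000, "", "Exchange"),
    r("EX_succ", "1 succ_e =>", 0, 1000, "", "Exchange"),
    r("EX_biom", "1 biom_e =>", 0, 1000, "", "Exchange"),
    # transporters
    r("GLCt", "1 glc_e => 1 glc_c", 0, 1000, "Slc2a2", "Transport"),
    r("FRUt", "1 fru_e => 1 fru_c", 0, 1000, "Slc2a5", "Transport"),
    r("FAt", "1 fa_e => 1 fa_c", 0, 1000, "Cd36", "Transport"),
    r("ALAt", "1 ala_e => 1 ala_c", 0, 1000, "Slc1a4", "Transport"),
    r("O2t", "1 o2_e <=> 1 o2_c", -1000, 1000, "", "Transport"),
    r("O2tm", "1 o2_c <=> 1 o2_m", -1000, 1000, "", "Transport"),
    r("CO2t", "1 co2_c <=> 1 co2_e", -1000, 1000, "", "Transport"),
    r("CO2tm", "1 co2_m <=> 1 co2_c", -1000, 1000, "", "Transport"),
    r("H2Ot", "1 h2o_e <=> 1 h2o_c", -1000, 1000, "", "Transport"),
    r("H2Otm", "1 h2o_c <=> 1 h2o_m", -1000, 1000, "", "Transport"),
    r("GLYCt", "1 glyc_c => 1 glyc_e", 0, 1000, "Aqp9", "Transport"),
    r("SUCCtm", "1 succ_m => 1 succ_c", 0, 1000, "Slc25a10", "Transport"),
    r("SUCCt", "1 succ_c => 1 succ_e", 0, 1000, "Slc13a3", "Transport"),
    r("PYRtm", "1 pyr_c => 1 pyr_m", 0, 1000, "Mpc1", "Transport"),
    # glycolysis
    r("HEX1", "1 glc_c => 1 g6p_c", 0, 1000, "Gck", "Glycolysis"),
    r("PFK", "1 g6p_c => 1 fbp_c", 0, 1000, "Pfkl", "Glycolysis"),
    r("FBA", "1 fbp_c => 1 gap_c + 1 dhap_c", 0, 1000, "Aldob", "Glycolysis"),
    r("TPI", "1 dhap_c <=> 1 gap_c", -1000, 1000, "Tpi1", "Glycolysis"),
    r("GAPDH", "1 gap_c + 0.5 o2_c => 1 pg3_c", 0, 1000, "Gapdh",
      "Glycolysis"),
    r("PYK", "1 pg3_c => 1 pyr_c + 1 h2o_c", 0, 1000, "Pklr", "Glycolysis"),
    # fructolysis
    r("KHK", "1 fru_c => 1 f1p_c", 0, 1000, "Khk", "Fructose metabolism"),
    r("ALDOB", "1 f1p_c => 1 dhap_c + 1 ga_c", 0, 1000, "Aldob",
      "Fructose metabolism"),
    r("TKFC", "1 ga_c => 1 gap_c", 0, 1000, "Tkfc", "Fructose metabolism"),
    # glycerol branch
    r("GPD", "1 dhap_c => 1 g3p_c", 0, 1000, "Gpd1", "Glycerol metabolism"),
    r("G3PP", "1 g3p_c => 1 glyc_c", 0, 1000, "Pgp", "Glycerol metabolism"),
    # serine synthesis (transamination against alanine)
    r("PHGDH", "1 pg3_c + 1 ala_c => 1 ser_c + 1 pyr_c", 0, 1000,
      "Phgdh and Psat1", "Serine metabolism"),
    # fatty acid activation and acylglycerol synthesis
    r("FACOAL", "1 fa_c => 1 facoa_c", 0, 1000, "Acsl1",
      "Fatty acid activation"),
    r("GPAT", "1 g3p_c + 3 facoa_c => 1 tag_c + 3 h2o_c", 0, 1000,
      "(Gpam or Gpat2) and Lpin1", "Glycerolipid metabolism"),
    # carnitine shuttle and beta-oxidation
    r("CPT", "1 facoa_c => 1 facoa_m", 0, 1000, "Cpt1a and Cpt2",
      "Carnitine shuttle"),
    r("FAOX", "1 facoa_m + 11 o2_m => 8 accoa_m + 8 h2o_m", 0, 1000,
      "Acadl or Acadm", "Beta oxidation"),
    # TCA cycle
    r("PDH", "1 pyr_m + 0.5 o2_m => 1 accoa_m + 1 co2_m", 0, 1000,
      "Pdha1 and Pdhb", "TCA cycle"),
    r("PC", "1 pyr_m + 1 co2_m => 1 oaa_m", 0, 1000, "Pcx", "TCA cycle"),
    r("CS", "1 accoa_m + 1 oaa_m => 1 cit_m", 0, 1000, "Cs", "TCA cycle"),
    r("IDH", "1 cit_m => 1 akg_m + 1 co2_m", 0, 1000, "Idh2", "TCA cycle"),
    r("AKGDH", "1 akg_m + 0.5 o2_m => 1 succ_m + 1 co2_m", 0, 1000,
      "Ogdh or Dhtkd1", "TCA cycle"),
    r("SDH", "1 succ_m + 1.5 o2_m => 1 oaa_m + 2 h2o_m", 0, 1000,
      "Sdha and Fh1", "TCA cycle"),
    # biomass pseudo-reaction: lipid + protein + carbohydrate precursors
    r("BIOMASS", "1 tag_c + 2 ser_c + 2 g6p_c => 1 biom_e", 0, 1000, "",
      "Biomass"))
}

toyGeneTable <- function() {
  g <- function(id, pathway)
    data.frame(id = id, name = id, pathway = pathway,
               stringsAsFactors = FALSE)
  rbind(
    g("Slc2a2", "transport"), g("Slc2a5", "transport"),
    g("Cd36", "fa_uptake"), g("Slc1a4", "transport"),
    g("Aqp9", "transport"), g("Slc25a10", "transport"),
    g("Slc13a3", "transport"), g("Mpc1", "transport"),
    g("Gck", "glycolysis"), g("Pfkl", "glycolysis"),
    g("Aldob", "glycolysis"), g("Tpi1", "glycolysis"),
    g("Gapdh", "glycolysis"), g("Pklr", "glycolysis"),
    g("Khk", "fructolysis"), g("Tkfc", "fructolysis"),
    g("Gpd1", "glycerol"), g("Pgp", "glycerol"),
    g("Phgdh", "serine_synthesis"), g("Psat1", "serine_synthesis"),
    g("Acsl1", "fa_activation"),
    g("Gpam", "lipid_synthesis"), g("Gpat2", "lipid_synthesis"),
    g("Lpin1", "lipid_synthesis"),
    g("Cpt1a", "beta_oxidation"), g("Cpt2", "beta_oxidation"),
    g("Acadl", "beta_oxidation"), g("Acadm", "beta_oxidation"),
    g("Pdha1", "tca"), g("Pdhb", "tca"), g("Pcx", "tca"), g("Cs", "tca"),
    g("Idh2", "tca"), g("Ogdh", "tca"), g("Dhtkd1", "tca"),
    g("Sdha", "tca"), g("Fh1", "tca"))
}

#' Generate the toy hepatic metabolic model
#'
#' A small (~47 reaction) three-compartment hepatocyte-like network:
#' glucose/fructose uptake and glycolysis, fructolysis branching to a
#' glycerol efflux, a TCA cycle with succinate efflux, fatty-acid uptake
#' and activation to acyl-CoA with the choice of mitochondrial
#' beta-oxidation (via a carnitine shuttle) or acylglycerol synthesis (via
#' glycerol-3-phosphate acyltransferase), a serine-synthesis branch, O2 and
#' CO2 exchange, and a biomass pseudo-reaction consuming lipid
#' (triacylglycerol), protein (serine) and carbohydrate (hexose phosphate)
#' precursors. Every internal reaction is carbon balanced by construction
#' and carries a GPR rule with pathway-tagged genes (exchanges, gas/water
#' diffusion and the biomass pseudo-reaction are orphan).
#'
#' @param seed integer seed; affects only the optional extra reactions
#'   (the core network is fixed).
#' @param n_extra_reactions number of additional carbon-balanced dead-cycle
#'   reaction pairs to append (each adds one metabolite, two reactions and
#'   one gene), for scaling experiments.
#' @return A validated [MetabolicModel-class] with objective `"BIOMASS"`.
#' @examples
#' toy <- makeToyHepaticModel()
#' toy
#' @export
makeToyHepaticModel <- function(seed = 1, n_extra_reactions = 0) {
  mets <- toyMetTable()
  rxns <- toyRxnTable()
  genes <- toyGeneTable()
  if (n_extra_reactions > 0) {
    set.seed(seed)
    pool <- mets$id[mets$compartment == "c" & !is.na(mets$formula)]
    src <- sample(pool, n_extra_reactions, replace = TRUE)
    for (k in seq_len(n_extra_reactions)) {
      xid <- sprintf("xmet%02d_c", k)
      mets <- rbind(mets, data.frame(
        id = xid, name = paste("extra metabolite", k), compartment = "c",
        formula = mets$formula[mets$id == src[k]], stringsAsFactors = FALSE))
      gid <- sprintf("Extra%02d", k)
      genes <- rbind(genes, data.frame(id = gid, name = gid,
                                       pathway = "extra",
                                       stringsAsFactors = FALSE))
      rxns <- rbind(rxns,
        data.frame(id = sprintf("XFWD%02d", k),
                   equation = paste("1", src[k], "=> 1", xid),
                   lower_bound = 0, upper_bound = 1000, gpr = gid,
                   subsystem = "Extra", stringsAsFactors = FALSE),
        data.frame(id = sprintf("XREV%02d", k),
                   equation = paste("1", xid, "=> 1", src[k]),
                   lower_bound = 0, upper_bound = 1000, gpr = gid,
                   subsystem = "Extra", stringsAsFactors = FALSE))
    }
  }
  parsed <- lapply(seq_len(nrow(rxns)),
                   function(i) parseEquation(rxns$equation[i], rxns$id[i]))
  stoich <- stats::setNames(lapply(parsed, `[[`, "stoich"), rxns$id)
  rxns$equation <- NULL
  MetabolicModel(mets = mets, rxns = rxns, S = stoich, genes = genes,
                 objective = "BIOMASS", compartments = c("e", "c", "m"))
}

#' Fixed synthetic diet fixtures
#'
#' Two fixed (non-random) diet compositions over the toy model's nutrients:
#' a control-diet-like composition (carbohydrate-rich, no fructose) and a
#' western-style-diet-like composition (lipid-rich, fructose-containing,
#' higher total dietary carbon). Both use the standard 3 g/day intake.
#'
#' @return list with elements `cd` and `wd` ([DietSpec-class]).
#' @examples
#' diets <- makeSyntheticDiets()
#' dietCarbonFlux(diets$wd) > dietCarbonFlux(diets$cd)
#' @export
makeSyntheticDiets <- function() {
  entry <- function(met, pct, cls, mw, cb)
    data.frame(metabolite = met, percent_w_w = pct, class = cls, mw = mw,
               carbons = cb, stringsAsFactors = FALSE)
  cd <- rbind(
    entry("glc_e", 60, "carbohydrate", 180.156, 6),
    entry("fru_e", 0, "carbohydrate", 180.156, 6),
    entry("fa_e", 6, "lipid", 256.43, 16),
    entry("ala_e", 18, "amino_acid", 89.094, 3))
  wd <- rbind(
    entry("glc_e", 25, "carbohydrate", 180.156, 6),
    entry("fru_e", 25, "carbohydrate", 180.156, 6),
    entry("fa_e", 20, "lipid", 256.43, 16),
    entry("ala_e", 18, "amino_acid", 89.094, 3))
  list(cd = dietSpec("CD", cd, intake = 3),
       wd = dietSpec("WD", wd, intake = 3))
}

#' Synthetic respiratory gas-exchange fixtures
#'
#' Gas measurements scaled to the toy network's flux magnitudes (the toy
#' diet supplies ~100 mmol C/day, two orders of magnitude below a real
#' mouse, so the gas volumes are scaled down accordingly).
#'
#' @return list with elements `o2` and `co2` ([gasExchangeSpec()]).
#' @export
makeSyntheticGas <- function() {
  list(o2 = gasExchangeSpec("O2", density = 1.429, volume = 0.045),
       co2 = gasExchangeSpec("CO2", density = 1.977, volume = 0.050))
}

#' Synthetic tumor / peritumoral expression profiles
#'
#' Draws a log-normal baseline expression value for every model gene
#' (meanlog `log(5)`, sdlog 0.35 by default -- the same order of magnitude
#' as the diet-derived uptake bounds, so expression and diet constraints
#' are both active) and derives the two conditions: the peritumoral-like
#' profile (PT) is the baseline; the tumor-like profile (T) scales
#' beta-oxidation/carnitine-shuttle genes by 0.25 and lipid-synthesis and
#' serine-synthesis genes by 4, reproducing the qualitative expression
#' differences between tumors and surrounding liver.
#'
#' Pathway-level baseline abundances place the expression-derived
#' capacities of the regulated pathways (lipid synthesis, serine synthesis,
#' beta-oxidation) at the same scale as the diet-driven flux demands --
#' the regime in which diet and expression constraints interact -- while
#' central-carbon enzymes are in excess, as in liver.
#'
#' @param model the toy [MetabolicModel-class] (genes must be
#'   pathway-tagged).
#' @param seed integer seed; identical seeds give identical profiles.
#' @param baseline_meanlog,baseline_sdlog parameters of the log-normal
#'   baseline.
#' @param pathway_scale named numeric vector of per-pathway baseline
#'   multipliers (applied to both conditions).
#' @return list with elements `t` and `pt` ([ExpressionProfile-class]).
#' @export
makeSyntheticExpression <- function(model, seed = 1,
                                    baseline_meanlog = log(5),
                                    baseline_sdlog = 0.35,
                                    pathway_scale = c(lipid_synthesis = 0.1,
                                                      serine_synthesis = 0.2,
                                                      beta_oxidation = 0.5)) {
  g <- modelGenes(model)
  set.seed(seed)
  base <- stats::rlnorm(nrow(g), meanlog = baseline_meanlog,
                        sdlog = baseline_sdlog)
  ps <- pathway_scale[g$pathway]
  base <- base * ifelse(is.na(ps), 1, ps)
  names(base) <- g$id
  factor <- ifelse(g$pathway == "beta_oxidation", 0.25,
                   ifelse(g$pathway %in% c("lipid_synthesis",
                                           "serine_synthesis"), 4, 1))
  tvals <- base * factor
  names(tvals) <- g$id
  list(t = expressionProfile("T", tvals, unit = "FPKM"),
       pt = expressionProfile("PT", base, unit = "FPKM"))
}

#' Metabolic task fixtures for the toy model
#'
#' Three growth/function tasks: glucose oxidation to CO2, biomass
#' production from the full nutrient set, and fructose conversion to
#' glycerol.
#'
#' @return list of [metabolicTask()] objects.
#' @export
makeSyntheticTasks <- function() {
  inp <- function(...) {
    v <- c(...)
    data.frame(metabolite = names(v), max_uptake = unname(v),
               stringsAsFactors = FALSE)
  }
  outp <- function(...) {
    v <- c(...)
    data.frame(metabolite = names(v), min_production = unname(v),
               stringsAsFactors = FALSE)
  }
  list(
    metabolicTask("glucose_oxidation",
                  inputs = inp(glc_e = 10, o2_e = 100),
                  outputs = outp(co2_e = 1, h2o_e = 0)),
    metabolicTask("biomass_production",
                  inputs = inp(glc_e = 10, fa_e = 5, ala_e = 10, o2_e = 100),
                  outputs = outp(biom_e = 0.1, co2_e = 0, h2o_e = 0,
                                 glyc_e = 0, succ_e = 0)),
    metabolicTask("fructose_to_glycerol",
                  inputs = inp(fru_e = 10, o2_e = 100),
                  outputs = outp(glyc_e = 1, h2o_e = 0, co2_e = 0)))
}

#' Inject known flaws into a model
#'
#' Test harness for the curation operations: appends the requested number
#' of carbon-imbalanced reactions (each converts an existing
#' formula-carrying metabolite into a new dead-end metabolite whose formula
#' gains one carbon), exact duplicate reactions (copies of random internal
#' reactions under new ids) and self-amplifying stoichiometrically
#' inconsistent reactions (a fresh formula-less metabolite X with X -> 2X),
#' and returns the machine-readable ground truth.
#'
#' @param model a [MetabolicModel-class].
#' @param n_imbalanced,n_duplicate,n_inconsistent flaw counts (>= 0).
#' @param seed integer seed for the random choices.
#' @return list with `model` (perturbed) and `truth` (list:
#'   `imbalanced` reaction ids, `duplicates` data.frame kept/removed ids,
#'   `inconsistent` metabolite ids).
#' @export
perturbModel <- function(model, n_imbalanced = 2, n_duplicate = 2,
                         n_inconsistent = 1, seed = 1) {
  stopifnot(n_imbalanced >= 0, n_duplicate >= 0, n_inconsistent >= 0)
  set.seed(seed)
  internal <- model@rxns$id[!model@rxns$is_exchange]
  if (n_duplicate > length(internal))
    stop("not enough internal reactions to duplicate")
  mets <- model@mets
  rxns <- model@rxns
  S <- model@S
  addRxn <- function(id, stoich, lb, ub, gpr, subsystem) {
    rxns <<- rbind(rxns, data.frame(
      id = id, name = id, lower_bound = lb, upper_bound = ub, gpr = gpr,
      subsystem = subsystem, is_exchange = FALSE, stringsAsFactors = FALSE))
    col <- Matrix::sparseMatrix(i = match(names(stoich), mets$id),
                                j = rep(1, length(stoich)), x = unname(stoich),
                                dims = c(nrow(mets), 1))
    S <<- cbind(S, col)
  }

  truth <- list(imbalanced = character(0),
                duplicates = data.frame(kept = character(0),
                                        removed = character(0),
                                        stringsAsFactors = FALSE),
                inconsistent = character(0))

  # carbon-imbalanced dead ends
  carbon_src <- mets$id[!is.na(mets$formula) &
                          elementCount(mets$formula, "C") > 0 &
                          mets$compartment != "e"]
  src <- sample(carbon_src, n_imbalanced, replace = TRUE)
  for (k in seq_len(n_imbalanced)) {
    p <- parseFormula(mets$formula[mets$id == src[k]])[[1]]
    p["C"] <- p["C"] + 1
    f <- paste0(names(p), ifelse(p == 1, "", p), collapse = "")
    xid <- sprintf("imbmet%02d_c", k)
    mets <- rbind(mets, data.frame(id = xid, name = xid, compartment = "c",
                                   formula = f, stringsAsFactors = FALSE))
    S <- rbind2(S, Matrix::Matrix(0, 1, ncol(S), sparse = TRUE))
    rid <- sprintf("IMB%02d", k)
    addRxn(rid, stats::setNames(c(-1, 1), c(src[k], xid)), 0, 1000, "",
           "Injected")
    truth$imbalanced <- c(truth$imbalanced, rid)
  }

  # exact duplicates
  dup_src <- sample(internal, n_duplicate)
  for (k in seq_len(n_duplicate)) {
    j <- match(dup_src[k], rxns$id)
    x <- S[, j]
    nz <- which(x != 0)
    rid <- paste0(dup_src[k], "_dup")
    addRxn(rid, stats::setNames(x[nz], mets$id[nz]),
           rxns$lower_bound[j], rxns$upper_bound[j], rxns$gpr[j],
           rxns$subsystem[j])
    truth$duplicates <- rbind(truth$duplicates,
                              data.frame(kept = dup_src[k], removed = rid,
                                         stringsAsFactors = FALSE))
  }

  # self-amplifying inconsistent metabolites (no formula: the elemental
  # check reports them undetermined, keeping the imbalance truth exact)
  for (k in seq_len(n_inconsistent)) {
    xid <- sprintf("inconsmet%02d_c", k)
    mets <- rbind(mets, data.frame(id = xid, name = xid, compartment = "c",
                                   formula = NA_character_,
                                   stringsAsFactors = FALSE))
    S <- rbind2(S, Matrix::Matrix(0, 1, ncol(S), sparse = TRUE))
    addRxn(sprintf("INCONS%02d", k), stats::setNames(1, xid), 0, 1000, "",
           "Injected")
    truth$inconsistent <- c(truth$inconsistent, xid)
  }

  dimnames(S) <- list(mets$id, rxns$id)
  out <- methods::new("MetabolicModel", mets = mets, rxns = rxns,
                      S = methods::as(S, "CsparseMatrix"),
                      genes = model@genes, objective = model@objective,
                      compartments = model@compartments)
  list(model = out, truth = truth)
}
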