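twoCompModel <- function() {
  MetabolicModel(
    mets = data.frame(id = c("a_c", "b_c", "a_m"),
                      compartment = c("c", "c", "m"),
                      formula = c("C2H4O2", "C2H4O2", "C2H4O2")),
    rxns = data.frame(id = c("R1", "R2"),
                      lower_bound = 0, upper_bound = 10),
    S = list(R1 = c(a_c = -1, b_c = 1), R2 = c(a_m = -1, b_c = 1)))
}

test_that("identifier mapping merges same-compartment collisions only", {
  m <- twoCompModel()
  mapping <- data.frame(source_namespace = "native",
                        source_id = c("a_c", "b_c", "a_m"),
                        target_id = c("K1", "K1", "K1"),
                        stringsAsFactors = FALSE)
  out <- mapMetaboliteIds(m, mapping)
  mm <- out$model
  # a_c and b_c merge (same compartment); a_m stays separate, and the
  # colliding bare target id is compartment-qualified
  expect_setequal(metabolites(mm)$id, c("K1_c", "K1_m"))
  expect_identical(metabolites(mm)$compartment, c("c", "m"))
  # R1 had K1 on both sides with net zero -> dropped and flagged
  expect_equal(sum(stoichiometricMatrix(mm)[, "R1"] != 0), 0)
  expect_identical(out$report$cancelled$reaction, "R1")
  # R2 re-pointed: consumes mitochondrial K1, produces cytosolic K1
  expect_equal(as.numeric(stoichiometricMatrix(mm)[, "R2"]), c(1, -1))
})

test_that("unmapped metabolites are retained and listed", {
  m <- twoCompModel()
  mapping <- data.frame(source_namespace = "native", source_id = "a_c",
                        target_id = "K1", stringsAsFactors = FALSE)
  out <- mapMetaboliteIds(m, mapping)
  expect_setequal(out$report$unmapped, c("b_c", "a_m"))
  expect_true(all(c("K1", "b_c", "a_m") %in% metabolites(out$model)$id))
})

test_that("merging disjoint models adds counts; merge with self is idempotent", {
  a <- chainModel()
  b <- twoCompModel()
  merged <- mergeModels(list(first = a, second = b))$model
  expect_identical(nReactions(merged), nReactions(a) + nReactions(b))
  expect_identical(nMetabolites(merged), nMetabolites(a) + nMetabolites(b))

  twice <- mergeModels(list(x = a, y = a))
  expect_identical(nReactions(twice$model), nReactions(a))
  expect_setequal(twice$report$provenance$sources, c("x,y"))
  dedup <- removeDuplicates(twice$model)$model
  expect_equal(as.matrix(stoichiometricMatrix(dedup)),
               as.matrix(stoichiometricMatrix(a)))
})

test_that("shared-metabolite overlap fraction is recovered on designed models", {
  # two 4-metabolite models sharing exactly 2 metabolites -> union 6,
  # intersection 2/4 = 0.5 of each model's metabolite set
  mk <- function(ids, rid) MetabolicModel(
    mets = data.frame(id = ids, compartment = "c"),
    rxns = data.frame(id = rid, lower_bound = 0, upper_bound = 10),
    S = stats::setNames(list(stats::setNames(c(-1, 1, -1, 1), ids)), rid))
  m1 <- mk(c("s1", "s2", "u1", "u2"), "Ra")
  m2 <- mk(c("s1", "s2", "w1", "w2"), "Rb")
  shared <- intersect(metabolites(m1)$id, metabolites(m2)$id)
  expect_equal(length(shared) / nMetabolites(m1), 0.5)
  merged <- mergeModels(list(m1, m2))$model
  expect_identical(nMetabolites(merged), 6L)
})

test_that("duplicate removal honours direction normalisation and stoichiometry", {
  mets <- data.frame(id = c("A", "B"), compartment = "c")
  m <- MetabolicModel(
    mets = mets,
    rxns = data.frame(id = c("F1", "F2", "RV", "DIFF"),
                      lower_bound = c(0, 0, -1000, 0),
                      upper_bound = c(10, 20, 1000, 10),
                      gpr = c("g1", "g2", "g3", "")),
    S = list(F1 = c(A = -1, B = 1), F2 = c(A = -1, B = 1),
             RV = c(A = 1, B = -1),  # reverse-written, reversible
             DIFF = c(A = -1, B = 2)),
    genes = data.frame(id = c("g1", "g2", "g3")))
  out <- removeDuplicates(m)
  kept <- reactions(out$model)
  # F2 collapses into F1; reversible reverse-written RV also collapses
  expect_setequal(kept$id, c("F1", "DIFF"))
  expect_setequal(out$report$removed, c("F2", "RV"))
  f1 <- kept[kept$id == "F1", ]
  expect_equal(f1$lower_bound, -1000)  # widest after flipping RV
  expect_equal(f1$upper_bound, 1000)
  vals <- c(g1 = 1, g2 = 10, g3 = 100)
  expect_equal(oracleGpr(f1$gpr, vals), 111)  # OR-joined rules

  # irreversible A->B vs irreversible B->A are NOT duplicates
  m2 <- MetabolicModel(
    mets = mets,
    rxns = data.frame(id = c("FWD", "BWD"), lower_bound = 0,
                      upper_bound = 10),
    S = list(FWD = c(A = -1, B = 1), BWD = c(A = 1, B = -1)))
  expect_identical(nrow(removeDuplicates(m2)$report), 0L)

  # idempotence
  again <- removeDuplicates(out$model)
  expect_identical(nrow(again$report), 0L)
  expect_equal(as.matrix(stoichiometricMatrix(again$model)),
               as.matrix(stoichiometricMatrix(out$model)))
})

test_that("duplicate removal never changes the biomass optimum", {
  toy <- toyFixture()
  pert <- perturbModel(toy, n_imbalanced = 0, n_duplicate = 3,
                       n_inconsistent = 0, seed = 5)
  before <- objectiveValue(fba(pert$model))
  after <- objectiveValue(fba(removeDuplicates(pert$model)$model))
  expect_equal(after, before, tolerance = 1e-6)
})

test_that("elemental balance classifies reactions and scales linearly", {
  m <- MetabolicModel(
    mets = data.frame(id = c("glcX", "lacX", "pyrX", "mystery"),
                      compartment = "c",
                      formula = c("C6H12O6", "C3H6O3", "C3H4O3", NA)),
    rxns = data.frame(id = c("GLY", "BAD", "UND", "EX"),
                      lower_bound = 0, upper_bound = 10,
                      is_exchange = c(FALSE, FALSE, FALSE, TRUE)),
    S = list(GLY = c(glcX = -1, lacX = 2),
             BAD = c(glcX = -1, pyrX = 1),
             UND = c(glcX = -1, mystery = 1),
             EX = c(glcX = -1)))
  bal <- elementalBalance(m)
  expect_identical(stats::setNames(bal$status, bal$reaction),
                   c(GLY = "balanced", BAD = "imbalanced",
                     UND = "undetermined", EX = "exchange"))
  expect_equal(bal$C[bal$reaction == "BAD"], -3)
  expect_equal(bal$O[bal$reaction == "BAD"], -3)

  # scaling the reaction by k scales imbalances by k
  m2 <- m
  m2@S[, "BAD"] <- 3 * m2@S[, "BAD"]
  bal2 <- elementalBalance(m2, "BAD")
  expect_equal(bal2$C, 3 * bal$C[bal$reaction == "BAD"])
})

test_that("task checking passes designed tasks and fails impossible ones", {
  toy <- toyFixture()
  tasks <- makeSyntheticTasks()
  res <- checkTasks(toy, tasks)
  expect_true(all(res == "pass"))

  impossible <- metabolicTask(
    "glc_from_o2",
    inputs = data.frame(metabolite = "o2_e", max_uptake = 100),
    outputs = data.frame(metabolite = "glc_e", min_production = 1))
  unknown <- metabolicTask(
    "ghost", outputs = data.frame(metabolite = "ghost_e",
                                  min_production = 1))
  res2 <- checkTasks(toy, list(impossible, unknown))
  expect_identical(as.character(res2), c("fail", "fail"))
  expect_match(attr(res2, "reasons")[["ghost"]], "unknown metabolite")

  expect_length(checkTasks(toy, list()), 0)
})

test_that("pruning removes imbalanced dead ends and keeps essential routes", {
  toy <- toyFixture()
  tasks <- makeSyntheticTasks()
  pert <- perturbModel(toy, n_imbalanced = 2, n_duplicate = 0,
                       n_inconsistent = 0, seed = 3)
  out <- pruneImbalanced(pert$model, tasks)
  expect_setequal(out$report$pruned, pert$truth$imbalanced)
  expect_length(out$report$retained_flagged, 0)
  expect_equal(objectiveValue(fba(out$model)),
               objectiveValue(fba(pert$model)), tolerance = 1e-6)

  # an imbalanced reaction that is the sole biomass precursor route stays
  ess <- toy
  j <- match("GPAT", ess@rxns$id)
  ess@S["tag_c", j] <- 2  # breaks carbon balance of an essential reaction
  out2 <- pruneImbalanced(ess, tasks = list())
  expect_identical(out2$report$retained_flagged, "GPAT")
  expect_length(out2$report$pruned, 0)

  # clean model: nothing to prune
  out3 <- pruneImbalanced(toy, tasks = list())
  expect_length(out3$report$pruned, 0)
  expect_identical(nReactions(out3$model), nReactions(toy))
})

test_that("stoichiometric consistency flags only mass-creating metabolites", {
  # A <=> B is consistent
  ab <- MetabolicModel(
    mets = data.frame(id = c("A", "B"), compartment = "c"),
    rxns = data.frame(id = "R1", lower_bound = -10, upper_bound = 10),
    S = list(R1 = c(A = -1, B = 1)))
  expect_length(stoichiometricConsistency(ab), 0)

  # internal A -> 2A creates mass from nothing
  dbl <- MetabolicModel(
    mets = data.frame(id = c("A", "B"), compartment = "c"),
    rxns = data.frame(id = c("DOUBLE", "R1"),
                      lower_bound = 0, upper_bound = 10,
                      is_exchange = FALSE),
    S = list(DOUBLE = c(A = 1), R1 = c(A = -1, B = 1)))
  expect_identical(stoichiometricConsistency(dbl), c("A", "B"))

  # only exchange reactions: nothing internal to test
  exo <- MetabolicModel(
    mets = data.frame(id = "A", compartment = "e"),
    rxns = data.frame(id = "EX_A", lower_bound = -10, upper_bound = 10),
    S = list(EX_A = c(A = -1)))
  expect_length(stoichiometricConsistency(exo), 0)
})

test_that("consistency agrees with brute-force search on tiny models", {
  # brute force: metabolite i is consistent iff an integer mass vector in
  # {0..6}^n with m_i >= 1 satisfies t(S_int) m = 0 (scale-invariance makes
  # the integer grid sufficient for these coefficient sizes)
  bruteConsistent <- function(model) {
    S <- as.matrix(stoichiometricMatrix(model))
    S <- S[, !reactions(model)$is_exchange, drop = FALSE]
    n <- nrow(S)
    grid <- as.matrix(expand.grid(rep(list(0:6), n)))
    ok <- grid[rowSums(abs(grid %*% S)) == 0, , drop = FALSE]
    vapply(seq_len(n), function(i) any(ok[, i] >= 1), logical(1))
  }
  set.seed(31)
  for (k in 1:8) {
    n_met <- sample(2:4, 1)
    n_rxn <- sample(1:3, 1)
    S <- matrix(sample(c(-2, -1, 0, 1, 2), n_met * n_rxn, replace = TRUE),
                n_met, n_rxn)
    m <- MetabolicModel(
      mets = data.frame(id = paste0("M", seq_len(n_met)), compartment = "c"),
      rxns = data.frame(id = paste0("R", seq_len(n_rxn)),
                        lower_bound = 0, upper_bound = 10,
                        is_exchange = FALSE),
      S = S)
    inc_lp <- stoichiometricConsistency(m)
    inc_bf <- metabolites(m)$id[!bruteConsistent(m)]
    expect_setequal(inc_lp, inc_bf)
  }
})
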