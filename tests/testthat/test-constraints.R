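test_that("diet bounds follow the mass-to-flux conversion arithmetic", {
  toy <- toyFixture()
  d <- dietSpec("test", data.frame(
    metabolite = c("glc_e", "fru_e"),
    percent_w_w = c(10, 0),
    class = "carbohydrate", mw = 180.156, carbons = 6), intake = 3)
  bm <- dietBounds(d, toy)
  # 0.10 * 3 / 180.156 * 1000 mmol/day, as uptake cap on the exchange
  b_glc <- -bm$lower[bm$reaction == "EX_glc"]
  expect_equal(b_glc, 0.10 * 3 / 180.156 * 1000, tolerance = 1e-12)
  expect_equal(signif(b_glc, 5), 1.6652)
  # zero percent -> metabolite unavailable
  expect_equal(bm$lower[bm$reaction == "EX_fru"], 0)
  # secretion side untouched
  expect_true(all(is.na(bm$upper)))
  expect_identical(attr(bm, "units"), "mmol/mouse/day")
})

test_that("diet bounds are linear in intake and percent", {
  toy <- toyFixture()
  diets <- dietFixture()
  b1 <- dietBounds(diets$wd, toy)
  d2 <- diets$wd
  d2@intake <- 6
  b2 <- dietBounds(d2, toy)
  expect_equal(b2$lower, 2 * b1$lower)
  e3 <- diets$wd@entries
  e3$percent_w_w <- e3$percent_w_w / 2
  b3 <- dietBounds(dietSpec("half", e3, intake = 3), toy)
  expect_equal(b3$lower, b1$lower / 2)
})

test_that("missing exchange reactions are reported by metabolite", {
  toy <- toyFixture()
  d <- dietSpec("bad", data.frame(metabolite = "unobtainium_e",
                                  percent_w_w = 1, class = "other",
                                  mw = 100, carbons = 1))
  expect_error(dietBounds(d, toy), "unobtainium_e")
})

test_that("pooled components split equally and inherit the class", {
  d <- dietSpec("pools", data.frame(
    metabolite = c("satfa_pool", "mufa_pool", "glc_e"),
    percent_w_w = c(8, 6, 50),
    class = c("lipid", "lipid", "carbohydrate"),
    mw = c(270, 270, 180.156), carbons = c(16, 18, 6)))
  rules <- list(
    satfa_pool = data.frame(
      metabolite = c("palmitate_e", "stearate_e", "myristate_e",
                     "laurate_e"),
      mw = c(256.43, 284.48, 228.37, 200.32), carbons = c(16, 18, 14, 12)),
    mufa_pool = data.frame(
      metabolite = c("eicosenoate_e", "octadecenoate_e", "palmitoleate_e"),
      mw = c(310.5, 282.5, 254.4), carbons = c(20, 18, 16)))
  out <- splitPooledComponents(d, rules)
  e <- out@entries
  expect_false(any(c("satfa_pool", "mufa_pool") %in% e$metabolite))
  expect_equal(e$percent_w_w[e$metabolite == "palmitate_e"], 2)
  expect_equal(e$percent_w_w[e$metabolite == "eicosenoate_e"], 2)
  expect_true(all(e$class[e$metabolite == "palmitoleate_e"] == "lipid"))
  expect_equal(sum(e$percent_w_w), 64)  # mass conserved
  expect_equal(e$percent_w_w[e$metabolite == "glc_e"], 50)

  expect_identical(splitPooledComponents(d, list())@entries, d@entries)
  expect_error(splitPooledComponents(
    d, list(satfa_pool = data.frame(metabolite = character(0),
                                    mw = numeric(0),
                                    carbons = numeric(0)))), "empty")
})

test_that("gas bounds convert volume to a minimum flux in the right direction", {
  toy <- toyFixture()
  o2 <- gasExchangeSpec("O2", density = 1.429, volume = 1)
  bm <- gasBounds(o2, toy, "EX_o2")
  # 1.429 * 1 / 31.998 * 1000 = 44.66 mmol/day forced uptake; EX_o2 is
  # export-oriented so the constraint lands on the upper bound as -b
  expect_equal(-bm$upper, 1.429 / 31.998 * 1000, tolerance = 1e-12)
  expect_equal(signif(-bm$upper, 4), 44.66)
  expect_true(is.na(bm$lower))
  expect_identical(attr(bm, "units"), "mmol/mouse/day")

  co2 <- gasExchangeSpec("CO2", density = 1.977, volume = 0.5)
  bm2 <- gasBounds(co2, toy, "EX_co2")
  expect_equal(bm2$lower, 1.977 * 0.5 / 44.009 * 1000, tolerance = 1e-12)

  zero <- gasBounds(gasExchangeSpec("O2", 1.429, 0), toy, "EX_o2")
  expect_true(is.na(zero$lower) && is.na(zero$upper))
})

test_that("carbon flux sums carbons times flux and is additive", {
  expect_equal(carbonFlux(c(glc = 2), c(glc = 6)), 12)
  expect_equal(carbonFlux(numeric(0), numeric(0)), 0)
  expect_error(carbonFlux(c(x = 1), c(y = 6)), "x")
  a <- c(glc = 2, fru = 1)
  b <- c(fa = 0.5)
  cb <- c(glc = 6, fru = 6, fa = 16)
  expect_equal(carbonFlux(c(a, b), cb),
               carbonFlux(a, cb) + carbonFlux(b, cb))
  # diet fixture total matches a spreadsheet-style sum
  diets <- dietFixture()
  e <- diets$cd@entries
  manual <- sum(e$percent_w_w / 100 * 3 / e$mw * 1000 * e$carbons)
  expect_equal(dietCarbonFlux(diets$cd), manual, tolerance = 1e-12)
})

test_that("E-flux arithmetic: OR sums, AND takes the minimum, symmetry", {
  m <- MetabolicModel(
    mets = data.frame(id = c("A", "B"), compartment = "c"),
    rxns = data.frame(id = c("IRR", "REV", "ORPH", "EX_A"),
                      lower_bound = c(0, -1000, 0, -1000),
                      upper_bound = c(1000, 1000, 1000, 1000),
                      gpr = c("g1 or g2", "g1", "", "")),
    S = list(IRR = c(A = -1, B = 1), REV = c(A = -1, B = 1),
             ORPH = c(A = -1, B = 1), EX_A = c(A = -1)),
    genes = data.frame(id = c("g1", "g2")))
  expr <- expressionProfile("c1", c(g1 = 5, g2 = 7))
  bm <- efluxBounds(m, expr)
  expect_setequal(bm$reaction, c("IRR", "REV"))  # orphan + exchange absent
  expect_equal(bm$lower[bm$reaction == "IRR"], 0)
  expect_equal(bm$upper[bm$reaction == "IRR"], 12)
  expect_equal(bm$lower[bm$reaction == "REV"], -5)
  expect_equal(bm$upper[bm$reaction == "REV"], 5)
})

test_that("E-flux agrees with an independent rule evaluator on random rules", {
  toy <- toyFixture()
  genes <- modelGenes(toy)$id
  set.seed(19)
  for (k in 1:100) {
    rule <- randomGpr(genes)
    vals <- stats::setNames(stats::runif(length(genes), 0, 50), genes)
    vals[sample(genes, 3)] <- NA  # unmeasured genes contribute 0
    measured <- vals[!is.na(vals)]
    tree <- parseGpr(rule)
    expect_equal(sydicos:::gprEval(tree, measured, missing = 0),
                 oracleGpr(rule, measured, missing = 0), tolerance = 1e-12)
  }
})

test_that("raising expression never shrinks E-flux bound intervals", {
  toy <- toyFixture()
  set.seed(4)
  vals <- stats::setNames(stats::rlnorm(nrow(modelGenes(toy)), log(5), 0.5),
                          modelGenes(toy)$id)
  b1 <- efluxBounds(toy, expressionProfile("lo", vals))
  for (g in sample(names(vals), 10)) {
    vals2 <- vals
    vals2[g] <- vals2[g] * 3
    b2 <- efluxBounds(toy, expressionProfile("hi", vals2))
    expect_true(all(b2$upper >= b1$upper - 1e-12))
    expect_true(all(b2$lower <= b1$lower + 1e-12))
  }
})

test_that("expression classes partition the FPKM axis at 1, 10 and 50", {
  expect_identical(classifyExpression(c(50, 120)), c("high", "high"))
  expect_identical(classifyExpression(c(10, 49.999)), c("medium", "medium"))
  expect_identical(classifyExpression(c(1, 9.999)), c("low", "low"))
  expect_identical(classifyExpression(c(0, 0.5, 0.999)),
                   c("none", "none", "none"))
  expect_error(classifyExpression(-1), "non-negative")
})

test_that("constraint layers compose with last-wins precedence", {
  toy <- toyFixture()
  expect_identical(applyConstraints(toy, list()), toy)

  l1 <- data.frame(reaction = "PFK", lower = 0, upper = 3)
  l2 <- data.frame(reaction = "HEX1", lower = 0, upper = 4)
  m <- applyConstraints(toy, list(l1, l2))
  b <- bounds(m)
  expect_equal(b$upper[b$reaction == "PFK"], 3)
  expect_equal(b$upper[b$reaction == "HEX1"], 4)

  l3 <- data.frame(reaction = "PFK", lower = 0, upper = 7)
  m2 <- applyConstraints(toy, list(l1, l3))
  expect_equal(bounds(m2)$upper[bounds(m2)$reaction == "PFK"], 7)

  # structural irreversibility is never widened
  neg <- data.frame(reaction = "PFK", lower = -5, upper = 5)
  m3 <- applyConstraints(toy, list(neg))
  expect_equal(bounds(m3)$lower[bounds(m3)$reaction == "PFK"], 0)

  conflict <- data.frame(reaction = "PFK", lower = 5, upper = 1)
  expect_error(applyConstraints(toy, list(conflict)), "PFK")
})

test_that("expression gating removes silent dead ends but keeps essentials", {
  toy <- toyFixture()
  # glucose oxidation + biomass production (the glycerol task would make
  # the glycerol branch essential, defeating the dead-end check)
  tasks <- makeSyntheticTasks()[1:2]
  vals <- stats::setNames(rep(20, nrow(modelGenes(toy))),
                          modelGenes(toy)$id)

  # everything expressed -> unchanged
  out <- expressionGateExtraction(toy, expressionProfile("all", vals), tasks)
  expect_identical(nReactions(out$model), nReactions(toy))

  # silencing the glycerol-export branch (not needed for biomass) removes
  # it; silencing an essential transporter keeps the reaction
  vals2 <- vals
  vals2[c("Aqp9", "Pgp")] <- 0.1   # glycerol branch silent
  vals2["Cd36"] <- 0.2             # fatty-acid uptake silent but essential
  out2 <- expressionGateExtraction(toy, expressionProfile("gate", vals2),
                                   tasks)
  expect_false("G3PP" %in% reactions(out2$model)$id)
  expect_false("GLYCt" %in% reactions(out2$model)$id)
  expect_true("FAt" %in% reactions(out2$model)$id)
  expect_true("FAt" %in% out2$report$reinstated)
  # the gated model still performs all tasks
  expect_true(all(checkTasks(out2$model, tasks) == "pass"))
})
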