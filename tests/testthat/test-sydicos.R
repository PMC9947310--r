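test_that("diet swaps move classes from the reference and keep the rest", {
  diets <- dietFixture()
  lipid <- swapDiet(swapPlan("l", diets$wd, diets$cd, "lipid"))
  e <- lipid@entries
  cd <- diets$cd@entries
  wd <- diets$wd@entries
  expect_equal(e$percent_w_w[e$metabolite == "fa_e"],
               cd$percent_w_w[cd$metabolite == "fa_e"])
  expect_equal(e$percent_w_w[e$metabolite == "glc_e"],
               wd$percent_w_w[wd$metabolite == "glc_e"])
  expect_equal(e$percent_w_w[e$metabolite == "fru_e"],
               wd$percent_w_w[wd$metabolite == "fru_e"])
  expect_equal(lipid@intake, diets$wd@intake)

  # empty swap leaves the base untouched
  none <- swapDiet(swapPlan("n", diets$wd, diets$cd))
  expect_equal(none@entries$percent_w_w, wd$percent_w_w)

  # swapping a class absent from the reference zeroes base-only members
  ref <- dietSpec("ref", cd[cd$metabolite != "fa_e", ])
  noref <- swapDiet(swapPlan("x", diets$wd, ref, "lipid"))
  expect_equal(noref@entries$percent_w_w[noref@entries$metabolite == "fa_e"],
               0)

  # class mismatch for a shared metabolite errors
  bad <- diets$cd
  bad@entries$class[bad@entries$metabolite == "fa_e"] <- "other"
  expect_error(swapDiet(swapPlan("b", diets$wd, bad, "lipid")),
               "class mismatch")
})

test_that("swapping is involutive on the swapped classes", {
  diets <- dietFixture()
  there <- swapDiet(swapPlan("t", diets$wd, diets$cd,
                             c("lipid", "carbohydrate")))
  back <- swapDiet(swapPlan("b", there, diets$wd,
                            c("lipid", "carbohydrate")))
  a <- back@entries[order(back@entries$metabolite), ]
  b <- diets$wd@entries[order(diets$wd@entries$metabolite), ]
  expect_equal(a$percent_w_w, b$percent_w_w)
  expect_identical(a$metabolite, b$metabolite)
})

test_that("sugar restriction zeroes unlisted carbohydrates only", {
  diets <- dietFixture()
  only_glc <- restrictSugars(diets$wd, "glc_e")
  e <- only_glc@entries
  expect_equal(e$percent_w_w[e$metabolite == "fru_e"], 0)
  expect_equal(e$percent_w_w[e$metabolite == "glc_e"], 25)
  expect_equal(e$percent_w_w[e$metabolite == "fa_e"], 20)

  both <- restrictSugars(diets$wd, c("glc_e", "fru_e"))
  expect_equal(both@entries$percent_w_w, diets$wd@entries$percent_w_w)

  none <- restrictSugars(diets$wd, character(0))
  expect_equal(sum(none@entries$percent_w_w[none@entries$class ==
                                              "carbohydrate"]), 0)

  expect_error(restrictSugars(diets$wd, "fa_e"), "non-carbohydrate")
})

test_that("flux distance is the Euclidean metric on shared reactions", {
  a <- makeFD(c(R1 = 0, R2 = 0))
  b <- makeFD(c(R1 = 3, R2 = 4))
  expect_equal(fluxDistance(a, a), 0)
  expect_equal(fluxDistance(a, b), 5)
  expect_equal(fluxDistance(b, a), 5)
  expect_error(fluxDistance(a, methods::new(
    "FluxDistribution", fluxes = numeric(0), objective_value = NA_real_,
    status = "infeasible")), "optimal")
  expect_warning(fluxDistance(a, makeFD(c(R1 = 1))), "intersection")
})

test_that("distance matrices are symmetric, zero-diagonal and normalised", {
  set.seed(5)
  ds <- lapply(1:4, function(i)
    makeFD(stats::setNames(stats::rnorm(6), paste0("R", 1:6))))
  names(ds) <- paste0("d", 1:4)
  dm <- distanceMatrix(ds, normalize = TRUE)
  v <- dm@values
  expect_true(dm@normalized)
  expect_equal(max(v), 1)
  expect_equal(diag(v), stats::setNames(rep(0, 4), paste0("d", 1:4)))
  expect_true(all(v >= 0 & v <= 1))
  raw <- distanceMatrix(ds, normalize = FALSE)@values
  expect_equal(v, raw / max(raw))

  same <- distanceMatrix(list(a = ds[[1]], b = ds[[1]]))
  expect_equal(same@values, matrix(0, 2, 2, dimnames = list(c("a", "b"),
                                                            c("a", "b"))))
  expect_error(distanceMatrix(ds[1]), "at least two")
})

test_that("flux ratios code carried, new and off reactions", {
  a <- makeFD(c(R1 = 4, R2 = 1e-12, R3 = 2, R4 = -6))
  b <- makeFD(c(R1 = 2, R2 = 1e-12, R3 = 0, R4 = 3))
  fr <- fluxRatio(a, b, epsilon = 1e-9)
  expect_equal(fr$ratio[fr$reaction == "R1"], 2)
  expect_identical(fr$code[fr$reaction == "R2"], "off")
  expect_identical(fr$code[fr$reaction == "R3"], "new")
  expect_equal(fr$ratio[fr$reaction == "R4"], 2)  # absolute values

  same <- fluxRatio(a, a, epsilon = 1e-9)
  carried <- same$code == "ratio"
  expect_true(all(same$ratio[carried] == 1))
})

test_that("exchange accounting balances carbon through the pseudo-boundary", {
  toy <- toyFixture()
  diets <- dietFixture()
  m <- applyConstraints(toy, list(dietBounds(diets$wd, toy)))
  sol <- pfba(m)
  s <- effluxInfluxSummary(sol, toy)
  expect_true(all(s$perMetabolite$flux >= 0))
  glc_row <- s$perMetabolite[s$perMetabolite$metabolite == "glc_e", ]
  expect_equal(glc_row$carbon_flux, glc_row$flux * 6)
  # all internal reactions are carbon balanced -> boundary carbon conserved
  expect_equal(s$totalInflux, s$totalEfflux, tolerance = 1e-6)

  frozen <- setBounds(toy, reactions(toy)$id, lower = 0, upper = 0)
  sol0 <- fba(frozen)
  s0 <- effluxInfluxSummary(sol0, toy)
  expect_equal(s0$totalInflux, 0)
  expect_equal(s0$totalEfflux, 0)
})

test_that("subsystem reaction ratios count carried reactions only", {
  m <- MetabolicModel(
    mets = data.frame(id = c("A", "B"), compartment = "c"),
    rxns = data.frame(id = paste0("R", 1:6),
                      lower_bound = -10, upper_bound = 10,
                      subsystem = c("S1", "S1", "S1", "S1", "S2", "S3")),
    S = stats::setNames(rep(list(c(A = -1, B = 1)), 6), paste0("R", 1:6)))
  a <- makeFD(c(R1 = 5, R2 = 4, R3 = 3, R4 = 1, R5 = 2, R6 = 0))
  b <- makeFD(c(R1 = 1, R2 = 1, R3 = 1, R4 = 2, R5 = 1, R6 = 0))
  ssr <- subsystemReactionRatio(a, b, m, flux_epsilon = 1e-6)
  expect_setequal(ssr$subsystem, c("S1", "S2"))  # S3 carries no flux
  s1 <- ssr[ssr$subsystem == "S1", ]
  expect_equal(s1$n_reactions_with_flux, 4)
  expect_equal(s1$n_higher_in_a, 3)
  expect_equal(s1$reaction_ratio, 0.75)
  expect_equal(ssr$reaction_ratio[ssr$subsystem == "S2"], 1)
  expect_true(all(ssr$reaction_ratio >= 0 & ssr$reaction_ratio <= 1))
})

test_that("differential subnetworks follow connectivity through real metabolites", {
  # chain into biomass: D1 and D2 differ and connect via real metabolites;
  # ISO differs but only shares water with the rest
  m <- MetabolicModel(
    mets = data.frame(id = c("a_c", "b_c", "p_c", "h2o_c", "x_c", "y_c"),
                      compartment = "c"),
    rxns = data.frame(id = c("D1", "D2", "BIO", "ISO"),
                      lower_bound = 0, upper_bound = 10,
                      subsystem = "core"),
    S = list(D1 = c(a_c = -1, b_c = 1, h2o_c = 1),
             D2 = c(b_c = -1, p_c = 1),
             BIO = c(p_c = -1),
             ISO = c(x_c = -1, y_c = 1, h2o_c = 1)),
    objective = "BIO")
  a <- makeFD(c(D1 = 5, D2 = 5, BIO = 5, ISO = 3))
  b <- makeFD(c(D1 = 1, D2 = 1, BIO = 1, ISO = 1))
  sub <- differentialSubnetwork(a, b, m)
  expect_setequal(reactions(sub)$id, c("D1", "D2", "BIO"))
  expect_false("ISO" %in% reactions(sub)$id)

  # empty differential set -> empty subnetwork
  empty <- differentialSubnetwork(a, a, m)
  expect_identical(nReactions(empty), 0L)

  # biomass sharing nothing with the differential set warns and is empty
  a2 <- makeFD(c(D1 = 1, D2 = 1, BIO = 1, ISO = 3))
  expect_warning(sub2 <- differentialSubnetwork(a2, b, m), "biomass")
  expect_identical(nReactions(sub2), 0L)
})

test_that("a SyDiCoS batch is the outer product of models and plans", {
  toy <- toyFixture()
  diets <- dietFixture()
  ex <- makeSyntheticExpression(toy, seed = 2)
  mt <- applyConstraints(toy, list(efluxBounds(toy, ex$t)))
  mp <- applyConstraints(toy, list(efluxBounds(toy, ex$pt)))
  plans <- list(
    wd = swapPlan("wd", diets$wd, diets$cd),
    full = swapPlan("full", diets$wd, diets$cd,
                    c("carbohydrate", "lipid", "amino_acid")))
  res <- runSydicos(list(T = mt, PT = mp), plans,
                    gas_layers = gasLayers(toy))
  expect_length(res$distributions, 4)
  expect_setequal(names(res$distributions),
                  c("T|wd", "T|full", "PT|wd", "PT|full"))
  expect_true(all(res$status$status == "optimal"))

  # batch equals the loop of singles
  single <- pfba(applyConstraints(
    mt, c(list(dietBounds(swapDiet(plans$wd), mt)), gasLayers(toy))))
  expect_equal(fluxes(res$distributions[["T|wd"]]), fluxes(single))
})
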