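# Rewiring an ecGEM through amino-acid drains, and SBML round trips.

test_that("rewiring preserves the optimal growth of the parent model", {
  toy <- toyEC1()
  acid <- buildAcidFBA(toy$model, buildXi(toy$proteins))
  zP <- objectiveValue(maximizeGrowth(toy$model))
  zA <- objectiveValue(maximizeGrowth(acid))
  expect_lt(abs(zA - zP) / zP, 1e-6)
  # structure: 20 drains, rewired sources consume only amino-acid species
  expect_length(drainReactions(acid), 20)
  S <- stoichiometry(acid)
  for (src in acid@sourceReactions) {
    consumed <- rownames(S)[S[, src] < 0]
    expect_true(all(consumed %in% acid@aaMetabolites))
  }
  # pool bound unchanged from parent
  expect_equal(poolBound(acid), poolBound(toy$model))
})

test_that("strict mode names enzymes without composition rows", {
  toy <- makeToyEcgem(c(E1 = "AAAA", E2 = "GGGG", E3 = "AAGG"),
                      kcats = c(100, 1000, 500), yields = c(1, 0.5, 0.8))
  xi <- buildXi(toy$proteins[1:2])
  expect_error(buildAcidFBA(toy$model, xi), "E3")
  # lenient mode imputes the mean composition at the parent MW and keeps
  # the optimum
  acid <- suppressMessages(buildAcidFBA(toy$model, xi, strict = FALSE))
  zP <- objectiveValue(maximizeGrowth(toy$model))
  zA <- objectiveValue(maximizeGrowth(acid))
  expect_lt(abs(zA - zP) / zP, 1e-6)
  # imputed row still carries the draw reaction's full mass cost
  expect_equal(unname(1000 * rowSums(xiMatrix(compositionMatrix(acid)))[3]),
               unname(1000 * enzymeMW(toy$model)["prot_E3"]))
})

test_that("xi disagreeing with the draw-reaction MW warns and wins", {
  toy <- toyEC1()
  # composition built from the wrong sequence for E1 (longer chain)
  xi <- buildXi(c(E1 = "AAAAAA", E2 = "GGGG"))
  expect_warning(acid <- buildAcidFBA(toy$model, xi), "E1")
  expect_equal(unname(enzymeMW(acid)["prot_E1"]), 6 * 71.079 / 1000)
})

test_that("identifier collisions are rejected", {
  toy <- toyEC1()
  bad <- toy$model
  rn <- rownames(bad@S)
  rn[match("S_c", rn)] <- "aa_A"
  rownames(bad@S) <- rn
  expect_error(buildAcidFBA(bad, buildXi(toy$proteins)), "collision")
})

test_that("a model without enzymes gains 20 dead-end drains only", {
  ec <- emptyEnzymeModel()
  acid <- buildAcidFBA(ec, buildXi(character(0)))
  expect_length(drainReactions(acid), 20)
  zP <- objectiveValue(maximizeGrowth(ec))
  sol <- maximizeGrowth(acid)
  expect_equal(objectiveValue(sol), zP)
  # drains are dead ends: zero flux in any steady state
  expect_true(all(abs(fluxes(sol)[drainReactions(acid)]) < 1e-9))
})

test_that("permuting composition rows leaves the optimum unchanged", {
  toy <- toyRichAcid()
  xi <- compositionMatrix(toy$model)
  perm <- buildXi(rev(stats::setNames(
    vapply(proteinIds(xi), function(p) toy$proteins[[p]], character(1)),
    proteinIds(xi))))
  acidPerm <- buildAcidFBA(toy$parent, perm)
  expect_equal(objectiveValue(maximizeGrowth(acidPerm)),
               objectiveValue(maximizeGrowth(toy$model)))
})

test_that("uniform variants keep per-enzyme mass cost and optimum", {
  toy <- toyAcid()
  prof <- aaProfileAtOptimum(toy$model)$profile
  uni <- makeUniformVariant(toy$model, prof)
  expect_equal(unname(1000 * rowSums(xiMatrix(compositionMatrix(uni)))),
               unname(1000 * enzymeMW(toy$model)))
  expect_equal(objectiveValue(maximizeGrowth(uni)),
               objectiveValue(maximizeGrowth(toy$model)))
  # both enzymes draw each amino acid in proportion to the shared profile
  xiU <- xiMatrix(compositionMatrix(uni))
  fr <- sweep(xiU, 1, rowSums(xiU), "/")
  expect_equal(fr[1, ], fr[2, ], tolerance = 1e-12)
  # unnormalized profiles are rejected
  expect_error(makeUniformVariant(toy$model, rep(0.045, 20)), "sum to 1")
})

test_that("mass closure holds structurally in feasible solutions", {
  toy <- toyAcid()
  for (frac in c(1.0, 0.8, 0.3)) {
    res <- aaProfileAtOptimum(toy$model, optFraction = frac)
    expectMassClosure(toy$model, res$solution)
    expect_equal(sum(profileMass(res$profile)),
                 unname(fluxes(res$solution)[poolReaction(toy$model)]),
                 tolerance = 1e-9)
  }
})

test_that("models round-trip through SBML with identical optima", {
  toy <- toyNutrient()
  f <- withr::local_tempfile(fileext = ".xml")
  writeModelSBML(toy$model, f)
  back <- suppressMessages(readAcidFBAModelSBML(f))
  expect_equal(objectiveValue(maximizeGrowth(back)),
               objectiveValue(maximizeGrowth(toy$model)))
  # constraint matrix identical up to row/column order
  S1 <- stoichiometry(toy$model)
  S2 <- stoichiometry(back)
  expect_setequal(rownames(S1), rownames(S2))
  expect_setequal(colnames(S1), colnames(S2))
  expect_equal(S2[rownames(S1), colnames(S1)], S1)
  expect_equal(unname(upperBounds(back)[colnames(S1)]),
               unname(upperBounds(toy$model)))
  # drains present exactly once per amino acid
  expect_length(unique(drainReactions(back)), 20)
  # composition matrix survives
  expect_equal(xiMatrix(compositionMatrix(back))[proteinIds(compositionMatrix(toy$model)), ],
               xiMatrix(compositionMatrix(toy$model)))
  # nutrient-class annotation survives
  a1 <- exchangeAnnotation(toy$model)
  a2 <- exchangeAnnotation(back)
  expect_setequal(paste(a1$reaction, a1$class), paste(a2$reaction, a2$class))

  # plain ecGEM reader on the same file classifies the GECKO parts
  ec <- suppressMessages(readEcModelSBML(f))
  expect_length(enzymeMetabolites(ec), 2)
  expect_equal(poolReaction(ec), poolReaction(toy$model))
})

test_that("GECKO classification errors are specific", {
  toy <- toyEC1()
  f <- withr::local_tempfile(fileext = ".xml")
  writeModelSBML(toy$model, f)
  expect_error(suppressMessages(
    readEcModelSBML(f, poolMetabolite = "no_such_pool")),
    "no protein pool exchange")
  # remove a draw reaction: enzyme metabolite left without one
  txt <- readLines(f)
  drop <- grep('reaction id="draw_prot_E1"', txt)
  end <- drop + grep("</reaction>", txt[drop:length(txt)])[1] - 1
  writeLines(txt[-(drop:end)], f)
  expect_error(suppressMessages(readEcModelSBML(f)),
               "prot_E1 must have exactly one draw reaction")
})
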