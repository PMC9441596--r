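# Growth maximization, parsimonious profiles, drain FVA, chemostat sweeps
# and mode comparisons, checked against the analytic vertex solutions.

test_that("growth maximization matches the analytic vertex", {
  ex <- toyEC1Exact()
  toy <- toyAcid()
  sol <- maximizeGrowth(toy$model)
  expect_equal(objectiveValue(sol), ex$z, tolerance = 1e-8)
  expect_equal(objectiveValue(sol), 6.4757288, tolerance = 1e-6)

  # capacity constraint slack: huge pool -> uptake-limited optimum 10
  big <- toyAcid(poolBound = 1e4)
  expect_equal(objectiveValue(maximizeGrowth(big$model)), 10,
               tolerance = 1e-9)
  # no enzyme mass -> no growth
  zero <- toyAcid(poolBound = 0)
  expect_equal(objectiveValue(maximizeGrowth(zero$model)), 0,
               tolerance = 1e-12)
})

test_that("the optimal amino-acid profile matches the vertex masses", {
  ex <- toyEC1Exact()
  toy <- toyAcid()
  res <- aaProfileAtOptimum(toy$model)
  m <- profileMass(res$profile)
  # route masses: a_Ala = w1 v1, a_Gly = w2 v2 at the binding vertex
  expect_equal(unname(m["A"]), ex$w1 * ex$v1, tolerance = 1e-8)
  expect_equal(unname(m["G"]), ex$w2 * ex$v2, tolerance = 1e-8)
  expect_equal(unname(m["A"]), 0.008391, tolerance = 1e-3)
  expect_equal(unname(m["G"]), 0.001609, tolerance = 1e-3)
  expect_equal(sum(m), 0.01, tolerance = 1e-9)  # pool bound, binding
  fr <- profileFraction(res$profile)
  expect_equal(unname(fr[c("A", "G")]), c(0.839, 0.161), tolerance = 1e-3)
  expectMassClosure(toy$model, res$solution)
})

test_that("zero demanded growth needs no proteome", {
  toy <- toyAcid()
  res <- aaProfileAtOptimum(toy$model, optFraction = 0)
  expect_true(all(profileMass(res$profile) < 1e-12))
})

test_that("pool minimization picks the cost-efficient route", {
  ex <- toyEC1Exact()
  toy <- toyAcid()
  # E2 is cheaper per biomass: pool(mu) = 2 mu w2 while uptake allows
  mp <- minPoolAtGrowth(toy$model, 3)
  expect_equal(mp$poolFlux, 2 * 3 * ex$w2, tolerance = 1e-8)
  expect_equal(mp$poolFlux, 0.001369, tolerance = 1e-3)
  expectMassClosure(toy$model, mp$solution)
  # at the maximum the bound itself is needed
  mp2 <- minPoolAtGrowth(toy$model, ex$z)
  expect_equal(mp2$poolFlux, 0.01, tolerance = 1e-8)
  # above the maximum: infeasible status, not an error
  mp3 <- minPoolAtGrowth(toy$model, 1.1 * ex$z)
  expect_identical(solutionStatus(mp3$solution), "infeasible")
  expect_null(mp3$profile)
})

test_that("FVA envelopes contain the parsimonious point solution", {
  toy <- toyRichAcid()
  for (frac in c(0.99, 1.0)) {
    fva <- drainFVA(toy$model, optFraction = frac)
    expect_true(all(fva$min <= fva$max + 1e-12))
    pt <- profileMass(aaProfileAtOptimum(toy$model, optFraction = frac)$profile)
    expect_true(all(pt >= fva$min - 1e-8))
    expect_true(all(pt <= fva$max + 1e-8))
  }
})

test_that("structurally absent amino acids have pinned zero ranges", {
  toy <- toyAcid()  # sequences use only A and G
  fva <- drainFVA(toy$model, optFraction = 0.99)
  absent <- !(fva$code %in% c("A", "G"))
  expect_true(all(abs(fva$min[absent]) < 1e-9))
  expect_true(all(abs(fva$max[absent]) < 1e-9))
  expect_true(all(is.na(fva$relVariability[absent])))
})

test_that("uniform composition collapses all drain variabilities", {
  # with one shared composition, every drain is a fixed share of the pool
  # flux, so all relative variabilities coincide exactly
  toy <- toyRichAcid()
  uni <- makeUniformVariant(toy$model,
                            aaProfileAtOptimum(toy$model)$profile)
  fva <- drainFVA(uni, optFraction = 0.99)
  rv <- fva$relVariability[!is.na(fva$relVariability)]
  expect_length(rv, 20)
  expect_lt(max(rv) - min(rv), 1e-6)
})

test_that("enzyme-limited uniform control sits at the optimality slack", {
  # pool as the only binding constraint: growth is proportional to pool
  # flux, so the common relative variability is the 1% slack itself,
  # 0.01 / 0.995
  toy <- toyRichAcid(uptake = 1e5)
  uni <- makeUniformVariant(toy$model,
                            aaProfileAtOptimum(toy$model)$profile)
  fva <- drainFVA(uni, optFraction = 0.99)
  rv <- fva$relVariability[!is.na(fva$relVariability)]
  expect_length(rv, 20)
  expect_lt(max(rv) - min(rv), 1e-6)
  expect_equal(mean(rv), 0.01 / 0.995, tolerance = 1e-6)
})

test_that("growth is non-decreasing in the pool bound", {
  z <- vapply(c(0, 1e-3, 3e-3, 0.01, 0.03, 0.1, 1),
              function(p) objectiveValue(maximizeGrowth(toyAcid(poolBound = p)$model)),
              numeric(1))
  expect_true(all(diff(z) >= -1e-10))
})

test_that("chemostat sweeps trace the route switch and the critical rate", {
  ex <- toyEC1Exact()
  toy <- toyAcid()
  sw <- chemostatSweep(toy$model, seq(1, 5, by = 1),
                       ptotal = function(mu) 0.5)
  # below the uptake kink (mu <= 5) the cheap route alone carries growth:
  # constant pure-glycine profile and linear pool usage
  expect_true(all(abs(sw$profiles[, "G"] - 1) < 1e-9))
  expect_equal(sw$table$poolFlux, 2 * seq(1, 5) * ex$w2, tolerance = 1e-9)
  expect_true(is.na(sw$criticalMu))

  # enzyme-limited variant: pool binds exactly at mu* = P / (2 w2)
  toyEL <- toyAcid(uptake = 1e5)
  muStar <- 0.01 / (2 * ex$w2)   # also the maximal growth rate here
  grid <- c(0.5, 0.9, 0.999, 1) * muStar
  swEL <- chemostatSweep(toyEL$model, grid, ptotal = function(mu) 0.5)
  expect_equal(swEL$criticalMu, muStar, tolerance = 1e-12)
  expect_true(all(swEL$table$feasible))

  # a p_total table is interpolated; constant table equals the constant fn
  swTab <- chemostatSweep(toy$model, seq(1, 5, by = 1),
                          ptotal = data.frame(mu = c(0, 10),
                                              ptotal = c(0.5, 0.5)))
  expect_equal(swTab$table$poolFlux, sw$table$poolFlux)

  # infeasible grid points are skipped, not fatal
  swInf <- suppressMessages(
    chemostatSweep(toy$model, c(6, 7), ptotal = function(mu) 0.5))
  expect_identical(swInf$table$feasible, c(TRUE, FALSE))
})

test_that("condition files apply bound overrides and blocks", {
  toy <- toyAcid()
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("bounds:",
               "  - reaction: EX_C_glc",
               "    ub: 4",
               "blocked:",
               "  - r_E1"), f)
  cond <- readConditionFile(f)
  m <- applyConditions(toy$model, cond)
  expect_equal(unname(upperBounds(m)["EX_C_glc"]), 4)
  expect_equal(unname(upperBounds(m)["r_E1"]), 0)
  # empty condition set is the identity
  expect_equal(applyConditions(toy$model, NULL), toy$model)
  # E1 blocked and uptake 4: all growth through E2 at yield 0.5
  expect_equal(objectiveValue(maximizeGrowth(m)), 2, tolerance = 1e-9)
})

test_that("mode comparison contrasts profiles with a sentinel policy", {
  toy <- toyAcid()
  # identical setups: zero deviation everywhere
  same <- compareModes(toy$model, list(conditions = NULL),
                       list(conditions = NULL))
  expect_equal(max(same$deviation, na.rm = TRUE), 0)
  expect_equal(same$median, 0)

  # pool-binding optimum (mixed routes) vs pool-slack growth (pure E2)
  cm <- compareModes(toy$model,
                     fermentative = list(conditions = NULL),
                     respiratory = list(conditions = NULL, growth = 3))
  # glycine fraction: |0.1609 - 1| / 1
  ex <- toyEC1Exact()
  fr <- ex$w2 * ex$v2 / (ex$w1 * ex$v1 + ex$w2 * ex$v2)
  expect_equal(unname(cm$deviation["G"]), abs(fr - 1), tolerance = 1e-6)
  # alanine appears only in the fermentative profile: sentinel NA
  expect_true(is.na(cm$deviation["A"]))
  expect_gte(cm$median, 0)

  # forced single-route setups exercise the zero-denominator guard
  e1only <- list(conditions = list(blocked = "r_E2"))
  e2only <- list(conditions = list(blocked = "r_E1"))
  cm2 <- compareModes(toy$model, e1only, e2only)
  expect_true(is.na(cm2$deviation["A"]))   # resp has no alanine
  expect_equal(unname(cm2$deviation["G"]), 1)  # ferm has no glycine
})
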