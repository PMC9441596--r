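# Species distributions: loading, hard proportionality constraints, and
# minimally-different quadratic fits.

test_that("distribution tables load in both unit conventions", {
  uni <- data.frame(code = aminoAcidCodes(), fraction = rep(0.05, 20))
  d <- loadDistribution(uni)
  expect_equal(unname(distributionFraction(d)), rep(0.05, 20))

  # missing amino acid named in the error
  miss <- uni[uni$code != "W", ]
  expect_error(loadDistribution(miss), "tryptophan absent")
  expect_error(loadDistribution(transform(uni, fraction = c(-0.05, rep(0.05, 19)))),
               "non-negative")

  # biomass coefficients (mmol/gDW) convert by residue-mass weighting:
  # hand computation with three non-zero rows
  coef <- data.frame(code = aminoAcidCodes(), coefficient = 0)
  coef$coefficient[coef$code == "A"] <- 2
  coef$coefficient[coef$code == "G"] <- 1
  coef$coefficient[coef$code == "W"] <- 0.5
  d2 <- loadDistribution(coef)
  hand <- c(2 * 71.079, 1 * 57.052, 0.5 * 186.214)
  hand <- hand / sum(hand)
  expect_equal(unname(distributionFraction(d2)[c("A", "G", "W")]), hand)

  # off-unity fractions renormalize with a warning
  off <- transform(uni, fraction = rep(0.045, 20))
  expect_warning(d3 <- loadDistribution(off), "renormalizing")
  expect_equal(sum(distributionFraction(d3)), 1)

  # TSV round trip with unit inference from the header
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(uni, f, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_equal(distributionFraction(loadDistribution(f)),
               distributionFraction(d))
})

test_that("hard profile constraints reproduce the analytic optima", {
  toy <- toyAcid()
  ex <- toyEC1Exact()
  # pure glycine: only the E2 route is expressible; optimum = uptake * y2
  gly <- speciesDist(c(G = 1))
  expect_equal(referenceGrowthState(toy$model, gly)$growth, 5,
               tolerance = 1e-8)
  # pure tryptophan: no enzyme contains W; nothing can be expressed
  trp <- speciesDist(c(W = 1))
  expect_equal(referenceGrowthState(toy$model, trp)$growth, 0,
               tolerance = 1e-12)
  # the model's own optimal fractions leave the optimum unchanged
  own <- speciesDist(profileFraction(aaProfileAtOptimum(toy$model)$profile))
  expect_equal(referenceGrowthState(toy$model, own)$growth, ex$z,
               tolerance = 1e-8)
})

test_that("profile differences follow the sentinel policy", {
  toy <- toyAcid()
  own <- aaProfileAtOptimum(toy$model)$profile
  d0 <- profileDifference(own, speciesDist(profileFraction(own)))
  expect_equal(max(d0, na.rm = TRUE), 0)
  # two-amino-acid arithmetic: q = (0.6, 0.4) vs p = (0.5, 0.5)
  q <- stats::setNames(rep(0, 20), aminoAcidCodes())
  q[c("A", "G")] <- c(0.6, 0.4)
  d <- profileDifference(q, speciesDist(c(A = 0.5, G = 0.5)))
  expect_equal(unname(d[c("A", "G")]), c(0.2, 0.2))
  # p = 0 with q > 0 is a sentinel, both-zero is 0
  q2 <- stats::setNames(rep(0, 20), aminoAcidCodes())
  q2[c("A", "C")] <- c(0.5, 0.5)
  d2 <- profileDifference(q2, speciesDist(c(A = 1)))
  expect_true(is.na(d2["C"]))
  expect_equal(unname(d2["G"]), 0)
})

test_that("the quadratic fit matches a dense grid search", {
  toy <- toyAcid()
  gly <- speciesDist(c(G = 1))
  refG <- 5
  for (fr in c(0.6, 1.2)) {
    fit <- minEuclideanFit(toy$model, gly, fr, refG)
    expect_identical(fit$status, "optimal")
    oracle <- gridFitOracle(toy$proteins, c(100, 1000), c(1, 0.5),
                            uptake = 10, pool = 0.01, mu = fr * refG,
                            p = unname(distributionFraction(gly)),
                            n = 4000)
    expect_lte(fit$distance, oracle + 1e-6)
    expect_equal(fit$distance, oracle, tolerance = 1e-3)
  }
})

test_that("feasible targets are hit exactly, infeasible ones approached", {
  toy <- toyAcid()
  gly <- speciesDist(c(G = 1))
  refG <- 5
  # below the E2-only capacity the target profile is attainable
  lo <- minEuclideanFit(toy$model, gly, 0.5, refG)
  expect_lt(lo$distance, 1e-6)
  expect_gt(profileFraction(lo$profile)["G"], 1 - 1e-4)
  # above it, alanine must be blended in and the distance is positive
  hi <- minEuclideanFit(toy$model, gly, 1.2, refG)
  expect_gt(hi$distance, 1e-4)
  expect_gt(profileFraction(hi$profile)["A"], 0.1)
  # beyond the unconstrained maximum: infeasible
  inf <- minEuclideanFit(toy$model, gly, 1.4, refG)
  expect_identical(inf$status, "infeasible")
})

test_that("fit distance is zero exactly when the hard constraint is feasible", {
  toy <- toyAcid()
  gly <- speciesDist(c(G = 1))
  glyMax <- referenceGrowthState(toy$model, gly)$growth   # 5
  refG <- glyMax
  for (fr in seq(0.2, 1.25, by = 0.15)) {
    fit <- minEuclideanFit(toy$model, gly, fr, refG)
    feasible <- fr * refG <= glyMax + 1e-9
    if (feasible) {
      expect_lt(fit$distance, 1e-6)
    } else {
      expect_gt(fit$distance, 1e-6)
    }
  }
})

test_that("minimal distance grows with growth once the pool binds", {
  toy <- toyAcid()
  gly <- speciesDist(c(G = 1))
  fits <- vapply(seq(1.0, 1.29, by = 0.05), function(fr) {
    minEuclideanFit(toy$model, gly, fr, 5)$distance
  }, numeric(1))
  expect_true(all(diff(fits) > -1e-9))
})

test_that("growth-fraction scans tabulate the rising divergence", {
  toy <- toyAcid()
  # reference state: growth maximized under the hard glycine-only profile
  gly <- speciesDist(c(G = 1))
  refG <- referenceGrowthState(toy$model, gly)$growth   # 5
  scan <- growthFractionScan(toy$model, gly, refG)
  expect_true(all(c("fraction", "code", "absRelDiff") %in% colnames(scan)))
  # the reference profile is held at relative growth rates up to 1.0 ...
  below <- scan[scan$fraction <= 1 + 1e-9 & scan$feasible, ]
  expect_lt(max(below$distance), 1e-6)
  # ... and must be abandoned, increasingly, above the critical point
  above <- scan[scan$fraction > 1 + 1e-9 & scan$feasible, ]
  expect_gt(min(above$distance), 1e-6)
  byFrac <- tapply(above$distance, above$fraction, unique)
  expect_true(all(diff(byFrac) > 0))
  # the default grid ends at the unconstrained-maximum growth ratio
  expect_lte(max(scan$fraction) * refG,
             objectiveValue(maximizeGrowth(toy$model)) + 1e-6)
  # single fraction: one row per amino acid
  one <- growthFractionScan(toy$model, gly, refG, fractions = 0.1)
  expect_equal(nrow(one), 20)
  # fractions beyond the upper bound are flagged, not fatal
  over <- growthFractionScan(toy$model, gly, refG,
                             fractions = c(0.5, 1.5))
  expect_identical(unique(over$feasible[over$fraction == 1.5]), FALSE)
})
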