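# Shared fixtures, all generated in code.

# ToyEC-1: the reference two-enzyme model. Exact optimum from the analytic
# vertex: v1 = (P - w2 U)/(w1 - w2), v2 = U - v1, z = y1 v1 + y2 v2 with
# w_k = MW_k/1000/kcat_k.
toyEC1Exact <- function(uptake = 10, pool = 0.01) {
  w1 <- 4 * 71.079 / 1000 / 100    # E1 = AAAA, kcat 100
  w2 <- 4 * 57.052 / 1000 / 1000   # E2 = GGGG, kcat 1000
  v1 <- (pool - w2 * uptake) / (w1 - w2)
  v2 <- uptake - v1
  list(w1 = w1, w2 = w2, v1 = v1, v2 = v2, z = v1 + 0.5 * v2)
}

toyAcid <- function(uptake = 10, poolBound = 0.01) {
  toy <- toyEC1(uptake = uptake, poolBound = poolBound)
  list(model = buildAcidFBA(toy$model, buildXi(toy$proteins)),
       parent = toy$model, proteins = toy$proteins)
}

# two enzymes whose sequences jointly and severally cover all 20 amino
# acids, so that every drain is active; used for the uniform-composition
# control where all 20 variabilities must be comparable
richSequences <- function() {
  c(EA = paste(rep("ACDEFGHIKLMNPQRSTVWY", 6), collapse = ""),
    EB = paste(rep("YWVTSRQPNMLKIHGFEDCA", 4), collapse = ""))
}

toyRichAcid <- function(uptake = 10, poolBound = 0.01) {
  toy <- makeToyEcgem(richSequences(), kcats = c(100, 1000),
                      yields = c(1, 0.5), uptake = uptake,
                      poolBound = poolBound)
  list(model = buildAcidFBA(toy$model, buildXi(toy$proteins)),
       parent = toy$model, proteins = toy$proteins)
}

# model with all four elemental classes and a spread of carbon sources
toyNutrient <- function(uptake = 10, poolBound = 0.01) {
  src <- list(
    C = list(list(id = "EX_C_glc", yield = 1),
             list(id = "EX_C_gal", yield = 0.5),
             list(id = "EX_C_bad", usable = FALSE)),
    N = list(list(id = "EX_N_nh4")),
    P = list(list(id = "EX_P_pi")),
    S = list(list(id = "EX_S_so4")))
  toy <- makeToyEcgem(c(E1 = "AAAA", E2 = "GGGG"), kcats = c(100, 1000),
                      yields = c(1, 0.5), uptake = uptake,
                      poolBound = poolBound, sources = src)
  list(model = buildAcidFBA(toy$model, buildXi(toy$proteins)),
       parent = toy$model, proteins = toy$proteins)
}

# enzyme-free metabolic model with a pool exchange (K = 0 edge case)
emptyEnzymeModel <- function(poolBound = 0.01, uptake = 10) {
  mets <- c("S_c", "P_c", "prot_pool")
  rxns <- c("EX_C_glc", "conv", "biomass", "prot_pool_exchange")
  S <- matrix(0, 3, 4, dimnames = list(mets, rxns))
  S["S_c", "EX_C_glc"] <- 1
  S["S_c", "conv"] <- -1; S["P_c", "conv"] <- 1
  S["P_c", "biomass"] <- -1
  S["prot_pool", "prot_pool_exchange"] <- 1
  new("EcModel", S = S, lb = rep(0, 4), ub = c(uptake, 1000, 1000, poolBound),
      objective = c(0, 0, 1, 0),
      poolReaction = "prot_pool_exchange", poolMetabolite = "prot_pool",
      enzymeMetabolites = character(0),
      drawReactions = stats::setNames(character(0), character(0)),
      enzymeMW = stats::setNames(numeric(0), character(0)),
      exchangeAnnotation = data.frame(reaction = character(0),
                                      class = character(0)))
}

speciesDist <- function(fracs, label = "test") {
  p <- stats::setNames(rep(0, 20), aminoAcidCodes())
  p[names(fracs)] <- fracs
  new("SpeciesDistribution", species = label, fraction = p / sum(p))
}

expectMassClosure <- function(model, solution, tol = 1e-9) {
  expect_lte(massClosureGap(model, solution), tol)
}

# brute-force per-character residue tally, independent of countResidues
bruteTally <- function(sequence) {
  out <- stats::setNames(integer(20), aminoAcidCodes())
  for (ch in strsplit(sequence, "")[[1]]) out[ch] <- out[ch] + 1L
  out
}

# dense grid search oracle for the Euclidean profile fit on a 2-enzyme toy:
# enumerate feasible route-flux pairs, derive drain masses, minimize the
# quadratic objective directly
gridFitOracle <- function(proteins, kcats, yields, uptake, pool, mu, p,
                          n = 400) {
  xi <- xiMatrix(buildXi(proteins))
  w <- vapply(proteins, proteinMW, numeric(1)) / 1000 / kcats
  best <- Inf
  # biomass mu = y1 v1 + y2 v2 -> line segment in (v1, v2)
  v1max <- min(uptake, mu / yields[1], pool / w[1])
  for (v1 in seq(0, v1max, length.out = n)) {
    v2 <- (mu - yields[1] * v1) / yields[2]
    if (v2 < -1e-12 || v1 + v2 > uptake + 1e-9) next
    if (w[1] * v1 + w[2] * v2 > pool + 1e-12) next
    e <- c(v1 / kcats[1], v2 / kcats[2])
    a <- as.vector(t(xi) %*% e)
    tt <- sum(a)
    val <- sum((a - p * tt)^2)
    if (val < best) best <- val
  }
  sqrt(best)
}
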