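## Phenotype simulation: growth maximization, parsimonious profile
## extraction, drain-level FVA, chemostat sweeps, and mode comparisons.

.BIO_EQ_TOL <- 1e-9   # relative tolerance when fixing biomass at optimum
.POOL_SLACK_TOL <- 1e-8  # g/gDW; pool considered binding below this slack

#' Maximize growth
#'
#' Solves the model's flux balance problem for its designated objective
#' (biomass) reaction. Infeasibility is reported in the solution status, not
#' raised.
#'
#' @param model An \linkS4class{EcModel} or \linkS4class{AcidFBAModel}.
#' @return A \linkS4class{FluxSolution}.
#' @export
setGeneric("maximizeGrowth", function(model) standardGeneric("maximizeGrowth"))

#' @rdname maximizeGrowth
#' @export
setMethod("maximizeGrowth", "EcModel", function(model) {
  biomassReaction(model)  # errors when none designated
  .modelLP(model, objective = model@objective, maximize = TRUE)
})

## minimize sum |v| at fixed bounds, by splitting reversible fluxes.
## costs: numeric per-reaction weights (default 1 everywhere).
.minTotalFlux <- function(model, lb, ub, costs = NULL) {
  S <- model@S
  n <- ncol(S)
  if (is.null(costs)) costs <- rep(1, n)
  neg <- which(lb < 0)
  Sx <- S
  lbx <- pmax(lb, 0)
  ubx <- pmax(ub, 0)
  cx <- costs
  if (length(neg)) {
    Sx <- cbind(S, -S[, neg, drop = FALSE])
    lbx <- c(lbx, pmax(-ub[neg], 0))
    ubx <- c(ubx, -lb[neg])
    cx <- c(cx, costs[neg])
    colnames(Sx) <- c(colnames(S), paste0(".rev_", colnames(S)[neg]))
  }
  res <- .simplexSolve(cx, Sx, rep(0, nrow(Sx)), lbx, ubx, maximize = FALSE)
  if (res$status != "optimal") return(list(status = res$status))
  v <- res$x[seq_len(n)]
  if (length(neg)) v[neg] <- v[neg] - res$x[n + seq_along(neg)]
  list(status = "optimal", fluxes = stats::setNames(v, colnames(S)),
       fluxSum = res$objective)
}

.profileFromFluxes <- function(model, v) {
  .newProfile(unname(v[model@drainReactions]))
}

#' Amino-acid profile at (near-)optimal growth
#'
#' Fixes the biomass flux at \code{optFraction} times its maximum, minimizes
#' the overall sum of absolute fluxes (parsimonious step, giving a unique
#' flux distribution), and reads the amino-acid profile off the drain
#' reactions.
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param optFraction Fraction of the maximal growth at which biomass is
#'   fixed (equality), default 1.0.
#' @param includePseudo Include enzyme draws, drains and the pool exchange in
#'   the minimized flux sum (default \code{TRUE}); \code{FALSE} restricts
#'   the sum to ordinary metabolic reactions.
#' @return List with \code{solution} (\linkS4class{FluxSolution}; objective
#'   is the fixed biomass flux), \code{profile}
#'   (\linkS4class{AminoAcidProfile}) and \code{fluxSum}.
#' @export
aaProfileAtOptimum <- function(model, optFraction = 1.0,
                               includePseudo = TRUE) {
  stopifnot(methods::is(model, "AcidFBAModel"),
            optFraction >= 0, optFraction <= 1)
  opt <- maximizeGrowth(model)
  if (solutionStatus(opt) != "optimal")
    return(list(solution = opt, profile = NULL, fluxSum = NA_real_))
  zfix <- optFraction * objectiveValue(opt)
  bio <- match(biomassReaction(model), colnames(model@S))
  lb <- model@lb; ub <- model@ub
  lb[bio] <- zfix * (1 - .BIO_EQ_TOL)
  ub[bio] <- zfix * (1 + .BIO_EQ_TOL) + (zfix == 0) * 0
  costs <- rep(1, ncol(model@S))
  if (!includePseudo) {
    pseudo <- c(model@drawReactions, model@drainReactions,
                model@poolReaction)
    costs[match(pseudo, colnames(model@S))] <- 0
  }
  res <- .minTotalFlux(model, lb, ub, costs)
  if (res$status != "optimal")
    return(list(solution = .newSolution(res$status), profile = NULL,
                fluxSum = NA_real_))
  sol <- .newSolution("optimal", objective = unname(res$fluxes[bio]),
                      fluxes = res$fluxes)
  list(solution = sol, profile = .profileFromFluxes(model, res$fluxes),
       fluxSum = res$fluxSum)
}

#' Minimal protein-pool usage at a fixed growth rate
#'
#' Fixes the biomass flux at \code{mu}, minimizes the pool exchange flux
#' (the overall use of metabolic protein), then — as a lexicographic
#' tie-break — fixes the pool at its minimum and minimizes the total flux
#' sum to obtain a unique amino-acid distribution.
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param mu Growth rate to enforce (biomass flux units).
#' @param tieBreak Run the secondary flux-sum minimization (default TRUE).
#' @return List with \code{solution}, \code{profile}, \code{poolFlux}; an
#'   infeasible \code{mu} yields status "infeasible" and NULL profile.
#' @export
minPoolAtGrowth <- function(model, mu, tieBreak = TRUE) {
  stopifnot(methods::is(model, "AcidFBAModel"), mu >= 0)
  bio <- match(biomassReaction(model), colnames(model@S))
  poolIdx <- match(model@poolReaction, colnames(model@S))
  lb <- model@lb; ub <- model@ub
  lb[bio] <- mu * (1 - .BIO_EQ_TOL)
  ub[bio] <- mu * (1 + .BIO_EQ_TOL)
  if (mu == 0) { lb[bio] <- 0; ub[bio] <- 0 }
  obj <- numeric(ncol(model@S)); obj[poolIdx] <- 1
  res <- .simplexSolve(obj, model@S, rep(0, nrow(model@S)), lb, ub,
                       maximize = FALSE)
  if (res$status != "optimal")
    return(list(solution = .newSolution(res$status), profile = NULL,
                poolFlux = NA_real_))
  poolMin <- res$objective
  v <- stats::setNames(res$x, colnames(model@S))
  if (tieBreak) {
    lb2 <- lb; ub2 <- ub
    lb2[poolIdx] <- poolMin * (1 - .BIO_EQ_TOL)
    ub2[poolIdx] <- poolMin * (1 + .BIO_EQ_TOL) + (poolMin == 0) * 0
    res2 <- .minTotalFlux(model, lb2, ub2)
    if (res2$status == "optimal") v <- res2$fluxes
  }
  sol <- .newSolution("optimal", objective = unname(v[bio]), fluxes = v)
  list(solution = sol, profile = .profileFromFluxes(model, v),
       poolFlux = poolMin)
}

#' Flux variability of the amino-acid drains
#'
#' Constrains the biomass flux to at least \code{optFraction} of its maximum
#' and, per drain, minimizes and maximizes its flux. The relative
#' variability is the range normalized by the mean flux, taken as the
#' interval midpoint \code{(max + min) / 2}; a degenerate midpoint (below
#' 1e-9 g/gDW, i.e. numerically zero) yields \code{NA} rather than infinity.
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param optFraction Optimality threshold (default 0.99).
#' @param equality Use an equality instead of \code{>=} on the biomass flux
#'   (default FALSE).
#' @return A data.frame with one row per amino acid: \code{code},
#'   \code{min}, \code{max}, \code{midpoint}, \code{relVariability}.
#' @export
drainFVA <- function(model, optFraction = 0.99, equality = FALSE) {
  stopifnot(methods::is(model, "AcidFBAModel"),
            optFraction > 0, optFraction <= 1)
  opt <- maximizeGrowth(model)
  if (solutionStatus(opt) != "optimal")
    stop("model is ", solutionStatus(opt),
         "; cannot run variability analysis", call. = FALSE)
  zfix <- optFraction * objectiveValue(opt)
  bio <- match(biomassReaction(model), colnames(model@S))
  lb <- model@lb; ub <- model@ub
  lb[bio] <- zfix
  if (equality) ub[bio] <- zfix
  drains <- model@drainReactions
  res <- lapply(drains, function(d) {
    obj <- stats::setNames(1, d)
    lo <- .modelLP(model, obj, maximize = FALSE, lb = lb, ub = ub)
    hi <- .modelLP(model, obj, maximize = TRUE, lb = lb, ub = ub)
    c(lo = objectiveValue(lo), hi = objectiveValue(hi))
  })
  mn <- vapply(res, `[[`, 0, "lo")
  mx <- vapply(res, `[[`, 0, "hi")
  mid <- (mn + mx) / 2
  rel <- ifelse(mid > 1e-9, (mx - mn) / mid, NA_real_)
  data.frame(code = aminoAcidCodes(), min = unname(mn), max = unname(mx),
             midpoint = unname(mid), relVariability = unname(rel),
             stringsAsFactors = FALSE)
}

## ---- condition files -------------------------------------------------

#' Apply a condition set to a model
#'
#' A condition set is a list with optional elements \code{bounds} (a list of
#' \code{list(reaction =, lb =, ub =)} overrides) and \code{blocked} (a
#' character vector of reactions fixed to zero flux), as produced by
#' \code{\link{readConditionFile}}.
#'
#' @param model An \linkS4class{EcModel}.
#' @param conditions Condition list, or \code{NULL} (returned unchanged).
#' @return The adjusted model.
#' @export
applyConditions <- function(model, conditions) {
  if (is.null(conditions)) return(model)
  for (b in conditions$bounds) {
    model <- setReactionBounds(model, b$reaction,
                               lb = if (!is.null(b$lb)) b$lb,
                               ub = if (!is.null(b$ub)) b$ub)
  }
  if (length(conditions$blocked))
    model <- setReactionBounds(model, conditions$blocked, lb = 0, ub = 0)
  model
}

#' Read a YAML condition file
#'
#' @param path YAML file with optional keys \code{bounds} (list of
#'   reaction/lb/ub entries) and \code{blocked} (list of reaction ids).
#' @return A condition list for \code{\link{applyConditions}}.
#' @export
readConditionFile <- function(path) {
  y <- yaml::read_yaml(path)
  list(bounds = y$bounds,
       blocked = as.character(unlist(y$blocked)))
}

## ---- chemostat sweep -------------------------------------------------

#' Chemostat growth-rate sweep
#'
#' For each growth rate on the grid, sets the pool bound to
#' \code{sigmaF * ptotal(mu)}, enforces the growth rate, minimizes the pool
#' usage (with the parsimonious tie-break), and records the amino-acid
#' profile. The critical growth rate is the first grid point at which the
#' pool constraint is binding (slack below 1e-8 g/gDW).
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param muGrid Strictly increasing growth-rate grid (1/h).
#' @param ptotal Either a function of mu returning the total protein
#'   fraction (g/gDW), or a two-column table/data.frame (mu, ptotal)
#'   interpolated piecewise-linearly with flat extrapolation.
#' @param sigmaF Product sigma * f converting protein fraction to pool bound;
#'   defaults to the model's current pool bound divided by 0.5 (i.e. the
#'   parent bound at the default total protein fraction).
#' @param conditions Optional condition list applied before sweeping.
#' @return List with \code{table} (per-mu data.frame: mu, ptotal, poolBound,
#'   poolFlux, binding, feasible), \code{profiles} (mass-fraction matrix,
#'   one row per feasible mu), \code{masses} (drain-mass matrix) and
#'   \code{criticalMu} (NA when the pool never binds on the grid).
#' @export
chemostatSweep <- function(model, muGrid, ptotal, sigmaF = NULL,
                           conditions = NULL) {
  stopifnot(methods::is(model, "AcidFBAModel"),
            all(diff(muGrid) > 0))
  if (is.function(ptotal)) {
    pt <- ptotal
  } else {
    tab <- as.data.frame(ptotal)
    stopifnot(ncol(tab) >= 2)
    pt <- stats::approxfun(tab[[1]], tab[[2]], method = "linear", rule = 2)
  }
  if (is.null(sigmaF)) sigmaF <- poolBound(model) / 0.5
  model <- applyConditions(model, conditions)

  n <- length(muGrid)
  poolB <- poolF <- rep(NA_real_, n)
  ptv <- vapply(muGrid, pt, numeric(1))
  feasible <- logical(n)
  fracs <- masses <- matrix(NA_real_, n, 20,
                            dimnames = list(NULL, aminoAcidCodes()))
  for (i in seq_len(n)) {
    b <- sigmaF * ptv[i]
    if (!is.finite(b) || b < 0 || ptv[i] <= 0 || ptv[i] > 1)
      stop("ptotal(mu) must lie in (0, 1]; got ", format(ptv[i]),
           " at mu = ", format(muGrid[i]), call. = FALSE)
    poolB[i] <- b
    m <- model
    poolBound(m) <- b
    res <- minPoolAtGrowth(m, muGrid[i])
    if (solutionStatus(res$solution) != "optimal") {
      message("chemostat point mu = ", format(muGrid[i]),
              " infeasible; skipped")
      next
    }
    feasible[i] <- TRUE
    poolF[i] <- res$poolFlux
    fracs[i, ] <- profileFraction(res$profile)
    masses[i, ] <- profileMass(res$profile)
  }
  binding <- feasible & (poolB - poolF <= .POOL_SLACK_TOL)
  criticalMu <- if (any(binding)) muGrid[which(binding)[1L]] else NA_real_
  list(table = data.frame(mu = muGrid, ptotal = ptv, poolBound = poolB,
                          poolFlux = poolF, feasible = feasible,
                          binding = binding),
       profiles = fracs[feasible, , drop = FALSE],
       masses = masses[feasible, , drop = FALSE],
       criticalMu = criticalMu)
}

#' Compare amino-acid profiles of two metabolic modes
#'
#' Computes the amino-acid mass-fraction profile under two condition setups
#' (e.g. fully fermentative vs fully respiratory) and their per-amino-acid
#' absolute relative deviation |p_ferm - p_resp| / p_resp. Zero-denominator
#' entries are reported as \code{NA} and excluded from the median.
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param fermentative,respiratory Setups: each a list with optional
#'   \code{conditions} (see \code{\link{applyConditions}}) and optional
#'   \code{growth} — \code{NULL} maximizes growth then extracts the
#'   parsimonious profile; a number enforces that growth rate and minimizes
#'   pool usage.
#' @return List with \code{deviation} (named 20-vector), \code{median},
#'   and the two \linkS4class{AminoAcidProfile}s.
#' @export
compareModes <- function(model, fermentative, respiratory) {
  run <- function(setup) {
    m <- applyConditions(model, setup$conditions)
    res <- if (is.null(setup$growth)) aaProfileAtOptimum(m)
           else minPoolAtGrowth(m, setup$growth)
    if (is.null(res$profile))
      stop("setup infeasible (status ",
           solutionStatus(res$solution), ")", call. = FALSE)
    res$profile
  }
  pf <- run(fermentative)
  pr <- run(respiratory)
  f <- profileFraction(pf); r <- profileFraction(pr)
  dev <- ifelse(r > 0, abs(f - r) / r, ifelse(f == 0, 0, NA_real_))
  names(dev) <- aminoAcidCodes()
  list(deviation = dev, median = stats::median(dev, na.rm = TRUE),
       fermentative = pf, respiratory = pr)
}
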