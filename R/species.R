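## Species-specific amino-acid distributions: hard proportionality
## constraints and minimally-different profile fits.

#' Species amino-acid distribution
#'
#' A labelled relative mass distribution over the 20 proteinogenic amino
#' acids, e.g. extracted from the biomass objective function of another
#' organism's genome-scale model.
#'
#' @slot species Species label.
#' @slot fraction Named numeric 20-vector of relative mass fractions
#'   summing to 1.
#' @export
setClass("SpeciesDistribution", representation(
  species = "character",
  fraction = "numeric"
))

setValidity("SpeciesDistribution", function(object) {
  if (!identical(names(object@fraction), aminoAcidCodes()))
    return("fraction must be named by the canonical codes")
  if (any(object@fraction < 0)) return("fractions must be non-negative")
  if (abs(sum(object@fraction) - 1) > 1e-6)
    return("fractions must sum to 1")
  TRUE
})

setMethod("show", "SpeciesDistribution", function(object) {
  cat("SpeciesDistribution:", object@species, "\n")
  top <- sort(object@fraction, decreasing = TRUE)[1:3]
  cat("  top fractions:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
})

#' @rdname SpeciesDistribution-class
#' @param object A \code{SpeciesDistribution}.
#' @export
setGeneric("distributionFraction",
           function(object) standardGeneric("distributionFraction"))

#' @rdname SpeciesDistribution-class
#' @export
setMethod("distributionFraction", "SpeciesDistribution",
          function(object) object@fraction)

#' Load a species amino-acid distribution
#'
#' Reads a 20-row two-column table: one-letter \code{code} plus either mass
#' fractions or biomass coefficients (mmol/gDW). Coefficients are converted
#' to mass fractions by residue-mass weighting and normalized; fractions off
#' unity by more than 1e-6 are renormalized with a warning.
#'
#' @param source TSV path or a data.frame.
#' @param units \code{"auto"} (decide from the second column's header:
#'   \code{fraction}-like names mean mass fractions, \code{coefficient} /
#'   \code{mmol}-like names mean biomass coefficients), or explicitly
#'   \code{"fraction"} / \code{"coefficient"}.
#' @param species Label; defaults to the file name.
#' @return A \linkS4class{SpeciesDistribution}.
#' @export
loadDistribution <- function(source, units = c("auto", "fraction",
                                               "coefficient"),
                             species = NULL) {
  units <- match.arg(units)
  if (is.character(source)) {
    if (is.null(species))
      species <- sub("\\.[^.]*$", "", basename(source))
    df <- utils::read.delim(source, stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(source)
    if (is.null(species)) species <- "unnamed"
  }
  if (ncol(df) < 2) stop("need a code column and a value column",
                         call. = FALSE)
  if (units == "auto") {
    h <- tolower(colnames(df)[2])
    units <- if (grepl("frac", h)) "fraction"
             else if (grepl("coef|mmol", h)) "coefficient"
             else stop("cannot infer units from column name '", h,
                       "'; pass units explicitly", call. = FALSE)
  }
  code <- toupper(as.character(df[[1]]))
  val <- as.numeric(df[[2]])
  hit <- match(aminoAcidCodes(), code)
  if (anyNA(hit)) {
    miss <- aminoAcidCodes()[is.na(hit)]
    stop(paste(.AA_NAME[miss], collapse = ", "), " absent from table",
         call. = FALSE)
  }
  val <- val[hit]
  if (any(is.na(val)) || any(val < 0))
    stop("values must be non-negative numbers", call. = FALSE)
  if (units == "coefficient") {
    mass <- val * .AA_RESIDUE_MASS
    frac <- mass / sum(mass)
  } else {
    tot <- sum(val)
    if (abs(tot - 1) > 1e-6) {
      warning("fractions sum to ", format(tot), "; renormalizing",
              call. = FALSE)
    }
    frac <- val / tot
  }
  names(frac) <- aminoAcidCodes()
  new("SpeciesDistribution", species = species, fraction = frac)
}

.T_RXN <- "aa_profile_total"

## add the auxiliary total column T (and its defining or coupling rows)
.withTotalColumn <- function(model, couplings = NULL, defineTotal = FALSE) {
  S <- model@S
  if (.T_RXN %in% colnames(S))
    stop("model already carries the auxiliary total column", call. = FALSE)
  S <- cbind(S, stats::setNames(rep(0, nrow(S)), NULL))
  colnames(S)[ncol(S)] <- .T_RXN
  drainIdx <- match(model@drainReactions, colnames(S))
  if (defineTotal) {
    row <- matrix(0, 1, ncol(S), dimnames = list("aa_total_balance", NULL))
    row[1, drainIdx] <- 1
    row[1, ncol(S)] <- -1
    S <- rbind(S, row)
  }
  if (!is.null(couplings)) {
    rows <- matrix(0, 20, ncol(S),
                   dimnames = list(paste0("couple_", aminoAcidCodes()),
                                   NULL))
    rows[cbind(seq_len(20), drainIdx)] <- 1
    rows[, ncol(S)] <- -couplings
    S <- rbind(S, rows)
  }
  model@S <- S
  model@lb <- c(model@lb, 0)
  model@ub <- c(model@ub, Inf)
  model@objective <- c(model@objective, 0)
  model
}

#' Constrain a model to a species amino-acid distribution
#'
#' Adds proportionality couplings \code{a_l = p_l * T} between every drain
#' flux and a free auxiliary total \code{T}, forcing the model's amino-acid
#' profile onto the given distribution while leaving its scale free.
#' Maximizing growth of the returned model defines the reference optimal
#' growth state; infeasibility is a legitimate outcome (reported by the
#' solution status, not an error).
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param dist A \linkS4class{SpeciesDistribution}.
#' @return The constrained \linkS4class{AcidFBAModel}.
#' @export
constrainProfile <- function(model, dist) {
  stopifnot(methods::is(model, "AcidFBAModel"),
            methods::is(dist, "SpeciesDistribution"))
  out <- .withTotalColumn(model, couplings = unname(dist@fraction))
  validObject(out)
  out
}

#' Minimally-different amino-acid profile at a growth level
#'
#' Fixes the biomass flux at \code{growthFraction * referenceGrowth} and
#' finds the feasible amino-acid profile of minimal Euclidean distance to
#' the species distribution, minimizing \code{sum_l (a_l - p_l T)^2} with
#' \code{T = sum_l a_l} (a convex quadratic program over the flux
#' polytope). The reported distance is recomputed from the unregularized
#' objective at the solution.
#'
#' @param model An \linkS4class{AcidFBAModel} (unconstrained profile).
#' @param dist A \linkS4class{SpeciesDistribution}.
#' @param growthFraction Fraction of \code{referenceGrowth} to enforce.
#' @param referenceGrowth Reference growth rate (see
#'   \code{\link{referenceGrowthState}}).
#' @param ridge Diagonal regularization making the projected Hessian
#'   positive definite; default 1e-12 (the objective is flat along the
#'   regularized directions, so the distance is unaffected to first order).
#' @return List with \code{status}, \code{profile}
#'   (\linkS4class{AminoAcidProfile}), \code{distance} (g/gDW), and
#'   \code{total} (T).
#' @export
minEuclideanFit <- function(model, dist, growthFraction, referenceGrowth,
                            ridge = 1e-12) {
  stopifnot(methods::is(model, "AcidFBAModel"),
            methods::is(dist, "SpeciesDistribution"),
            growthFraction > 0, referenceGrowth > 0)
  m <- .withTotalColumn(model, defineTotal = TRUE)
  bio <- match(biomassReaction(m), colnames(m@S))
  mu <- growthFraction * referenceGrowth
  m@lb[bio] <- mu; m@ub[bio] <- mu

  ## feasibility of the growth level first (clean status)
  feas <- .simplexSolve(numeric(ncol(m@S)), m@S, rep(0, nrow(m@S)),
                        m@lb, m@ub)
  if (feas$status != "optimal")
    return(list(status = "infeasible", profile = NULL,
                distance = NA_real_, total = NA_real_))

  n <- ncol(m@S)
  drainIdx <- match(m@drainReactions, colnames(m@S))
  tIdx <- match(.T_RXN, colnames(m@S))
  p <- unname(dist@fraction)
  D <- matrix(0, 20, n)
  D[cbind(seq_len(20), drainIdx)] <- 1
  D[, tIdx] <- -p
  H <- 2 * crossprod(D)
  diag(H) <- diag(H) + ridge

  ## constraints for quadprog: equalities S v = 0, then finite bounds
  Aeq <- t(m@S)
  beq <- rep(0, nrow(m@S))
  finL <- which(is.finite(m@lb))
  finU <- which(is.finite(m@ub))
  Al <- matrix(0, n, length(finL)); Al[cbind(finL, seq_along(finL))] <- 1
  Au <- matrix(0, n, length(finU)); Au[cbind(finU, seq_along(finU))] <- -1
  Amat <- cbind(Aeq, Al, Au)
  bvec <- c(beq, m@lb[finL], -m@ub[finU])
  sol <- tryCatch(
    quadprog::solve.QP(H, numeric(n), Amat, bvec, meq = nrow(m@S)),
    error = function(e) e)
  if (inherits(sol, "error"))
    return(list(status = "solver_error", profile = NULL,
                distance = NA_real_, total = NA_real_,
                message = conditionMessage(sol)))
  v <- sol$solution
  a <- v[drainIdx]
  tt <- v[tIdx]
  dist2 <- sum((a - p * tt)^2)     # unridged objective
  list(status = "optimal",
       profile = .newProfile(a),
       distance = sqrt(max(dist2, 0)),
       total = tt)
}

#' Reference optimal growth under a hard profile constraint
#'
#' Convenience wrapper: constrains the model to \code{dist} (see
#' \code{\link{constrainProfile}}) and maximizes growth.
#'
#' @inheritParams constrainProfile
#' @return List with \code{growth} (NA when infeasible) and \code{status}.
#' @export
referenceGrowthState <- function(model, dist) {
  sol <- maximizeGrowth(constrainProfile(model, dist))
  list(growth = objectiveValue(sol), status = solutionStatus(sol))
}

#' Per-amino-acid absolute relative difference between profiles
#'
#' \code{d_l = |q_l - p_l| / p_l} on normalized fractions; entries with
#' \code{p_l = 0} and \code{q_l > 0} are \code{NA} (sentinel), and 0 when
#' both are 0.
#'
#' @param profile An \linkS4class{AminoAcidProfile} or numeric 20-vector of
#'   fractions.
#' @param dist A \linkS4class{SpeciesDistribution} or numeric 20-vector.
#' @return Named numeric 20-vector.
#' @export
profileDifference <- function(profile, dist) {
  q <- if (methods::is(profile, "AminoAcidProfile"))
    profileFraction(profile) else profile
  p <- if (methods::is(dist, "SpeciesDistribution"))
    distributionFraction(dist) else dist
  stopifnot(length(q) == 20L, length(p) == 20L)
  d <- ifelse(p > 0, abs(q - p) / p, ifelse(q == 0, 0, NA_real_))
  names(d) <- aminoAcidCodes()
  d
}

#' Scan profile fits over growth fractions
#'
#' Runs \code{\link{minEuclideanFit}} at each growth fraction and tabulates
#' the per-amino-acid absolute relative differences to the species
#' distribution. The default grid runs from 0.1 in steps of 0.05 up to the
#' ratio of the model's unconstrained maximal growth to the reference
#' growth.
#'
#' @inheritParams minEuclideanFit
#' @param fractions Increasing growth fractions; default
#'   \code{seq(0.1, upper, by = 0.05)} with the upper end as above.
#' @return Long data.frame: \code{fraction}, \code{feasible},
#'   \code{distance}, \code{code}, \code{modelFraction},
#'   \code{speciesFraction}, \code{absRelDiff}.
#' @export
growthFractionScan <- function(model, dist, referenceGrowth,
                               fractions = NULL) {
  stopifnot(referenceGrowth > 0)
  if (is.null(fractions)) {
    zmax <- objectiveValue(maximizeGrowth(model))
    upper <- zmax / referenceGrowth
    fractions <- seq(0.1, upper, by = 0.05)
  }
  stopifnot(all(diff(fractions) > 0))
  rows <- lapply(fractions, function(fr) {
    fit <- minEuclideanFit(model, dist, fr, referenceGrowth)
    if (fit$status != "optimal") {
      return(data.frame(fraction = fr, feasible = FALSE,
                        distance = NA_real_, code = aminoAcidCodes(),
                        modelFraction = NA_real_,
                        speciesFraction = unname(dist@fraction),
                        absRelDiff = NA_real_, stringsAsFactors = FALSE))
    }
    d <- profileDifference(fit$profile, dist)
    data.frame(fraction = fr, feasible = TRUE, distance = fit$distance,
               code = aminoAcidCodes(),
               modelFraction = unname(profileFraction(fit$profile)),
               speciesFraction = unname(dist@fraction),
               absRelDiff = unname(d), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
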