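## Rewiring an ecGEM into its amino-acid-resolved form.
##
## The parent model's enzyme draw reactions (MW/1000 pool -> enzyme) are
## replaced by source reactions consuming amino-acid pseudo-metabolites at
## the composition-matrix stoichiometries, and 20 irreversible drain
## reactions route pool mass 1:1 into those amino-acid species. Because each
## xi row sums to MW/1000, the total pool cost of every enzyme is unchanged
## and the rewired model has exactly the parent's optimum.

.AA_MET_PREFIX <- "aa_"
.AA_DRAIN_PREFIX <- "draw_aa_"

.enzymeProteinIds <- function(model) {
  sub(paste0("^", .GECKO_ENZ_PREFIX), "", model@enzymeMetabolites)
}

#' Protein-pool configuration
#'
#' The effective pool bound is \code{sigma * f * ptotal} (g/gDW) unless an
#' explicit \code{bound} overrides the product: \code{sigma} is the average
#' in-vivo enzyme saturation, \code{f} the mass fraction of the proteome
#' covered by the model, and \code{ptotal} the total cellular protein
#' fraction (default 0.5 g/gDW).
#'
#' @param sigma,f Dimensionless factors in (0, 1].
#' @param ptotal Total protein fraction in (0, 1], g/gDW.
#' @param bound Optional explicit pool bound (g/gDW), overriding the product.
#' @return An object of class \code{PoolConfig}.
#' @export
poolConfig <- function(sigma = 1, f = 1, ptotal = 0.5, bound = NULL) {
  stopifnot(sigma > 0, sigma <= 1, f > 0, f <= 1, ptotal > 0, ptotal <= 1)
  if (!is.null(bound)) stopifnot(is.numeric(bound), bound >= 0)
  structure(list(sigma = sigma, f = f, ptotal = ptotal, bound = bound),
            class = "PoolConfig")
}

.effectivePoolBound <- function(cfg) {
  if (!is.null(cfg$bound)) cfg$bound else cfg$sigma * cfg$f * cfg$ptotal
}

#' Build an amino-acid-resolved model from an ecGEM
#'
#' @param ec An \linkS4class{EcModel}.
#' @param xi A \linkS4class{CompositionMatrix} whose rows cover the model's
#'   proteins (row names may be bare protein identifiers or full enzyme
#'   pseudo-metabolite identifiers).
#' @param pool \code{NULL} to keep the parent pool bound verbatim (default),
#'   a single number (g/gDW), or a \code{\link{poolConfig}}.
#' @param strict If \code{TRUE} (default), an enzyme without a xi row is an
#'   error; if \code{FALSE}, missing enzymes are assigned the mean relative
#'   composition of the present proteins scaled to the parent draw reaction's
#'   molecular weight, with a message.
#' @param mwTolerance Relative disagreement between a xi row sum and the
#'   parent draw reaction's MW coefficient above which a warning lists the
#'   deviation (default 0.005). The xi row always wins, preserving internal
#'   consistency of the amino-acid mass balances.
#' @return An \linkS4class{AcidFBAModel}.
#' @export
#' @examples
#' toy <- toyEC1()
#' mod <- buildAcidFBA(toy$model, buildXi(toy$proteins))
#' mod
buildAcidFBA <- function(ec, xi, pool = NULL, strict = TRUE,
                         mwTolerance = 0.005) {
  stopifnot(methods::is(ec, "EcModel"), methods::is(xi, "CompositionMatrix"))
  ximat <- xiMatrix(xi)
  enzMets <- ec@enzymeMetabolites
  protIds <- .enzymeProteinIds(ec)

  ## accept either bare protein ids or enzyme-metabolite ids as xi rows
  rowFor <- match(protIds, rownames(ximat))
  alt <- match(enzMets, rownames(ximat))
  rowFor[is.na(rowFor)] <- alt[is.na(rowFor)]
  missing <- is.na(rowFor)
  rows <- matrix(0, length(enzMets), 20L,
                 dimnames = list(enzMets, aminoAcidCodes()))
  if (any(!missing)) rows[!missing, ] <- ximat[rowFor[!missing], , drop = FALSE]
  if (any(missing)) {
    if (strict)
      stop("no composition row for enzyme(s): ",
           paste(protIds[missing], collapse = ", "), call. = FALSE)
    if (all(missing))
      stop("no composition rows available to impute from", call. = FALSE)
    meanFrac <- colMeans(sweep(rows[!missing, , drop = FALSE], 1L,
                               rowSums(rows[!missing, , drop = FALSE]), `/`))
    for (k in which(missing))
      rows[k, ] <- meanFrac * ec@enzymeMW[enzMets[k]]
    message("imputed mean composition for ",
            sum(missing), " enzyme(s) without sequence: ",
            paste(protIds[missing], collapse = ", "))
  }

  ## MW consistency: xi wins over the parent draw coefficient
  if (length(enzMets)) {
    xiMW <- rowSums(rows)                      # g/mmol
    parentMW <- ec@enzymeMW[enzMets]
    dev <- abs(xiMW - parentMW) / parentMW
    off <- which(dev > mwTolerance & !missing)
    if (length(off))
      warning("xi row sum deviates >", format(100 * mwTolerance),
              "% from the draw-reaction MW for: ",
              paste(sprintf("%s (%.2f%%)", protIds[off], 100 * dev[off]),
                    collapse = ", "),
              "; using the xi row sums", call. = FALSE)
  }

  codes <- aminoAcidCodes()
  aaMets <- stats::setNames(paste0(.AA_MET_PREFIX, codes), codes)
  drains <- stats::setNames(paste0(.AA_DRAIN_PREFIX, codes), codes)
  clash <- c(intersect(aaMets, rownames(ec@S)),
             intersect(drains, colnames(ec@S)))
  if (length(clash))
    stop("identifier collision with existing species/reactions: ",
         paste(clash, collapse = ", "), call. = FALSE)

  S <- rbind(ec@S, matrix(0, 20L, ncol(ec@S),
                          dimnames = list(aaMets, NULL)))
  poolRow <- match(ec@poolMetabolite, rownames(S))
  ## rewire each draw reaction: drop pool consumption, consume amino acids
  for (k in seq_along(enzMets)) {
    j <- match(ec@drawReactions[enzMets[k]], colnames(S))
    S[poolRow, j] <- 0
    S[aaMets, j] <- -rows[k, ]
  }
  ## append the 20 drains: pool -> amino acid, 1:1 mass
  D <- matrix(0, nrow(S), 20L, dimnames = list(rownames(S), drains))
  D[poolRow, ] <- -1
  D[cbind(match(aaMets, rownames(S)), seq_len(20L))] <- 1
  S <- cbind(S, D)

  lb <- c(ec@lb, rep(0, 20L))
  ub <- c(ec@ub, rep(Inf, 20L))
  objective <- c(ec@objective, rep(0, 20L))

  model <- new("AcidFBAModel",
    S = S, lb = lb, ub = ub, objective = objective,
    poolReaction = ec@poolReaction,
    poolMetabolite = ec@poolMetabolite,
    enzymeMetabolites = enzMets,
    drawReactions = ec@drawReactions,
    enzymeMW = stats::setNames(rowSums(rows), enzMets),
    exchangeAnnotation = ec@exchangeAnnotation,
    aaMetabolites = aaMets,
    drainReactions = drains,
    sourceReactions = ec@drawReactions,
    xi = new("CompositionMatrix",
             xi = `rownames<-`(rows, protIds)))
  if (!is.null(pool)) {
    poolBound(model) <- if (inherits(pool, "PoolConfig"))
      .effectivePoolBound(pool) else pool
  }
  validObject(model)
  model
}

#' Uniform-composition variant of a model
#'
#' Replaces every composition row by the protein's molecular weight times one
#' fixed amino-acid distribution, so all enzymes share the same relative
#' composition while their total pool cost is unchanged. This is the control
#' in which any rerouting between enzymes leaves the relative amino-acid
#' usage untouched.
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param profile An \linkS4class{AminoAcidProfile}, or a numeric 20-vector
#'   of mass fractions in canonical code order summing to 1 (tolerance
#'   1e-6).
#' @return The rebuilt \linkS4class{AcidFBAModel}.
#' @export
makeUniformVariant <- function(model, profile) {
  stopifnot(methods::is(model, "AcidFBAModel"))
  p <- if (methods::is(profile, "AminoAcidProfile"))
    profileFraction(profile) else profile
  stopifnot(is.numeric(p), length(p) == 20L)
  if (abs(sum(p) - 1) > 1e-6)
    stop("profile fractions must sum to 1 (got ", format(sum(p)), ")",
         call. = FALSE)
  if (any(p < 0)) stop("profile fractions must be non-negative", call. = FALSE)
  p <- unname(p)

  enzMets <- model@enzymeMetabolites
  newxi <- outer(unname(model@enzymeMW[enzMets]), p)  # g/mmol rows
  dimnames(newxi) <- list(.enzymeProteinIds(model), aminoAcidCodes())

  S <- model@S
  aaRows <- match(model@aaMetabolites, rownames(S))
  for (k in seq_along(enzMets)) {
    j <- match(model@sourceReactions[enzMets[k]], colnames(S))
    S[aaRows, j] <- -newxi[k, ]
  }
  model@S <- S
  model@xi <- new("CompositionMatrix", xi = newxi)
  validObject(model)
  model
}

#' Structural mass-closure gap of a solution
#'
#' In every feasible solution of an amino-acid-resolved model the summed
#' drain fluxes equal the pool exchange flux (the amino-acid mass balances
#' summed over all 20 species). Returns the absolute discrepancy, which
#' should be at numerical noise level (<= 1e-9 g/gDW).
#'
#' @param model An \linkS4class{AcidFBAModel}.
#' @param solution A \linkS4class{FluxSolution} for that model.
#' @return Absolute gap in g/gDW.
#' @export
massClosureGap <- function(model, solution) {
  v <- fluxes(solution)
  abs(sum(v[model@drainReactions]) - v[model@poolReaction])
}
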