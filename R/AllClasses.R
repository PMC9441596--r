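## Central S4 classes.
##
## An EcModel is a GECKO-style enzyme-constrained model: an ordinary
## stoichiometric matrix in which enzymes appear as pseudo-metabolites
## (consumed at 1/kcat by the reactions they catalyze, produced by a draw
## reaction that spends protein-pool mass), plus one pool pseudo-metabolite
## whose exchange flux (g/gDW) is capped. An AcidFBAModel is an EcModel whose
## draw reactions have been rewired through 20 amino-acid pseudo-metabolites.
## All constraints are of the form S v = 0 with box bounds on v, which is the
## form the package's LP layer consumes directly.

#' @import methods
NULL

#' Amino-acid composition matrix
#'
#' The K x 20 matrix xi whose entry \code{xi[k, l]} is the gram of amino acid
#' l per mmol of protein k (g/mmol), built from residue counts times average
#' residue masses. Row order is the input protein order; columns follow
#' \code{\link{aminoAcidCodes}}.
#'
#' @slot xi Numeric matrix, rownames = protein identifiers, colnames = the 20
#'   canonical one-letter codes, all entries >= 0.
#' @export
setClass("CompositionMatrix", representation(xi = "matrix"))

setValidity("CompositionMatrix", function(object) {
  xi <- object@xi
  if (!is.numeric(xi)) return("xi must be numeric")
  if (ncol(xi) != 20L) return("xi must have 20 columns")
  if (!identical(colnames(xi), aminoAcidCodes()))
    return("xi columns must be the canonical amino-acid codes, in order")
  if (nrow(xi) > 0 && is.null(rownames(xi)))
    return("xi rows must be named by protein identifier")
  if (anyDuplicated(rownames(xi)))
    return("duplicate protein identifiers")
  if (any(xi < 0)) return("xi entries must be non-negative")
  TRUE
})

#' Enzyme-constrained metabolic model
#'
#' A stoichiometric model with GECKO conventions: enzyme pseudo-metabolites,
#' one draw reaction per enzyme spending protein-pool mass at MW/1000 g/mmol,
#' and a single pool exchange reaction whose upper bound is the available
#' metabolic protein mass (g/gDW). All constraints are steady-state mass
#' balances \code{S v = 0} plus flux bounds.
#'
#' @slot S Dense stoichiometric matrix (metabolites x reactions), with
#'   dimnames.
#' @slot lb,ub Numeric flux bounds per reaction.
#' @slot objective Numeric objective coefficients per reaction (the biomass
#'   reaction carries the non-zero entry).
#' @slot poolReaction Identifier of the protein-pool exchange reaction.
#' @slot poolMetabolite Identifier of the pool pseudo-metabolite.
#' @slot enzymeMetabolites Identifiers of the enzyme pseudo-metabolites.
#' @slot drawReactions Named character; for each enzyme metabolite (name) the
#'   identifier of its draw (or rewired source) reaction.
#' @slot enzymeMW Named numeric; pool mass spent per mmol of each enzyme
#'   (g/mmol), i.e. MW/1000 as used in the draw reaction.
#' @slot exchangeAnnotation data.frame with columns \code{reaction} and
#'   \code{class} assigning exchange reactions to elemental nutrient classes
#'   (may be empty).
#' @export
setClass("EcModel", representation(
  S = "matrix",
  lb = "numeric",
  ub = "numeric",
  objective = "numeric",
  poolReaction = "character",
  poolMetabolite = "character",
  enzymeMetabolites = "character",
  drawReactions = "character",
  enzymeMW = "numeric",
  exchangeAnnotation = "data.frame"
))

setValidity("EcModel", function(object) {
  S <- object@S
  n <- ncol(S)
  if (is.null(rownames(S)) || is.null(colnames(S)))
    return("S must carry metabolite and reaction identifiers as dimnames")
  if (anyDuplicated(colnames(S)) || anyDuplicated(rownames(S)))
    return("duplicate reaction or metabolite identifiers")
  if (length(object@lb) != n || length(object@ub) != n ||
      length(object@objective) != n)
    return("lb, ub and objective must have one entry per reaction")
  if (any(object@lb > object@ub)) return("lb must not exceed ub")
  if (length(object@poolReaction) != 1L ||
      !(object@poolReaction %in% colnames(S)))
    return("exactly one pool exchange reaction must be present")
  if (!(object@poolMetabolite %in% rownames(S)))
    return("pool metabolite not found")
  if (!all(object@enzymeMetabolites %in% rownames(S)))
    return("enzyme metabolite(s) not found")
  if (length(object@drawReactions) != length(object@enzymeMetabolites))
    return("every enzyme metabolite needs exactly one draw reaction")
  if (length(object@drawReactions) &&
      (!all(names(object@drawReactions) %in% object@enzymeMetabolites) ||
       !all(object@drawReactions %in% colnames(S))))
    return("draw reactions must map enzyme metabolites to model reactions")
  if (length(object@enzymeMW) &&
      (any(object@enzymeMW <= 0) ||
       !all(names(object@enzymeMW) %in% object@enzymeMetabolites)))
    return("enzymeMW must be positive and named by enzyme metabolite")
  TRUE
})

#' Amino-acid-resolved enzyme-constrained model
#'
#' An \linkS4class{EcModel} in which each enzyme draw reaction has been
#' replaced by a source reaction consuming amino-acid pseudo-metabolites at
#' the stoichiometries of the composition matrix, and 20 irreversible drain
#' reactions route pool mass 1:1 into the amino-acid pseudo-metabolites.
#'
#' @slot aaMetabolites Named character (by one-letter code): the 20
#'   amino-acid pseudo-metabolite identifiers.
#' @slot drainReactions Named character (by code): the 20 drain reaction
#'   identifiers.
#' @slot sourceReactions Named character (by enzyme metabolite): the rewired
#'   enzyme source reactions (same identifiers as the parent draw reactions).
#' @slot xi The \linkS4class{CompositionMatrix} backing the rewiring.
#' @export
setClass("AcidFBAModel", contains = "EcModel", representation(
  aaMetabolites = "character",
  drainReactions = "character",
  sourceReactions = "character",
  xi = "CompositionMatrix"
))

setValidity("AcidFBAModel", function(object) {
  if (length(object@aaMetabolites) != 20L ||
      !identical(names(object@aaMetabolites), aminoAcidCodes()))
    return("need 20 amino-acid metabolites named by canonical code")
  if (length(object@drainReactions) != 20L ||
      !identical(names(object@drainReactions), aminoAcidCodes()))
    return("need 20 drain reactions named by canonical code")
  if (!all(object@aaMetabolites %in% rownames(object@S)))
    return("amino-acid metabolite(s) missing from S")
  if (!all(object@drainReactions %in% colnames(object@S)))
    return("drain reaction(s) missing from S")
  if (any(object@lb[match(object@drainReactions, colnames(object@S))] != 0))
    return("drain reactions must be irreversible with lower bound 0")
  TRUE
})

#' Solution of a flux optimization
#'
#' @slot objective Objective value (NA unless status is "optimal").
#' @slot fluxes Named numeric flux vector over all reactions.
#' @slot status One of "optimal", "infeasible", "unbounded".
#' @export
setClass("FluxSolution", representation(
  objective = "numeric",
  fluxes = "numeric",
  status = "character"
))

setValidity("FluxSolution", function(object) {
  if (!object@status %in% c("optimal", "infeasible", "unbounded"))
    return("status must be optimal, infeasible or unbounded")
  TRUE
})

#' Amino-acid usage profile
#'
#' Mass fluxes of the 20 amino-acid drains and their normalized distribution.
#'
#' @slot mass Named numeric 20-vector of drain fluxes a_l (g/gDW).
#' @slot fraction Named numeric 20-vector a_l / sum(a); all zero when the
#'   total mass is zero.
#' @export
setClass("AminoAcidProfile", representation(
  mass = "numeric",
  fraction = "numeric"
))

setValidity("AminoAcidProfile", function(object) {
  if (!identical(names(object@mass), aminoAcidCodes()) ||
      !identical(names(object@fraction), aminoAcidCodes()))
    return("mass and fraction must be named by the canonical codes")
  if (any(object@mass < -1e-9)) return("mass must be non-negative")
  tot <- sum(object@mass)
  if (tot > 0 && abs(sum(object@fraction) - 1) > 1e-6)
    return("fractions must sum to 1 when total mass is positive")
  TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "CompositionMatrix", function(object) {
  cat("CompositionMatrix:", nrow(object@xi), "proteins x 20 amino acids",
      "(g/mmol)\n")
  if (nrow(object@xi)) {
    mw <- 1000 * rowSums(object@xi)
    cat("  protein MW range:", format(min(mw), digits = 6), "-",
        format(max(mw), digits = 6), "g/mol\n")
  }
})

setMethod("show", "EcModel", function(object) {
  cat(class(object), "with", nrow(object@S), "metabolites,",
      ncol(object@S), "reactions,", length(object@enzymeMetabolites),
      "enzymes\n")
  cat("  pool exchange:", object@poolReaction,
      sprintf("(bound %.6g g/gDW)\n", poolBound(object)))
})

setMethod("show", "FluxSolution", function(object) {
  cat("FluxSolution:", object@status)
  if (object@status == "optimal")
    cat(", objective =", format(object@objective, digits = 8))
  cat("\n")
})

setMethod("show", "AminoAcidProfile", function(object) {
  cat("AminoAcidProfile: total mass",
      format(sum(object@mass), digits = 6), "g/gDW\n")
  top <- sort(object@fraction, decreasing = TRUE)[1:3]
  cat("  top fractions:",
      paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
})
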