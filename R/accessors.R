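## Accessor generics and methods. Slots are never reached into from user
## code; these are the supported surface.

#' @rdname CompositionMatrix-class
#' @param object,x A package object.
#' @export
setGeneric("xiMatrix", function(object) standardGeneric("xiMatrix"))

#' @rdname CompositionMatrix-class
#' @export
setMethod("xiMatrix", "CompositionMatrix", function(object) object@xi)

#' @rdname CompositionMatrix-class
#' @export
setGeneric("proteinIds", function(object) standardGeneric("proteinIds"))

#' @rdname CompositionMatrix-class
#' @export
setMethod("proteinIds", "CompositionMatrix",
          function(object) rownames(object@xi))

#' Model accessors
#'
#' @param object An \linkS4class{EcModel} or \linkS4class{AcidFBAModel}.
#' @name model-accessors
NULL

#' @rdname model-accessors
#' @export
setGeneric("reactionIds", function(object) standardGeneric("reactionIds"))

#' @rdname model-accessors
#' @export
setMethod("reactionIds", "EcModel", function(object) colnames(object@S))

#' @rdname model-accessors
#' @export
setGeneric("metaboliteIds", function(object) standardGeneric("metaboliteIds"))

#' @rdname model-accessors
#' @export
setMethod("metaboliteIds", "EcModel", function(object) rownames(object@S))

#' @rdname model-accessors
#' @export
setGeneric("stoichiometry", function(object) standardGeneric("stoichiometry"))

#' @rdname model-accessors
#' @export
setMethod("stoichiometry", "EcModel", function(object) object@S)

#' @rdname model-accessors
#' @export
setGeneric("lowerBounds", function(object) standardGeneric("lowerBounds"))

#' @rdname model-accessors
#' @export
setMethod("lowerBounds", "EcModel", function(object) {
  stats::setNames(object@lb, colnames(object@S))
})

#' @rdname model-accessors
#' @export
setGeneric("upperBounds", function(object) standardGeneric("upperBounds"))

#' @rdname model-accessors
#' @export
setMethod("upperBounds", "EcModel", function(object) {
  stats::setNames(object@ub, colnames(object@S))
})

#' @rdname model-accessors
#' @export
setGeneric("objectiveCoefficients",
           function(object) standardGeneric("objectiveCoefficients"))

#' @rdname model-accessors
#' @export
setMethod("objectiveCoefficients", "EcModel", function(object) {
  stats::setNames(object@objective, colnames(object@S))
})

#' @rdname model-accessors
#' @export
setGeneric("biomassReaction",
           function(object) standardGeneric("biomassReaction"))

#' @rdname model-accessors
#' @export
setMethod("biomassReaction", "EcModel", function(object) {
  idx <- which(object@objective != 0)
  if (length(idx) == 0L)
    stop("no biomass reaction designated (all objective coefficients zero)",
         call. = FALSE)
  colnames(object@S)[idx]
})

#' @rdname model-accessors
#' @export
setGeneric("poolReaction", function(object) standardGeneric("poolReaction"))

#' @rdname model-accessors
#' @export
setMethod("poolReaction", "EcModel", function(object) object@poolReaction)

#' @rdname model-accessors
#' @export
setGeneric("poolBound", function(object) standardGeneric("poolBound"))

#' @rdname model-accessors
#' @export
setMethod("poolBound", "EcModel", function(object) {
  unname(object@ub[match(object@poolReaction, colnames(object@S))])
})

#' @rdname model-accessors
#' @param value Replacement value.
#' @export
setGeneric("poolBound<-", function(object, value) standardGeneric("poolBound<-"))

#' @rdname model-accessors
#' @export
setReplaceMethod("poolBound", "EcModel", function(object, value) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  object@ub[match(object@poolReaction, colnames(object@S))] <- value
  object
})

#' @rdname model-accessors
#' @export
setGeneric("enzymeMetabolites",
           function(object) standardGeneric("enzymeMetabolites"))

#' @rdname model-accessors
#' @export
setMethod("enzymeMetabolites", "EcModel",
          function(object) object@enzymeMetabolites)

#' @rdname model-accessors
#' @export
setGeneric("enzymeMW", function(object) standardGeneric("enzymeMW"))

#' @rdname model-accessors
#' @export
setMethod("enzymeMW", "EcModel", function(object) object@enzymeMW)

#' @rdname model-accessors
#' @export
setGeneric("drawReactions", function(object) standardGeneric("drawReactions"))

#' @rdname model-accessors
#' @export
setMethod("drawReactions", "EcModel", function(object) object@drawReactions)

#' @rdname model-accessors
#' @export
setGeneric("exchangeAnnotation",
           function(object) standardGeneric("exchangeAnnotation"))

#' @rdname model-accessors
#' @export
setMethod("exchangeAnnotation", "EcModel",
          function(object) object@exchangeAnnotation)

#' @rdname model-accessors
#' @export
setGeneric("drainReactions", function(object) standardGeneric("drainReactions"))

#' @rdname model-accessors
#' @export
setMethod("drainReactions", "AcidFBAModel",
          function(object) object@drainReactions)

#' @rdname model-accessors
#' @export
setGeneric("compositionMatrix",
           function(object) standardGeneric("compositionMatrix"))

#' @rdname model-accessors
#' @export
setMethod("compositionMatrix", "AcidFBAModel", function(object) object@xi)

#' Set bounds of one or more reactions
#'
#' Returns a copy of the model with the given reaction bounds replaced.
#'
#' @param object An \linkS4class{EcModel}.
#' @param reactions Character vector of reaction identifiers.
#' @param lb,ub Numeric replacement bounds, recycled to the number of
#'   reactions; \code{NULL} leaves the respective bound untouched.
#' @return The modified model.
#' @export
setGeneric("setReactionBounds", function(object, reactions, lb = NULL,
                                         ub = NULL) {
  standardGeneric("setReactionBounds")
})

#' @rdname setReactionBounds
#' @export
setMethod("setReactionBounds", "EcModel",
          function(object, reactions, lb = NULL, ub = NULL) {
  idx <- match(reactions, colnames(object@S))
  if (anyNA(idx))
    stop("unknown reaction(s): ",
         paste(reactions[is.na(idx)], collapse = ", "), call. = FALSE)
  if (!is.null(lb)) object@lb[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) object@ub[idx] <- rep_len(ub, length(idx))
  validObject(object)
  object
})

## ---- FluxSolution / AminoAcidProfile ---------------------------------

#' @rdname FluxSolution-class
#' @param object A \linkS4class{FluxSolution}.
#' @export
setGeneric("objectiveValue", function(object) standardGeneric("objectiveValue"))

#' @rdname FluxSolution-class
#' @export
setMethod("objectiveValue", "FluxSolution", function(object) object@objective)

#' @rdname FluxSolution-class
#' @export
setGeneric("fluxes", function(object) standardGeneric("fluxes"))

#' @rdname FluxSolution-class
#' @export
setMethod("fluxes", "FluxSolution", function(object) object@fluxes)

#' @rdname FluxSolution-class
#' @export
setGeneric("solutionStatus", function(object) standardGeneric("solutionStatus"))

#' @rdname FluxSolution-class
#' @export
setMethod("solutionStatus", "FluxSolution", function(object) object@status)

#' @rdname AminoAcidProfile-class
#' @param object An \linkS4class{AminoAcidProfile}.
#' @export
setGeneric("profileMass", function(object) standardGeneric("profileMass"))

#' @rdname AminoAcidProfile-class
#' @export
setMethod("profileMass", "AminoAcidProfile", function(object) object@mass)

#' @rdname AminoAcidProfile-class
#' @export
setGeneric("profileFraction", function(object) standardGeneric("profileFraction"))

#' @rdname AminoAcidProfile-class
#' @export
setMethod("profileFraction", "AminoAcidProfile", function(object) object@fraction)

## internal constructor helpers

.newProfile <- function(mass) {
  mass <- pmax(mass, 0)
  names(mass) <- aminoAcidCodes()
  tot <- sum(mass)
  frac <- if (tot > 0) mass / tot else stats::setNames(rep(0, 20), aminoAcidCodes())
  new("AminoAcidProfile", mass = mass, fraction = frac)
}

.newSolution <- function(status, objective = NA_real_, fluxes = numeric(0)) {
  new("FluxSolution", objective = objective, fluxes = fluxes, status = status)
}
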