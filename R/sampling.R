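## Random sampling of nutrient conditions.
##
## A condition is one exchange reaction per elemental class (C, N, P, S).
## Viability of a candidate source is judged by swapping it in for the
## reference source of its class (all other classes at reference) and
## requiring a minimal growth rate. Sampling is uniform with replacement
## over the per-class source lists under a single master seed.

.ELEMENT_CLASSES <- c("C", "N", "P", "S")

.classMembers <- function(annotation, cls) {
  annotation$reaction[annotation$class == cls]
}

## the open (ub > 0) member of a class, falling back to the first member
.referenceSource <- function(model, annotation, cls) {
  members <- .classMembers(annotation, cls)
  if (!length(members)) stop("no exchange reactions annotated for class ",
                             cls, call. = FALSE)
  ubs <- upperBounds(model)[members]
  open <- members[ubs > 0]
  if (length(open)) open[1L] else members[1L]
}

#' Identify viable nutrient sources of an elemental class
#'
#' A candidate exchange is viable if, with the reference source of its class
#' replaced by the candidate (other classes untouched), the maximal growth
#' rate reaches \code{threshold}. The candidate inherits the reference
#' source's uptake bound.
#'
#' @param model An \linkS4class{EcModel} or \linkS4class{AcidFBAModel} with
#'   a non-empty exchange annotation.
#' @param elementClass One of \code{"C"}, \code{"N"}, \code{"P"},
#'   \code{"S"}.
#' @param threshold Minimal growth rate counted as viable (default 1e-4).
#' @param annotation Exchange-class table; defaults to the model's own.
#' @return Character vector of viable exchange identifiers (possibly empty,
#'   with a warning).
#' @export
findViableSources <- function(model, elementClass, threshold = 1e-4,
                              annotation = exchangeAnnotation(model)) {
  if (!elementClass %in% .ELEMENT_CLASSES)
    stop("unknown element class '", elementClass,
         "' (expected C, N, P or S)", call. = FALSE)
  members <- .classMembers(annotation, elementClass)
  if (!length(members))
    stop("no exchange reactions annotated for class ", elementClass,
         call. = FALSE)
  ref <- .referenceSource(model, annotation, elementClass)
  refUb <- upperBounds(model)[ref]
  viable <- character(0)
  for (cand in members) {
    m <- setReactionBounds(model, members, ub = 0)
    m <- setReactionBounds(m, cand, ub = unname(refUb))
    sol <- maximizeGrowth(m)
    if (solutionStatus(sol) == "optimal" &&
        objectiveValue(sol) >= threshold)
      viable <- c(viable, cand)
  }
  if (!length(viable))
    warning("no viable ", elementClass, " source at threshold ",
            format(threshold), call. = FALSE)
  viable
}

#' Sample random nutrient conditions
#'
#' Draws \code{n} conditions, each one source per elemental class, uniformly
#' at random with replacement. Reproducible under the seed; the caller's RNG
#' state is untouched.
#'
#' @param sourcesByClass Named list with non-empty character vectors for
#'   each of the classes \code{C}, \code{N}, \code{P}, \code{S}.
#' @param n Number of conditions (> 0).
#' @param seed Integer master seed.
#' @return A data.frame with \code{n} rows and columns C, N, P, S; the seed
#'   is recorded in attribute \code{"seed"}.
#' @export
sampleConditions <- function(sourcesByClass, n, seed) {
  if (!is.numeric(n) || n <= 0)
    stop("n must be positive", call. = FALSE)
  n <- as.integer(n)
  if (!all(.ELEMENT_CLASSES %in% names(sourcesByClass)))
    stop("sourcesByClass must contain all classes C, N, P, S",
         call. = FALSE)
  if (any(vapply(sourcesByClass[.ELEMENT_CLASSES], length, 0L) == 0L))
    stop("every class needs at least one source", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  out <- lapply(.ELEMENT_CLASSES, function(cls) {
    src <- sourcesByClass[[cls]]
    src[sample.int(length(src), n, replace = TRUE)]
  })
  names(out) <- .ELEMENT_CLASSES
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  attr(df, "seed") <- seed
  df
}

#' Amino-acid profiles across sampled nutrient conditions
#'
#' For each condition: all class-member exchanges are closed, the selected
#' source of each class is opened to a large finite bound (uptake limits
#' removed), growth is maximized, the flux sum is minimized, and the
#' amino-acid profile recorded. Optionally drain-level FVA is run at
#' \code{optFraction}. Infeasible (or non-growing) conditions are excluded
#' with a message.
#'
#' @param model An \linkS4class{AcidFBAModel} with exchange annotation.
#' @param conditions A data.frame as from \code{\link{sampleConditions}}.
#' @param optFraction Optimality threshold for the optional FVA.
#' @param fva Run drain FVA per condition (default FALSE).
#' @param openBound Uptake bound given to each selected source (default
#'   1000).
#' @param annotation Exchange-class table; defaults to the model's own.
#' @return List: \code{conditions} (the retained rows), \code{fractions}
#'   (N x 20 mass-fraction matrix), \code{deviation} (relative deviation of
#'   each entry from its column mean), \code{fva} (long data.frame or NULL),
#'   \code{nExcluded}.
#' @export
profilesAcrossConditions <- function(model, conditions, optFraction = 0.99,
                                     fva = FALSE, openBound = 1000,
                                     annotation = exchangeAnnotation(model)) {
  stopifnot(methods::is(model, "AcidFBAModel"), nrow(conditions) >= 1)
  allMembers <- annotation$reaction
  keep <- logical(nrow(conditions))
  fracs <- matrix(NA_real_, nrow(conditions), 20,
                  dimnames = list(NULL, aminoAcidCodes()))
  fvaRows <- list()
  for (i in seq_len(nrow(conditions))) {
    sel <- unlist(conditions[i, .ELEMENT_CLASSES], use.names = FALSE)
    if (!all(sel %in% allMembers))
      stop("condition ", i, " selects unannotated exchange(s): ",
           paste(setdiff(sel, allMembers), collapse = ", "), call. = FALSE)
    m <- setReactionBounds(model, allMembers, ub = 0)
    m <- setReactionBounds(m, sel, ub = openBound)
    res <- aaProfileAtOptimum(m)
    if (is.null(res$profile) || objectiveValue(res$solution) <= 1e-9) {
      message("condition ", i, " infeasible or non-growing; excluded")
      next
    }
    keep[i] <- TRUE
    fracs[i, ] <- profileFraction(res$profile)
    if (fva) {
      fv <- drainFVA(m, optFraction = optFraction)
      fv$condition <- i
      fvaRows[[length(fvaRows) + 1L]] <- fv
    }
  }
  if (!any(keep)) stop("all conditions infeasible", call. = FALSE)
  fracs <- fracs[keep, , drop = FALSE]
  mu <- colMeans(fracs)
  dev <- sweep(fracs, 2L, mu, `-`)
  dev <- sweep(dev, 2L, ifelse(mu > 0, mu, NA_real_), `/`)
  list(conditions = conditions[keep, , drop = FALSE],
       fractions = fracs,
       deviation = dev,
       fva = if (length(fvaRows)) do.call(rbind, fvaRows) else NULL,
       nExcluded = sum(!keep))
}
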