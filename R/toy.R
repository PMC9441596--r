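## Synthetic toy ecGEMs with analytically known optima.
##
## Topology: one external substrate S taken up through one or more carbon
## exchange reactions (EX -> yield_src * S), K parallel enzymatic routes
## S -> yield_k * P (each consuming 1/kcat_k of its enzyme pseudo-metabolite),
## and a biomass reaction P -> (objective). GECKO bookkeeping -- enzyme draw
## reactions at MW/1000 g/mmol and a capped pool exchange -- is constructed
## exactly as in genome-scale models, so every downstream operation sees the
## real conventions. Optional nitrogen/phosphorus/sulphur pseudo-nutrients
## are consumed by biomass at a small stoichiometry with ample exchange
## bounds, so they never move the optimum but give the nutrient-sampling
## machinery real elemental classes to work with. Biomass flux is used
## directly as the growth rate (no maintenance), which keeps closed forms.

.GECKO_ENZ_PREFIX <- "prot_"
.GECKO_POOL_MET <- "prot_pool"
.GECKO_POOL_RXN <- "prot_pool_exchange"

#' Build a toy enzyme-constrained model
#'
#' Constructs a small GECKO-style \linkS4class{EcModel} with K parallel
#' enzyme routes and known analytic optima (see \code{\link{toyOracle}}),
#' together with the protein sequences backing its composition matrix.
#'
#' @param sequences Named character vector of protein sequences; names are
#'   the protein identifiers.
#' @param kcats Numeric turnover numbers (1/h), one per enzyme.
#' @param yields Numeric product yields of each route (product per substrate).
#' @param uptake Upper bound of each open carbon exchange
#'   (mmol gDW^-1 h^-1); default 10.
#' @param poolBound Upper bound of the protein-pool exchange (g/gDW);
#'   default 0.01.
#' @param sources Optional named list over elemental classes (\code{C},
#'   \code{N}, \code{P}, \code{S}); each element is a list of source specs
#'   \code{list(id =, yield =, usable =)}. The first source of each class is
#'   open, the rest closed. Default: a single carbon source of yield 1 and no
#'   other classes.
#' @return A list with elements \code{model} (\linkS4class{EcModel}) and
#'   \code{proteins} (named character vector of sequences).
#' @export
#' @examples
#' toy <- makeToyEcgem(c(E1 = "AAAA", E2 = "GGGG"),
#'                     kcats = c(100, 1000), yields = c(1, 0.5))
#' toy$model
makeToyEcgem <- function(sequences, kcats, yields, uptake = 10,
                         poolBound = 0.01, sources = NULL) {
  K <- length(sequences)
  stopifnot(K >= 1, length(kcats) == K, length(yields) == K,
            all(kcats > 0), all(yields > 0), uptake >= 0, poolBound >= 0)
  ids <- names(sequences)
  if (is.null(ids) || any(ids == "") || anyDuplicated(ids))
    stop("sequences must be uniquely named by protein identifier",
         call. = FALSE)
  mw <- vapply(sequences, proteinMW, numeric(1))

  if (is.null(sources))
    sources <- list(C = list(list(id = "EX_C_glc", yield = 1, usable = TRUE)))
  if (is.null(sources$C) || !length(sources$C))
    stop("at least one carbon source is required", call. = FALSE)

  enzMets <- paste0(.GECKO_ENZ_PREFIX, ids)
  classMet <- c(N = "nut_N_c", P = "nut_P_c", S = "nut_S_c")
  usedClasses <- intersect(names(classMet), names(sources))

  mets <- c("S_c", "P_c", classMet[usedClasses], enzMets, .GECKO_POOL_MET)
  deadMets <- character(0)

  rxn <- list()  # list of list(id, stoich (named), lb, ub, obj)
  annot <- list()
  for (cls in names(sources)) {
    specs <- sources[[cls]]
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      y <- if (is.null(sp$yield)) 1 else sp$yield
      usable <- if (is.null(sp$usable)) TRUE else sp$usable
      target <- if (cls == "C") "S_c" else unname(classMet[cls])
      if (!usable) {
        target <- paste0("dead_", sp$id, "_c")
        deadMets <- c(deadMets, target)
      }
      open <- (i == 1L)
      ubound <- if (!open) 0 else if (cls == "C") uptake else 1000
      rxn[[length(rxn) + 1L]] <- list(
        id = sp$id, stoich = stats::setNames(y, target),
        lb = 0, ub = ubound, obj = 0)
      annot[[length(annot) + 1L]] <- data.frame(
        reaction = sp$id, class = cls, stringsAsFactors = FALSE)
    }
  }
  for (k in seq_len(K)) {
    st <- c(-1, yields[k], -1 / kcats[k])
    names(st) <- c("S_c", "P_c", enzMets[k])
    rxn[[length(rxn) + 1L]] <- list(
      id = paste0("r_", ids[k]), stoich = st, lb = 0, ub = 1000, obj = 0)
  }
  bio <- c("P_c" = -1)
  if (length(usedClasses))
    bio <- c(bio, stats::setNames(rep(-0.01, length(usedClasses)),
                                  classMet[usedClasses]))
  rxn[[length(rxn) + 1L]] <- list(id = "biomass", stoich = bio,
                                  lb = 0, ub = 1000, obj = 1)
  for (k in seq_len(K)) {
    st <- c(-mw[k] / 1000, 1)
    names(st) <- c(.GECKO_POOL_MET, enzMets[k])
    rxn[[length(rxn) + 1L]] <- list(
      id = paste0("draw_", enzMets[k]), stoich = st, lb = 0, ub = 1000,
      obj = 0)
  }
  rxn[[length(rxn) + 1L]] <- list(
    id = .GECKO_POOL_RXN,
    stoich = stats::setNames(1, .GECKO_POOL_MET),
    lb = 0, ub = poolBound, obj = 0)

  mets <- c(mets, deadMets)
  S <- matrix(0, length(mets), length(rxn),
              dimnames = list(mets, vapply(rxn, `[[`, "", "id")))
  for (j in seq_along(rxn)) S[names(rxn[[j]]$stoich), j] <- rxn[[j]]$stoich

  model <- new("EcModel",
    S = S,
    lb = vapply(rxn, `[[`, 0, "lb"),
    ub = vapply(rxn, `[[`, 0, "ub"),
    objective = vapply(rxn, `[[`, 0, "obj"),
    poolReaction = .GECKO_POOL_RXN,
    poolMetabolite = .GECKO_POOL_MET,
    enzymeMetabolites = enzMets,
    drawReactions = stats::setNames(paste0("draw_", enzMets), enzMets),
    enzymeMW = stats::setNames(mw / 1000, enzMets),
    exchangeAnnotation = do.call(rbind, annot))
  validObject(model)
  list(model = model, proteins = sequences)
}

#' The reference two-enzyme toy model
#'
#' K = 2 parallel routes: E1 = "AAAA" (kcat 100/h, yield 1.0) and
#' E2 = "GGGG" (kcat 1000/h, yield 0.5), substrate uptake bound 10, pool
#' bound 0.01 g/gDW. Its optimum (growth 6.4757, routes 2.9515/7.0485) is
#' known from vertex enumeration.
#'
#' @param uptake,poolBound Override the default bounds.
#' @return As \code{\link{makeToyEcgem}}.
#' @export
toyEC1 <- function(uptake = 10, poolBound = 0.01) {
  makeToyEcgem(c(E1 = "AAAA", E2 = "GGGG"), kcats = c(100, 1000),
               yields = c(1, 0.5), uptake = uptake, poolBound = poolBound)
}

#' Analytic optimum of a toy model by vertex enumeration
#'
#' Independent ground truth for the toy topology: the growth LP reduces to
#' route fluxes v_k >= 0 under two aggregate constraints (total uptake and
#' pool mass), whose vertices have at most two non-zero routes and are
#' enumerated exhaustively. No LP code is shared with the solver.
#'
#' @param kcats,yields Route parameters as in \code{\link{makeToyEcgem}}.
#' @param mw Protein molecular weights (g/mol), e.g.
#'   \code{vapply(sequences, proteinMW, numeric(1))}.
#' @param uptake,poolBound Constraint levels; either may be \code{Inf}.
#' @return List with \code{objective} (maximal growth), \code{routes}
#'   (optimal route fluxes), and \code{degenerate} (TRUE when several
#'   vertices attain the optimum).
#' @export
toyOracle <- function(kcats, yields, mw, uptake = 10, poolBound = 0.01) {
  K <- length(kcats)
  stopifnot(length(yields) == K, length(mw) == K, K <= 8)
  w <- mw / 1000 / kcats                     # pool mass per unit route flux
  verts <- list(rep(0, K))
  for (k in seq_len(K)) {
    if (is.finite(uptake)) {
      v <- rep(0, K); v[k] <- uptake
      if (w[k] * uptake <= poolBound * (1 + 1e-12)) verts <- c(verts, list(v))
    }
    if (is.finite(poolBound)) {
      v <- rep(0, K); v[k] <- poolBound / w[k]
      if (v[k] <= uptake * (1 + 1e-12)) verts <- c(verts, list(v))
    }
  }
  if (is.finite(uptake) && is.finite(poolBound)) {
    for (k in seq_len(K - 1)) for (k2 in (k + 1):K) {
      det <- w[k2] - w[k]
      if (abs(det) < 1e-15) next
      vk <- (w[k2] * uptake - poolBound) / det
      vk2 <- uptake - vk
      if (vk >= -1e-12 && vk2 >= -1e-12) {
        v <- rep(0, K); v[k] <- max(vk, 0); v[k2] <- max(vk2, 0)
        verts <- c(verts, list(v))
      }
    }
  }
  if (!length(verts)) stop("no feasible vertex found", call. = FALSE)
  if (!is.finite(uptake) && !is.finite(poolBound))
    stop("unbounded toy: both uptake and pool are infinite", call. = FALSE)
  objs <- vapply(verts, function(v) sum(yields * v), numeric(1))
  best <- max(objs)
  hit <- which(objs >= best - 1e-9 * max(1, abs(best)))
  vbest <- verts[[hit[1L]]]
  distinct <- length(unique(lapply(verts[hit], function(v) round(v, 9)))) > 1L
  list(objective = best,
       routes = stats::setNames(vbest, names(kcats)),
       degenerate = distinct)
}

#' Generate a random toy ecGEM
#'
#' Random parallel-route models for property testing: kcats log-uniform in
#' 10..1e4 per hour, sequences of length 50..500 with uniform residues,
#' yields uniform in 0.2..2, pool bound log-uniform in 0.001..0.1 g/gDW,
#' uptake fixed at 10. Reproducible under the seed; the caller's RNG state
#' is left untouched.
#'
#' @param nEnzymes Number of parallel routes (1..8).
#' @param seed Integer seed.
#' @return As \code{\link{makeToyEcgem}}, plus \code{spec} with the drawn
#'   parameters.
#' @export
makeRandomEcgem <- function(nEnzymes, seed) {
  stopifnot(nEnzymes >= 1, nEnzymes <= 8)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  kcats <- 10^stats::runif(nEnzymes, 1, 4)
  yields <- stats::runif(nEnzymes, 0.2, 2)
  lens <- sample(50:500, nEnzymes, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(aminoAcidCodes(), L, replace = TRUE), collapse = "")
  }, character(1))
  names(seqs) <- sprintf("RP%02d", seq_len(nEnzymes))
  pool <- 10^stats::runif(1, -3, -1)
  toy <- makeToyEcgem(seqs, kcats, yields, uptake = 10, poolBound = pool)
  toy$spec <- list(kcats = kcats, yields = yields, lengths = lens,
                   poolBound = pool, uptake = 10, seed = seed)
  toy
}
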