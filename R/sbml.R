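## SBML Level 3 (+ fbc version 2) writer and reader for the subset these
## models need: species, reactions with stoichiometric speciesReferences,
## global bound parameters referenced per reaction, and one maximization
## objective. Nutrient-class annotations ride along in reaction notes.
## Infinite bounds are serialized as +/-1e30 and mapped back on read.

.SBML_INF <- 1e30

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

.fmtNum <- function(x) {
  x <- ifelse(x == Inf, .SBML_INF, ifelse(x == -Inf, -.SBML_INF, x))
  sprintf("%.17g", x)
}

#' Write a model as SBML
#'
#' Serializes an \linkS4class{EcModel} or \linkS4class{AcidFBAModel} as
#' SBML L3V1 with the fbc-v2 flux-bound and objective scheme. Reading the
#' file back (\code{\link{readEcModelSBML}} /
#' \code{\link{readAcidFBAModelSBML}}) yields an equivalent model: same
#' optimum and same constraint matrix up to row/column order.
#'
#' @param model The model to write.
#' @param path Output file.
#' @param id Model identifier inside the file.
#' @return \code{path}, invisibly.
#' @export
writeModelSBML <- function(model, path, id = "acidfba_model") {
  S <- model@S
  rxns <- colnames(S); mets <- rownames(S)
  annot <- model@exchangeAnnotation
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('  <model id="%s" fbc:strict="true">', .xmlEscape(id)),
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>')
  lines <- c(lines, sprintf(
    paste0('      <species id="%s" compartment="c" hasOnlySubstanceUnits=',
           '"false" boundaryCondition="false" constant="false"/>'),
    .xmlEscape(mets)))
  lines <- c(lines, '    </listOfSpecies>', '    <listOfParameters>')
  lines <- c(lines, sprintf(
    '      <parameter id="bnd_lb_%d" value="%s" constant="true"/>',
    seq_along(rxns), .fmtNum(model@lb)))
  lines <- c(lines, sprintf(
    '      <parameter id="bnd_ub_%d" value="%s" constant="true"/>',
    seq_along(rxns), .fmtNum(model@ub)))
  lines <- c(lines, '    </listOfParameters>', '    <listOfReactions>')
  for (j in seq_along(rxns)) {
    st <- S[, j]
    sub <- which(st < 0); prod <- which(st > 0)
    cls <- if (nrow(annot)) annot$class[match(rxns[j], annot$reaction)]
           else NA_character_
    lines <- c(lines, sprintf(
      paste0('      <reaction id="%s" reversible="%s" fast="false" ',
             'fbc:lowerFluxBound="bnd_lb_%d" fbc:upperFluxBound="bnd_ub_%d">'),
      .xmlEscape(rxns[j]), tolower(model@lb[j] < 0), j, j))
    if (!is.na(cls) && length(cls))
      lines <- c(lines, sprintf(
        paste0('        <notes><body xmlns="http://www.w3.org/1999/xhtml">',
               '<p>nutrient_class: %s</p></body></notes>'), cls))
    if (length(sub)) {
      lines <- c(lines, '        <listOfReactants>', sprintf(
        paste0('          <speciesReference species="%s" stoichiometry=',
               '"%s" constant="true"/>'),
        .xmlEscape(mets[sub]), .fmtNum(-st[sub])),
        '        </listOfReactants>')
    }
    if (length(prod)) {
      lines <- c(lines, '        <listOfProducts>', sprintf(
        paste0('          <speciesReference species="%s" stoichiometry=',
               '"%s" constant="true"/>'),
        .xmlEscape(mets[prod]), .fmtNum(st[prod])),
        '        </listOfProducts>')
    }
    lines <- c(lines, '      </reaction>')
  }
  lines <- c(lines, '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>')
  nz <- which(model@objective != 0)
  lines <- c(lines, sprintf(
    paste0('          <fbc:fluxObjective fbc:reaction="%s" ',
           'fbc:coefficient="%s"/>'),
    .xmlEscape(rxns[nz]), .fmtNum(model@objective[nz])))
  lines <- c(lines, '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>', '    </fbc:listOfObjectives>',
    '  </model>', '</sbml>')
  writeLines(lines, path)
  invisible(path)
}

## parse the raw structural content of an SBML file
.parseSBML <- function(path) {
  doc <- xml2::read_xml(path)
  getAttr <- function(node, name) {
    a <- xml2::xml_attrs(node)
    v <- a[name]
    if (is.na(v)) v <- a[paste0("fbc:", name)]
    unname(v)
  }
  spNodes <- xml2::xml_find_all(doc, "//*[local-name()='species']")
  mets <- vapply(spNodes, getAttr, "", "id")
  if (!length(mets)) stop("unreadable SBML: no species found", call. = FALSE)
  parNodes <- xml2::xml_find_all(doc, "//*[local-name()='parameter']")
  params <- stats::setNames(
    as.numeric(vapply(parNodes, getAttr, "", "value")),
    vapply(parNodes, getAttr, "", "id"))
  rxNodes <- xml2::xml_find_all(doc, "//*[local-name()='reaction']")
  rxns <- vapply(rxNodes, getAttr, "", "id")
  if (!length(rxns)) stop("unreadable SBML: no reactions found",
                          call. = FALSE)
  S <- matrix(0, length(mets), length(rxns),
              dimnames = list(mets, rxns))
  lb <- ub <- numeric(length(rxns))
  cls <- rep(NA_character_, length(rxns))
  for (j in seq_along(rxNodes)) {
    node <- rxNodes[[j]]
    lbRef <- getAttr(node, "lowerFluxBound")
    ubRef <- getAttr(node, "upperFluxBound")
    if (is.na(lbRef) || is.na(ubRef) ||
        is.na(params[lbRef]) || is.na(params[ubRef]))
      stop("reaction ", rxns[j], " lacks resolvable flux bounds",
           call. = FALSE)
    lb[j] <- params[[lbRef]]; ub[j] <- params[[ubRef]]
    for (sr in xml2::xml_find_all(
           node, ".//*[local-name()='listOfReactants']/*")) {
      S[getAttr(sr, "species"), j] <-
        S[getAttr(sr, "species"), j] - as.numeric(getAttr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(
           node, ".//*[local-name()='listOfProducts']/*")) {
      S[getAttr(sr, "species"), j] <-
        S[getAttr(sr, "species"), j] + as.numeric(getAttr(sr, "stoichiometry"))
    }
    note <- xml2::xml_find_first(node, ".//*[local-name()='p']")
    if (!inherits(note, "xml_missing")) {
      txt <- xml2::xml_text(note)
      if (grepl("^nutrient_class:", txt))
        cls[j] <- trimws(sub("^nutrient_class:", "", txt))
    }
  }
  lb[lb <= -.SBML_INF] <- -Inf
  ub[ub >= .SBML_INF] <- Inf
  objective <- numeric(length(rxns))
  foNodes <- xml2::xml_find_all(doc, "//*[local-name()='fluxObjective']")
  for (node in foNodes) {
    rid <- getAttr(node, "reaction")
    objective[match(rid, rxns)] <- as.numeric(getAttr(node, "coefficient"))
  }
  list(S = S, lb = lb, ub = ub, objective = objective, class = cls)
}

## classify GECKO structure from parsed content
.classifyGecko <- function(parsed, enzymePrefix, poolMetabolite) {
  S <- parsed$S
  mets <- rownames(S)
  if (!poolMetabolite %in% mets)
    stop("no protein pool exchange: pool metabolite '", poolMetabolite,
         "' not found", call. = FALSE)
  ## pool exchange: sole stoichiometry is producing the pool metabolite
  poolRow <- match(poolMetabolite, mets)
  isPoolEx <- vapply(seq_len(ncol(S)), function(j) {
    nz <- which(S[, j] != 0)
    length(nz) == 1L && nz == poolRow && S[poolRow, j] > 0
  }, logical(1))
  if (!any(isPoolEx))
    stop("no protein pool exchange reaction found", call. = FALSE)
  poolRxn <- colnames(S)[which(isPoolEx)[1L]]
  enzMets <- setdiff(grep(paste0("^", enzymePrefix), mets, value = TRUE),
                     poolMetabolite)
  draws <- character(0); mw <- numeric(0)
  aaRows <- grep(paste0("^", .AA_MET_PREFIX), mets, value = TRUE)
  aaRows <- aaRows[aaRows %in% paste0(.AA_MET_PREFIX, aminoAcidCodes())]
  for (e in enzMets) {
    producing <- which(S[e, ] > 0)
    if (length(producing) != 1L)
      stop("enzyme metabolite ", e, " must have exactly one draw reaction (",
           length(producing), " found)", call. = FALSE)
    j <- producing
    draws[e] <- colnames(S)[j]
    cost <- -sum(S[c(poolMetabolite, aaRows), j])
    if (cost <= 0)
      stop("draw reaction for ", e, " spends no pool mass", call. = FALSE)
    mw[e] <- cost
  }
  annot <- data.frame(reaction = colnames(S), class = parsed$class,
                      stringsAsFactors = FALSE)
  annot <- annot[!is.na(annot$class), , drop = FALSE]
  rownames(annot) <- NULL
  list(poolRxn = poolRxn, enzMets = enzMets, draws = draws, mw = mw,
       annot = annot, aaMets = aaRows)
}

#' Read a GECKO-style enzyme-constrained model from SBML
#'
#' Parses the file and classifies the GECKO structure: enzyme
#' pseudo-metabolites by prefix, the single pool exchange (the reaction
#' producing only the pool metabolite), per-enzyme draw reactions, and
#' their molecular-weight coefficients. Counts are reported via
#' \code{message}.
#'
#' @param path SBML file.
#' @param enzymePrefix Enzyme pseudo-metabolite prefix (default
#'   \code{"prot_"}).
#' @param poolMetabolite Pool pseudo-metabolite identifier (default
#'   \code{"prot_pool"}).
#' @return An \linkS4class{EcModel}.
#' @export
readEcModelSBML <- function(path, enzymePrefix = .GECKO_ENZ_PREFIX,
                            poolMetabolite = .GECKO_POOL_MET) {
  parsed <- .parseSBML(path)
  cls <- .classifyGecko(parsed, enzymePrefix, poolMetabolite)
  message("read ", ncol(parsed$S), " reactions, ", nrow(parsed$S),
          " species, ", length(cls$enzMets), " enzymes, pool exchange '",
          cls$poolRxn, "'")
  model <- new("EcModel",
    S = parsed$S, lb = parsed$lb, ub = parsed$ub,
    objective = parsed$objective,
    poolReaction = cls$poolRxn, poolMetabolite = poolMetabolite,
    enzymeMetabolites = cls$enzMets,
    drawReactions = cls$draws,
    enzymeMW = cls$mw,
    exchangeAnnotation = cls$annot)
  validObject(model)
  model
}

#' Read an amino-acid-resolved model from SBML
#'
#' As \code{\link{readEcModelSBML}}, but additionally recognizes the 20
#' amino-acid pseudo-metabolites (\code{aa_<code>}) and drain reactions
#' (\code{draw_aa_<code>}) and rebuilds the composition matrix from the
#' enzyme source stoichiometries.
#'
#' @inheritParams readEcModelSBML
#' @return An \linkS4class{AcidFBAModel}.
#' @export
readAcidFBAModelSBML <- function(path, enzymePrefix = .GECKO_ENZ_PREFIX,
                                 poolMetabolite = .GECKO_POOL_MET) {
  parsed <- .parseSBML(path)
  cls <- .classifyGecko(parsed, enzymePrefix, poolMetabolite)
  codes <- aminoAcidCodes()
  aaMets <- stats::setNames(paste0(.AA_MET_PREFIX, codes), codes)
  drains <- stats::setNames(paste0(.AA_DRAIN_PREFIX, codes), codes)
  if (!all(aaMets %in% rownames(parsed$S)))
    stop("missing amino-acid pseudo-metabolite(s)", call. = FALSE)
  if (!all(drains %in% colnames(parsed$S)))
    stop("missing amino-acid drain reaction(s)", call. = FALSE)
  protIds <- sub(paste0("^", enzymePrefix), "", cls$enzMets)
  xi <- matrix(0, length(cls$enzMets), 20L,
               dimnames = list(protIds, codes))
  for (k in seq_along(cls$enzMets)) {
    xi[k, ] <- -parsed$S[aaMets, cls$draws[cls$enzMets[k]]]
  }
  model <- new("AcidFBAModel",
    S = parsed$S, lb = parsed$lb, ub = parsed$ub,
    objective = parsed$objective,
    poolReaction = cls$poolRxn, poolMetabolite = poolMetabolite,
    enzymeMetabolites = cls$enzMets,
    drawReactions = cls$draws,
    enzymeMW = cls$mw,
    exchangeAnnotation = cls$annot,
    aaMetabolites = aaMets,
    drainReactions = drains,
    sourceReactions = cls$draws,
    xi = new("CompositionMatrix", xi = xi))
  validObject(model)
  model
}
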