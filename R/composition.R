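## Building the composition matrix xi from protein sequences.

#' Build the amino-acid composition matrix
#'
#' For K proteins, builds the K x 20 matrix xi with
#' \code{xi[k, l] = count_kl * residueMass_l / 1000} (gram of amino acid l
#' per mmol of protein k). Row order preserves input order. By construction
#' \code{1000 * rowSums(xi)} equals \code{\link{proteinMW}} of each sequence
#' exactly (same summation convention), which is what keeps the amino-acid
#' mass balances consistent with the protein-pool budget.
#'
#' @param proteins Named character vector of sequences (names = protein
#'   identifiers), or a \code{Biostrings::AAStringSet}.
#' @param strict Passed to \code{\link{countResidues}}.
#' @return A \linkS4class{CompositionMatrix}.
#' @export
#' @examples
#' buildXi(c(P1 = "GG", P2 = "AAAA"))
buildXi <- function(proteins, strict = TRUE) {
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins), names(proteins))
  }
  K <- length(proteins)
  if (K == 0L) {
    xi <- matrix(numeric(0), 0L, 20L,
                 dimnames = list(character(0), aminoAcidCodes()))
    return(new("CompositionMatrix", xi = xi))
  }
  ids <- names(proteins)
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("proteins must be named by identifier", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate protein identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (any(!nzchar(proteins)))
    stop("empty sequence for ",
         paste(ids[!nzchar(proteins)], collapse = ", "), call. = FALSE)
  counts <- t(vapply(proteins, countResidues, integer(20), strict = strict))
  xi <- sweep(counts, 2L, .AA_RESIDUE_MASS, `*`) / 1000
  dimnames(xi) <- list(ids, aminoAcidCodes())
  new("CompositionMatrix", xi = xi)
}

#' Read a proteome FASTA
#'
#' Reads protein sequences from FASTA, extracting UniProt-style accessions
#' (\code{sp|ACC|NAME} or \code{tr|ACC|NAME} headers) or, failing that, the
#' first whitespace-delimited token of the header, as protein identifiers.
#'
#' @param path FASTA file.
#' @param uniprot If \code{TRUE} (default), headers matching the UniProt
#'   scheme have their accession extracted; set \code{FALSE} to always use
#'   the first header token verbatim.
#' @return Named character vector of uppercase sequences.
#' @export
readProteome <- function(path, uniprot = TRUE) {
  if (file.size(path) == 0) return(stats::setNames(character(0), character(0)))
  aa <- Biostrings::readAAStringSet(path)
  seqs <- toupper(as.character(aa))
  hdr <- names(aa)
  ids <- vapply(strsplit(hdr, "[ \t]"), function(x) x[1L], character(1))
  if (uniprot) {
    up <- grepl("^(sp|tr)\\|[^|]+\\|", ids)
    ids[up] <- sub("^(sp|tr)\\|([^|]+)\\|.*$", "\\2", ids[up])
  }
  if (any(!nzchar(seqs)))
    stop("empty sequence for ", paste(ids[!nzchar(seqs)], collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate protein identifiers in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  stats::setNames(unname(seqs), ids)
}

#' Write / read a composition matrix as TSV
#'
#' Plain-text interchange format: one row per protein, first column
#' \code{protein_id}, then the 20 one-letter codes, values in g/mmol.
#'
#' @param xi A \linkS4class{CompositionMatrix}.
#' @param path File path.
#' @return \code{readXi} returns a \linkS4class{CompositionMatrix};
#'   \code{writeXi} returns \code{path} invisibly.
#' @export
writeXi <- function(xi, path) {
  stopifnot(methods::is(xi, "CompositionMatrix"))
  df <- data.frame(protein_id = proteinIds(xi), xiMatrix(xi),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeXi
#' @export
readXi <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!identical(colnames(df), c("protein_id", aminoAcidCodes())))
    stop("malformed composition table: expected protein_id + 20 codes",
         call. = FALSE)
  xi <- as.matrix(df[, aminoAcidCodes(), drop = FALSE])
  rownames(xi) <- df$protein_id
  new("CompositionMatrix", xi = xi)
}
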