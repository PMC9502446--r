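## Central S4 classes.  Coordinate convention throughout: codon and residue
## indices are 0-based half-open internally; every written report is 1-based
## inclusive.

setClassUnion("listOrNULL", c("list", "NULL"))

#' GeneSet: a validated set of coding sequences
#'
#' Wraps a \code{DNAStringSet} of coding sequences that have passed CDS
#' validation: every sequence is a non-empty multiple of 3 over
#' \{A,C,G,T,N\}, with at most one stop codon, which (if present) is the
#' final codon.  Gene identifiers (names) are unique and iteration order is
#' input order.  Construct with \code{\link{GeneSet}} or via
#' \code{\link{validateCds}}.
#'
#' @slot sequences A named \code{DNAStringSet} of CDS.
#' @exportClass GeneSet
setClass("GeneSet", representation(sequences = "DNAStringSet"))

.validGeneSet <- function(object) {
    x <- object@sequences
    if (length(x) == 0L) return(TRUE)
    msg <- character()
    ids <- names(x)
    if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
        msg <- c(msg, "all sequences must carry a non-empty gene_id name")
    else if (anyDuplicated(ids))
        msg <- c(msg, sprintf("duplicate gene_id: %s",
                              paste(unique(ids[duplicated(ids)]), collapse = ", ")))
    w <- Biostrings::width(x)
    if (any(w == 0L))
        msg <- c(msg, "empty sequences are not valid CDS")
    if (any(w %% 3L != 0L))
        msg <- c(msg, sprintf("CDS length not a multiple of 3: %s",
                              paste(head(ids[w %% 3L != 0L], 5L), collapse = ", ")))
    if (length(msg) == 0L) {
        chars <- as.character(x)
        bad <- grepl("[^ACGTN]", chars)
        if (any(bad))
            msg <- c(msg, sprintf("characters outside {A,C,G,T,N} in: %s",
                                  paste(head(ids[bad], 5L), collapse = ", ")))
        else {
            internal <- vapply(chars, .hasInternalStop, logical(1L), USE.NAMES = FALSE)
            if (any(internal))
                msg <- c(msg, sprintf("internal stop codon in: %s",
                                      paste(head(ids[internal], 5L), collapse = ", ")))
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("GeneSet", .validGeneSet)

#' CugCensus: per-gene CUG codon counts and totals
#'
#' Result of \code{\link{censusCug}}.  \code{perGene} has one row per gene in
#' input order (\code{gene_id}, \code{n_cug}); \code{positions} holds the
#' 0-based codon indices of each CUG.  Totals satisfy
#' \code{genesWithCug + genesWithoutCug == genesTotal},
#' \code{cugCodonsTotal == sum(n_cug)} and
#' \code{maxCugPerGene == max(n_cug)} (0 for an empty set).
#'
#' @slot perGene data.frame with columns \code{gene_id}, \code{n_cug}.
#' @slot positions named list of 0-based integer codon indices, ascending.
#' @slot genesTotal,genesWithCug,genesWithoutCug,cugCodonsTotal,maxCugPerGene
#'   integer totals.
#' @slot histogram named integer vector: n_cug value -> number of genes.
#' @exportClass CugCensus
setClass("CugCensus", representation(
    perGene = "data.frame",
    positions = "list",
    genesTotal = "integer",
    genesWithCug = "integer",
    genesWithoutCug = "integer",
    cugCodonsTotal = "integer",
    maxCugPerGene = "integer",
    histogram = "integer"))

.validCugCensus <- function(object) {
    msg <- character()
    pg <- object@perGene
    if (nrow(pg) == 0L && length(object@positions) == 0L) {
        if (object@genesTotal != 0L || object@cugCodonsTotal != 0L)
            return("empty census must have zero totals")
        return(TRUE)
    }
    if (!identical(pg$gene_id, names(object@positions)))
        msg <- c(msg, "positions must be named by gene_id in perGene order")
    nlen <- vapply(object@positions, length, integer(1L))
    if (length(nlen) && !identical(unname(nlen), as.integer(pg$n_cug)))
        msg <- c(msg, "length(codon_positions) must equal n_cug for every gene")
    if (object@genesWithCug + object@genesWithoutCug != object@genesTotal)
        msg <- c(msg, "genesWithCug + genesWithoutCug != genesTotal")
    if (object@cugCodonsTotal != sum(as.integer(pg$n_cug)))
        msg <- c(msg, "cugCodonsTotal != sum(n_cug)")
    expectedMax <- if (nrow(pg)) max(as.integer(pg$n_cug)) else 0L
    if (object@maxCugPerGene != expectedMax)
        msg <- c(msg, "maxCugPerGene inconsistent with per-gene counts")
    if (length(msg)) msg else TRUE
}
setValidity("CugCensus", .validCugCensus)

#' DualProteome: the Ser- and Leu-restricted decodings of a gene set
#'
#' Result of \code{\link{translateDual}}.  For every gene the two proteins
#' have equal length and differ exactly at the CUG-encoded residues, where
#' the serine decoding carries \code{S} and the leucine decoding \code{L}.
#'
#' @slot ser,leu named \code{AAStringSet}, parallel to each other.
#' @slot cugIndices named list of 0-based residue indices, ascending.
#' @exportClass DualProteome
setClass("DualProteome", representation(
    ser = "AAStringSet", leu = "AAStringSet", cugIndices = "list"))

.validDualProteome <- function(object) {
    msg <- character()
    if (!identical(names(object@ser), names(object@leu)) ||
        !identical(names(object@ser), names(object@cugIndices)))
        msg <- c(msg, "ser, leu and cugIndices must share names and order")
    if (!identical(Biostrings::width(object@ser), Biostrings::width(object@leu)))
        msg <- c(msg, "ser and leu proteins must have equal lengths")
    if (length(object@ser)) {
        serc <- strsplit(as.character(object@ser), "", fixed = TRUE)
        leuc <- strsplit(as.character(object@leu), "", fixed = TRUE)
        for (i in seq_along(serc)) {
            idx <- object@cugIndices[[i]] + 1L
            diff <- which(serc[[i]] != leuc[[i]])
            if (!identical(diff, as.integer(idx))) {
                msg <- c(msg, sprintf("proteins for %s differ away from cugIndices",
                                      names(object@ser)[i]))
                break
            }
            if (length(idx) &&
                (any(serc[[i]][idx] != "S") || any(leuc[[i]][idx] != "L"))) {
                msg <- c(msg, sprintf("CUG residues for %s are not S/L",
                                      names(object@ser)[i]))
                break
            }
        }
    }
    if (length(msg)) msg else TRUE
}
setValidity("DualProteome", .validDualProteome)

#' IsoformCounts: proteome-size hypotheses under CUG ambiguity
#'
#' \code{unrestricted} counts every CUG independently Ser or Leu
#' (\eqn{\sum_g 2^{n_g}}); \code{restricted} assumes all CUG positions in a
#' protein share one amino acid (one protein for a CUG-free gene, two
#' otherwise).  \code{restrictedLiteral} is the alternative literal reading
#' \code{genesWithoutCug + 2 * cugCodonsTotal}.
#'
#' @slot unrestricted,restricted,restrictedLiteral numeric counts.
#' @slot genesTotal integer.
#' @exportClass IsoformCounts
setClass("IsoformCounts", representation(
    unrestricted = "numeric", restricted = "numeric",
    restrictedLiteral = "numeric", genesTotal = "integer"))

.validIsoformCounts <- function(object) {
    msg <- character()
    if (object@unrestricted < object@restricted)
        msg <- c(msg, "unrestricted must be >= restricted")
    if (object@genesTotal > 0L &&
        (object@unrestricted < object@genesTotal ||
         object@restricted < object@genesTotal))
        msg <- c(msg, "both counts must be >= genesTotal for a non-empty set")
    if (length(msg)) msg else TRUE
}
setValidity("IsoformCounts", .validIsoformCounts)

#' PkaSet: group pKas for charge-balance pI computation
#'
#' Polypeptide mode uses the terminal pKas plus the ionizable side chains
#' (D, E, C, Y acidic; H, K, R basic) once per residue.  Free-amino-acid mode
#' uses the residue's alpha-carboxyl and alpha-amino pKas plus its side chain
#' if ionizable.
#'
#' @slot name character scalar.
#' @slot polyNterm,polyCterm terminal-group pKas (polypeptide mode).
#' @slot polySide named numeric: side-chain pKas in a polypeptide.
#' @slot sideAcidity named character: "acidic" or "basic" per ionizable side chain.
#' @slot freeCarboxyl,freeAmino named numeric over the 20 residues.
#' @slot freeSide named numeric: free-amino-acid side-chain pKas.
#' @exportClass PkaSet
setClass("PkaSet", representation(
    name = "character",
    polyNterm = "numeric", polyCterm = "numeric",
    polySide = "numeric", sideAcidity = "character",
    freeCarboxyl = "numeric", freeAmino = "numeric", freeSide = "numeric"))

.validPkaSet <- function(object) {
    pk <- c(object@polyNterm, object@polyCterm, object@polySide,
            object@freeCarboxyl, object@freeAmino, object@freeSide)
    msg <- character()
    if (any(!is.finite(pk)) || any(pk <= 0) || any(pk >= 14))
        msg <- c(msg, "all pKas must lie in (0, 14)")
    if (!all(names(object@polySide) %in% names(object@sideAcidity)))
        msg <- c(msg, "every ionizable side chain needs an acidity flag")
    if (!all(object@sideAcidity %in% c("acidic", "basic")))
        msg <- c(msg, "sideAcidity values must be 'acidic' or 'basic'")
    if (length(msg)) msg else TRUE
}
setValidity("PkaSet", .validPkaSet)

#' HydropathyScale: per-residue hydropathy values
#'
#' A complete map over the 20 canonical amino acids; \code{X} residues are
#' skipped (excluded from numerator and denominator) by \code{\link{gravy}}.
#'
#' @slot name character scalar.
#' @slot values named numeric of length 20.
#' @exportClass HydropathyScale
setClass("HydropathyScale", representation(name = "character", values = "numeric"))

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
           "L","K","M","F","P","S","T","W","Y","V")

.validHydropathyScale <- function(object) {
    if (!setequal(names(object@values), .AA20) || length(object@values) != 20L)
        return("scale must define exactly the 20 canonical residues")
    if (any(!is.finite(object@values)))
        return("scale values must be finite")
    TRUE
}
setValidity("HydropathyScale", .validHydropathyScale)

#' FoldChangeMatrix: log2 delta-delta-Cq fold changes
#'
#' Result of \code{\link{ddcqLog2fc}}.  The long table retains replicate-mean
#' and SD Cq values for audit.  Invariants: the reference gene's log2FC is 0
#' in every condition, and the basal condition's log2FC is 0 for every gene.
#'
#' @slot long data.frame: gene, condition, phase, n_reps, mean_cq, sd_cq,
#'   dcq, ddcq, log2fc.
#' @slot referenceGene,basalCondition character scalars.
#' @exportClass FoldChangeMatrix
setClass("FoldChangeMatrix", representation(
    long = "data.frame", referenceGene = "character", basalCondition = "character"))

.validFoldChangeMatrix <- function(object) {
    lg <- object@long
    msg <- character()
    tol <- 1e-9
    refRows <- lg$gene == object@referenceGene
    if (any(abs(lg$log2fc[refRows]) > tol))
        msg <- c(msg, "reference gene log2fc must be 0 in every condition")
    basRows <- lg$condition == object@basalCondition
    if (any(abs(lg$log2fc[basRows]) > tol))
        msg <- c(msg, "basal condition log2fc must be 0 for every gene")
    if (length(msg)) msg else TRUE
}
setValidity("FoldChangeMatrix", .validFoldChangeMatrix)
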