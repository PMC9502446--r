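#' Census CUG codons over a gene set
#'
#' Scans every coding sequence in frame and records the 0-based codon index
#' of each CUG (exactly the codon \code{CTG} after U/T normalization; codons
#' containing \code{N} never count).  A final stop codon is excluded from the
#' codon positions but a CTG immediately before it is counted normally.
#'
#' @param genes A \code{\link[=GeneSet-class]{GeneSet}}.
#' @return A \code{\link[=CugCensus-class]{CugCensus}}.
#' @examples
#' cen <- censusCug(GeneSet(c(g1 = "ATGCTGCTGTAA", g2 = "ATGAAATAA")))
#' cugHistogram(cen)
#' @export
censusCug <- function(genes) {
    stopifnot(is(genes, "GeneSet"))
    seqs <- as.character(sequences(genes))
    ids <- geneIds(genes)
    positions <- lapply(seqs, function(s) {
        cod <- .codonsOf(s)
        which(cod == "CTG") - 1L  # CTG is never a stop, so no final-stop filter needed
    })
    names(positions) <- ids
    n <- vapply(positions, length, integer(1L), USE.NAMES = FALSE)
    hist <- table(factor(n, levels = sort(unique(n))))
    new("CugCensus",
        perGene = data.frame(gene_id = as.character(ids), n_cug = n,
                             stringsAsFactors = FALSE),
        positions = positions,
        genesTotal = length(ids),
        genesWithCug = sum(n > 0L),
        genesWithoutCug = sum(n == 0L),
        cugCodonsTotal = as.integer(sum(n)),
        maxCugPerGene = if (length(n)) max(n) else 0L,
        histogram = setNames(as.integer(hist), names(hist)))
}

#' @describeIn CugCensus-class per-gene table (gene_id, n_cug)
#' @param x,object A CugCensus.
#' @export
setGeneric("perGene", function(x) standardGeneric("perGene"))
#' @rdname CugCensus-class
#' @export
setMethod("perGene", "CugCensus", function(x) x@perGene)

#' @describeIn CugCensus-class 0-based CUG codon indices per gene
#' @export
setGeneric("cugPositions", function(x) standardGeneric("cugPositions"))
#' @rdname CugCensus-class
#' @export
setMethod("cugPositions", "CugCensus", function(x) x@positions)

#' @describeIn CugCensus-class histogram of n_cug values
#' @export
setGeneric("cugHistogram", function(x) standardGeneric("cugHistogram"))
#' @rdname CugCensus-class
#' @export
setMethod("cugHistogram", "CugCensus", function(x) x@histogram)

#' @describeIn CugCensus-class named totals vector
#' @export
setGeneric("censusTotals", function(x) standardGeneric("censusTotals"))
#' @rdname CugCensus-class
#' @export
setMethod("censusTotals", "CugCensus", function(x)
    c(genes_total = x@genesTotal, genes_with_cug = x@genesWithCug,
      genes_without_cug = x@genesWithoutCug, cug_codons_total = x@cugCodonsTotal,
      max_cug_per_gene = x@maxCugPerGene))

setMethod("show", "CugCensus", function(object) {
    cat("CugCensus\n")
    t <- censusTotals(object)
    cat(sprintf("  %d genes; %d with >=1 CUG (%.1f%%), %d without\n",
                t[["genes_total"]], t[["genes_with_cug"]],
                if (t[["genes_total"]]) 100 * t[["genes_with_cug"]] / t[["genes_total"]] else 0,
                t[["genes_without_cug"]]))
    cat(sprintf("  %d CUG codons total; max per gene %d\n",
                t[["cug_codons_total"]], t[["max_cug_per_gene"]]))
})

## dual genetic codes: standard everywhere except CTG
.CODE_LEU <- Biostrings::GENETIC_CODE          # CTG -> L (standard)
.CODE_SER <- { x <- Biostrings::GENETIC_CODE; x[["CTG"]] <- "S"; x }

.translateWith <- function(codons, code) {
    aa <- unname(code[codons])
    aa[is.na(aa)] <- "X"    # codons containing N
    aa
}

#' Dual restricted translation of a gene set
#'
#' Translates every CDS twice under the standard genetic code, decoding CUG
#' restrictively as serine in one proteome and as leucine in the other.  A
#' final stop codon is dropped; codons containing \code{N} translate to
#' \code{X} in both proteomes.
#'
#' @param genes A \code{\link[=GeneSet-class]{GeneSet}}, or a single CDS as a
#'   character string (returned as a one-gene proteome named \code{cds}).
#' @return A \code{\link[=DualProteome-class]{DualProteome}}.
#' @examples
#' dp <- translateDual(GeneSet(c(g1 = "ATGCTGTAA")))
#' as.character(serProteins(dp))   # "MS"
#' as.character(leuProteins(dp))   # "ML"
#' @export
translateDual <- function(genes) {
    if (is.character(genes) && length(genes) == 1L && is.null(names(genes)))
        genes <- GeneSet(c(cds = genes))
    if (!is(genes, "GeneSet")) genes <- GeneSet(genes)
    seqs <- as.character(sequences(genes))
    ids <- geneIds(genes)
    ser <- character(length(seqs)); leu <- character(length(seqs))
    idx <- vector("list", length(seqs))
    for (i in seq_along(seqs)) {
        cod <- .codonsOf(seqs[[i]])
        if (length(cod) && cod[length(cod)] %in% .STOPS)
            cod <- cod[-length(cod)]
        ser[i] <- paste(.translateWith(cod, .CODE_SER), collapse = "")
        leu[i] <- paste(.translateWith(cod, .CODE_LEU), collapse = "")
        idx[[i]] <- which(cod == "CTG") - 1L
    }
    names(idx) <- ids
    new("DualProteome",
        ser = setNames(Biostrings::AAStringSet(ser), ids),
        leu = setNames(Biostrings::AAStringSet(leu), ids),
        cugIndices = idx)
}

#' @describeIn DualProteome-class serine-decoded proteome
#' @param x,object A DualProteome.
#' @export
setGeneric("serProteins", function(x) standardGeneric("serProteins"))
#' @rdname DualProteome-class
#' @export
setMethod("serProteins", "DualProteome", function(x) x@ser)

#' @describeIn DualProteome-class leucine-decoded proteome
#' @export
setGeneric("leuProteins", function(x) standardGeneric("leuProteins"))
#' @rdname DualProteome-class
#' @export
setMethod("leuProteins", "DualProteome", function(x) x@leu)

#' @describeIn DualProteome-class 0-based CUG residue indices per gene
#' @export
setGeneric("cugResidueIndices", function(x) standardGeneric("cugResidueIndices"))
#' @rdname DualProteome-class
#' @export
setMethod("cugResidueIndices", "DualProteome", function(x) x@cugIndices)

#' @rdname DualProteome-class
#' @export
setMethod("length", "DualProteome", function(x) length(x@ser))

setMethod("show", "DualProteome", function(object) {
    cat(sprintf("DualProteome over %d gene(s); %d CUG-encoded residue(s)\n",
                length(object), sum(lengths(object@cugIndices))))
})

#' Isoform-count hypotheses for CUG ambiguity
#'
#' Two counting hypotheses for the number of distinct polypeptides a
#' CUG-ambiguous proteome can produce.  Unrestricted (random, per-codon
#' charging): \eqn{\sum_g 2^{n_g}} over all genes, a CUG-free gene
#' contributing \eqn{2^0 = 1}.  Restricted (all CUG positions in a protein
#' charged alike): one protein per CUG-free gene plus two per CUG-carrying
#' gene.  The literal alternative reading, one Ser and one Leu protein per
#' CUG codon, is co-reported as \code{restrictedLiteral}.
#'
#' @param census A \code{\link[=CugCensus-class]{CugCensus}}.
#' @return An \code{\link[=IsoformCounts-class]{IsoformCounts}}.
#' @seealso \code{\link{isoformCountsFromTotals}} for the totals-only form.
#' @examples
#' cen <- censusCug(GeneSet(c(a = "ATGAAA", b = "ATGCTG", c = "ATGCTGCTG")))
#' isoformCounts(cen)   # unrestricted 1+2+4 = 7, restricted 1+2+2 = 5
#' @export
isoformCounts <- function(census) {
    stopifnot(is(census, "CugCensus"))
    n <- perGene(census)$n_cug
    new("IsoformCounts",
        unrestricted = if (length(n)) sum(2 ^ n) else 0,
        restricted = census@genesWithoutCug + 2 * census@genesWithCug,
        restrictedLiteral = census@genesWithoutCug + 2 * census@cugCodonsTotal,
        genesTotal = census@genesTotal)
}

#' Restricted isoform count from printed totals
#'
#' The restricted hypothesis needs only the gene totals: genes without a CUG
#' contribute one protein each and genes with at least one CUG contribute
#' two (an all-Ser and an all-Leu form).
#'
#' @param genesTotal Total number of annotated genes.
#' @param genesWithCug Number of genes with at least one CUG codon.
#' @return \code{(genesTotal - genesWithCug) + 2 * genesWithCug}, as numeric.
#' @examples
#' isoformCountsFromTotals(6272, 4110)   # 10382
#' @export
isoformCountsFromTotals <- function(genesTotal, genesWithCug) {
    stopifnot(genesWithCug <= genesTotal, genesWithCug >= 0)
    (genesTotal - genesWithCug) + 2 * genesWithCug
}

setMethod("show", "IsoformCounts", function(object) {
    cat("IsoformCounts\n")
    cat(sprintf("  unrestricted (sum 2^n): %s\n",
                format(object@unrestricted, big.mark = ",", scientific = FALSE)))
    cat(sprintf("  restricted (1 or 2 per gene): %s\n",
                format(object@restricted, big.mark = ",", scientific = FALSE)))
    cat(sprintf("  restricted, literal 2n reading: %s\n",
                format(object@restrictedLiteral, big.mark = ",", scientific = FALSE)))
})

#' Codon-usage table over a gene set
#'
#' Counts all 64 codons in frame over every CDS (including stop codons) and
#' reports frequency per thousand codons.  Codons containing \code{N} are
#' not counted.
#'
#' @param genes A \code{\link[=GeneSet-class]{GeneSet}} (must be non-empty).
#' @return data.frame with columns \code{codon} (all 64, alphabetical),
#'   \code{count}, \code{per_thousand}.
#' @examples
#' cu <- codonUsage(GeneSet(c(g1 = "ATGCTGTAA")))
#' cu[cu$count > 0, ]
#' @export
codonUsage <- function(genes) {
    stopifnot(is(genes, "GeneSet"))
    if (length(genes) == 0L)
        stop("codonUsage requires a non-empty gene set")
    all64 <- sort(names(Biostrings::GENETIC_CODE))
    cod <- unlist(lapply(as.character(sequences(genes)), .codonsOf),
                  use.names = FALSE)
    cod <- cod[cod %in% all64]
    counts <- table(factor(cod, levels = all64))
    total <- sum(counts)
    data.frame(codon = all64,
               count = as.integer(counts),
               per_thousand = 1000 * as.integer(counts) / total,
               stringsAsFactors = FALSE)
}

#' Write census, isoform-count and codon-usage tables
#'
#' Deterministic TSV writers: column order fixed, row order is input gene
#' order, floats rendered with the number of decimals declared in the
#' \code{#}-prefixed header.  Codon positions are written 1-based.
#'
#' @param census A \code{CugCensus}.
#' @param counts An \code{IsoformCounts}.
#' @param usage A codon-usage data.frame from \code{\link{codonUsage}}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @name writeCugTables
NULL

#' @rdname writeCugTables
#' @export
writeCensusTsv <- function(census, path) {
    pg <- perGene(census)
    pos1 <- vapply(cugPositions(census), function(p)
        paste(p + 1L, collapse = ","), character(1L))
    df <- data.frame(gene_id = pg$gene_id, n_cug = pg$n_cug,
                     positions_1based = unname(pos1), stringsAsFactors = FALSE)
    .writeTsv(df, path, comments = c("CUG codon census; positions are 1-based codon indices"))
}

#' @rdname writeCugTables
#' @export
writeIsoformCountsTsv <- function(counts, path) {
    df <- data.frame(genes_total = counts@genesTotal,
                     unrestricted = counts@unrestricted,
                     restricted = counts@restricted,
                     restricted_literal = counts@restrictedLiteral)
    .writeTsv(df, path, comments = "isoform-count hypotheses", decimals = 0L)
}

#' @rdname writeCugTables
#' @export
writeCodonUsageTsv <- function(usage, path) {
    .writeTsv(usage, path, comments = "codon usage; per_thousand = 1000*count/total",
              decimals = 2L)
}
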