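#' Read a FASTA file into a sequence set
#'
#' Parses a multi-record FASTA file, concatenating wrapped sequence lines,
#' stripping whitespace and folding to upper case.  Nucleotide alphabets are
#' normalized to DNA letters internally (\code{U -> T}); the original form is
#' remembered in the \code{origForm} attribute so \code{\link{writeFasta}}
#' can round-trip RNA input.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of \code{"dna"}, \code{"rna"}, \code{"protein"}.
#' @return A named \code{DNAStringSet} (nucleotide alphabets) or
#'   \code{AAStringSet} (protein), records in file order, with attribute
#'   \code{origForm} set to the \code{alphabet} argument.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">g1", "ATGCTGTAA"), fa)
#' readFasta(fa, "dna")
#' @export
readFasta <- function(path, alphabet = c("dna", "rna", "protein")) {
    alphabet <- match.arg(alphabet)
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L)
        stop("empty FASTA file: ", path)
    seqs <- toupper(gsub("[[:space:]]", "", as.character(raw)))
    ids <- sub("\\s.*$", "", names(raw))
    desc <- sub("^\\S+\\s*", "", names(raw))
    if (anyDuplicated(ids))
        stop("duplicate record id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ## U and T are interconvertible on read for both nucleotide alphabets
    allowed <- switch(alphabet,
        dna = "ACGTUN", rna = "ACGUTN",
        protein = paste0(paste(.AA20, collapse = ""), "X*"))
    bad <- regexpr(sprintf("[^%s]", allowed), seqs)
    if (any(bad > 0L)) {
        i <- which(bad > 0L)[1L]
        stop(sprintf("invalid character '%s' at position %d in record '%s'",
                     substr(seqs[i], bad[i], bad[i]), bad[i], ids[i]))
    }
    if (alphabet %in% c("dna", "rna"))
        seqs <- .normalizeNuc(seqs)
    out <- if (alphabet == "protein") Biostrings::AAStringSet(seqs)
           else Biostrings::DNAStringSet(seqs)
    names(out) <- ids
    attr(out, "origForm") <- alphabet
    attr(out, "descriptions") <- desc
    out
}

#' Write sequences to FASTA
#'
#' Writes 60-column-wrapped FASTA.  If the set carries an
#' \code{origForm == "rna"} attribute (or \code{asRna = TRUE}) nucleotide
#' sequences are written back in RNA form (\code{T -> U}).
#'
#' @param x A named \code{XStringSet} or named character vector, or a
#'   \code{\link{GeneSet}}.
#' @param path Output path.
#' @param asRna Write nucleotides with U instead of T.  Defaults to the
#'   \code{origForm} attribute left by \code{\link{readFasta}}.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, asRna = identical(attr(x, "origForm"), "rna")) {
    if (is(x, "GeneSet")) x <- sequences(x)
    seqs <- as.character(x)
    if (isTRUE(asRna)) {
        seqs <- chartr("T", "U", seqs)
        x <- Biostrings::RNAStringSet(seqs)
    } else if (is.character(x)) {
        x <- Biostrings::BStringSet(seqs)
    }
    names(x) <- names(seqs)
    Biostrings::writeXStringSet(x, path, width = 60L)
    invisible(path)
}

#' Construct a GeneSet from sequences
#'
#' @param x A named \code{DNAStringSet} or named character vector of CDS that
#'   already satisfy the CDS invariants (see \linkS4class{GeneSet}).  Use
#'   \code{\link{validateCds}} to build a GeneSet from unvalidated records.
#' @return A \code{\link[=GeneSet-class]{GeneSet}}.
#' @examples
#' GeneSet(c(g1 = "ATGCTGTAA", g2 = "ATGAAA"))
#' @export
GeneSet <- function(x) {
    if (is.character(x)) x <- Biostrings::DNAStringSet(x)
    new("GeneSet", sequences = x)
}

#' @describeIn GeneSet-class sequences as a DNAStringSet
#' @param x,object A GeneSet.
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname GeneSet-class
#' @export
setMethod("sequences", "GeneSet", function(x) x@sequences)

#' @describeIn GeneSet-class gene identifiers in input order
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname GeneSet-class
#' @export
setMethod("geneIds", "GeneSet", function(x) names(x@sequences))

#' @rdname GeneSet-class
#' @export
setMethod("length", "GeneSet", function(x) length(x@sequences))

#' @rdname GeneSet-class
#' @param i index
#' @param j,drop,... ignored
#' @export
setMethod("[", "GeneSet", function(x, i, j, ..., drop = TRUE)
    new("GeneSet", sequences = x@sequences[i]))

setMethod("show", "GeneSet", function(object) {
    cat(sprintf("GeneSet with %d coding sequence(s)\n", length(object)))
    w <- Biostrings::width(object@sequences)
    if (length(object))
        cat(sprintf("  codons per gene: %d-%d (median %.0f)\n",
                    min(w) %/% 3L, max(w) %/% 3L, stats::median(w) / 3))
})

#' Validate coding sequences
#'
#' Checks that DNA records are valid coding sequences: non-empty, length a
#' positive multiple of 3, characters in \{A,C,G,T,N\}, and at most one stop
#' codon which (if present) is the final codon.  The start codon is not
#' required to be ATG, since annotation exports vary.
#'
#' @param records A named \code{DNAStringSet} or named character vector
#'   (e.g. from \code{\link{readFasta}}).
#' @param policy \code{"strict"}: any violation is an error.  \code{"skip"}:
#'   offending records are excluded, with reasons in the \code{rejected}
#'   attribute.  \code{"coerce"}: a trailing incomplete codon is trimmed;
#'   internal stops are still rejected (excluded, as in skip).
#' @return A \code{\link[=GeneSet-class]{GeneSet}}; attribute
#'   \code{rejected} is a data.frame (gene_id, reason) of exclusions.
#' @examples
#' validateCds(c(g1 = "ATGCTGTAA"))
#' validateCds(c(g1 = "ATGCT"), policy = "coerce")   # trimmed to "ATG"
#' @export
validateCds <- function(records, policy = c("strict", "skip", "coerce")) {
    policy <- match.arg(policy)
    if (is(records, "XStringSet")) records <- as.character(records)
    ids <- names(records)
    if (is.null(ids) || any(!nzchar(ids)))
        stop("records must be named by gene_id")
    if (anyDuplicated(ids))
        stop("duplicate gene_id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- .normalizeNuc(records)
    keep <- character(0); kept <- character(0)
    rejected <- data.frame(gene_id = character(), reason = character())
    fail <- function(id, reason) {
        if (policy == "strict")
            stop(sprintf("CDS validation failed for '%s': %s", id, reason))
        rejected[nrow(rejected) + 1L, ] <<- list(id, reason)
    }
    for (i in seq_along(seqs)) {
        s <- seqs[[i]]; id <- ids[[i]]
        if (nchar(s) == 0L) { fail(id, "empty sequence"); next }
        if (grepl("[^ACGTN]", s)) {
            fail(id, sprintf("invalid character at position %d",
                             regexpr("[^ACGTN]", s)))
            next
        }
        if (nchar(s) %% 3L != 0L) {
            if (policy == "coerce") {
                s <- substr(s, 1L, nchar(s) - nchar(s) %% 3L)
                if (nchar(s) == 0L) { fail(id, "no complete codon"); next }
            } else { fail(id, "length not a multiple of 3"); next }
        }
        if (.hasInternalStop(s)) { fail(id, "internal stop codon"); next }
        kept <- c(kept, id); keep <- c(keep, s)
    }
    if (nrow(rejected))
        message(sprintf("validateCds: excluded %d record(s) [%s]", nrow(rejected),
                        paste(rejected$gene_id, rejected$reason,
                              sep = ": ", collapse = "; ")))
    gs <- GeneSet(setNames(keep, kept))
    attr(gs, "rejected") <- rejected
    gs
}
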