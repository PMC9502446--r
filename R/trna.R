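#' The bundled synthetic tRNA cloverleaf template
#'
#' A constructed 76-nt cloverleaf-like sequence (not a natural tRNA) with
#' the CAG anticodon at positions 34--36 (1-based) and all three identity
#' elements present: G33, GGG and CCC motifs inside the TpsiC-arm window,
#' and a discriminator G ahead of the terminal CCA.
#'
#' @return Named character vector of length 1 (T-normalized DNA letters).
#' @export
trnaTemplate <- function() {
    x <- readFasta(.extdata("trna_cag_template_synthetic.fasta"), "rna")
    setNames(as.character(x), names(x))
}

#' Annotate a tRNA with a simplified cloverleaf frame
#'
#' Locates the anticodon as the occurrence of the given triplet closest to
#' the sequence midpoint (anticodons sit near the center of a tRNA), then
#' derives: \code{pos33_index}, the base immediately 5' of the anticodon
#' (canonical position 33); \code{discriminator_index}, the final base or
#' the base 5' of a terminal CCA (canonical position 73); and
#' \code{tpsic_span}, the TpsiC-arm search window running from 10 bases past
#' the anticodon to the discriminator.  All indices 0-based; spans
#' half-open.  Full Sprinzl numbering is deliberately not implemented; these
#' sequence-relative rules reproduce the canonical calls on standard-length
#' tRNAs.
#'
#' @param trna tRNA sequence (character scalar or length-1 named vector; U
#'   or T accepted).
#' @param anticodon Anticodon triplet, default \code{"CAG"}.
#' @return List: \code{anticodon_start}, \code{anticodon_end} (half-open),
#'   \code{pos33_index}, \code{tpsic_start}, \code{tpsic_end} (half-open),
#'   \code{discriminator_index}, \code{has_cca}.
#' @export
annotateCloverleaf <- function(trna, anticodon = "CAG") {
    seq <- .normalizeNuc(as.character(trna)[1L])
    n <- nchar(seq)
    if (n < 60L || n > 120L)
        stop("tRNA length out of the expected 60-120 nt range: ", n)
    anticodon <- .normalizeNuc(anticodon)
    occ <- gregexpr(anticodon, seq, fixed = TRUE)[[1L]]
    if (occ[1L] == -1L)
        stop("anticodon ", anticodon, " not found in sequence")
    occ0 <- as.integer(occ) - 1L              # 0-based starts
    edge <- occ0 < 15L | occ0 + 3L > n - 15L  # acceptor-proximal ends
    if (all(edge))
        stop("anticodon found only within the acceptor-proximal 15 bases; ",
             "cannot place the anticodon loop")
    occ0 <- occ0[!edge]
    center <- occ0 + 1                        # triplet midpoint, 0-based
    start <- occ0[which.min(abs(center - (n - 1) / 2))]
    hasCca <- substr(seq, n - 2L, n) == "CCA"
    disc <- if (hasCca) n - 4L else n - 1L    # 0-based
    tpsicStart <- start + 3L + 10L
    if (tpsicStart >= disc)
        stop("sequence too short 3' of the anticodon for a TpsiC window")
    list(anticodon_start = start, anticodon_end = start + 3L,
         pos33_index = start - 1L,
         tpsic_start = tpsicStart, tpsic_end = disc,
         discriminator_index = disc, has_cca = hasCca)
}

#' Detect the three tRNA_CAG identity elements
#'
#' The three sequence features that let both SerRS and LeuRS recognize the
#' hybrid tRNA_CAG: (i) a G at canonical position 33, immediately 5' of the
#' CAG anticodon; (ii) GGG and CCC motifs in the TpsiC arm (both must occur
#' inside the annotated window); (iii) a discriminator G at canonical
#' position 73.  Deterministic for a fixed sequence and anticodon, and
#' invariant to U/T representation.
#'
#' @param trna tRNA sequence (U or T letters).
#' @param ann Annotation from \code{\link{annotateCloverleaf}} (computed if
#'   \code{NULL}).
#' @param anticodon Anticodon triplet used when \code{ann} is \code{NULL}.
#' @return One-row data.frame: \code{feature_i_g33},
#'   \code{feature_ii_tpsic_ggg_ccc}, \code{feature_iii_discriminator_g}
#'   (logical), plus the inspected indices (1-based in the report columns
#'   \code{pos33_1based}, \code{tpsic_window_1based},
#'   \code{discriminator_1based}).
#' @export
detectIdentityElements <- function(trna, ann = NULL, anticodon = "CAG") {
    seq <- .normalizeNuc(as.character(trna)[1L])
    if (is.null(ann)) ann <- annotateCloverleaf(seq, anticodon)
    n <- nchar(seq)
    idx <- c(ann$pos33_index, ann$discriminator_index, ann$tpsic_end - 1L)
    if (any(idx < 0L | idx >= n))
        stop("annotation index out of bounds for this sequence")
    at <- function(i) substr(seq, i + 1L, i + 1L)
    window <- substr(seq, ann$tpsic_start + 1L, ann$tpsic_end)
    data.frame(
        feature_i_g33 = at(ann$pos33_index) == "G",
        feature_ii_tpsic_ggg_ccc = grepl("GGG", window, fixed = TRUE) &&
            grepl("CCC", window, fixed = TRUE),
        feature_iii_discriminator_g = at(ann$discriminator_index) == "G",
        pos33_1based = ann$pos33_index + 1L,
        tpsic_window_1based = sprintf("%d-%d", ann$tpsic_start + 1L, ann$tpsic_end),
        discriminator_1based = ann$discriminator_index + 1L,
        stringsAsFactors = FALSE)
}

#' Identity-element report for a set of tRNAs
#'
#' @param trnas Named character vector or \code{XStringSet} of tRNA
#'   sequences.
#' @param anticodon Anticodon triplet, default \code{"CAG"}.
#' @return data.frame, one row per tRNA (column \code{id} first), as from
#'   \code{\link{detectIdentityElements}}.
#' @export
identityElementReport <- function(trnas, anticodon = "CAG") {
    ids <- names(trnas)
    if (is.null(ids)) ids <- sprintf("trna_%d", seq_along(trnas))
    seqs <- as.character(trnas)
    rows <- lapply(seq_along(seqs), function(i)
        cbind(id = ids[i],
              detectIdentityElements(seqs[[i]], anticodon = anticodon),
              stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Pairwise identity distance matrix
#'
#' Distances \code{d(i,j) = 1 - identity(i,j)}.  With
#' \code{source = "pairwise_nw"} identity comes from
#' \code{\link{globalAlign}} per pair (gapped columns count against
#' identity).  With \code{source = "supplied_msa"} the sequences must be
#' pre-aligned to equal length; identity is computed over columns where not
#' both members are gaps (a single gap counts as a mismatch).
#'
#' @param seqs Named character vector or \code{XStringSet}; at least 3.
#' @param source \code{"pairwise_nw"} or \code{"supplied_msa"}.
#' @param match,mismatch,gap Alignment scores for the pairwise route.
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distanceMatrix <- function(seqs, source = c("pairwise_nw", "supplied_msa"),
                           match = 1, mismatch = -1, gap = -2) {
    source <- match.arg(source)
    seqs <- setNames(.normalizeNuc(as.character(seqs)), names(seqs))
    k <- length(seqs)
    if (k < 3L)
        stop("distanceMatrix requires at least 3 sequences")
    if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
        stop("sequences must carry unique names")
    if (source == "supplied_msa" && length(unique(nchar(seqs))) != 1L)
        stop("supplied_msa requires equal-length aligned records")
    d <- matrix(0, k, k, dimnames = list(names(seqs), names(seqs)))
    for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
        ident <- if (source == "pairwise_nw") {
            globalAlign(seqs[[i]], seqs[[j]], match, mismatch, gap)$identity
        } else {
            a <- strsplit(seqs[[i]], "", fixed = TRUE)[[1L]]
            b <- strsplit(seqs[[j]], "", fixed = TRUE)[[1L]]
            use <- !(a == "-" & b == "-")
            if (!any(use)) stop("all-gap pair in supplied MSA")
            sum(a[use] == b[use] & a[use] != "-") / sum(use)
        }
        d[i, j] <- d[j, i] <- 1 - ident
    }
    d
}
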