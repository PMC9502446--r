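## Independent oracles, deliberately naive: these re-derive expected values
## by enumeration or direct summation and must stay independent of the
## package code paths they check.

## exhaustive global-alignment score by plain recursion over all alignments
bruteAlignScore <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    av <- strsplit(a, "")[[1]]
    bv <- strsplit(b, "")[[1]]
    rec <- function(i, j) {
        if (i == 0 && j == 0) return(0)
        best <- -Inf
        if (i > 0 && j > 0)
            best <- max(best, rec(i - 1, j - 1) +
                                  if (av[i] == bv[j]) match else mismatch)
        if (i > 0) best <- max(best, rec(i - 1, j) + gap)
        if (j > 0) best <- max(best, rec(i, j - 1) + gap)
        best
    }
    rec(length(av), length(bv))
}

## group-by-group Henderson-Hasselbalch summation straight off the data file
naiveNetCharge <- function(protein, pH) {
    tb <- read.delim(system.file("extdata", "pka_default.tsv",
                                 package = "cugDecode"),
                     comment.char = "#", stringsAsFactors = FALSE)
    pos <- function(pka) 1 / (1 + 10^(pH - pka))
    neg <- function(pka) -1 / (1 + 10^(pka - pH))
    q <- pos(tb$poly_pk_side[tb$residue == "Nterm"]) +
         neg(tb$poly_pk_side[tb$residue == "Cterm"])
    for (ch in strsplit(protein, "")[[1]]) {
        row <- tb[tb$residue == ch, ]
        if (nrow(row) == 1 && !is.na(row$poly_pk_side)) {
            q <- q + if (row$side_acidity == "acidic") neg(row$poly_pk_side)
                     else pos(row$poly_pk_side)
        }
    }
    q
}

## distinct-protein count by explicit enumeration of Ser/Leu assignments
bruteIsoformCount <- function(geneSeqs) {
    total <- 0
    for (s in geneSeqs) {
        cod <- substring(s, seq(1, nchar(s) - 2, 3), seq(3, nchar(s), 3))
        if (cod[length(cod)] %in% c("TAA", "TAG", "TGA"))
            cod <- cod[-length(cod)]
        idx <- which(cod == "CTG")
        gc <- Biostrings::GENETIC_CODE
        proteins <- character(0)
        grid <- if (length(idx))
            expand.grid(rep(list(c("S", "L")), length(idx)),
                        stringsAsFactors = FALSE)
        else data.frame(row.names = 1)
        for (r in seq_len(nrow(grid))) {
            aa <- unname(gc[cod]); aa[is.na(aa)] <- "X"
            if (length(idx)) aa[idx] <- unlist(grid[r, ])
            proteins <- c(proteins, paste(aa, collapse = ""))
        }
        total <- total + length(unique(proteins))
    }
    total
}

## random tree with positive branch lengths and its additive distance matrix
randomAdditiveCase <- function(ntaxa) {
    tr <- ape::rtree(ntaxa, rooted = FALSE,
                     br = function(n) runif(n, 0.05, 1))
    tr$tip.label <- sort(tr$tip.label)  # label order independent of topology
    list(tree = tr, d = ape::cophenetic.phylo(tr))
}

## topology equality for unrooted trees
sameTopology <- function(t1, t2) {
    ape::dist.topo(ape::unroot(t1), ape::unroot(t2)) == 0
}

## small helper: random peptide from the 20 canonical residues
randomPeptide <- function(len) {
    aa <- c("A","R","N","D","C","Q","E","G","H","I",
            "L","K","M","F","P","S","T","W","Y","V")
    paste(sample(aa, len, replace = TRUE), collapse = "")
}
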