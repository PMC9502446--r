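test_that("censusCug counts CUG codons in frame with exact positions", {
    cen <- censusCug(GeneSet(c(g1 = "ATGCTGCTGTAA")))
    expect_identical(perGene(cen)$n_cug, 2L)
    expect_identical(cugPositions(cen)$g1, c(1L, 2L))

    cen0 <- censusCug(GeneSet(c(g1 = "ATGAAATAA")))
    expect_identical(censusTotals(cen0)[["genes_without_cug"]], 1L)

    cen3 <- censusCug(GeneSet(c(a = "ATGAAATAA", b = "ATGCTGTAA",
                                c = "ATGCTGCTGTAA")))
    expect_identical(cugHistogram(cen3), c(`0` = 1L, `1` = 1L, `2` = 1L))
    expect_identical(censusTotals(cen3)[["cug_codons_total"]], 2L + 1L)
    expect_identical(censusTotals(cen3)[["max_cug_per_gene"]], 2L)

    ## out-of-frame CTG trigrams and N-containing codons never count
    cenx <- censusCug(GeneSet(c(g = "ATGACTGAACNGTAA")))
    expect_identical(perGene(cenx)$n_cug, 0L)
})

test_that("census totals satisfy the class invariants on random synthetic sets", {
    for (seed in 1:5) {
        sim <- simulateGenes(geneSimConfig(nGenes = 40, codonRange = c(10, 80),
                                           seed = seed))
        cen <- censusCug(sim$genes)
        t <- censusTotals(cen)
        expect_identical(t[["genes_with_cug"]] + t[["genes_without_cug"]],
                         t[["genes_total"]])
        expect_identical(t[["cug_codons_total"]], sum(perGene(cen)$n_cug))
        expect_identical(t[["max_cug_per_gene"]], max(perGene(cen)$n_cug))
        expect_true(all(vapply(cugPositions(cen), length, 1L) ==
                            perGene(cen)$n_cug))
        expect_true(all(vapply(cugPositions(cen), function(p)
            !is.unsorted(p, strictly = TRUE), TRUE)))
    }
})

test_that("translateDual produces the Ser/Leu pair with correct residues", {
    dp <- translateDual("ATGCTGTAA")
    expect_identical(unname(as.character(serProteins(dp))), "MS")
    expect_identical(unname(as.character(leuProteins(dp))), "ML")
    expect_identical(unname(cugResidueIndices(dp)[[1]]), 1L)

    dp2 <- translateDual("ATGAAA")
    expect_identical(unname(as.character(serProteins(dp2))), "MK")
    expect_identical(unname(as.character(leuProteins(dp2))), "MK")
    expect_length(cugResidueIndices(dp2)[[1]], 0L)

    dp3 <- translateDual("ATGCTGNNNCTG")
    expect_identical(unname(as.character(serProteins(dp3))), "MSXS")
    expect_identical(unname(as.character(leuProteins(dp3))), "MLXL")
    expect_identical(unname(cugResidueIndices(dp3)[[1]]), c(1L, 3L))
})

test_that("Hamming distance between decodings equals the census count", {
    sim <- simulateGenes(geneSimConfig(nGenes = 30, codonRange = c(20, 120),
                                       seed = 7))
    cen <- censusCug(sim$genes)
    dual <- translateDual(sim$genes)
    ham <- mapply(function(s, l) {
        sum(strsplit(s, "")[[1]] != strsplit(l, "")[[1]])
    }, as.character(serProteins(dual)), as.character(leuProteins(dual)))
    expect_identical(unname(as.integer(ham)), perGene(cen)$n_cug)
})

test_that("isoform counting follows both hypotheses", {
    cen <- censusCug(GeneSet(c(a = "ATGAAA", b = "ATGCTG", c = "ATGCTGCTG")))
    ic <- isoformCounts(cen)
    expect_identical(ic@unrestricted, 1 + 2 + 4)
    expect_identical(ic@restricted, 1 + 2 + 2)
    expect_identical(ic@restrictedLiteral, 1 + 2 * 3)

    empty <- isoformCounts(censusCug(GeneSet(character(0))))
    expect_identical(empty@unrestricted, 0)
    expect_identical(empty@restricted, 0)

    expect_identical(isoformCountsFromTotals(6272, 4110), 10382)
})

test_that("unrestricted count equals brute-force isoform enumeration", {
    sim <- simulateGenes(geneSimConfig(
        nGenes = 20, codonRange = c(15, 40),
        cugCounts = as.integer(c(0, 1, 2, 3, 10, rep(c(0, 1, 2, 4), 3),
                                 5, 6, 0)), seed = 21))
    cen <- censusCug(sim$genes)
    expect_identical(isoformCounts(cen)@unrestricted,
                     bruteIsoformCount(as.character(sequences(sim$genes))))
})

test_that("codonUsage counts all codons and normalizes to 1000", {
    cu <- codonUsage(GeneSet(c(g1 = "ATGCTGTAA")))
    expect_identical(nrow(cu), 64L)
    expect_identical(cu$count[cu$codon == "ATG"], 1L)
    expect_identical(cu$count[cu$codon == "CTG"], 1L)
    expect_identical(cu$count[cu$codon == "TAA"], 1L)
    expect_equal(cu$per_thousand[cu$codon == "ATG"], 1000 / 3, tolerance = 1e-9)
    expect_identical(sum(cu$count), 3L)

    sim <- simulateGenes(geneSimConfig(nGenes = 15, codonRange = c(30, 90),
                                       seed = 3))
    cu2 <- codonUsage(sim$genes)
    expect_equal(sum(cu2$per_thousand), 1000, tolerance = 0.01)

    ## scale invariance: duplicating every gene leaves frequencies unchanged
    seqs <- as.character(sequences(sim$genes))
    twice <- GeneSet(setNames(c(seqs, seqs),
                              c(names(seqs), paste0(names(seqs), "_bis"))))
    expect_equal(codonUsage(twice)$per_thousand, cu2$per_thousand,
                 tolerance = 1e-9)

    expect_error(codonUsage(GeneSet(character(0))), "non-empty")
})
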