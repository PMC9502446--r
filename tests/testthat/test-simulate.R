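test_that("simulateGenes plants exact CUG counts and positions", {
    sim <- simulateGenes(geneSimConfig(nGenes = 3, codonRange = c(40, 40),
                                       cugCounts = c(0L, 1L, 31L), seed = 2))
    cen <- censusCug(sim$genes)
    expect_identical(perGene(cen)$n_cug, c(0L, 1L, 31L))
    expect_identical(cugPositions(cen), sim$truth$positions)
    expect_identical(censusTotals(cen)[["genes_with_cug"]], 2L)

    ## all-zero config closes with the census
    sim0 <- simulateGenes(geneSimConfig(nGenes = 10, codonRange = c(10, 30),
                                        cugCounts = rep(0L, 10), seed = 3))
    expect_identical(censusTotals(censusCug(sim0$genes))[["genes_with_cug"]], 0L)

    ## planted counts exceeding available positions error
    expect_error(simulateGenes(geneSimConfig(nGenes = 1, codonRange = c(5, 5),
                                             cugCounts = 4L, seed = 1)),
                 "exceeds")
})

test_that("simulated genes are valid CDS with the requested shape", {
    cfg <- geneSimConfig(nGenes = 120, codonRange = c(50, 200), seed = 11)
    sim <- simulateGenes(cfg)
    expect_s4_class(sim$genes, "GeneSet")   # constructor enforces validity
    expect_identical(length(sim$genes), 120L)
    cen <- censusCug(sim$genes)
    expect_lte(censusTotals(cen)[["max_cug_per_gene"]], cfg$maxCug)
    expect_identical(perGene(cen)$n_cug, sim$truth$per_gene$n_cug)
    expect_identical(sim$truth$isoform_restricted,
                     isoformCounts(cen)@restricted)
    ## every simulated CDS ends with a stop and starts with ATG
    seqs <- as.character(sequences(sim$genes))
    expect_true(all(substr(seqs, 1, 3) == "ATG"))
    expect_true(all(substring(seqs, nchar(seqs) - 2) %in%
                        c("TAA", "TAG", "TGA")))
})

test_that("the same seed reproduces identical FASTA bytes", {
    cfg <- geneSimConfig(nGenes = 25, codonRange = c(20, 60), seed = 99)
    f1 <- withr::local_tempfile(fileext = ".fasta")
    f2 <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(simulateGenes(cfg)$genes, f1)
    writeFasta(simulateGenes(cfg)$genes, f2)
    expect_identical(readLines(f1), readLines(f2))
    ## and the sampled CUG distribution honours the configured zero class
    big <- simulateGenes(geneSimConfig(nGenes = 800, zeroFraction = 0.34,
                                       codonRange = c(50, 100), seed = 12))
    zfrac <- mean(big$truth$per_gene$n_cug == 0)
    expect_gt(zfrac, 0.25); expect_lt(zfrac, 0.43)
})

test_that("simulateTrnas realizes every identity-element toggle vector", {
    sim <- simulateTrnas(seed = 1)
    expect_identical(nrow(sim$truth), 8L)
    rep <- identityElementReport(sim$trnas)
    expect_identical(rep$feature_i_g33, sim$truth$feature_i_g33)
    expect_identical(rep$feature_ii_tpsic_ggg_ccc,
                     sim$truth$feature_ii_tpsic_ggg_ccc)
    expect_identical(rep$feature_iii_discriminator_g,
                     sim$truth$feature_iii_discriminator_g)

    one <- simulateTrnas(toggles = list(c(FALSE, TRUE, TRUE)), seed = 1)
    r1 <- detectIdentityElements(one$trnas[[1]])
    expect_false(r1$feature_i_g33)
    expect_true(r1$feature_ii_tpsic_ggg_ccc)
    expect_true(r1$feature_iii_discriminator_g)
})

test_that("background tRNA mutations never touch the diagnostic calls", {
    sim <- simulateTrnas(backgroundRate = 0.3, seed = 6)
    rep <- identityElementReport(sim$trnas)
    expect_identical(rep$feature_i_g33, sim$truth$feature_i_g33)
    expect_identical(rep$feature_ii_tpsic_ggg_ccc,
                     sim$truth$feature_ii_tpsic_ggg_ccc)
    expect_identical(rep$feature_iii_discriminator_g,
                     sim$truth$feature_iii_discriminator_g)
    ## with a positive rate the variants differ from the template 5' arm
    expect_false(all(substr(sim$trnas, 1, 26) ==
                         substr(unname(trnaTemplate()), 1, 26)))
})

test_that("simulateCq honours the design invariants and its seed", {
    e <- matrix(c(0, 0, 0, 2), 2, dimnames = list(c("ref", "g"), c("b", "s")))
    expect_error(simulateCq(e, referenceGene = "g"), "reference gene")
    expect_error(simulateCq(e, basalCondition = "s"), "zero planted effect")
    expect_error(simulateCq(e, replicates = 0), ">= 1")
    s1 <- simulateCq(e, noiseSd = 0.2, seed = 10)
    s2 <- simulateCq(e, noiseSd = 0.2, seed = 10)
    expect_identical(s1$table, s2$table)
    expect_identical(nrow(s1$table), 2L * 2L * 3L)
    expect_true(all(s1$table$cq > 0 & s1$table$cq < 45))
})
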