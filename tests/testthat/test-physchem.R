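pk <- loadPkaSet()
kd <- loadHydropathyScale("kyte_doolittle")

test_that("netCharge matches symmetry, limits and the group-by-group oracle", {
    ## free glycine is neutral at the mean of its two alpha pKas
    mid <- (2.34 + 9.60) / 2
    expect_lt(abs(netCharge("G", mid, pk, mode = "free_amino_acid")), 1e-9)

    set.seed(42)
    for (i in 1:10) {
        p <- randomPeptide(sample(3:40, 1))
        expect_gt(netCharge(p, 0, pk), 0)
        expect_lt(netCharge(p, 14, pk), 0)
    }

    for (p in c("DK", "ACDEFGHIKLMNPQRSTVWY", "HHHH", "EEKK"))
        for (ph in c(2, 5, 7, 9, 12))
            expect_equal(netCharge(p, ph, pk), naiveNetCharge(p, ph),
                         tolerance = 1e-12)

    expect_equal(netCharge("SXS", 7, pk), netCharge("SS", 7, pk))
    expect_error(netCharge("SZ", 7, pk), "unknown residue")
})

test_that("net charge is strictly decreasing in pH (bisection validity)", {
    set.seed(9)
    grid <- seq(0, 14, by = 0.25)
    for (i in 1:20) {
        p <- randomPeptide(sample(1:50, 1))
        q <- netCharge(p, grid, pk)
        expect_true(all(diff(q) < 0))
    }
})

test_that("computePI reproduces the free Ser/Leu anchors and is a zero of netCharge", {
    expect_identical(round(computePI("S", pk, mode = "free_amino_acid"), 2), 5.68)
    expect_identical(round(computePI("L", pk, mode = "free_amino_acid"), 2), 5.98)
    ## ionizable side chains move the free pI in the expected direction
    expect_lt(computePI("D", pk, mode = "free_amino_acid"), 4)
    expect_gt(computePI("K", pk, mode = "free_amino_acid"), 9)

    set.seed(13)
    for (i in 1:25) {
        p <- randomPeptide(sample(2:60, 1))
        pi <- computePI(p, pk)
        expect_lt(abs(netCharge(p, pi, pk)), 1e-3)
    }
})

test_that("piShift implements all three rules and vanishes without CUG", {
    for (rule in c("recompute", "paper_flat", "paper_length_weighted"))
        expect_identical(piShift(0, 100, 5, 5, rule), 0)
    expect_equal(piShift(2, 300, rule = "paper_flat"), -0.6)
    expect_equal(piShift(2, 300, rule = "paper_length_weighted"), -0.6 / 300)
    expect_equal(piShift(1, 10, piSer = 6.1, piLeu = 6.05, rule = "recompute"),
                 -0.05)
    expect_error(piShift(1, 10, rule = "recompute"), "needs")

    ## Ser and Leu side chains do not ionize, so the solver pI is
    ## decoding-invariant up to bisection tolerance
    dual <- translateDual(GeneSet(c(g = "ATGCTGGATAAACTGTGGTAA")))
    prof <- physchemProfiles(dual)
    expect_lt(abs(prof$pi_shift_recompute), 2e-4)
})

test_that("gravy follows the scale table, mean/sum modes and the X skip rule", {
    expect_identical(gravy("L", kd), 3.8)
    expect_equal(gravy("LS", kd), (3.8 - 0.8) / 2)
    expect_equal(gravy("LS", kd, mode = "sum"), 3.0)
    expect_equal(gravy("LXS", kd), (3.8 - 0.8) / 2)   # X skipped both sides
    expect_error(gravy("XX", kd), "no residues")
})

test_that("hydropathy shift obeys the closed form (hLeu-hSer)*n/L on every scale", {
    sim <- simulateGenes(geneSimConfig(nGenes = 60, codonRange = c(30, 150),
                                       seed = 17))
    dual <- translateDual(sim$genes)
    prof <- physchemProfiles(dual)
    for (nm in hydropathyScaleNames()) {
        sc <- loadHydropathyScale(nm)
        dLS <- sc@values[["L"]] - sc@values[["S"]]
        expect_equal(prof[[paste0("shift_", nm)]],
                     dLS * prof$n_cug / prof$length, tolerance = 1e-12)
    }
    ## Leu is more hydrophobic than Ser in all three scales
    expect_true(all(prof$shift_kyte_doolittle[prof$n_cug > 0] > 0))
})

test_that("shiftCensus counts planted designs and ignores input order", {
    prof <- data.frame(
        gene_id = c("a", "b", "c", "d"),
        shift_kyte_doolittle = c(0.05, 0.05, 0.001, 0),
        shift_eisenberg_consensus = c(0.4, 0.1, 0.002, 0),
        shift_eisenberg_normalized = c(-0.35, 0.4, 0.003, 0),
        stringsAsFactors = FALSE)
    sc <- shiftCensus(prof)
    expect_identical(sc$per_scale$n_any_variation, c(3L, 3L, 3L))
    expect_identical(sc$per_scale$n_high_shift, c(2L, 1L, 2L))
    expect_identical(sc$intersection, "a")   # above all three cutoffs

    shuffled <- prof[c(3, 1, 4, 2), ]
    sc2 <- shiftCensus(shuffled)
    expect_identical(sort(sc2$per_scale$n_high_shift),
                     sort(sc$per_scale$n_high_shift))
    expect_identical(sc2$intersection, "a")

    ## all-zero proteome: nothing varies
    zero <- prof
    zero[2:4] <- 0
    sc0 <- shiftCensus(zero)
    expect_true(all(sc0$per_scale$n_any_variation == 0L))
    expect_length(sc0$intersection, 0L)

    expect_error(shiftCensus(prof, thresholds = c(kyte_doolittle = 0.03)),
                 "no threshold")
})

test_that("binPI assigns closed ranges with the shared-boundary tie rule", {
    b <- binPI(c(4.5, 5.5, 6.5))
    counts <- setNames(b$count, b$name)
    expect_identical(counts[["peak_4.2-5.2"]], 1L)
    expect_identical(counts[["valley_5.3-5.9"]], 1L)
    expect_identical(counts[["peak_6-6.9"]], 1L)

    b0 <- binPI(numeric(0))
    expect_true(all(b0$count == 0L))

    ## exactly 10.1 is counted once, in the 9-10.1 peak
    b1 <- binPI(10.1)
    expect_identical(sum(b1$count), 1L)
    expect_identical(b1$count[b1$name == "peak_9-10.1"], 1L)

    bad <- data.frame(name = c("x", "y"), kind = "peak",
                      lo = c(1, 2), hi = c(3, 4))
    expect_error(binPI(5, bad), "overlapping")
})
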