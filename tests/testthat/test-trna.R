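tmpl <- unname(trnaTemplate())

test_that("annotateCloverleaf derives the canonical frame on the template", {
    ann <- annotateCloverleaf(tmpl)
    expect_identical(ann$anticodon_start, 33L)
    expect_identical(ann$pos33_index, 32L)
    expect_identical(ann$discriminator_index, 72L)  # base 5' of terminal CCA
    expect_true(ann$has_cca)
    expect_identical(ann$tpsic_start, ann$anticodon_end + 10L)
    expect_lt(ann$tpsic_end, 73L)

    ## without a terminal CCA the discriminator is the final base
    noCca <- substr(tmpl, 1, nchar(tmpl) - 3)
    ann2 <- annotateCloverleaf(noCca)
    expect_identical(ann2$discriminator_index, nchar(noCca) - 1L)
    expect_false(ann2$has_cca)

    ## midpoint rule: the central occurrence wins over an edge occurrence
    two <- paste0(strrep("A", 10), "CAG", strrep("A", 21), "CAG",
                  strrep("A", 30))
    ann3 <- annotateCloverleaf(two)
    expect_identical(ann3$anticodon_start, 34L)

    expect_error(annotateCloverleaf(paste(rep("A", 76), collapse = "")),
                 "not found")
    edgeOnly <- paste0("CAG", strrep("A", 73))
    expect_error(annotateCloverleaf(edgeOnly), "acceptor-proximal")
})

test_that("detectIdentityElements calls the three features and single toggles", {
    rep0 <- detectIdentityElements(tmpl)
    expect_true(rep0$feature_i_g33)
    expect_true(rep0$feature_ii_tpsic_ggg_ccc)
    expect_true(rep0$feature_iii_discriminator_g)
    expect_identical(rep0$pos33_1based, 33L)
    expect_identical(rep0$discriminator_1based, 73L)

    mut <- function(s, i, ch) { substr(s, i, i) <- ch; s }
    m1 <- detectIdentityElements(mut(unname(tmpl), 33, "T"))
    expect_false(m1$feature_i_g33)
    expect_true(m1$feature_ii_tpsic_ggg_ccc)
    expect_true(m1$feature_iii_discriminator_g)

    m3 <- detectIdentityElements(mut(unname(tmpl), 73, "A"))
    expect_true(m3$feature_i_g33)
    expect_true(m3$feature_ii_tpsic_ggg_ccc)
    expect_false(m3$feature_iii_discriminator_g)
})

test_that("identity-element detection is invariant to U/T representation", {
    asRna <- chartr("T", "U", unname(tmpl))
    expect_identical(detectIdentityElements(asRna),
                     detectIdentityElements(unname(tmpl)))
})

test_that("distanceMatrix is 1 - identity under both conventions", {
    s <- c(x = strrep("ACGT", 15), y = strrep("ACGT", 15), z = strrep("ACGT", 15))
    d <- distanceMatrix(s)
    expect_true(all(d == 0))

    ## 2 mismatches over 50 aligned columns -> d = 0.04
    a <- strrep("A", 50)
    b <- paste0(strrep("A", 48), "CC")
    dm <- distanceMatrix(c(a = a, b = b, c = a), source = "supplied_msa")
    expect_equal(dm["a", "b"], 0.04)
    expect_equal(dm["a", "c"], 0)

    set.seed(19)
    seqs <- setNames(vapply(1:4, function(i)
        paste(sample(c("A", "C", "G", "T"), 60, TRUE), collapse = ""),
        character(1)), letters[1:4])
    d2 <- distanceMatrix(seqs)
    expect_identical(d2, t(d2))
    expect_true(all(diag(d2) == 0))
    expect_true(all(d2 >= 0 & d2 <= 1))

    expect_error(distanceMatrix(seqs[1:2]), "at least 3")
    expect_error(distanceMatrix(c(a = "AC-", b = "ACGT", c = "ACGT"),
                                source = "supplied_msa"), "equal-length")
})

test_that("MSA distances ignore columns gapped in both members", {
    msa <- c(a = "AC--GT", b = "AC--GA", c = "ACTTGT")
    d <- distanceMatrix(msa, source = "supplied_msa")
    expect_equal(d["a", "b"], 1 - 3 / 4)   # both-gap columns dropped
    expect_equal(d["a", "c"], 1 - 4 / 6)   # single gaps count as mismatch
})
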