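test_that("readFasta parses, normalizes U/T and reports duplicate ids", {
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">g1 some desc", "ATGCTG", "TAA"), fa)
    x <- readFasta(fa, "dna")
    expect_identical(as.character(x), c(g1 = "ATGCTGTAA"))

    writeLines(c(">r1", "GCUUCAGUU"), fa)
    r <- readFasta(fa, "rna")
    expect_identical(as.character(r), c(r1 = "GCTTCAGTT"))
    expect_identical(attr(r, "origForm"), "rna")

    writeLines(c(">g1", "ATG", ">g1", "TTT"), fa)
    expect_error(readFasta(fa, "dna"), "g1")

    writeLines(c(">g1", "ATGQ"), fa)
    expect_error(readFasta(fa, "dna"), "position 4")

    expect_error(readFasta(file.path(tempdir(), "absent.fa"), "dna"), "not found")
    file.create(fa)
    expect_error(readFasta(fa, "dna"))
})

test_that("FASTA round trip is identity on normalized records", {
    set.seed(11)
    seqs <- vapply(1:5, function(i)
        paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = ""),
        character(1))
    names(seqs) <- paste0("s", 1:5)
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(Biostrings::DNAStringSet(seqs), fa)
    back <- readFasta(fa, "dna")
    expect_identical(as.character(back), seqs)
    ## RNA-origin records round-trip in RNA form
    fa2 <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">r1", "GCUUCAGUU"), fa2)
    r <- readFasta(fa2, "rna")
    fa3 <- withr::local_tempfile(fileext = ".fasta")
    writeFasta(r, fa3)
    expect_identical(as.character(readFasta(fa3, "rna")), c(r1 = "GCTTCAGTT"))
    expect_match(readLines(fa3)[2], "U")
})

test_that("validateCds enforces the CDS invariants per policy", {
    expect_identical(as.character(sequences(validateCds(c(g1 = "ATGCTGTAA")))),
                     c(g1 = "ATGCTGTAA"))
    expect_error(validateCds(c(g1 = "ATGCT")), "multiple of 3")
    co <- validateCds(c(g1 = "ATGCT"), policy = "coerce")
    expect_identical(as.character(sequences(co)), c(g1 = "ATG"))
    for (pol in c("strict", "skip", "coerce")) {
        if (pol == "strict") {
            expect_error(validateCds(c(g1 = "ATGTAACTG"), policy = pol),
                         "internal stop")
        } else {
            suppressMessages(gs <- validateCds(c(g1 = "ATGTAACTG"), policy = pol))
            expect_identical(length(gs), 0L)
            expect_identical(attr(gs, "rejected")$reason, "internal stop codon")
        }
    }
    expect_error(validateCds(c(g1 = "")), "empty")
    ## non-ATG starts are accepted (annotation exports vary)
    expect_silent(validateCds(c(g1 = "TTGAAATAA")))
})

test_that("coerce policy always yields lengths divisible by 3", {
    set.seed(4)
    for (i in 1:25) {
        n <- sample(1:30, 1)
        s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
        gs <- tryCatch(suppressMessages(
            validateCds(setNames(s, "g"), policy = "coerce")),
            error = function(e) NULL)
        if (!is.null(gs) && length(gs) > 0)
            expect_identical(Biostrings::width(sequences(gs)) %% 3L, 0L)
    }
})

test_that("TSV writers are deterministic and render declared decimals", {
    gs <- GeneSet(c(a = "ATGCTGTAA", b = "ATGAAA", c = "ATGCTGCTG"))
    cen <- censusCug(gs)
    f1 <- withr::local_tempfile(fileext = ".tsv")
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeCensusTsv(cen, f1)
    writeCensusTsv(cen, f2)
    expect_identical(readLines(f1), readLines(f2))
    lines <- readLines(f1)
    expect_match(lines[grepl("^#", lines)][2], "decimals=")
    expect_identical(sum(!grepl("^#", lines)) - 1L, 3L)  # header + 3 data rows
    ## empty result set -> header-only file
    f3 <- withr::local_tempfile(fileext = ".tsv")
    writeCensusTsv(censusCug(GeneSet(character(0))), f3)
    body <- readLines(f3)
    expect_identical(sum(!grepl("^#", body)), 1L)
})
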