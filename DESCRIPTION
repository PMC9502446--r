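Package: cugDecode
Title: Dual Serine/Leucine Decoding of CUG Codons in CTG-Ser1 Clade Yeasts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying the ambiguous decoding of the CUG codon in
    CTG-Ser1 clade yeasts such as Debaryomyces hansenii and Candida albicans.
    Provides CUG codon censusing over coding-sequence sets, dual restricted
    translation (all-serine and all-leucine proteomes), isoform-count
    hypotheses (2^n unrestricted and per-gene restricted counting),
    codon-usage tables, proteome-wide isoelectric-point and hydropathy shift
    censuses under multiple hydropathy scales, tRNA_CAG identity-element
    detection on a simplified cloverleaf frame, pairwise global alignment and
    neighbor-joining distance trees, log2 delta-delta-Cq expression fold
    changes, and a synthetic-data generator with planted ground truth so the
    whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    ape,
    jsonlite,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
biocViews: Sequencing, Alignment, Phylogenetics, GeneExpression, Proteomics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
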