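## Synthetic-data generators.  Every generator takes an explicit seed, emits
## its planted ground truth alongside the data, and is closed with the
## pipeline stage that consumes it (census/detector/fold-change recover the
## truth at zero noise).

.SENSE_NON_CTG <- {
    gc <- Biostrings::GENETIC_CODE
    sort(setdiff(names(gc)[gc != "*"], "CTG"))
}

#' Configuration for the coding-sequence simulator
#'
#' The defaults emulate the published shape of the D. hansenii CUG census: a
#' ~34\% CUG-free class, carriers following a geometric tail with mode 1,
#' and a hard maximum of 31 CUG codons per gene.  Gene lengths are uniform
#' over a codon-count range and background codons are drawn from the 60
#' non-CTG sense codons with a GC-content bias.
#'
#' @param nGenes Number of genes to simulate.
#' @param codonRange Length range in codons, stop included.
#' @param zeroFraction Probability a gene carries no CUG.
#' @param geomProb Success probability of the (1-shifted) geometric carrier
#'   distribution: P(n) proportional to geomProb (1-geomProb)^(n-1), n >= 1.
#' @param maxCug Hard maximum CUG count per gene.
#' @param gc GC content used to weight background codons.
#' @param cugCounts Optional integer vector (length \code{nGenes}) of exact
#'   planted CUG counts, overriding the distribution.
#' @param seed Integer seed fixing all draws.
#' @return List of class \code{"geneSimConfig"}.
#' @export
geneSimConfig <- function(nGenes = 500L, codonRange = c(100L, 600L),
                          zeroFraction = 0.34, geomProb = 0.34, maxCug = 31L,
                          gc = 0.36, cugCounts = NULL, seed = 1L) {
    stopifnot(zeroFraction >= 0, zeroFraction <= 1,
              geomProb > 0, geomProb <= 1, maxCug >= 0L,
              gc > 0, gc < 1, codonRange[1L] >= 3L,
              codonRange[2L] >= codonRange[1L])
    if (!is.null(cugCounts)) stopifnot(length(cugCounts) == nGenes)
    structure(list(nGenes = as.integer(nGenes),
                   codonRange = as.integer(codonRange),
                   zeroFraction = zeroFraction, geomProb = geomProb,
                   maxCug = as.integer(maxCug), gc = gc,
                   cugCounts = cugCounts, seed = as.integer(seed)),
              class = "geneSimConfig")
}

#' Simulate coding sequences with planted CUG counts
#'
#' Builds each gene codon by codon: the first codon is ATG, the final codon
#' a stop, exactly the planted number of CTG codons is placed at uniformly
#' drawn codon positions (never the first codon or the stop), and remaining
#' codons are drawn from the 60 non-CTG sense codons weighted by the
#' requested GC content.  Same seed, same bytes.
#'
#' @param cfg A \code{\link{geneSimConfig}}.
#' @return List: \code{genes} (a \code{\link[=GeneSet-class]{GeneSet}}) and
#'   \code{truth} (class \code{"simTruth"}): per-gene planted \code{n_cug}
#'   and 0-based codon \code{positions}, plus the implied isoform counts.
#' @export
simulateGenes <- function(cfg = geneSimConfig()) {
    stopifnot(inherits(cfg, "geneSimConfig"))
    .withSeed(cfg$seed, {
        nG <- cfg$nGenes
        lens <- if (cfg$codonRange[1L] == cfg$codonRange[2L])
            rep(cfg$codonRange[1L], nG)
        else sample(cfg$codonRange[1L]:cfg$codonRange[2L], nG, replace = TRUE)
        avail <- lens - 2L   # codon slots excluding first codon and final stop
        counts <- cfg$cugCounts
        if (is.null(counts)) {
            carrier <- runif(nG) >= cfg$zeroFraction
            counts <- integer(nG)
            tail <- 1L + rgeom(sum(carrier), cfg$geomProb)
            counts[carrier] <- pmin(tail, cfg$maxCug)
            counts <- pmin(counts, avail)   # short genes cap their own tail
        }
        counts <- as.integer(counts)
        if (any(counts > avail))
            stop("planted n_cug exceeds available codon positions for gene(s): ",
                 paste(which(counts > avail), collapse = ", "))
        gcw <- vapply(.SENSE_NON_CTG, function(cod) {
            g <- sum(strsplit(cod, "")[[1L]] %in% c("G", "C"))
            cfg$gc ^ g * (1 - cfg$gc) ^ (3 - g)
        }, numeric(1L))
        ids <- sprintf("simgene_%04d", seq_len(nG))
        seqs <- character(nG)
        pos <- vector("list", nG)
        for (i in seq_len(nG)) {
            L <- lens[i]
            cod <- sample(.SENSE_NON_CTG, L, replace = TRUE, prob = gcw)
            cod[1L] <- "ATG"
            cod[L] <- sample(.STOPS, 1L)
            slots <- seq.int(2L, L - 1L)
            p <- sort(slots[sample.int(length(slots), counts[i])])
            cod[p] <- "CTG"
            pos[[i]] <- p - 1L   # 0-based codon indices
            seqs[i] <- paste(cod, collapse = "")
        }
        names(pos) <- ids
        truth <- structure(list(
            per_gene = data.frame(gene_id = ids, n_cug = counts,
                                  stringsAsFactors = FALSE),
            positions = pos,
            isoform_unrestricted = sum(2 ^ counts),
            isoform_restricted = sum(counts == 0L) + 2 * sum(counts > 0L),
            seed = cfg$seed), class = "simTruth")
        list(genes = GeneSet(setNames(seqs, ids)), truth = truth)
    })
}

.DIAG_FEATURES <- c("i_g33", "ii_tpsic", "iii_discriminator")

#' Simulate tRNA variants with toggled identity elements
#'
#' Starting from a template that carries all three identity elements,
#' produces one variant per requested toggle vector by minimal mutation:
#' feature (i) off = pos33 G -> T; feature (ii) off = the middle base of the
#' GGG motif in the TpsiC window -> A; feature (iii) off = discriminator
#' G -> A.  Optional background mutations are applied at a per-site rate in
#' the D-arm region (5' of the anticodon loop), away from all diagnostic
#' sites.  \code{\link{detectIdentityElements}} recovers each planted vector
#' exactly.
#'
#' @param toggles Logical matrix (variants x 3) or list of length-3 logical
#'   vectors; \code{TRUE} = feature present.  Default: all 8 combinations.
#' @param template tRNA template sequence carrying all three features
#'   (default \code{\link{trnaTemplate}}).
#' @param backgroundRate Per-site background mutation rate in the D-arm
#'   region (default 0).
#' @param seed Integer seed (only background mutations draw from it).
#' @param anticodon Anticodon triplet.
#' @return List: \code{trnas} (named character vector) and \code{truth}
#'   (data.frame id + the three planted feature columns).
#' @export
simulateTrnas <- function(toggles = NULL, template = trnaTemplate(),
                          backgroundRate = 0, seed = 1L, anticodon = "CAG") {
    if (is.null(toggles))
        toggles <- as.matrix(expand.grid(i = c(TRUE, FALSE), ii = c(TRUE, FALSE),
                                         iii = c(TRUE, FALSE)))
    if (is.list(toggles)) toggles <- do.call(rbind, toggles)
    toggles <- matrix(as.logical(toggles), ncol = 3L)
    seq <- .normalizeNuc(as.character(template)[1L])
    ann <- annotateCloverleaf(seq, anticodon)
    base <- detectIdentityElements(seq, ann)
    if (!all(base$feature_i_g33, base$feature_ii_tpsic_ggg_ccc,
             base$feature_iii_discriminator_g))
        stop("template must carry all three identity elements")
    window <- substr(seq, ann$tpsic_start + 1L, ann$tpsic_end)
    gggAt <- as.integer(regexpr("GGG", window, fixed = TRUE)) - 1L + ann$tpsic_start
    diag0 <- c(ann$pos33_index, ann$anticodon_start:(ann$anticodon_end - 1L),
               gggAt:(gggAt + 2L), ann$discriminator_index)
    .withSeed(seed, {
        out <- character(nrow(toggles))
        for (v in seq_len(nrow(toggles))) {
            ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
            if (!toggles[v, 1L]) ch[ann$pos33_index + 1L] <- "T"
            if (!toggles[v, 2L]) ch[gggAt + 2L] <- "A"   # middle base of GGG
            if (!toggles[v, 3L]) ch[ann$discriminator_index + 1L] <- "A"
            if (backgroundRate > 0) {
                region <- setdiff(seq.int(0L, ann$pos33_index - 2L), diag0)
                hit <- region[runif(length(region)) < backgroundRate]
                for (s in hit)
                    ch[s + 1L] <- sample(setdiff(c("A", "C", "G", "T"), ch[s + 1L]), 1L)
            }
            out[v] <- paste(ch, collapse = "")
        }
        ids <- sprintf("simtrna_%s", apply(toggles, 1L, function(t)
            paste(ifelse(t, "1", "0"), collapse = "")))
        truth <- data.frame(id = ids,
                            feature_i_g33 = toggles[, 1L],
                            feature_ii_tpsic_ggg_ccc = toggles[, 2L],
                            feature_iii_discriminator_g = toggles[, 3L],
                            stringsAsFactors = FALSE)
        list(trnas = setNames(out, ids), truth = truth)
    })
}

#' Simulate a replicate Cq table with planted fold changes
#'
#' Emulates the RT-qPCR design: a stably expressed reference gene, a
#' no-stress basal condition and replicate measurements (default
#' triplicates).  \code{Cq(g,c,r) = base(g) - effect(g,c) + N(0, noiseSd)},
#' so \code{\link{ddcqLog2fc}} recovers \code{effect} exactly at zero noise.
#' The reference gene's effect is 0 everywhere, as is every gene's effect in
#' the basal condition.
#'
#' @param effects Numeric matrix of planted log2 fold changes, genes x
#'   conditions (dimnames required).  Reference-gene row and basal-condition
#'   column must be all zero.
#' @param referenceGene,basalCondition Ids; defaults: first row, first
#'   column of \code{effects}.
#' @param noiseSd Gaussian noise SD in cycles.
#' @param replicates Replicates per (gene, condition); >= 1.
#' @param phase Growth-phase label for the table.
#' @param seed Integer seed.
#' @return List: \code{table} (Cq data.frame: gene, condition, phase,
#'   replicate, cq) and \code{truth} (the effects matrix plus design
#'   parameters).
#' @export
simulateCq <- function(effects, referenceGene = rownames(effects)[1L],
                       basalCondition = colnames(effects)[1L],
                       noiseSd = 0.2, replicates = 3L,
                       phase = "logarithmic", seed = 1L) {
    stopifnot(is.matrix(effects), !is.null(rownames(effects)),
              !is.null(colnames(effects)))
    if (replicates < 1L) stop("replicates must be >= 1")
    if (any(effects[referenceGene, ] != 0))
        stop("reference gene must have zero planted effect in every condition")
    if (any(effects[, basalCondition] != 0))
        stop("every gene must have zero planted effect in the basal condition")
    genes <- rownames(effects); conds <- colnames(effects)
    .withSeed(seed, {
        baseCq <- setNames(runif(length(genes), 18, 30), genes)
        rows <- expand.grid(replicate = seq_len(replicates), condition = conds,
                            gene = genes, stringsAsFactors = FALSE)[, 3:1]
        cq <- baseCq[rows$gene] - effects[cbind(rows$gene, rows$condition)] +
            rnorm(nrow(rows), 0, noiseSd)
        tab <- data.frame(gene = rows$gene, condition = rows$condition,
                          phase = phase, replicate = rows$replicate,
                          cq = unname(cq), stringsAsFactors = FALSE)
        truth <- structure(list(effects = effects, base_cq = baseCq,
                                reference_gene = referenceGene,
                                basal_condition = basalCondition,
                                noise_sd = noiseSd, replicates = replicates,
                                seed = seed), class = "simTruth")
        list(table = tab, truth = truth)
    })
}

#' Write a simulation truth object as JSON
#'
#' @param truth A \code{simTruth} (or the truth data.frame from
#'   \code{\link{simulateTrnas}}).
#' @param path Output JSON path.
#' @return \code{path}, invisibly.
#' @export
writeSimTruthJson <- function(truth, path) {
    jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}
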