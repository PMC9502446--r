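#' Build a run configuration
#'
#' A declarative configuration for \code{\link{runAll}}.  Provide at least
#' one input (or a simulate block); absent branches are skipped.  Can also
#' be read from a YAML file with the same field names via
#' \code{\link{readRunConfig}}.
#'
#' @param cdsFasta Path to a CDS FASTA (nucleotide, one record per gene).
#' @param trnaFasta Path to a tRNA gene FASTA (unaligned; pairwise route).
#' @param trnaMsa Path to an externally produced tRNA MSA FASTA.
#' @param cqTsv Path to a Cq TSV (gene, condition, phase, replicate, cq).
#' @param referenceGene,basalCondition Expression-branch identifiers.
#' @param simulateGenesCfg Optional \code{\link{geneSimConfig}} used when
#'   \code{cdsFasta} is absent.
#' @param pkaSet pKa set name or path (see \code{\link{loadPkaSet}}).
#' @param scales Character vector of hydropathy scale names/paths.
#' @param thresholds Named high-shift cutoffs per scale.
#' @param piShiftRule Default pI shift rule to highlight in reports.
#' @param gravyMode \code{"mean"} or \code{"sum"}.
#' @param cdsPolicy CDS validation policy (\code{\link{validateCds}}).
#' @param alignScores Named numeric: match, mismatch, gap.
#' @param treeSource \code{"pairwise_nw"} or \code{"supplied_msa"}.
#' @param anticodon Anticodon triplet for the tRNA branch.
#' @param outDir Output directory (created if needed).
#' @param seed Seed for simulate mode.
#' @return List of class \code{"runConfig"}.
#' @export
runConfig <- function(cdsFasta = NULL, trnaFasta = NULL, trnaMsa = NULL,
                      cqTsv = NULL, referenceGene = NULL, basalCondition = NULL,
                      simulateGenesCfg = NULL,
                      pkaSet = "default",
                      scales = hydropathyScaleNames(),
                      thresholds = c(kyte_doolittle = 0.03,
                                     eisenberg_consensus = 0.3,
                                     eisenberg_normalized = 0.3),
                      piShiftRule = "paper_length_weighted",
                      gravyMode = "mean", cdsPolicy = "strict",
                      alignScores = c(match = 1, mismatch = -1, gap = -2),
                      treeSource = "pairwise_nw", anticodon = "CAG",
                      outDir = tempfile("cugdecode_run_"), seed = 1L) {
    cfg <- structure(as.list(environment()), class = "runConfig")
    validateRunConfig(cfg)
    cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   \code{\link{runConfig}}.
#' @return A validated \code{runConfig}.
#' @export
readRunConfig <- function(path) {
    y <- yaml::read_yaml(path)
    known <- names(formals(runConfig))
    unknown <- setdiff(names(y), known)
    if (length(unknown))
        stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    if (!is.null(y$thresholds)) y$thresholds <- unlist(y$thresholds)
    if (!is.null(y$alignScores)) y$alignScores <- unlist(y$alignScores)
    if (!is.null(y$simulateGenesCfg))
        y$simulateGenesCfg <- do.call(geneSimConfig, y$simulateGenesCfg)
    do.call(runConfig, y)
}

#' Validate a run configuration (fail fast)
#'
#' Checks that at least one branch has input, that every referenced file
#' exists and that every named pKa set and hydropathy scale resolves --
#' before any stage runs.
#'
#' @param cfg A \code{runConfig}.
#' @return \code{cfg}, invisibly; errors otherwise.
#' @export
validateRunConfig <- function(cfg) {
    hasCds <- !is.null(cfg$cdsFasta) || !is.null(cfg$simulateGenesCfg)
    hasTrna <- !is.null(cfg$trnaFasta) || !is.null(cfg$trnaMsa)
    hasCq <- !is.null(cfg$cqTsv)
    if (!hasCds && !hasTrna && !hasCq)
        stop("config names no inputs and no simulate block")
    for (p in c(cfg$cdsFasta, cfg$trnaFasta, cfg$trnaMsa, cfg$cqTsv))
        if (!file.exists(p)) stop("input file not found: ", p)
    loadPkaSet(cfg$pkaSet)
    for (s in cfg$scales) loadHydropathyScale(s)
    missing <- setdiff(cfg$scales[!file.exists(cfg$scales)], names(cfg$thresholds))
    missing <- c(missing, setdiff(basename(cfg$scales[file.exists(cfg$scales)]),
                                  names(cfg$thresholds)))
    if (hasCds && length(missing))
        stop("no high-shift threshold for scale(s): ",
             paste(missing, collapse = ", "))
    if (hasCq && (is.null(cfg$referenceGene) || is.null(cfg$basalCondition)))
        stop("expression branch needs referenceGene and basalCondition")
    invisible(cfg)
}

#' Run the whole analysis pipeline
#'
#' Executes the stages in dependency order -- CDS branch (census, dual
#' proteomes, isoform counts, codon usage, physchem profiles, shift census,
#' pI bins), tRNA branch (identity-element report, distance matrix, NJ
#' tree) and expression branch (log2 ddCq matrix) -- skipping branches
#' whose input is absent.  A stage error aborts its branch, is recorded in
#' the manifest, and leaves the other branches' outputs intact.  Identical
#' config and inputs reproduce identical outputs (timestamps excluded).
#'
#' @param cfg A \code{\link{runConfig}} or path to a YAML config file.
#' @return The run manifest (list), invisibly; also written as
#'   \code{manifest.json} in the output directory alongside all stage TSVs.
#' @export
runAll <- function(cfg) {
    if (is.character(cfg)) cfg <- readRunConfig(cfg)
    validateRunConfig(cfg)
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    logFile <- file.path(cfg$outDir, "run.log")
    logLine <- function(...) {
        msg <- sprintf(...)
        message(msg)
        cat(msg, "\n", file = logFile, append = TRUE)
    }
    manifest <- list(
        package_version = as.character(utils::packageVersion("cugDecode")),
        started = format(Sys.time(), usetz = TRUE),
        config = lapply(cfg, function(x)
            if (inherits(x, "geneSimConfig")) unclass(x) else x),
        input_checksums = local({
            paths <- c(cds = cfg$cdsFasta, trna = cfg$trnaFasta,
                       msa = cfg$trnaMsa, cq = cfg$cqTsv)
            if (length(paths)) as.list(tools::md5sum(unlist(paths))) else list()
        }),
        stages = list())
    stage <- function(name, fun) {
        res <- tryCatch(list(status = "ok", rows = fun()),
                        error = function(e) list(status = "error",
                                                 message = conditionMessage(e)))
        manifest$stages[[name]] <<- res
        logLine("stage %-16s %s%s", name, res$status,
                if (res$status == "ok" && !is.null(res$rows))
                    sprintf(" (%d rows)", res$rows) else "")
        res$status == "ok"
    }
    out <- function(f) file.path(cfg$outDir, f)

    ## --- CDS branch -------------------------------------------------------
    genes <- NULL
    if (!is.null(cfg$cdsFasta)) {
        stage("read_cds", function() {
            genes <<- validateCds(readFasta(cfg$cdsFasta, "dna"),
                                  policy = cfg$cdsPolicy)
            length(genes)
        })
    } else if (!is.null(cfg$simulateGenesCfg)) {
        stage("simulate_genes", function() {
            sim <- simulateGenes(cfg$simulateGenesCfg)
            genes <<- sim$genes
            writeFasta(sim$genes, out("simulated_genes.fasta"))
            writeSimTruthJson(sim$truth, out("simulated_genes_truth.json"))
            length(genes)
        })
    }
    if (!is.null(genes)) {
        census <- NULL; dual <- NULL; profiles <- NULL
        ok <- stage("census", function() {
            census <<- censusCug(genes)
            writeCensusTsv(census, out("census.tsv"))
            census@genesTotal
        })
        ok <- ok && stage("isoform_counts", function() {
            writeIsoformCountsTsv(isoformCounts(census), out("isoform_counts.tsv"))
            1L
        })
        ok <- ok && stage("codon_usage", function() {
            writeCodonUsageTsv(codonUsage(genes), out("codon_usage.tsv"))
            64L
        })
        ok <- ok && stage("dual_translate", function() {
            dual <<- translateDual(genes)
            length(dual)
        })
        ok <- ok && stage("physchem", function() {
            scales <- setNames(lapply(cfg$scales, loadHydropathyScale),
                               vapply(cfg$scales, function(s)
                                   if (file.exists(s)) basename(s) else s, ""))
            profiles <<- physchemProfiles(dual, loadPkaSet(cfg$pkaSet),
                                          scales, gravyMode = cfg$gravyMode)
            writeProfilesTsv(profiles, out("physchem_profiles.tsv"))
            nrow(profiles)
        })
        ok && stage("shift_census", function() {
            sc <- shiftCensus(profiles, cfg$thresholds)
            writeShiftCensusJson(sc, out("shift_census.json"))
            bins <- binPI(profiles$pi_ser)
            writePiBinsTsv(bins, out("pi_bins.tsv"))
            nrow(sc$per_scale)
        })
    }

    ## --- tRNA branch ------------------------------------------------------
    if (!is.null(cfg$trnaFasta) || !is.null(cfg$trnaMsa)) {
        trnas <- NULL
        msa <- !is.null(cfg$trnaMsa)
        ok <- stage("read_trna", function() {
            fa <- readFasta(if (msa) cfg$trnaMsa else cfg$trnaFasta, "rna")
            trnas <<- setNames(as.character(fa), names(fa))
            length(trnas)
        })
        ok <- ok && stage("identity_elements", function() {
            rep <- identityElementReport(gsub("-", "", trnas, fixed = TRUE),
                                         anticodon = cfg$anticodon)
            .writeTsv(rep, out("trna_identity_elements.tsv"),
                      comments = "tRNA identity-element report; indices 1-based")
            nrow(rep)
        })
        ok && stage("tree", function() {
            d <- distanceMatrix(trnas,
                                source = if (msa) "supplied_msa" else cfg$treeSource,
                                match = cfg$alignScores[["match"]],
                                mismatch = cfg$alignScores[["mismatch"]],
                                gap = cfg$alignScores[["gap"]])
            .writeTsv(cbind(data.frame(id = rownames(d)), as.data.frame(d)),
                      out("trna_distances.tsv"),
                      comments = "1 - pairwise identity")
            writeNewick(neighborJoining(d), out("tree.nwk"))
            nrow(d)
        })
    }

    ## --- expression branch ------------------------------------------------
    if (!is.null(cfg$cqTsv)) {
        stage("expression", function() {
            fcm <- ddcqLog2fc(readCqTable(cfg$cqTsv),
                              cfg$referenceGene, cfg$basalCondition)
            writeFoldChangeTsv(fcm, out("expression_log2fc.tsv"),
                               longPath = out("expression_long.tsv"))
            nrow(foldChanges(fcm))
        })
    }

    manifest$finished <- format(Sys.time(), usetz = TRUE)
    jsonlite::write_json(manifest, file.path(cfg$outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
    invisible(manifest)
}
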