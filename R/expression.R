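#' Read a Cq table
#'
#' Reads a TSV with columns \code{gene}, \code{condition}, \code{phase},
#' \code{replicate}, \code{cq} and validates that every Cq is finite and in
#' (0, 45) cycles.
#'
#' @param path TSV path (\code{#} comment lines allowed).
#' @return data.frame with the five columns.
#' @export
readCqTable <- function(path) {
    tb <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("gene", "condition", "phase", "replicate", "cq")
    missing <- setdiff(need, names(tb))
    if (length(missing))
        stop("Cq table lacks column(s): ", paste(missing, collapse = ", "))
    .checkCq(tb)
    tb[need]
}

.checkCq <- function(tb) {
    if (any(!is.finite(tb$cq)))
        stop("non-finite Cq value(s)")
    if (any(tb$cq <= 0 | tb$cq >= 45))
        stop("Cq values must lie in (0, 45) cycles")
    invisible(tb)
}

#' Log2 delta-delta-Cq fold changes (Livak)
#'
#' Replicates are averaged on the Cq scale, then within each growth phase:
#' \deqn{\Delta Cq(g,c) = \bar{Cq}(g,c) - \bar{Cq}(ref,c)}
#' \deqn{\Delta\Delta Cq(g,c) = \Delta Cq(g,c) - \Delta Cq(g,basal)}
#' \deqn{log2FC(g,c) = -\Delta\Delta Cq(g,c)}
#' so one cycle earlier than expected means a two-fold higher transcript
#' abundance.  Adding a constant to every Cq of one condition leaves all
#' fold changes unchanged.
#'
#' @param table Cq data.frame as from \code{\link{readCqTable}} or
#'   \code{\link{simulateCq}}.
#' @param referenceGene Stably expressed reference gene id (e.g. DhRPS3);
#'   must be present in every condition and phase.
#' @param basalCondition No-stress basal condition id; must be present for
#'   every gene and phase.
#' @return A \code{\link[=FoldChangeMatrix-class]{FoldChangeMatrix}}.
#' @export
ddcqLog2fc <- function(table, referenceGene, basalCondition) {
    .checkCq(table)
    if (!referenceGene %in% table$gene)
        stop("reference gene not in table: ", referenceGene)
    if (!basalCondition %in% table$condition)
        stop("basal condition not in table: ", basalCondition)
    if (!"phase" %in% names(table)) table$phase <- "single"
    geneOrder <- unique(table$gene)
    condOrder <- unique(table$condition)
    agg <- aggregate(cq ~ gene + condition + phase, table,
                     function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
    lg <- data.frame(gene = agg$gene, condition = agg$condition,
                     phase = agg$phase,
                     n_reps = as.integer(agg$cq[, "n"]),
                     mean_cq = agg$cq[, "mean"], sd_cq = agg$cq[, "sd"],
                     stringsAsFactors = FALSE)
    lg <- lg[order(match(lg$phase, unique(table$phase)),
                   match(lg$gene, geneOrder),
                   match(lg$condition, condOrder)), ]
    rownames(lg) <- NULL
    lg$dcq <- NA_real_; lg$ddcq <- NA_real_
    for (ph in unique(lg$phase)) {
        sel <- lg$phase == ph
        sub <- lg[sel, ]
        refCq <- setNames(sub$mean_cq[sub$gene == referenceGene],
                          sub$condition[sub$gene == referenceGene])
        if (!all(unique(sub$condition) %in% names(refCq)))
            stop("reference gene missing in phase '", ph, "' for condition(s): ",
                 paste(setdiff(unique(sub$condition), names(refCq)), collapse = ", "))
        dcq <- sub$mean_cq - refCq[sub$condition]
        basal <- setNames(dcq[sub$condition == basalCondition],
                          sub$gene[sub$condition == basalCondition])
        if (!all(unique(sub$gene) %in% names(basal)))
            stop("basal condition missing in phase '", ph, "' for gene(s): ",
                 paste(setdiff(unique(sub$gene), names(basal)), collapse = ", "))
        lg$dcq[sel] <- unname(dcq)
        lg$ddcq[sel] <- unname(dcq - basal[sub$gene])
    }
    lg$log2fc <- -lg$ddcq
    new("FoldChangeMatrix", long = lg,
        referenceGene = referenceGene, basalCondition = basalCondition)
}

#' @describeIn FoldChangeMatrix-class the long-format table
#' @param x,object A FoldChangeMatrix.
#' @export
setGeneric("foldChanges", function(x) standardGeneric("foldChanges"))
#' @rdname FoldChangeMatrix-class
#' @export
setMethod("foldChanges", "FoldChangeMatrix", function(x) x@long)

#' @describeIn FoldChangeMatrix-class genes x conditions log2FC matrix for one phase
#' @param phase Growth phase to extract (default: first in the table).
#' @export
setGeneric("fcMatrix", function(x, phase = NULL) standardGeneric("fcMatrix"))
#' @rdname FoldChangeMatrix-class
#' @export
setMethod("fcMatrix", "FoldChangeMatrix", function(x, phase = NULL) {
    lg <- x@long
    if (is.null(phase)) phase <- lg$phase[1L]
    lg <- lg[lg$phase == phase, ]
    genes <- unique(lg$gene); conds <- unique(lg$condition)
    m <- matrix(NA_real_, length(genes), length(conds),
                dimnames = list(genes, conds))
    m[cbind(match(lg$gene, genes), match(lg$condition, conds))] <- lg$log2fc
    m
})

setMethod("show", "FoldChangeMatrix", function(object) {
    lg <- object@long
    cat(sprintf("FoldChangeMatrix: %d gene(s) x %d condition(s) x %d phase(s)\n",
                length(unique(lg$gene)), length(unique(lg$condition)),
                length(unique(lg$phase))))
    cat(sprintf("  reference gene %s; basal condition %s\n",
                object@referenceGene, object@basalCondition))
})

#' Write fold-change outputs
#'
#' Writes the genes-by-conditions log2FC matrix per phase plus (optionally)
#' the long-format audit table with replicate means and SDs.
#'
#' @param fcm A \code{FoldChangeMatrix}.
#' @param path Output TSV path for the matrix.
#' @param longPath Optional path for the long-format table.
#' @return \code{path}, invisibly.
#' @export
writeFoldChangeTsv <- function(fcm, path, longPath = NULL) {
    lg <- foldChanges(fcm)
    wide <- do.call(rbind, lapply(unique(lg$phase), function(ph) {
        m <- fcMatrix(fcm, ph)
        data.frame(phase = ph, gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
    }))
    .writeTsv(wide, path,
              comments = sprintf("log2 ddCq fold change; reference=%s basal=%s",
                                 fcm@referenceGene, fcm@basalCondition))
    if (!is.null(longPath))
        .writeTsv(lg, longPath, comments = "long-format ddCq audit table")
    invisible(path)
}
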