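#' Load a pKa set
#'
#' Loads the bundled default pKa table (Lehninger free-amino-acid alpha and
#' side-chain pKas; EMBOSS-tradition polypeptide group pKas) or a user TSV
#' with the same columns (\code{residue}, \code{free_pk_carboxyl},
#' \code{free_pk_amino}, \code{free_pk_side}, \code{poly_pk_side},
#' \code{side_acidity}; rows \code{Nterm}/\code{Cterm} carry the terminal
#' pKas).
#'
#' @param name \code{"default"} or a path to a TSV file.
#' @return A \code{\link[=PkaSet-class]{PkaSet}}.
#' @export
loadPkaSet <- function(name = "default") {
    path <- if (file.exists(name)) name
            else if (name == "default") .extdata("pka_default.tsv")
            else stop("unknown pKa set: ", name)
    tb <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    term <- tb[tb$residue %in% c("Nterm", "Cterm"), ]
    res <- tb[!tb$residue %in% c("Nterm", "Cterm"), ]
    side <- setNames(res$poly_pk_side, res$residue)
    side <- side[!is.na(side)]
    acid <- setNames(res$side_acidity, res$residue)
    acid <- acid[!is.na(acid)]
    new("PkaSet",
        name = if (name == "default") "default" else basename(path),
        polyNterm = term$poly_pk_side[term$residue == "Nterm"],
        polyCterm = term$poly_pk_side[term$residue == "Cterm"],
        polySide = side,
        sideAcidity = acid,
        freeCarboxyl = setNames(res$free_pk_carboxyl, res$residue),
        freeAmino = setNames(res$free_pk_amino, res$residue),
        freeSide = setNames(res$free_pk_side, res$residue)[!is.na(res$free_pk_side)])
}

setMethod("show", "PkaSet", function(object)
    cat(sprintf("PkaSet '%s': termini %.2f/%.2f; ionizable side chains: %s\n",
                object@name, object@polyNterm, object@polyCterm,
                paste(names(object@polySide), collapse = ""))))

#' Bundled hydropathy scale names
#'
#' @return Character vector of the bundled scale names.
#' @export
hydropathyScaleNames <- function()
    c("kyte_doolittle", "eisenberg_consensus", "eisenberg_normalized")

#' Load a hydropathy scale
#'
#' Loads one of the three bundled scales (Kyte--Doolittle, Eisenberg
#' consensus, Eisenberg normalized consensus) or a user TSV with columns
#' \code{residue}, \code{value} covering the 20 canonical amino acids.
#'
#' @param name A name from \code{\link{hydropathyScaleNames}} or a TSV path.
#' @return A \code{\link[=HydropathyScale-class]{HydropathyScale}}.
#' @export
loadHydropathyScale <- function(name) {
    path <- if (file.exists(name)) name
            else if (name %in% hydropathyScaleNames())
                .extdata(sprintf("hydropathy_%s.tsv", name))
            else stop("unknown hydropathy scale: ", name)
    tb <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    new("HydropathyScale",
        name = if (file.exists(name)) basename(path) else name,
        values = setNames(tb$value, tb$residue))
}

setMethod("show", "HydropathyScale", function(object)
    cat(sprintf("HydropathyScale '%s' (S %.2f, L %.2f)\n", object@name,
                object@values[["S"]], object@values[["L"]])))

.charCounts <- function(protein) {
    ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
    table(factor(ch, levels = unique(ch)))
}

#' Net charge of a protein at a given pH
#'
#' Henderson--Hasselbalch charge balance: each basic group contributes
#' \eqn{+1/(1+10^{pH-pKa})} and each acidic group \eqn{-1/(1+10^{pKa-pH})}.
#' Polypeptide mode counts the two termini once plus every ionizable side
#' chain; free-amino-acid mode (single residue only) uses the residue's
#' alpha-carboxyl and alpha-amino pKas plus its side chain if ionizable.
#' \code{X} residues contribute no charge; any other unknown character is an
#' error.  Vectorized over \code{pH}.
#'
#' @param protein Amino-acid string.
#' @param pH Numeric vector of pH values in [0, 14].
#' @param pkas A \code{\link[=PkaSet-class]{PkaSet}}.
#' @param mode \code{"polypeptide"} or \code{"free_amino_acid"}.
#' @return Net charge in elementary charge units, one value per pH.
#' @examples
#' pk <- loadPkaSet()
#' netCharge("DK", 7, pk)
#' @export
netCharge <- function(protein, pH, pkas = loadPkaSet(),
                      mode = c("polypeptide", "free_amino_acid")) {
    mode <- match.arg(mode)
    stopifnot(nzchar(protein), all(pH >= 0 & pH <= 14))
    basicTerm <- function(pka) 1 / (1 + 10 ^ (pH - pka))
    acidTerm <- function(pka) -1 / (1 + 10 ^ (pka - pH))
    if (mode == "free_amino_acid") {
        if (nchar(protein) != 1L)
            stop("free_amino_acid mode requires a single residue")
        if (!protein %in% names(pkas@freeCarboxyl))
            stop("unknown residue: ", protein)
        q <- acidTerm(pkas@freeCarboxyl[[protein]]) +
             basicTerm(pkas@freeAmino[[protein]])
        if (protein %in% names(pkas@freeSide)) {
            q <- q + if (pkas@sideAcidity[[protein]] == "acidic")
                acidTerm(pkas@freeSide[[protein]])
            else basicTerm(pkas@freeSide[[protein]])
        }
        return(q)
    }
    counts <- .charCounts(protein)
    unknown <- setdiff(names(counts), c(.AA20, "X"))
    if (length(unknown))
        stop("unknown residue character(s): ", paste(unknown, collapse = ", "))
    q <- basicTerm(pkas@polyNterm) + acidTerm(pkas@polyCterm)
    for (res in intersect(names(counts), names(pkas@polySide))) {
        n <- as.numeric(counts[[res]])
        q <- q + n * if (pkas@sideAcidity[[res]] == "acidic")
            acidTerm(pkas@polySide[[res]]) else basicTerm(pkas@polySide[[res]])
    }
    q
}

#' Isoelectric point by charge-balance bisection
#'
#' Finds the unique pH in [0, 14] where \code{\link{netCharge}} crosses zero
#' (the charge curve is strictly decreasing in pH), by bisection to
#' \code{|delta pH| < tol}.  Full precision is returned; reports round to
#' 2 decimals.
#'
#' @inheritParams netCharge
#' @param tol Bisection tolerance on pH (default 1e-4).
#' @return The isoelectric point in pH units.
#' @examples
#' round(computePI("S", mode = "free_amino_acid"), 2)   # 5.68
#' round(computePI("L", mode = "free_amino_acid"), 2)   # 5.98
#' @export
computePI <- function(protein, pkas = loadPkaSet(),
                      mode = c("polypeptide", "free_amino_acid"), tol = 1e-4) {
    mode <- match.arg(mode)
    lo <- 0; hi <- 14
    while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (netCharge(protein, mid, pkas, mode) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
}

#' Isoelectric-point shift between the Leu and Ser decodings
#'
#' Three rules are exposed because the underlying conventions differ.
#' \code{recompute}: \code{pi_leu - pi_ser} from the full charge-balance
#' solver (analytically ~0, since neither Ser nor Leu side chains ionize).
#' \code{paper_flat}: \eqn{-0.3 \times n_{CUG}}, the flat approximation of
#' subtracting the free Ser/Leu pI difference once per CUG-encoded residue.
#' \code{paper_length_weighted} (default): the flat shift diluted by protein
#' length, \eqn{-0.3 \times n_{CUG} / L}.
#'
#' @param nCug Number of CUG-encoded residues.
#' @param length Protein length in residues (> 0).
#' @param piSer,piLeu Solver pIs (required for \code{rule = "recompute"}).
#' @param rule One of \code{"paper_length_weighted"}, \code{"paper_flat"},
#'   \code{"recompute"}.
#' @return Shift in pH units (0 whenever \code{nCug == 0}).
#' @export
piShift <- function(nCug, length, piSer = NULL, piLeu = NULL,
                    rule = c("paper_length_weighted", "paper_flat", "recompute")) {
    rule <- match.arg(rule)
    stopifnot(length > 0)
    if (nCug == 0) return(0)
    switch(rule,
        paper_flat = -0.3 * nCug,
        paper_length_weighted = -0.3 * nCug / length,
        recompute = {
            if (is.null(piSer) || is.null(piLeu))
                stop("rule 'recompute' needs piSer and piLeu")
            piLeu - piSer
        })
}

#' GRAVY hydropathy of a protein
#'
#' Sums the per-residue scale values; \code{mean} mode (the GRAVY
#' convention, default) divides by the number of residues with defined
#' values.  \code{X} residues are excluded from both numerator and
#' denominator.
#'
#' @param protein Amino-acid string.
#' @param scale A \code{\link[=HydropathyScale-class]{HydropathyScale}}.
#' @param mode \code{"mean"} (GRAVY) or \code{"sum"}.
#' @return Dimensionless hydropathy score.
#' @examples
#' kd <- loadHydropathyScale("kyte_doolittle")
#' gravy("L", kd)               # 3.8, the scale's Leu entry
#' gravy("LS", kd)              # mean of Leu and Ser entries
#' @export
gravy <- function(protein, scale, mode = c("mean", "sum")) {
    mode <- match.arg(mode)
    stopifnot(is(scale, "HydropathyScale"), nzchar(protein))
    ch <- strsplit(protein, "", fixed = TRUE)[[1L]]
    vals <- scale@values[ch]   # NA for X or unknown
    n <- sum(!is.na(vals))
    if (n == 0L)
        stop("no residues with defined hydropathy values")
    s <- sum(vals, na.rm = TRUE)
    if (mode == "mean") s / n else s
}

#' Physicochemical profiles of a dual proteome
#'
#' For every gene computes length, n_cug, the two solver pIs, all three pI
#' shift rules, and GRAVY hydropathy under each scale for both decodings
#' plus the Leu-minus-Ser shift.  Under mean mode the shift obeys the closed
#' form \eqn{(h_{Leu} - h_{Ser}) \times n_{CUG} / L} exactly.
#'
#' @param dual A \code{\link[=DualProteome-class]{DualProteome}}.
#' @param pkas A \code{PkaSet}.
#' @param scales Named list of \code{HydropathyScale}s (default: the three
#'   bundled scales).
#' @param gravyMode \code{"mean"} (default) or \code{"sum"}.
#' @return data.frame, one row per gene: \code{gene_id}, \code{length},
#'   \code{n_cug}, \code{pi_ser}, \code{pi_leu}, \code{pi_shift_recompute},
#'   \code{pi_shift_flat}, \code{pi_shift_length_weighted}, and per scale
#'   \code{gravy_<scale>_ser}, \code{gravy_<scale>_leu}, \code{shift_<scale>}.
#' @export
physchemProfiles <- function(dual, pkas = loadPkaSet(), scales = NULL,
                             gravyMode = c("mean", "sum")) {
    gravyMode <- match.arg(gravyMode)
    stopifnot(is(dual, "DualProteome"))
    if (is.null(scales))
        scales <- setNames(lapply(hydropathyScaleNames(), loadHydropathyScale),
                           hydropathyScaleNames())
    ser <- as.character(serProteins(dual))
    leu <- as.character(leuProteins(dual))
    n <- lengths(cugResidueIndices(dual))
    len <- nchar(ser)
    piS <- vapply(ser, computePI, numeric(1L), pkas = pkas, USE.NAMES = FALSE)
    piL <- vapply(leu, computePI, numeric(1L), pkas = pkas, USE.NAMES = FALSE)
    out <- data.frame(gene_id = names(serProteins(dual)),
                      length = len, n_cug = unname(n),
                      pi_ser = piS, pi_leu = piL,
                      stringsAsFactors = FALSE)
    out$pi_shift_recompute <- ifelse(out$n_cug == 0, 0, piL - piS)
    out$pi_shift_flat <- -0.3 * out$n_cug
    out$pi_shift_length_weighted <- -0.3 * out$n_cug / out$length
    for (nm in names(scales)) {
        gs <- vapply(ser, gravy, numeric(1L), scale = scales[[nm]],
                     mode = gravyMode, USE.NAMES = FALSE)
        gl <- vapply(leu, gravy, numeric(1L), scale = scales[[nm]],
                     mode = gravyMode, USE.NAMES = FALSE)
        out[[paste0("gravy_", nm, "_ser")]] <- gs
        out[[paste0("gravy_", nm, "_leu")]] <- gl
        out[[paste0("shift_", nm)]] <- gl - gs
    }
    attr(out, "gravyMode") <- gravyMode
    out
}

#' Hydropathy shift census across scales
#'
#' Per scale, counts proteins with any hydropathy variation
#' (\code{|shift| > 0}) and with a high shift (\code{|shift| >= threshold},
#' compared at full precision), and intersects the high-shift identifier
#' sets across all scales.
#'
#' @param profiles Profile data.frame from \code{\link{physchemProfiles}}.
#' @param thresholds Named numeric: high-shift cutoff per scale.  Default is
#'   the published convention: 0.03 for Kyte--Doolittle and 0.3 for the two
#'   Eisenberg scales.
#' @return List with class \code{"shiftCensus"}: \code{per_scale}
#'   (data.frame scale, n_any_variation, n_high_shift), \code{intersection}
#'   (gene ids, input order), \code{thresholds}.
#' @export
shiftCensus <- function(profiles,
                        thresholds = c(kyte_doolittle = 0.03,
                                       eisenberg_consensus = 0.3,
                                       eisenberg_normalized = 0.3)) {
    scaleCols <- grep("^shift_", names(profiles), value = TRUE)
    scales <- sub("^shift_", "", scaleCols)
    missing <- setdiff(scales, names(thresholds))
    if (length(missing))
        stop("no threshold for scale(s): ", paste(missing, collapse = ", "))
    highSets <- list()
    per <- data.frame(scale = scales, n_any_variation = NA_integer_,
                      n_high_shift = NA_integer_, threshold = NA_real_,
                      stringsAsFactors = FALSE)
    for (k in seq_along(scales)) {
        sh <- profiles[[scaleCols[k]]]
        thr <- thresholds[[scales[k]]]
        per$n_any_variation[k] <- sum(abs(sh) > 0)
        high <- abs(sh) >= thr
        per$n_high_shift[k] <- sum(high)
        per$threshold[k] <- thr
        highSets[[scales[k]]] <- profiles$gene_id[high]
    }
    inter <- Reduce(intersect, highSets)
    structure(list(per_scale = per,
                   intersection = profiles$gene_id[profiles$gene_id %in% inter],
                   high_shift_sets = highSets,
                   thresholds = thresholds[scales]),
              class = "shiftCensus")
}

#' @export
print.shiftCensus <- function(x, ...) {
    cat("Hydropathy shift census\n")
    print(x$per_scale, row.names = FALSE)
    cat(sprintf("  high-shift intersection across %d scale(s): %d protein(s)\n",
                nrow(x$per_scale), length(x$intersection)))
    invisible(x)
}

#' Default pI bin ranges
#'
#' The six pH ranges used to compare proteome pI profiles: three on
#' distribution valleys (5.3--5.9, 7--8.9, 10.1--13) and three on peaks
#' (4.2--5.2, 6--6.9, 9--10.1).
#'
#' @return data.frame with columns \code{name}, \code{kind}, \code{lo},
#'   \code{hi} (closed ranges).
#' @export
defaultPiBins <- function() {
    data.frame(
        name = c("valley_5.3-5.9", "valley_7-8.9", "valley_10.1-13",
                 "peak_4.2-5.2", "peak_6-6.9", "peak_9-10.1"),
        kind = rep(c("valley", "peak"), each = 3L),
        lo = c(5.3, 7, 10.1, 4.2, 6, 9),
        hi = c(5.9, 8.9, 13, 5.2, 6.9, 10.1),
        stringsAsFactors = FALSE)
}

#' Bin pI values into peak/valley pH ranges
#'
#' Counts proteins whose pI falls in each closed range.  A value on a
#' boundary shared by two ranges is assigned once, to the range covering the
#' lower pH values (so exactly 10.1 counts in the 9--10.1 peak, not the
#' 10.1--13 valley).  Overlapping custom ranges are rejected except at
#' shared endpoints.
#'
#' @param pi Numeric vector of pI values.
#' @param ranges Ranges data.frame as from \code{\link{defaultPiBins}}.
#' @return \code{ranges} with an added \code{count} column (input range
#'   order preserved).
#' @export
binPI <- function(pi, ranges = defaultPiBins()) {
    ord <- order(ranges$lo, ranges$hi)
    sorted <- ranges[ord, ]
    if (nrow(sorted) > 1L) {
        ov <- sorted$lo[-1L] < sorted$hi[-nrow(sorted)]
        if (any(ov))
            stop("overlapping ranges: ", paste(sorted$name[c(ov, FALSE)], collapse = ", "))
    }
    counts <- integer(nrow(sorted))
    for (v in pi) {
        hit <- which(v >= sorted$lo & v <= sorted$hi)
        if (length(hit)) counts[hit[1L]] <- counts[hit[1L]] + 1L
    }
    ranges$count <- counts[order(ord)]
    ranges
}

#' Write physchem outputs
#'
#' @param profiles Profiles data.frame from \code{\link{physchemProfiles}}.
#' @param census A \code{shiftCensus} list.
#' @param bins Binned pI data.frame from \code{\link{binPI}}.
#' @param path Output path (TSV, or JSON for the shift-census summary).
#' @return \code{path}, invisibly.
#' @name writePhyschemTables
NULL

#' @rdname writePhyschemTables
#' @export
writeProfilesTsv <- function(profiles, path) {
    prof <- profiles
    prof$pi_ser <- round(prof$pi_ser, 2)
    prof$pi_leu <- round(prof$pi_leu, 2)
    .writeTsv(prof, path,
              comments = c("physicochemical profiles; pI reported to 2 decimals",
                           paste0("gravy_mode=", attr(profiles, "gravyMode"))),
              decimals = 4L)
}

#' @rdname writePhyschemTables
#' @export
writeShiftCensusJson <- function(census, path) {
    jsonlite::write_json(
        list(per_scale = census$per_scale,
             thresholds = as.list(census$thresholds),
             intersection = census$intersection,
             n_intersection = length(census$intersection)),
        path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(path)
}

#' @rdname writePhyschemTables
#' @export
writePiBinsTsv <- function(bins, path) {
    .writeTsv(bins, path, comments = "pI bin counts; closed pH ranges", decimals = 2L)
}
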