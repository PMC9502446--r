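#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining with the standard Q-criterion
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j}.  On Q ties the pair whose
#' (lexicographically sorted) representative taxon ids compare smallest is
#' joined, so results are deterministic.  Branch lengths follow the standard
#' formulas; the 3-taxon base case is solved exactly
#' (\eqn{a_A = (d_{AB} + d_{AC} - d_{BC})/2} and rotations).  Negative
#' branch lengths are preserved internally; clamp at serialization with
#' \code{\link{writeNewick}}.
#'
#' @param d Symmetric numeric distance matrix with zero diagonal,
#'   non-negative entries and unique dimnames; at least 3 taxa.
#' @return An unrooted \code{ape} \code{phylo} tree whose leaf set equals
#'   the taxon set.
#' @examples
#' d <- matrix(c(0, .2, .3, .2, 0, .4, .3, .4, 0), 3,
#'             dimnames = list(c("A","B","C"), c("A","B","C")))
#' neighborJoining(d)$edge.length   # branches 0.05, 0.15, 0.25
#' @export
neighborJoining <- function(d) {
    if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3L)
        stop("d must be a square matrix over >= 3 taxa")
    ids <- rownames(d)
    if (is.null(ids) || anyDuplicated(ids) ||
        !identical(ids, colnames(d)))
        stop("d needs matching, unique row/column names")
    if (max(abs(d - t(d))) > 1e-8 || any(diag(d) != 0) || any(d < 0))
        stop("d must be symmetric and non-negative with a zero diagonal")

    frag <- ids                 # newick fragment per active node
    rep <- ids                  # lexicographic representative per node
    D <- d
    while (nrow(D) > 3L) {
        r <- nrow(D)
        R <- rowSums(D)
        Q <- (r - 2) * D - outer(R, R, "+")
        diag(Q) <- Inf
        qmin <- min(Q)
        cand <- which(Q - qmin <= 1e-12, arr.ind = TRUE)
        cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
        key <- apply(cand, 1L, function(p) {
            pr <- sort(c(rep[p[1L]], rep[p[2L]]))
            paste(pr, collapse = "\r")
        })
        pick <- cand[order(key)[1L], ]
        i <- pick[[1L]]; j <- pick[[2L]]
        vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
        vj <- D[i, j] - vi
        newFrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], vi, frag[j], vj)
        newRep <- min(rep[i], rep[j])
        dNew <- (D[i, ] + D[j, ] - D[i, j]) / 2
        keep <- setdiff(seq_len(r), c(i, j))
        D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dNew[keep]),
                    c(dNew[keep], 0))
        nm <- c(rownames(D)[keep], newRep)
        dimnames(D2) <- list(nm, nm)
        D <- D2
        frag <- c(frag[keep], newFrag)
        rep <- c(rep[keep], newRep)
    }
    v1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
    v2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
    v3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
    nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                   frag[1], v1, frag[2], v2, frag[3], v3)
    ape::read.tree(text = nwk)
}

#' Write a tree to newick
#'
#' @param tree An \code{ape} \code{phylo}.
#' @param path Output path.
#' @param clampNegative Clamp negative branch lengths to 0 on write (the
#'   standard practice for NJ output); the in-memory tree is untouched.
#' @return \code{path}, invisibly.
#' @export
writeNewick <- function(tree, path, clampNegative = TRUE) {
    if (clampNegative && !is.null(tree$edge.length))
        tree$edge.length <- pmax(tree$edge.length, 0)
    ape::write.tree(tree, file = path)
    invisible(path)
}
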