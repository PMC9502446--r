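#' Needleman--Wunsch global alignment
#'
#' Optimal global alignment under a linear gap scheme, with a deterministic
#' traceback tie-break: on equal scores prefer the diagonal move, then the
#' vertical (gap in \code{b}), then the horizontal (gap in \code{a}).
#' Identity is matched columns over total alignment columns; columns with a
#' gap count as non-matches.
#'
#' @param a,b Sequences (character scalars or \code{XString}s); non-empty.
#' @param match,mismatch,gap Scores (defaults +1/-1/-2, linear gaps).
#' @return List: \code{alignedA}, \code{alignedB} (gapped strings of equal
#'   length), \code{score}, \code{identity} in [0, 1], \code{columns}.
#' @examples
#' globalAlign("ACGT", "ACTT")$identity   # 0.75
#' @export
globalAlign <- function(a, b, match = 1, mismatch = -1, gap = -2) {
    a <- as.character(a); b <- as.character(b)
    if (!nzchar(a) || !nzchar(b))
        stop("globalAlign requires non-empty sequences")
    av <- strsplit(a, "", fixed = TRUE)[[1L]]
    bv <- strsplit(b, "", fixed = TRUE)[[1L]]
    n <- length(av); m <- length(bv)
    S <- matrix(0, n + 1L, m + 1L)
    S[, 1L] <- gap * 0:n
    S[1L, ] <- gap * 0:m
    for (i in seq_len(n)) {
        sub <- ifelse(av[i] == bv, match, mismatch)
        row <- S[i, ]
        cur <- S[i + 1L, ]
        for (j in seq_len(m))
            cur[j + 1L] <- max(row[j] + sub[j], row[j + 1L] + gap, cur[j] + gap)
        S[i + 1L, ] <- cur
    }
    # traceback with diagonal > up > left preference
    i <- n; j <- m
    ra <- character(0); rb <- character(0)
    while (i > 0L || j > 0L) {
        if (i > 0L && j > 0L &&
            S[i + 1L, j + 1L] ==
                S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
            ra <- c(av[i], ra); rb <- c(bv[j], rb); i <- i - 1L; j <- j - 1L
        } else if (i > 0L && S[i + 1L, j + 1L] == S[i, j + 1L] + gap) {
            ra <- c(av[i], ra); rb <- c("-", rb); i <- i - 1L
        } else {
            ra <- c("-", ra); rb <- c(bv[j], rb); j <- j - 1L
        }
    }
    cols <- length(ra)
    ident <- sum(ra == rb & ra != "-") / cols
    list(alignedA = paste(ra, collapse = ""),
         alignedB = paste(rb, collapse = ""),
         score = S[n + 1L, m + 1L],
         identity = ident,
         columns = cols)
}
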