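## Small internal helpers shared across modules.

.STOPS <- c("TAA", "TAG", "TGA")

## split a DNA string into its codons (character vector)
.codonsOf <- function(seq) {
    n <- nchar(seq)
    substring(seq, seq.int(1L, n - 2L, by = 3L), seq.int(3L, n, by = 3L))
}

## TRUE if any non-final codon is a stop
.hasInternalStop <- function(seq) {
    cod <- .codonsOf(seq)
    if (length(cod) <= 1L) return(FALSE)
    any(cod[-length(cod)] %in% .STOPS)
}

.normalizeNuc <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

.extdata <- function(...) {
    path <- system.file("extdata", ..., package = "cugDecode", mustWork = TRUE)
    path
}

## deterministic seed scoping: run expr under seed if non-NULL
.withSeed <- function(seed, expr) {
    if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

## render numerics with fixed decimals for deterministic TSV output
.fmtNum <- function(x, decimals) {
    ifelse(is.na(x), "NA", formatC(x, format = "f", digits = decimals))
}

## write a data.frame as TSV with '#'-prefixed header comments
.writeTsv <- function(df, path, comments = character(), decimals = 4L) {
    num <- vapply(df, is.numeric, logical(1L)) &
        !vapply(df, is.integer, logical(1L))
    for (j in which(num)) df[[j]] <- .fmtNum(df[[j]], decimals)
    con <- file(path, open = "wt", encoding = "UTF-8")
    on.exit(close(con))
    for (cm in c(comments, sprintf("decimals=%d", decimals)))
        writeLines(paste0("# ", cm), con)
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}
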