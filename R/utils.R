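# small shared helpers

readTsv <- function(path, ...) {
    utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                      check.names = FALSE, ...)
}

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all n! permutations of 1..n as an (n!) x n integer matrix; used for the
# exact Spearman permutation null at small n (n <= 9 stays below 4e5 rows)
allPermutations <- function(n) {
    stopifnot(n >= 1L, n <= 9L)
    P <- matrix(1L, 1L, 1L)
    if (n == 1L) return(P)
    for (k in 2L:n) {
        m <- nrow(P)
        out <- matrix(0L, m * k, k)
        for (pos in seq_len(k)) {
            rows <- ((pos - 1L) * m + 1L):(pos * m)
            out[rows, pos] <- k
            out[rows, setdiff(seq_len(k), pos)] <- P
        }
        P <- out
    }
    P
}

# variant identity key used by blacklist / recurrence logic
variantKey <- function(df) {
    paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}
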