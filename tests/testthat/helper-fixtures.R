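# Fixtures built in code and independent oracles used across the suite.

# --- toy transcripts ------------------------------------------------------

# M G L *  (codon 2 = GGT): SNV playground
toyGenomeA <- paste0("AAA", "ATGGGTCTGTAA", "AAA")
toyTranscriptA <- function() {
    transcriptModel(gene = "TOYA", proteinId = "NP_TOYA", chrom = "g1",
                    cdsStarts = 4L, cdsEnds = 15L,
                    genomeSeq = toyGenomeA, strand = "+")
}

# M L G W *  (codon 2 = CTG, codon 3 = GGT): frameshift-masking playground
toyGenomeB <- paste0("AAA", "ATGCTGGGTTGGTAA", "AAA")
toyTranscriptB <- function() {
    transcriptModel(gene = "TOYB", proteinId = "NP_TOYB", chrom = "g2",
                    cdsStarts = 4L, cdsEnds = 18L,
                    genomeSeq = toyGenomeB, strand = "+")
}

# M E A S K L W *  (24 nt CDS at genomic 5..28): delins merge playground.
# Parent deletions of 4 bp (codons 2-3 region) and 2 bp (codon 4) are each
# frameshifts; applied jointly they are a net -6 in-frame delins.
toyGenomeC <- paste0("AAAA", "ATGGAAGCCTCGAAACTGTGGTAA", "AAAA")
toyTranscriptC <- function() {
    transcriptModel(gene = "TOYC", proteinId = "NP_TOYC", chrom = "g3",
                    cdsStarts = 5L, cdsEnds = 28L,
                    genomeSeq = toyGenomeC, strand = "+")
}
delinsParentA <- function()             # -4 bp, frameshift alone
    data.frame(sample_id = "S1", chrom = "g3", pos = 8L,
               ref = "GAAGC", alt = "G", af = 0.30, depth = 1000L)
delinsParentB <- function()             # -2 bp, frameshift alone
    data.frame(sample_id = "S1", chrom = "g3", pos = 14L,
               ref = "TCG", alt = "T", af = 0.28, depth = 1000L)

# --- tiny panel -----------------------------------------------------------

tinyPanel <- function() {
    ampliconPanel(name = c("A1", "A2", "A3"),
                  chrom = c("chr1", "chr1", "chr2"),
                  start = c(100L, 200L, 500L), end = c(250L, 350L, 700L),
                  fwdPrimerLen = 25L, revPrimerLen = 25L,
                  gene = c("G1", "G1", "G2"))
}

# --- independent oracles --------------------------------------------------

# all permutations of 1..n, recursively (independent of the package's
# iterative construction)
oraclePerms <- function(n) {
    if (n == 1L) return(matrix(1L, 1L, 1L))
    sub <- oraclePerms(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        rest <- setdiff(seq_len(n), i)
        cbind(i, matrix(rest[sub], nrow(sub)))
    }))
}

# brute-force exact two-sided Spearman permutation p and rho
oracleSpearman <- function(x, y) {
    rx <- rank(x); ry <- rank(y)
    rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
        sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
    P <- oraclePerms(length(x))
    rhos <- apply(P, 1L, function(ix) {
        ryp <- ry[ix]
        sum((rx - mean(rx)) * (ryp - mean(ryp))) /
            sqrt(sum((rx - mean(rx))^2) * sum((ryp - mean(ryp))^2))
    })
    list(rho = rho, p = mean(abs(rhos) >= abs(rho) - 1e-12))
}

# exhaustive margin-fixed enumeration of the two-sided Fisher p for a 2x2
# table [[a, b], [c, d]] (rows: class/other, cols: low/high bin)
oracleFisherP <- function(a, b, c, d) {
    r1 <- a + b; r2 <- c + d; c1 <- a + c
    xs <- max(0L, c1 - r2):min(r1, c1)
    probs <- stats::dhyper(xs, r1, r2, c1)
    pObs <- stats::dhyper(a, r1, r2, c1)
    sum(probs[probs <= pObs * (1 + 1e-7)])
}

# small deterministic variant table
makeVariants <- function(sample_id, af, ref = "C", alt = "T",
                         chrom = "chr1", pos = seq_along(af) + 1000L,
                         depth = 2000L) {
    n <- length(af)
    alt_reads <- pmax(1L, round(af * depth))
    data.frame(sample_id = rep_len(sample_id, n), chrom = rep_len(chrom, n),
               pos = rep_len(pos, n), ref = rep_len(ref, n),
               alt = rep_len(alt, n), af = af,
               depth = rep_len(depth, n),
               fwd_alt = alt_reads %/% 2L,
               rev_alt = alt_reads - alt_reads %/% 2L)
}
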