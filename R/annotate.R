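#' @include transcripts.R
NULL

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
         Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
         L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
         S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
         "*" = "Ter")

aa3 <- function(ch) unname(AA3[strsplit(ch, "")[[1]]])

seqTo3 <- function(ch) paste(aa3(ch), collapse = "")

#' Merge two read-phased variants into one complex variant
#'
#' Callers that emit a deletion and a nearby substitution as separate
#' records can turn a single in-frame complex allele into two apparent
#' frameshifts. When read-backed phasing puts both calls on the same
#' molecule, this merges them: both edits are applied to the reference
#' sequence over the spanning interval, and the minimal single REF/ALT
#' pair is derived by trimming the common suffix and prefix and
#' left-aligning in the VCF convention. The merged call takes the smaller
#' parent AF and records both parents for audit.
#'
#' @param a,b one-row data.frames (\code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{af}, ...); \code{b = NULL} returns \code{a}
#'   unchanged.
#' @param refSeq reference sequence (character) covering both variants.
#' @param refStart genomic position of the first base of \code{refSeq}.
#' @param maxSpan maximum allowed spanning interval in bp.
#' @return a one-row data.frame for the merged variant, with a
#'   \code{parents} audit column.
#' @export
mergePhased <- function(a, b, refSeq, refStart, maxSpan = 100L) {
    if (is.null(b)) return(a)
    if (!is.null(a$sample_id) && !is.null(b$sample_id) &&
        a$sample_id != b$sample_id)
        stop("phased variants must come from one sample")
    if (a$chrom != b$chrom) stop("phased variants must share a chromosome")
    if (a$pos > b$pos) { tmp <- a; a <- b; b <- tmp }
    aEnd <- a$pos + nchar(a$ref) - 1L
    bEnd <- b$pos + nchar(b$ref) - 1L
    if (bEnd - a$pos + 1L > maxSpan)
        stop("spanning interval exceeds ", maxSpan, " bp")
    if (aEnd >= b$pos)
        stop("overlapping conflicting edits: ",
             paste(a$chrom, a$pos, a$ref, a$alt, sep = ":"), " and ",
             paste(b$chrom, b$pos, b$ref, b$alt, sep = ":"))
    at <- function(p) p - refStart + 1L
    if (at(a$pos) < 1L || at(bEnd) > nchar(refSeq))
        stop("refSeq does not cover the spanning interval")
    chk <- function(v, vEnd) {
        obs <- substr(refSeq, at(v$pos), at(vEnd))
        if (obs != v$ref)
            stop("REF mismatch at ", v$pos, ": expected ", v$ref,
                 ", reference has ", obs)
    }
    chk(a, aEnd); chk(b, bEnd)
    refWin <- substr(refSeq, at(a$pos), at(bEnd))
    altWin <- paste0(a$alt,
                     substr(refSeq, at(aEnd) + 1L, at(b$pos) - 1L),
                     b$alt)
    norm <- normalizeAllele(a$pos, refWin, altWin, refSeq, refStart)
    out <- a
    out$pos <- norm$pos
    out$ref <- norm$ref
    out$alt <- norm$alt
    out$af <- min(a$af, b$af)
    if (!is.null(a$depth)) out$depth <- min(a$depth, b$depth)
    out$parents <- paste(
        paste(a$chrom, a$pos, a$ref, a$alt, sep = ":"),
        paste(b$chrom, b$pos, b$ref, b$alt, sep = ":"), sep = ";")
    out
}

# minimal VCF representation: trim common suffix, trim common prefix,
# then left-align indels against the supplied reference context
normalizeAllele <- function(pos, ref, alt, refSeq, refStart) {
    last <- function(s) substr(s, nchar(s), nchar(s))
    first <- function(s) substr(s, 1L, 1L)
    dropLast <- function(s) substr(s, 1L, nchar(s) - 1L)
    dropFirst <- function(s) substr(s, 2L, nchar(s))
    repeat {
        changed <- FALSE
        if (nchar(ref) > 0L && nchar(alt) > 0L &&
            last(ref) == last(alt) &&
            !(nchar(ref) == 1L && nchar(alt) == 1L)) {
            ref <- dropLast(ref); alt <- dropLast(alt); changed <- TRUE
        }
        if (nchar(ref) == 0L || nchar(alt) == 0L) {
            if (pos <= refStart)
                stop("cannot left-align: reference context exhausted")
            prev <- substr(refSeq, pos - refStart, pos - refStart)
            ref <- paste0(prev, ref); alt <- paste0(prev, alt)
            pos <- pos - 1L
            changed <- TRUE
        }
        if (!changed) break
    }
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           first(ref) == first(alt)) {
        ref <- dropFirst(ref); alt <- dropFirst(alt); pos <- pos + 1L
    }
    list(pos = pos, ref = ref, alt = alt)
}

#' Protein-level consequence of a variant on a transcript model
#'
#' Codon-aware annotation: the variant is mapped through the transcript's
#' CDS intervals (reverse-strand models reverse-complement the alleles),
#' the mutant coding sequence is translated, and the consequence is
#' classified as synonymous, missense, nonsense, frameshift (indel length
#' not a multiple of 3), or in-frame deletion/insertion/delins, with an
#' HGVS protein string in 3-letter code. Synonymous and non-coding
#' results carry a discard flag.
#'
#' When co-phased variants are supplied, expression logic is applied: a
#' frameshift or nonsense variant lying 5' of the annotated variant on
#' the same haplotype truncates the protein upstream, so the annotated
#' variant -- although genuinely present in the genome -- is never
#' expressed at protein level and is reported \code{expressed = FALSE}
#' (non-actionable).
#'
#' @param v one-row data.frame (\code{pos}, \code{ref}, \code{alt}).
#' @param t a \code{\linkS4class{TranscriptModel}}.
#' @param phasedContext data.frame of co-phased variants on the same
#'   haplotype (same columns as \code{v}), or \code{NULL}.
#' @return one-row data.frame: \code{hgvs_p}, \code{effect},
#'   \code{expressed}, \code{discard}, \code{cds_pos}.
#' @export
annotateProtein <- function(v, t, phasedContext = NULL) {
    res <- annotateOne(v, t)
    if (!is.null(phasedContext) && nrow(phasedContext) &&
        !is.na(res$cds_pos)) {
        for (j in seq_len(nrow(phasedContext))) {
            other <- annotateOne(phasedContext[j, , drop = FALSE], t)
            if (is.na(other$cds_pos)) next
            if (other$effect %in% c("frameshift", "nonsense") &&
                other$cds_pos < res$cds_pos)
                res$expressed <- FALSE
        }
    }
    res
}

annotateOne <- function(v, t) {
    lr <- nchar(v$ref)
    cdsLen <- length(t@sequence)
    iA <- cdsPosition(t, v$pos)
    iB <- cdsPosition(t, v$pos + lr - 1L)
    if (is.na(iA) || is.na(iB))
        return(data.frame(hgvs_p = "p.?", effect = "non-coding",
                          expressed = NA, discard = TRUE,
                          cds_pos = NA_integer_))
    refCds <- as.character(t@sequence)
    if (t@strand == "+") {
        i1 <- iA; i2 <- iB
        refAll <- v$ref; altAll <- v$alt
    } else {
        i1 <- iB; i2 <- iA
        rc <- function(s) as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(s)))
        refAll <- rc(v$ref); altAll <- rc(v$alt)
    }
    obs <- substr(refCds, i1, i2)
    if (obs != refAll)
        stop("REF allele does not match the transcript CDS at position ",
             i1, " (", obs, " vs ", refAll, ")")
    altCds <- paste0(substr(refCds, 1L, i1 - 1L), altAll,
                     substr(refCds, i2 + 1L, cdsLen))
    refP <- translateSeq(refCds)
    altP <- translateSeq(altCds)
    lenShift <- (nchar(v$alt) - nchar(v$ref)) %% 3L
    out <- proteinConsequence(refP, altP,
                              frameshift = lenShift != 0L,
                              indel = nchar(v$alt) != nchar(v$ref))
    out$cds_pos <- i1
    out
}

proteinConsequence <- function(refP, altP, frameshift, indel) {
    row <- function(hgvs, effect, discard = FALSE)
        data.frame(hgvs_p = hgvs, effect = effect, expressed = TRUE,
                   discard = discard)
    if (identical(refP, altP))
        return(row("p.(=)", "synonymous", discard = TRUE))
    rP <- strsplit(refP, "")[[1]]
    aP <- strsplit(altP, "")[[1]]
    if (frameshift) {
        i <- firstDiff(rP, aP)
        anchor <- if (i <= length(rP)) AA3[rP[i]] else "Ter"
        return(row(sprintf("p.%s%dfs", anchor, i), "frameshift"))
    }
    if (!indel) {
        diffs <- which(rP[seq_len(min(length(rP), length(aP)))] !=
                       aP[seq_len(min(length(rP), length(aP)))])
        if (length(diffs) == 1L) {
            i <- diffs
            if (aP[i] == "*")
                return(row(sprintf("p.%s%dTer", AA3[rP[i]], i),
                           "nonsense"))
            return(row(sprintf("p.%s%d%s", AA3[rP[i]], i, AA3[aP[i]]),
                       "missense"))
        }
        # multi-codon substitution: describe as delins over the changed run
    }
    # in-frame change: trim shared prefix/suffix of the two proteins
    k <- 0L
    while (k < min(length(rP), length(aP)) && rP[k + 1L] == aP[k + 1L])
        k <- k + 1L
    m <- 0L
    while (m < min(length(rP), length(aP)) - k &&
           rP[length(rP) - m] == aP[length(aP) - m])
        m <- m + 1L
    del <- rP[seq_len(length(rP) - m)][-seq_len(k)]
    ins <- aP[seq_len(length(aP) - m)][-seq_len(k)]
    if (!length(ins)) {
        hg <- if (length(del) == 1L)
            sprintf("p.%s%ddel", AA3[del[1]], k + 1L)
        else sprintf("p.%s%d_%s%ddel", AA3[del[1]], k + 1L,
                     AA3[del[length(del)]], k + length(del))
        return(row(hg, "inframe_del"))
    }
    if (!length(del)) {
        hg <- sprintf("p.%s%d_%s%dins%s", AA3[rP[k]], k,
                      AA3[rP[k + 1L]], k + 1L,
                      paste(AA3[ins], collapse = ""))
        return(row(hg, "inframe_ins"))
    }
    hg <- if (length(del) == 1L)
        sprintf("p.%s%ddelins%s", AA3[del[1]], k + 1L,
                paste(AA3[ins], collapse = ""))
    else sprintf("p.%s%d_%s%ddelins%s", AA3[del[1]], k + 1L,
                 AA3[del[length(del)]], k + length(del),
                 paste(AA3[ins], collapse = ""))
    row(hg, "inframe_delins")
}

firstDiff <- function(rP, aP) {
    n <- min(length(rP), length(aP))
    i <- which(rP[seq_len(n)] != aP[seq_len(n)])
    if (length(i)) i[1] else n + 1L
}
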