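#' @include AllClasses.R
NULL

#' Construct a TranscriptModel
#'
#' @param gene gene symbol.
#' @param proteinId protein accession used in reports (e.g. an NP_ id).
#' @param chrom chromosome of the CDS intervals.
#' @param cdsStarts,cdsEnds 1-based inclusive CDS interval coordinates in
#'   ascending genomic order.
#' @param genomeSeq \code{DNAString} (or character) holding the reference
#'   sequence of \code{chrom} (a synthetic mini-genome is fine); the
#'   spliced coding sequence is extracted and, for \code{strand == "-"},
#'   reverse-complemented.
#' @param strand \code{"+"} or \code{"-"}.
#' @return a \code{\linkS4class{TranscriptModel}}.
#' @export
transcriptModel <- function(gene, proteinId, chrom, cdsStarts, cdsEnds,
                            genomeSeq, strand = "+") {
    o <- order(cdsStarts)
    cdsStarts <- cdsStarts[o]; cdsEnds <- cdsEnds[o]
    genomeSeq <- Biostrings::DNAString(as.character(genomeSeq))
    pieces <- lapply(seq_along(cdsStarts), function(i)
        as.character(Biostrings::subseq(genomeSeq, cdsStarts[i], cdsEnds[i])))
    seq <- Biostrings::DNAString(paste(pieces, collapse = ""))
    if (strand == "-")
        seq <- Biostrings::reverseComplement(seq)
    partial <- FALSE
    if (length(seq) %% 3L != 0L) {
        warning("CDS length of ", gene, " not divisible by 3; ",
                "model flagged partial")
        partial <- TRUE
    } else if (as.character(Biostrings::subseq(seq, 1L, 3L)) != "ATG") {
        partial <- TRUE
    }
    cds <- GenomicRanges::GRanges(chrom,
        IRanges::IRanges(cdsStarts, cdsEnds), strand = strand)
    methods::new("TranscriptModel", gene = gene, proteinId = proteinId,
                 cds = cds, sequence = seq, strand = strand,
                 partial = partial)
}

#' Read transcript models from a GFF3-subset and FASTA
#'
#' Only \code{CDS} features are used; each must carry a \code{gene}
#' attribute (and optionally \code{protein_id}) and reference a sequence
#' present in the FASTA. CDS intervals of a gene are spliced in genomic
#' order and reverse-complemented for minus-strand genes, yielding the
#' strand-oriented coding sequence.
#'
#' @param gffPath path to a GFF3 file restricted to CDS features.
#' @param fastaPath path to the FASTA with the referenced sequences.
#' @return named list of \code{\linkS4class{TranscriptModel}}, one per gene.
#' @export
readTranscripts <- function(gffPath, fastaPath) {
    gff <- rtracklayer::import(gffPath)
    gff <- gff[tolower(as.character(gff$type)) == "cds"]
    if (!length(gff)) stop("no CDS features in ", gffPath)
    genome <- Biostrings::readDNAStringSet(fastaPath)
    names(genome) <- sub("\\s.*$", "", names(genome))
    mc <- S4Vectors::mcols(gff)
    geneCol <- intersect(c("gene", "gene_id", "Name"), colnames(mc))[1]
    if (is.na(geneCol)) stop("CDS features need a gene attribute")
    genes <- as.character(mc[[geneCol]])
    out <- lapply(split(seq_along(gff), genes), function(idx) {
        sub <- gff[idx]
        chrom <- unique(as.character(GenomicRanges::seqnames(sub)))
        if (length(chrom) > 1L)
            stop("CDS of one gene on multiple sequences: ",
                 paste(chrom, collapse = ","))
        if (!chrom %in% names(genome))
            stop("sequence ", chrom, " missing from FASTA")
        strand <- unique(as.character(GenomicRanges::strand(sub)))
        if (identical(strand, "*")) strand <- "+"
        pid <- if ("protein_id" %in% colnames(S4Vectors::mcols(sub)))
            unique(as.character(sub$protein_id))[1] else NA_character_
        transcriptModel(gene = genes[idx[1]],
                        proteinId = pid %||% NA_character_,
                        chrom = chrom,
                        cdsStarts = GenomicRanges::start(sub),
                        cdsEnds = GenomicRanges::end(sub),
                        genomeSeq = genome[[chrom]], strand = strand)
    })
    out
}

# map genomic positions to 1-based CDS coordinates (transcription
# direction); returns NA for positions outside the CDS
cdsPosition <- function(t, pos) {
    starts <- GenomicRanges::start(t@cds)
    ends <- GenomicRanges::end(t@cds)
    w <- ends - starts + 1L
    if (t@strand == "+") {
        o <- order(starts)
        before <- c(0L, cumsum(w[o]))[-(length(o) + 1L)]
        vapply(pos, function(p) {
            for (i in seq_along(o)) {
                e <- o[i]
                if (p >= starts[e] && p <= ends[e])
                    return(before[i] + (p - starts[e] + 1L))
            }
            NA_integer_
        }, integer(1))
    } else {
        o <- order(starts, decreasing = TRUE)
        before <- c(0L, cumsum(w[o]))[-(length(o) + 1L)]
        vapply(pos, function(p) {
            for (i in seq_along(o)) {
                e <- o[i]
                if (p >= starts[e] && p <= ends[e])
                    return(before[i] + (ends[e] - p + 1L))
            }
            NA_integer_
        }, integer(1))
    }
}

#' Translate the coding sequence of a transcript model
#'
#' @param t a \code{TranscriptModel}.
#' @return character protein sequence in 1-letter code, ending at (and
#'   including) the first stop when one is reached.
#' @export
translateCds <- function(t) {
    translateSeq(as.character(t@sequence))
}

# translate a nucleotide string, truncating to whole codons and stopping
# after the first stop codon ('*' retained)
translateSeq <- function(nt) {
    n <- floor(nchar(nt) / 3L) * 3L
    if (n == 0L) return("")
    aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(nt, 1L, n)), no.init.codon = TRUE))
    stop <- regexpr("*", aa, fixed = TRUE)
    if (stop > 0L) substr(aa, 1L, stop) else aa
}
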