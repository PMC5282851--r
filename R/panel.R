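#' @include AllGenerics.R
NULL

#' Construct an AmpliconPanel from parallel vectors
#'
#' Low-level constructor; most users go through \code{\link{readPanel}}.
#' Coordinates are 1-based inclusive genomic spans of the amplified product
#' (VCF convention); BED input is converted at the file boundary, never
#' here.
#'
#' @param name amplicon identifiers (unique).
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive span of the amplified product.
#' @param fwdPrimerLen,revPrimerLen bases covered by primer at the 5' and
#'   3' ends of the product.
#' @param gene gene symbol per amplicon.
#' @param strand \code{"+"} or \code{"-"} per amplicon.
#' @return an \code{\linkS4class{AmpliconPanel}}.
#' @export
ampliconPanel <- function(name, chrom, start, end, fwdPrimerLen,
                          revPrimerLen, gene, strand = "+") {
    if (any(start > end))
        stop("coordinate inversion: start > end for amplicon(s) ",
             paste(name[start > end], collapse = ", "))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                                 strand = strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = as.character(name), gene = as.character(gene),
        fwd_primer_len = as.integer(fwdPrimerLen),
        rev_primer_len = as.integer(revPrimerLen))
    geneChrom <- vapply(split(as.character(GenomicRanges::seqnames(gr)),
                              gene), function(ch) {
        u <- unique(ch)
        if (length(u) > 1L)
            stop("gene mapped to multiple chromosomes: ",
                 paste(u, collapse = ", "))
        u
    }, character(1))
    methods::new("AmpliconPanel", amplicons = gr, geneChrom = geneChrom)
}

#' Read an amplicon panel from BED + manifest
#'
#' The BED file gives the 0-based half-open spans of the amplified
#' products; the tab-separated manifest adds, per amplicon name, its gene
#' and the primer lengths at both ends (columns \code{name}, \code{gene},
#' \code{fwd_primer_len}, \code{rev_primer_len}, optional \code{strand}).
#' Coordinates are converted to the package's 1-based inclusive convention
#' on load.
#'
#' @param bedPath path to a BED file (chrom, start, end, name).
#' @param manifestPath path to the manifest TSV.
#' @return an \code{\linkS4class{AmpliconPanel}}.
#' @examples
#' p <- defaultPanel()
#' td <- tempfile(); dir.create(td)
#' writePanel(p, file.path(td, "p.bed"), file.path(td, "p.tsv"))
#' p2 <- readPanel(file.path(td, "p.bed"), file.path(td, "p.tsv"))
#' length(panelGenes(p2))
#' @export
readPanel <- function(bedPath, manifestPath) {
    bed <- utils::read.table(bedPath, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "name"))
    man <- readTsv(manifestPath)
    need <- c("name", "gene", "fwd_primer_len", "rev_primer_len")
    if (!all(need %in% colnames(man)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(bed$name))
        stop("duplicate amplicon names in BED: ",
             paste(unique(bed$name[duplicated(bed$name)]), collapse = ", "))
    miss <- setdiff(bed$name, man$name)
    if (length(miss))
        stop("missing manifest row for amplicon(s): ",
             paste(miss, collapse = ", "))
    man <- man[match(bed$name, man$name), ]
    ampliconPanel(name = bed$name, chrom = bed$chrom,
                  start = bed$start + 1L, end = bed$end,
                  fwdPrimerLen = man$fwd_primer_len,
                  revPrimerLen = man$rev_primer_len,
                  gene = man$gene,
                  strand = if ("strand" %in% colnames(man)) man$strand
                           else "+")
}

#' Write an amplicon panel to BED + manifest
#'
#' Inverse of \code{\link{readPanel}}; internal 1-based inclusive
#' coordinates are converted back to BED's 0-based half-open convention so
#' that a read/write round trip is coordinate-exact.
#'
#' @param panel an \code{AmpliconPanel}.
#' @param bedPath,manifestPath output paths.
#' @return invisibly, the two paths.
#' @export
writePanel <- function(panel, bedPath, manifestPath) {
    gr <- amplicons(panel)
    mc <- S4Vectors::mcols(gr)
    bed <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr) - 1L,
                      end = GenomicRanges::end(gr),
                      name = mc$name)
    utils::write.table(bed, bedPath, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    man <- data.frame(name = mc$name, gene = mc$gene,
                      fwd_primer_len = mc$fwd_primer_len,
                      rev_primer_len = mc$rev_primer_len,
                      strand = as.character(GenomicRanges::strand(gr)))
    writeTsv(man, manifestPath)
    invisible(c(bed = bedPath, manifest = manifestPath))
}

# 48 cancer genes of the amplicon panel with their (GRCh37) chromosomes.
PANEL_GENES <- c(
    ABL1 = "chr9",  AKT1 = "chr14",  ALK = "chr2",    APC = "chr5",
    ATM = "chr11",  BRAF = "chr7",   CDH1 = "chr16",  CDKN2A = "chr9",
    CSF1R = "chr5", CTNNB1 = "chr3", EGFR = "chr7",   ERBB2 = "chr17",
    ERBB4 = "chr2", FBXW7 = "chr4",  FGFR1 = "chr8",  FGFR2 = "chr10",
    FGFR3 = "chr4", FLT3 = "chr13",  GNA11 = "chr19", GNAQ = "chr9",
    GNAS = "chr20", HNF1A = "chr12", HRAS = "chr11",  IDH1 = "chr2",
    JAK2 = "chr9",  JAK3 = "chr19",  KDR = "chr4",    KIT = "chr4",
    KRAS = "chr12", MET = "chr7",    MLH1 = "chr3",   MPL = "chr1",
    NOTCH1 = "chr9", NPM1 = "chr5",  NRAS = "chr1",   PDGFRA = "chr4",
    PIK3CA = "chr3", PTEN = "chr10", PTPN11 = "chr12", RB1 = "chr13",
    RET = "chr10",  SMAD4 = "chr18", SMARCB1 = "chr22", SMO = "chr7",
    SRC = "chr20",  STK11 = "chr19", TP53 = "chr17",  VHL = "chr3")

#' Default 48-gene, 212-amplicon panel
#'
#' A synthetic stand-in for a commercial hotspot cancer panel: 212
#' amplicons tiling 48 cancer-related genes, with EGFR covered by 8
#' amplicons and MET by 5 (the multi-amplicon genes that matter for the
#' copy-number workflow), the remaining 199 amplicons distributed over the
#' other 46 genes. Amplicon products are 175 bp with 24/24 bp primer
#' footprints; genomic coordinates are synthetic but chromosome
#' assignments are real, so within-chromosome normalization scenarios
#' (e.g. MET against EGFR/BRAF/SMO on chr7) are faithful.
#'
#' @param ampliconLength product length in bp.
#' @param primerLen primer footprint at each end in bp.
#' @return an \code{\linkS4class{AmpliconPanel}} with 212 amplicons and 48
#'   genes.
#' @export
defaultPanel <- function(ampliconLength = 175L, primerLen = 24L) {
    genes <- names(PANEL_GENES)
    nAmp <- stats::setNames(rep(4L, length(genes)), genes)
    nAmp["EGFR"] <- 8L
    nAmp["MET"] <- 5L
    # distribute the remainder to reach 212 amplicons
    extra <- 212L - sum(nAmp)
    others <- setdiff(genes, c("EGFR", "MET"))
    nAmp[others[seq_len(extra)]] <- nAmp[others[seq_len(extra)]] + 1L
    name <- unlist(lapply(genes, function(g)
        sprintf("%s_amp%02d", g, seq_len(nAmp[g]))))
    gene <- rep(genes, nAmp)
    # lay genes out on their chromosomes at non-overlapping synthetic loci
    geneIdx <- stats::setNames(seq_along(genes), genes)
    offsetWithinGene <- unlist(lapply(nAmp, seq_len)) - 1L
    start <- 1e6L + geneIdx[gene] * 100000L + offsetWithinGene * 400L
    ampliconPanel(name = name, chrom = unname(PANEL_GENES[gene]),
                  start = unname(start),
                  end = unname(start) + ampliconLength - 1L,
                  fwdPrimerLen = primerLen, revPrimerLen = primerLen,
                  gene = gene, strand = "+")
}

#' Locate the amplicons covering a genomic position
#'
#' @param panel an \code{AmpliconPanel}.
#' @param chrom chromosome name.
#' @param pos 1-based position.
#' @param insertOnly when \code{TRUE}, only amplicons whose primer-free
#'   insert covers the position are returned.
#' @return integer indices into \code{amplicons(panel)}.
#' @export
ampliconsAt <- function(panel, chrom, pos, insertOnly = FALSE) {
    gr <- if (insertOnly) insertRegions(panel) else amplicons(panel)
    which(as.character(GenomicRanges::seqnames(gr)) == chrom &
          GenomicRanges::start(gr) <= pos & GenomicRanges::end(gr) >= pos)
}
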