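#' @include utils.R
NULL

#' Write one sample's variant calls as VCF 4.2
#'
#' Emits biallelic records with genotype, allele frequency, depth and
#' per-strand alt read counts as FORMAT fields (\code{GT:AF:DP:ADF:ADR}).
#' Truth labels are never written here; they live in a sidecar TSV.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{af}, \code{depth}, \code{fwd_alt}, \code{rev_alt}.
#' @param path output path.
#' @param sampleId sample column name in the VCF.
#' @return \code{path}, invisibly usable in pipelines.
#' @export
writeSampleVcf <- function(variants, path, sampleId) {
    hdr <- c("##fileformat=VCFv4.2",
        "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
        paste0("##FORMAT=<ID=AF,Number=1,Type=Float,Description=",
               "\"Fraction of covering reads supporting the alt allele\">"),
        paste0("##FORMAT=<ID=DP,Number=1,Type=Integer,Description=",
               "\"Covering read depth\">"),
        paste0("##FORMAT=<ID=ADF,Number=1,Type=Integer,Description=",
               "\"Alt-supporting reads on the forward strand\">"),
        paste0("##FORMAT=<ID=ADR,Number=1,Type=Integer,Description=",
               "\"Alt-supporting reads on the reverse strand\">"),
        paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", sampleId, sep = "\t"))
    rows <- character(0)
    if (nrow(variants)) {
        o <- order(variants$chrom, variants$pos, variants$ref,
                   variants$alt)
        v <- variants[o, ]
        rows <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS",
                      ".", "GT:AF:DP:ADF:ADR",
                      sprintf("0/1:%.6g:%d:%d:%d", v$af,
                              as.integer(v$depth), as.integer(v$fwd_alt),
                              as.integer(v$rev_alt)),
                      sep = "\t")
    }
    writeLines(c(hdr, rows), path)
    path
}

#' Read one sample's variant calls from a VCF
#'
#' Parses a VCF via \pkg{VariantAnnotation} and returns the tabular
#' variant representation the QC and post-processing stages use.
#' Multi-allelic records are split into biallelic rows at ingestion.
#'
#' @param path VCF path.
#' @param sampleId sample id to record; defaults to the VCF sample column.
#' @return data.frame with \code{sample_id}, \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{af}, \code{depth}, \code{fwd_alt},
#'   \code{rev_alt}, \code{filter}.
#' @export
readSampleVcf <- function(path, sampleId = NULL) {
    vcf <- VariantAnnotation::readVcf(path)
    vcf <- VariantAnnotation::expand(vcf)     # split multi-allelic rows
    rr <- SummarizedExperiment::rowRanges(vcf)
    if (is.null(sampleId)) {
        sn <- colnames(vcf)
        sampleId <- if (length(sn)) sn[1] else
            sub("\\.vcf(\\.gz)?$", "", basename(path))
    }
    n <- length(rr)
    getFmt <- function(id, default) {
        g <- VariantAnnotation::geno(vcf)
        if (id %in% names(g)) as.vector(g[[id]][, 1]) else
            rep(default, n)
    }
    data.frame(sample_id = sampleId,
               chrom = as.character(GenomicRanges::seqnames(rr)),
               pos = GenomicRanges::start(rr),
               ref = as.character(VariantAnnotation::ref(vcf)),
               alt = as.character(VariantAnnotation::alt(vcf)),
               af = as.numeric(getFmt("AF", NA_real_)),
               depth = as.integer(getFmt("DP", NA_integer_)),
               fwd_alt = as.integer(getFmt("ADF", NA_integer_)),
               rev_alt = as.integer(getFmt("ADR", NA_integer_)),
               filter = as.character(rr$FILTER))
}

#' Read all per-sample VCFs of a directory
#'
#' @param dir directory of \code{.vcf} files, one per sample.
#' @return combined data.frame of variant calls.
#' @export
readVcfDir <- function(dir) {
    files <- sort(list.files(dir, pattern = "\\.vcf$", full.names = TRUE))
    if (!length(files)) stop("no .vcf files under ", dir)
    do.call(rbind, lapply(files, readSampleVcf))
}

#' Read an amplicon coverage matrix TSV
#'
#' The TSV has samples as rows (first column \code{sample_id}) and
#' amplicon names as columns. Amplicon gene and chromosome annotation is
#' joined from the panel. Samples with all-zero coverage are rejected.
#'
#' @param path coverage TSV path.
#' @param panel an \code{AmpliconPanel} naming the amplicons.
#' @return \code{SummarizedExperiment}, amplicons x samples.
#' @export
readCoverageMatrix <- function(path, panel) {
    df <- readTsv(path)
    ids <- df$sample_id
    m <- t(as.matrix(df[, setdiff(colnames(df), "sample_id"),
                        drop = FALSE]))
    colnames(m) <- ids
    if (any(colSums(m) == 0))
        stop("all-zero coverage for sample(s): ",
             paste(ids[colSums(m) == 0], collapse = ", "))
    mc <- S4Vectors::mcols(amplicons(panel))
    hit <- match(rownames(m), mc$name)
    if (anyNA(hit))
        stop("coverage columns not on the panel: ",
             paste(rownames(m)[is.na(hit)], collapse = ", "))
    SummarizedExperiment::SummarizedExperiment(
        assays = list(depth = m),
        rowData = S4Vectors::DataFrame(
            gene = mc$gene[hit],
            chrom = as.character(GenomicRanges::seqnames(
                amplicons(panel)))[hit]))
}

#' Read an offline germline annotation database fixture
#'
#' Tab-separated lookup with columns \code{chrom}, \code{pos}, \code{ref},
#' \code{alt}, \code{pop_freq} (population allele frequency),
#' \code{dbsnp} and \code{cosmic} (0/1 membership flags). No live
#' database queries are ever made.
#'
#' @param path TSV path.
#' @return data.frame lookup for \code{\link{discriminateGermline}}.
#' @export
readGermlineDb <- function(path) {
    db <- readTsv(path)
    need <- c("chrom", "pos", "ref", "alt", "pop_freq", "dbsnp", "cosmic")
    if (!all(need %in% colnames(db)))
        stop("germline db needs columns: ", paste(need, collapse = ", "))
    db
}

#' Read a curated variant table
#'
#' Reads a report-style variant table (columns \code{gene},
#' \code{hgvs_p}, \code{patient}, \code{histology}, \code{af_percent},
#' \code{impact}), such as the bundled fixture of published non-EGFR panel
#' findings, and returns it sorted by gene for report rendering.
#'
#' @param path TSV path.
#' @return data.frame sorted by gene then protein change.
#' @export
readCuratedTable <- function(path) {
    df <- readTsv(path)
    need <- c("gene", "hgvs_p", "patient", "histology", "af_percent",
              "impact")
    if (!all(need %in% colnames(df)))
        stop("curated table needs columns: ",
             paste(need, collapse = ", "))
    df[order(df$gene, df$hgvs_p), ]
}
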