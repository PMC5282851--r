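#' @include AllClasses.R
NULL

#' Accessors for panel and cohort objects
#'
#' \code{amplicons} returns the amplicon \code{GRanges} of a panel;
#' \code{panelGenes} the gene symbols; \code{geneChromosome} the named
#' gene-to-chromosome map; \code{insertRegions} the primer-free inserts;
#' \code{spectrumCounts} the class x bin count matrix of a
#' \code{SpectrumTable}; \code{cohortVariants}, \code{sampleSheet},
#' \code{readEvidence} and \code{coverageMatrix} the components of a
#' \code{SimulatedCohort}.
#'
#' @param x an \code{AmpliconPanel}, \code{SpectrumTable} or
#'   \code{SimulatedCohort}.
#' @return See the individual generic descriptions.
#' @name accessors
#' @aliases amplicons panelGenes geneChromosome spectrumCounts
#'   cohortVariants sampleSheet readEvidence coverageMatrix
NULL

#' @rdname accessors
#' @export
setGeneric("amplicons", function(x) standardGeneric("amplicons"))

#' @rdname accessors
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))

#' @rdname accessors
#' @export
setGeneric("geneChromosome", function(x) standardGeneric("geneChromosome"))

#' Primer-free insert regions of a panel or amplicon
#'
#' Returns the interval of each amplicon actually informative for variant
#' evidence: \code{[start + fwd_primer_len, end - rev_primer_len]}. Primer
#' footprints are synthesised oligo sequence and carry no independent
#' evidence, so downstream filtering excludes variants supported only by
#' primer bases.
#'
#' @param x an \code{AmpliconPanel}.
#' @return \code{GRanges} of inserts, parallel to \code{amplicons(x)}.
#' @export
setGeneric("insertRegions", function(x) standardGeneric("insertRegions"))

#' @rdname accessors
#' @export
setGeneric("spectrumCounts", function(x) standardGeneric("spectrumCounts"))

#' @rdname accessors
#' @export
setGeneric("cohortVariants", function(x) standardGeneric("cohortVariants"))

#' @rdname accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname accessors
#' @export
setGeneric("readEvidence", function(x) standardGeneric("readEvidence"))

#' @rdname accessors
#' @export
setGeneric("coverageMatrix", function(x) standardGeneric("coverageMatrix"))

setMethod("amplicons", "AmpliconPanel", function(x) x@amplicons)

setMethod("panelGenes", "AmpliconPanel",
          function(x) sort(unique(S4Vectors::mcols(x@amplicons)$gene)))

setMethod("geneChromosome", "AmpliconPanel", function(x) x@geneChrom)

setMethod("insertRegions", "AmpliconPanel", function(x) {
    gr <- x@amplicons
    mc <- S4Vectors::mcols(gr)
    ins <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(gr),
        ranges = IRanges::IRanges(
            start = GenomicRanges::start(gr) + mc$fwd_primer_len,
            end = GenomicRanges::end(gr) - mc$rev_primer_len),
        strand = GenomicRanges::strand(gr))
    S4Vectors::mcols(ins) <- mc[, c("name", "gene")]
    ins
})

setMethod("spectrumCounts", "SpectrumTable", function(x) x@counts)

setMethod("cohortVariants", "SimulatedCohort", function(x) x@variants)
setMethod("sampleSheet", "SimulatedCohort", function(x) x@sampleSheet)
setMethod("readEvidence", "SimulatedCohort", function(x) x@readEvidence)
setMethod("coverageMatrix", "SimulatedCohort", function(x) x@coverage)

setMethod("show", "AmpliconPanel", function(object) {
    gr <- object@amplicons
    cat("AmpliconPanel with", length(gr), "amplicons across",
        length(object@geneChrom), "genes\n")
    if (length(gr)) {
        w <- GenomicRanges::width(gr)
        cat("  amplicon length:", min(w), "-", max(w), "bp;",
            "chromosomes:", length(unique(as.character(
                GenomicRanges::seqnames(gr)))), "\n")
    }
})

setMethod("show", "TranscriptModel", function(object) {
    cat("TranscriptModel", object@gene, "(", object@proteinId, ")",
        length(object@sequence), "nt CDS on", object@strand, "strand",
        if (object@partial) "[partial]" else "", "\n")
})

setMethod("show", "SpectrumTable", function(object) {
    cat("SpectrumTable:", sum(object@counts), "variants in",
        ncol(object@counts), "AF bins",
        if (object@pooled) "(cohort-pooled)" else "(single sample)", "\n")
})

setMethod("show", "SimulatedCohort", function(object) {
    cat("SimulatedCohort:", nrow(object@sampleSheet), "samples,",
        nrow(object@variants), "variant calls,",
        nrow(SummarizedExperiment::assay(object@coverage)), "amplicons\n")
    tr <- table(object@variants$truth)
    if (length(tr))
        cat("  truth:", paste(names(tr), tr, sep = "=", collapse = ", "), "\n")
})
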