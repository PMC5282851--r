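#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAString
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom methods new validObject is slot
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges start end width seqnames strand
#' @importFrom IRanges IRanges
NULL

#' AmpliconPanel: a targeted amplicon panel with primer footprints
#'
#' Holds the amplicons of a PCR panel as a \code{GRanges} (1-based inclusive
#' genomic spans of the amplified products) with per-amplicon metadata
#' columns \code{name}, \code{gene}, \code{fwd_primer_len} and
#' \code{rev_primer_len}, plus the gene-to-chromosome map derived from the
#' manifest. Primer footprints at both ends of each amplicon carry no
#' independent sequence evidence; \code{\link{insertRegions}} returns the
#' primer-free inserts used for evidence counting.
#'
#' @slot amplicons \code{GRanges} of amplified products with metadata
#'   columns \code{name}, \code{gene}, \code{fwd_primer_len},
#'   \code{rev_primer_len}.
#' @slot geneChrom named \code{character}; chromosome of each gene symbol.
#' @export
setClass("AmpliconPanel",
    representation(amplicons = "GRanges", geneChrom = "character"))

setValidity("AmpliconPanel", function(object) {
    gr <- object@amplicons
    mc <- S4Vectors::mcols(gr)
    need <- c("name", "gene", "fwd_primer_len", "rev_primer_len")
    if (!all(need %in% colnames(mc)))
        return(paste("amplicons must carry metadata columns:",
                     paste(need, collapse = ", ")))
    if (length(gr) == 0L) return(TRUE)
    if (anyDuplicated(mc$name)) return("duplicate amplicon names")
    if (any(!nzchar(mc$gene)) || anyNA(mc$gene))
        return("every amplicon needs a non-empty gene symbol")
    if (any(mc$fwd_primer_len < 0) || any(mc$rev_primer_len < 0))
        return("primer lengths must be non-negative")
    if (any(mc$fwd_primer_len + mc$rev_primer_len >= GenomicRanges::width(gr)))
        return("primer footprints leave no insert (fwd + rev >= amplicon length)")
    if (!setequal(unique(mc$gene), names(object@geneChrom)))
        return("geneChrom must map exactly the genes present on the panel")
    chrom <- as.character(GenomicRanges::seqnames(gr))
    if (any(object@geneChrom[mc$gene] != chrom))
        return("amplicon chromosome inconsistent with its gene's chromosome")
    TRUE
})

#' TranscriptModel: a minimal coding transcript for protein annotation
#'
#' A per-gene transcript reduced to what consequence annotation needs: the
#' ordered CDS intervals in genomic coordinates, the spliced
#' strand-oriented coding sequence, and the protein accession used in
#' reports. Reverse-strand models store the already reverse-complemented
#' coding sequence; genomic variants are mapped through the CDS intervals.
#'
#' @slot gene gene symbol.
#' @slot proteinId protein accession reported in HGVS output.
#' @slot cds \code{GRanges} of CDS intervals, ordered 5' to 3' in
#'   transcription direction.
#' @slot sequence \code{DNAString} spliced coding sequence (sense strand of
#'   the transcript).
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot partial \code{TRUE} when the CDS length is not a multiple of 3 or
#'   the sequence lacks a start codon; translation is then best-effort.
#' @export
setClass("TranscriptModel",
    representation(gene = "character", proteinId = "character",
                   cds = "GRanges", sequence = "DNAString",
                   strand = "character", partial = "logical"))

setValidity("TranscriptModel", function(object) {
    if (!object@strand %in% c("+", "-")) return("strand must be '+' or '-'")
    if (length(object@sequence) != sum(GenomicRanges::width(object@cds)))
        return("sequence length must equal total CDS width")
    if (length(object@sequence) %% 3L != 0L && !object@partial)
        return("CDS length not divisible by 3 requires partial = TRUE")
    TRUE
})

#' SpectrumTable: mutation counts by substitution class and AF bin
#'
#' Cross-classification of variant calls by raw substitution class (the 12
#' strand-specific single-nucleotide classes plus \code{mnv} and
#' \code{indel}) and half-open allele-frequency bin \code{(low, high]}.
#' The strand-symmetric 6-class view (e.g. \code{C:G>T:A}) is derived on
#' demand by \code{\link{collapseSpectrum}}, never stored.
#'
#' @slot counts integer matrix, classes x bins.
#' @slot binEdges ordered numeric AF bin edges spanning (0, 1].
#' @slot pooled \code{TRUE} for a cohort-pooled table, \code{FALSE} for a
#'   single sample.
#' @export
setClass("SpectrumTable",
    representation(counts = "matrix", binEdges = "numeric",
                   pooled = "logical"))

setValidity("SpectrumTable", function(object) {
    if (any(object@counts < 0)) return("negative counts")
    if (is.unsorted(object@binEdges, strictly = TRUE))
        return("bin edges must be strictly increasing")
    if (ncol(object@counts) != length(object@binEdges) - 1L)
        return("counts columns must match bins")
    TRUE
})

#' SimulationConfig: study conditions for the synthetic cohort generator
#'
#' Bundles every parameter of \code{\link{simulateCohort}}. Defaults encode
#' the cohort structure reported for FFPE amplicon panels: per-sample
#' artifact burden with negative-binomial counts whose mean falls
#' log-linearly with pre-normalization library concentration, a
#' C:G>T:A-dominated substitution spectrum, a low-AF artifact component on
#' (0, 0.10], and an additional 9--20\% AF artifact regime restricted to
#' degraded samples below a concentration trigger.
#'
#' @slot nSamples number of samples.
#' @slot concentrations pre-normalization library concentrations (ng/ul).
#' @slot lambdaA,lambdaB parameters of the artifact-rate model
#'   \eqn{\lambda(c) = \exp(a - b \log c)}.
#' @slot dispersion negative-binomial size parameter for artifact counts.
#' @slot spectrumWeights probability over the 12 raw substitution classes.
#' @slot lowAFShape Beta(shape1, shape2) of the low-AF artifact component.
#' @slot lowAFMax truncation point of the low-AF component (default 0.10).
#' @slot highAFTrigger concentration (ng/ul) below which the high-AF
#'   artifact regime is active.
#' @slot highAFShape Beta shape parameters of the high-AF component before
#'   rescaling.
#' @slot highAFRange AF interval the high-AF component is rescaled onto.
#' @slot highAFMean mean count of high-AF artifacts in a degraded sample.
#' @slot highAFDispersion negative-binomial size for high-AF counts.
#' @slot trueVariants data.frame of planted non-artifact variants
#'   (sample_id, gene, chrom, pos, ref, alt, af, origin).
#' @slot compoundEvents data.frame of phased variant pairs
#'   (sample_id, pos_a, ref_a, alt_a, pos_b, ref_b, alt_b, shared_fraction).
#' @slot cnvEvents data.frame of gene amplifications (sample_id, gene, fold).
#' @slot coverageSigma lognormal sigma of amplicon bias and depth noise.
#' @slot meanDepth target mean per-amplicon coverage depth.
#' @slot dropoutProb probability an amplicon drops out in a sample.
#' @slot seed integer seed; all randomness in a cohort flows from it.
#' @export
setClass("SimulationConfig",
    representation(nSamples = "integer", concentrations = "numeric",
                   lambdaA = "numeric", lambdaB = "numeric",
                   dispersion = "numeric", spectrumWeights = "numeric",
                   lowAFShape = "numeric", lowAFMax = "numeric",
                   highAFTrigger = "numeric", highAFShape = "numeric",
                   highAFRange = "numeric", highAFMean = "numeric",
                   highAFDispersion = "numeric",
                   trueVariants = "data.frame",
                   compoundEvents = "data.frame", cnvEvents = "data.frame",
                   coverageSigma = "numeric", meanDepth = "numeric",
                   dropoutProb = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    if (object@nSamples < 2L) return("need at least 2 samples")
    if (length(object@concentrations) != object@nSamples)
        return("one concentration per sample required")
    if (any(object@concentrations <= 0)) return("concentrations must be > 0")
    if (abs(sum(object@spectrumWeights) - 1) > 1e-9)
        return("spectrumWeights must sum to 1")
    if (length(object@spectrumWeights) != 12L)
        return("spectrumWeights must cover the 12 raw substitution classes")
    if (object@lowAFMax <= 0 || object@lowAFMax > 1)
        return("lowAFMax must lie in (0, 1]")
    if (nrow(object@trueVariants) &&
        (any(object@trueVariants$af <= 0) || any(object@trueVariants$af > 1)))
        return("true variant AFs must lie in (0, 1]")
    TRUE
})

#' SimulatedCohort: a synthetic FFPE panel cohort with ground truth
#'
#' Output of \code{\link{simulateCohort}}: the variant calls with truth
#' labels, the per-pair read co-occurrence evidence, the amplicon coverage
#' matrix as a \code{SummarizedExperiment} (amplicons x samples, amplicon
#' gene and chromosome in \code{rowData}), the sample sheet, the panel
#' simulated against, and the generating configuration.
#'
#' @slot variants data.frame of variant calls plus a \code{truth} column
#'   (\code{artifact}, \code{somatic}, \code{germline}); the truth column
#'   is written to a sidecar file, never to the VCFs.
#' @slot readEvidence data.frame of per-read joint observation counts for
#'   configured variant pairs.
#' @slot coverage \code{SummarizedExperiment} of depths.
#' @slot sampleSheet data.frame (sample_id, pre_norm_conc, total_reads).
#' @slot panel the \code{AmpliconPanel} used.
#' @slot config the generating \code{SimulationConfig}.
#' @export
setClass("SimulatedCohort",
    representation(variants = "data.frame", readEvidence = "data.frame",
                   coverage = "SummarizedExperiment",
                   sampleSheet = "data.frame", panel = "AmpliconPanel",
                   config = "SimulationConfig"))

setValidity("SimulatedCohort", function(object) {
    v <- object@variants
    if (nrow(v) && !all(v$sample_id %in% object@sampleSheet$sample_id))
        return("every variant's sample must exist in the sample sheet")
    dep <- SummarizedExperiment::assay(object@coverage)
    if (any(dep < 0) || any(dep != round(dep)))
        return("coverage must be non-negative integers")
    TRUE
})
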