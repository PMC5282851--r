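#' @include AllClasses.R panel.R qc.R
NULL

#' Build a SimulationConfig
#'
#' Constructs the study conditions for \code{\link{simulateCohort}}. The
#' defaults emulate a 26-sample FFPE amplicon-panel cohort: four samples
#' with pre-normalization library concentrations of 1.0--1.3 ng/ul
#' (degraded input) and the rest spread from 1.9 to 30 ng/ul; expected
#' artifact count falling log-linearly with concentration
#' (\eqn{\lambda(c) = e^{a} c^{-b}}, defaults giving a cohort total of
#' roughly 3000--3500 low-AF artifact calls); a substitution spectrum
#' placing 0.44 mass jointly on C>T and G>A; artifact AFs from
#' Beta(1.2, 30) truncated to (0, 0.10]; and, only in samples below the
#' 1.5 ng/ul trigger, an extra artifact component with AFs rescaled from
#' Beta(2, 2) onto 9--20\%.
#'
#' @param nSamples number of samples.
#' @param concentrations per-sample concentrations (ng/ul).
#' @param lambdaA,lambdaB artifact-rate parameters (see above).
#' @param dispersion negative-binomial size of artifact counts.
#' @param spectrumWeights named probability vector over the 12 raw
#'   substitution classes.
#' @param lowAFShape,lowAFMax truncated-Beta low-AF component.
#' @param highAFTrigger,highAFShape,highAFRange,highAFMean,highAFDispersion
#'   high-AF artifact regime of degraded samples.
#' @param trueVariants,compoundEvents,cnvEvents planted non-artifact
#'   events (see \code{\linkS4class{SimulationConfig}}).
#' @param coverageSigma,meanDepth,dropoutProb coverage model.
#' @param seed integer seed driving all randomness.
#' @return a \code{\linkS4class{SimulationConfig}}.
#' @export
simulationConfig <- function(nSamples = 26L,
        concentrations = NULL,
        lambdaA = log(400), lambdaB = 0.8, dispersion = 8,
        spectrumWeights = NULL,
        lowAFShape = c(1.2, 30), lowAFMax = 0.10,
        highAFTrigger = 1.5, highAFShape = c(2, 2),
        highAFRange = c(0.09, 0.20), highAFMean = 30,
        highAFDispersion = 3,
        trueVariants = emptyTrueVariants(),
        compoundEvents = emptyCompoundEvents(),
        cnvEvents = emptyCnvEvents(),
        coverageSigma = 0.15, meanDepth = 2000, dropoutProb = 0.005,
        seed = 1L) {
    nSamples <- as.integer(nSamples)
    if (is.null(concentrations)) {
        if (nSamples < 5L)
            stop("supply concentrations explicitly for nSamples < 5")
        concentrations <- c(1.0, 1.0, 1.3, 1.3,
            exp(seq(log(1.9), log(30), length.out = nSamples - 4L)))
    }
    if (is.null(spectrumWeights)) {
        spectrumWeights <- stats::setNames(rep(0.56 / 10, 12L),
                                           SUB_CLASSES)
        spectrumWeights[c("C>T", "G>A")] <- 0.22
    }
    methods::new("SimulationConfig", nSamples = nSamples,
        concentrations = concentrations, lambdaA = lambdaA,
        lambdaB = lambdaB, dispersion = dispersion,
        spectrumWeights = spectrumWeights, lowAFShape = lowAFShape,
        lowAFMax = lowAFMax, highAFTrigger = highAFTrigger,
        highAFShape = highAFShape, highAFRange = highAFRange,
        highAFMean = highAFMean, highAFDispersion = highAFDispersion,
        trueVariants = trueVariants, compoundEvents = compoundEvents,
        cnvEvents = cnvEvents, coverageSigma = coverageSigma,
        meanDepth = meanDepth, dropoutProb = dropoutProb,
        seed = as.integer(seed))
}

emptyTrueVariants <- function() {
    data.frame(sample_id = character(), gene = character(),
               chrom = character(), pos = integer(), ref = character(),
               alt = character(), af = numeric(), origin = character())
}

emptyCompoundEvents <- function() {
    data.frame(sample_id = character(), chrom = character(),
               pos_a = integer(), ref_a = character(), alt_a = character(),
               pos_b = integer(), ref_b = character(), alt_b = character(),
               af = numeric(), shared_fraction = numeric())
}

emptyCnvEvents <- function() {
    data.frame(sample_id = character(), gene = character(),
               fold = numeric())
}

# expected artifact count at concentration c
lambdaAt <- function(config, conc) {
    exp(config@lambdaA - config@lambdaB * log(conc))
}

# AF draws from the truncated low-AF Beta component (inverse-CDF)
drawLowAF <- function(n, shape, max) {
    ptr <- stats::pbeta(max, shape[1], shape[2])
    stats::qbeta(stats::runif(n) * ptr, shape[1], shape[2])
}

# per-variant read support given a true AF
drawSupport <- function(n, afTrue, meanDepth) {
    depth <- pmax(50L, stats::rnbinom(n, mu = meanDepth, size = 20))
    alt <- pmax(1L, stats::rbinom(n, depth, afTrue))
    fwd <- stats::rbinom(n, alt, 0.5)
    data.frame(depth = depth, af = alt / depth, fwd_alt = fwd,
               rev_alt = alt - fwd)
}

# random artifact loci on the panel's primer-free inserts; insertInfo
# precomputes the plain-vector view of insertRegions() once per cohort
insertInfo <- function(panel) {
    ins <- insertRegions(panel)
    list(start = GenomicRanges::start(ins),
         width = GenomicRanges::width(ins),
         chrom = as.character(GenomicRanges::seqnames(ins)),
         gene = S4Vectors::mcols(ins)$gene,
         name = S4Vectors::mcols(ins)$name)
}

drawArtifactLoci <- function(n, info) {
    idx <- sample.int(length(info$start), n, replace = TRUE)
    pos <- info$start[idx] + floor(stats::runif(n) * info$width[idx])
    list(chrom = info$chrom[idx], pos = as.integer(pos),
         gene = info$gene[idx], amplicon = info$name[idx])
}

#' Simulate a synthetic FFPE amplicon-panel cohort
#'
#' Generates, deterministically for a given config (all draws flow from
#' the single seed), a cohort of variant calls with ground-truth labels,
#' per-pair read co-occurrence evidence, an amplicon coverage matrix, and
#' a sample sheet. Per-sample low-AF artifact counts are negative-binomial
#' with mean \eqn{\lambda(c)}; each artifact gets a substitution class
#' from the spectrum weights, an AF from the truncated low-AF Beta, and a
#' random locus on a primer-free insert. Samples below the concentration
#' trigger additionally receive the 9--20\% AF artifact component.
#' Planted true variants, phased compound events and gene amplifications
#' come from the config.
#'
#' @param config a \code{\linkS4class{SimulationConfig}}.
#' @param panel the \code{AmpliconPanel} to simulate against.
#' @return a \code{\linkS4class{SimulatedCohort}}.
#' @examples
#' cfg <- simulationConfig(seed = 7)
#' cohort <- simulateCohort(cfg)
#' cohort
#' @export
simulateCohort <- function(config, panel = defaultPanel()) {
    methods::validObject(config)
    if (config@nSamples < 2L) stop("need at least 2 samples")
    set.seed(config@seed)
    ids <- sprintf("S%02d", seq_len(config@nSamples))
    conc <- config@concentrations
    lam <- lambdaAt(config, conc)
    nLow <- stats::rnbinom(config@nSamples, mu = lam,
                           size = config@dispersion)
    degradedIdx <- which(conc < config@highAFTrigger)
    nHigh <- integer(config@nSamples)
    if (length(degradedIdx))
        nHigh[degradedIdx] <- pmax(2L, stats::rnbinom(length(degradedIdx),
            mu = config@highAFMean, size = config@highAFDispersion))

    classes <- names(config@spectrumWeights)
    refOf <- substr(classes, 1L, 1L)
    altOf <- substr(classes, 3L, 3L)

    # one vectorized block over all samples (per-variant draws are iid
    # given the per-sample counts, so pooling preserves the model)
    nTot <- nLow + nHigh
    n <- sum(nTot)
    if (n > 0L) {
        sampleOf <- rep(ids, nTot)
        isHigh <- unlist(lapply(seq_len(config@nSamples), function(i)
            rep(c(FALSE, TRUE), c(nLow[i], nHigh[i]))),
            use.names = FALSE)
        cls <- sample.int(length(classes), n, replace = TRUE,
                          prob = config@spectrumWeights)
        afTrue <- numeric(n)
        afTrue[!isHigh] <- drawLowAF(sum(!isHigh), config@lowAFShape,
                                     config@lowAFMax)
        afTrue[isHigh] <- config@highAFRange[1] +
            diff(config@highAFRange) *
            stats::rbeta(sum(isHigh), config@highAFShape[1],
                         config@highAFShape[2])
        loci <- drawArtifactLoci(n, insertInfo(panel))
        sup <- drawSupport(n, afTrue, config@meanDepth)
        variants <- data.frame(sample_id = sampleOf, chrom = loci$chrom,
                   pos = loci$pos, ref = refOf[cls], alt = altOf[cls],
                   af = sup$af, depth = sup$depth,
                   fwd_alt = sup$fwd_alt, rev_alt = sup$rev_alt,
                   gene = loci$gene, amplicon = loci$amplicon,
                   truth = "artifact")
    } else {
        variants <- data.frame(sample_id = character(),
            chrom = character(), pos = integer(), ref = character(),
            alt = character(), af = numeric(), depth = integer(),
            fwd_alt = integer(), rev_alt = integer(), gene = character(),
            amplicon = character(), truth = character())
    }

    tv <- config@trueVariants
    if (nrow(tv)) {
        if (!all(tv$sample_id %in% ids))
            stop("trueVariants reference unknown samples")
        sup <- drawSupport(nrow(tv), tv$af, config@meanDepth)
        amp <- vapply(seq_len(nrow(tv)), function(j) {
            hit <- ampliconsAt(panel, tv$chrom[j], tv$pos[j],
                               insertOnly = TRUE)
            if (length(hit)) S4Vectors::mcols(amplicons(panel))$name[hit[1]]
            else NA_character_
        }, character(1))
        variants <- rbind(variants, data.frame(
            sample_id = tv$sample_id, chrom = tv$chrom, pos = tv$pos,
            ref = tv$ref, alt = tv$alt, af = sup$af, depth = sup$depth,
            fwd_alt = sup$fwd_alt, rev_alt = sup$rev_alt,
            gene = tv$gene, amplicon = amp, truth = tv$origin))
    }
    variants <- variants[order(variants$sample_id, variants$chrom,
                               variants$pos), ]
    rownames(variants) <- NULL

    coverage <- simulateCoverage(config, panel, ids = ids,
                                 useSeed = FALSE)
    sheet <- data.frame(sample_id = ids, pre_norm_conc = conc,
                        total_reads = unname(colSums(
                            SummarizedExperiment::assay(coverage))))
    cohort <- methods::new("SimulatedCohort", variants = variants,
        readEvidence = data.frame(variant_a = character(),
            variant_b = character(), sample_id = character(),
            n_both = integer(), n_a_only = integer(),
            n_b_only = integer(), n_neither = integer()),
        coverage = coverage, sampleSheet = sheet, panel = panel,
        config = config)

    ce <- config@compoundEvents
    for (j in seq_len(nrow(ce))) {
        pair <- data.frame(
            sample_id = ce$sample_id[j], chrom = ce$chrom[j],
            pos = c(ce$pos_a[j], ce$pos_b[j]),
            ref = c(ce$ref_a[j], ce$ref_b[j]),
            alt = c(ce$alt_a[j], ce$alt_b[j]),
            af = ce$af[j])
        cohort <- injectCompoundVariant(cohort, pair,
            sharedFraction = ce$shared_fraction[j], seed = NULL)
    }
    cohort
}

#' Inject a phased compound-variant pair with read evidence
#'
#' Adds (or locates) two variant calls on the same amplicon insert of one
#' sample and records their per-read joint observation counts. A
#' \code{sharedFraction} of 1 reproduces the fully phased case where every
#' mutant read carries both variants; intermediate fractions draw the
#' jointly-mutant read count binomially.
#'
#' @param cohort a \code{SimulatedCohort}.
#' @param pair data.frame of two rows (\code{sample_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{af}).
#' @param sharedFraction proportion of mutant reads carrying both
#'   variants.
#' @param seed integer to seed the draw; \code{NULL} continues the
#'   current RNG stream (used internally by \code{simulateCohort}).
#' @return the updated \code{SimulatedCohort}.
#' @export
injectCompoundVariant <- function(cohort, pair, sharedFraction,
                                  seed = NULL) {
    stopifnot(nrow(pair) == 2L, sharedFraction >= 0, sharedFraction <= 1)
    if (length(unique(pair$sample_id)) != 1L)
        stop("both variants must belong to one sample")
    if (!is.null(seed)) set.seed(seed)
    ampA <- ampliconsAt(cohort@panel, pair$chrom[1], pair$pos[1],
                        insertOnly = TRUE)
    ampB <- ampliconsAt(cohort@panel, pair$chrom[2], pair$pos[2],
                        insertOnly = TRUE)
    if (!length(intersect(ampA, ampB)))
        stop("variants lie on different amplicons")
    cfg <- cohort@config
    sup <- drawSupport(2L, rep(pair$af[1], 2L), cfg@meanDepth)
    # same molecule: both variants observed on a shared read population
    depth <- sup$depth[1]
    nMut <- pmax(1L, stats::rbinom(1L, depth, pair$af[1]))
    nBoth <- stats::rbinom(1L, nMut, sharedFraction)
    newRows <- data.frame(
        sample_id = pair$sample_id, chrom = pair$chrom, pos = pair$pos,
        ref = pair$ref, alt = pair$alt, af = nMut / depth, depth = depth,
        fwd_alt = stats::rbinom(2L, nMut, 0.5), rev_alt = 0L,
        gene = S4Vectors::mcols(amplicons(cohort@panel))$gene[ampA[1]],
        amplicon = S4Vectors::mcols(amplicons(cohort@panel))$name[ampA[1]],
        truth = "somatic")
    newRows$rev_alt <- nMut - newRows$fwd_alt
    key <- paste(newRows$chrom, newRows$pos, newRows$ref, newRows$alt,
                 sep = ":")
    ev <- data.frame(variant_a = key[1], variant_b = key[2],
                     sample_id = pair$sample_id[1],
                     n_both = nBoth, n_a_only = nMut - nBoth,
                     n_b_only = nMut - nBoth,
                     n_neither = max(0L, depth - 2L * nMut + nBoth))
    cohort@variants <- rbind(cohort@variants, newRows)
    cohort@readEvidence <- rbind(cohort@readEvidence, ev)
    methods::validObject(cohort)
    cohort
}

#' Simulate an amplicon coverage matrix
#'
#' Depth of sample \eqn{s} at amplicon \eqn{a} is
#' \code{round(meanDepth * bias_a * fold * noise)}, with a lognormal
#' per-amplicon bias and per-cell noise (both sigma =
#' \code{coverageSigma}), the gene fold from any configured amplification
#' event, and amplicon drop-out (zeroed) with the configured probability.
#' With sigma = 0, no events and no drop-out the matrix is constant.
#'
#' @param config a \code{SimulationConfig}.
#' @param panel the \code{AmpliconPanel}.
#' @param ids sample ids (defaults to S01..).
#' @param useSeed seed the RNG from the config (standalone use); the
#'   cohort generator passes \code{FALSE} to stay in its stream.
#' @return \code{SummarizedExperiment}, amplicons x samples, assay
#'   \code{"depth"}, \code{rowData} columns \code{gene} and \code{chrom}.
#' @export
simulateCoverage <- function(config, panel = defaultPanel(), ids = NULL,
                             useSeed = TRUE) {
    if (useSeed) set.seed(config@seed)
    if (is.null(ids)) ids <- sprintf("S%02d", seq_len(config@nSamples))
    ev <- config@cnvEvents
    if (nrow(ev)) {
        if (any(ev$fold <= 0)) stop("amplification fold must be > 0")
        if (!all(ev$gene %in% panelGenes(panel)))
            stop("cnvEvents reference genes absent from the panel")
    }
    gr <- amplicons(panel)
    nA <- length(gr); nS <- length(ids)
    genes <- S4Vectors::mcols(gr)$gene
    sigma <- config@coverageSigma
    bias <- if (sigma > 0) stats::rlnorm(nA, 0, sigma) else rep(1, nA)
    fold <- matrix(1, nA, nS)
    for (j in seq_len(nrow(ev))) {
        s <- match(ev$sample_id[j], ids)
        if (is.na(s)) stop("cnvEvents reference unknown sample ",
                           ev$sample_id[j])
        fold[genes == ev$gene[j], s] <- ev$fold[j]
    }
    noise <- if (sigma > 0)
        matrix(stats::rlnorm(nA * nS, 0, sigma), nA, nS)
    else matrix(1, nA, nS)
    depth <- round(config@meanDepth * bias * fold * noise)
    if (config@dropoutProb > 0)
        depth[matrix(stats::runif(nA * nS) < config@dropoutProb,
                     nA, nS)] <- 0
    dimnames(depth) <- list(S4Vectors::mcols(gr)$name, ids)
    SummarizedExperiment::SummarizedExperiment(
        assays = list(depth = depth),
        rowData = S4Vectors::DataFrame(
            gene = genes,
            chrom = as.character(GenomicRanges::seqnames(gr))))
}

#' Write a simulated cohort to disk
#'
#' Emits the formats the pipeline stages consume: one VCF 4.2 per sample
#' (AF and per-strand depths as FORMAT fields), a sample sheet TSV, the
#' coverage matrix TSV (rows samples, columns amplicons), the read
#' co-occurrence evidence TSV, and the ground-truth labels as a sidecar
#' TSV that is never written into the VCFs.
#'
#' @param cohort a \code{SimulatedCohort}.
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of written paths.
#' @export
writeCohort <- function(cohort, outdir) {
    dir.create(file.path(outdir, "vcf"), recursive = TRUE,
               showWarnings = FALSE)
    v <- cohort@variants
    vcfPaths <- vapply(cohort@sampleSheet$sample_id, function(s) {
        writeSampleVcf(v[v$sample_id == s, , drop = FALSE],
                       file.path(outdir, "vcf", paste0(s, ".vcf")), s)
    }, character(1))
    sheetPath <- writeTsv(cohort@sampleSheet,
                          file.path(outdir, "sample_sheet.tsv"))
    dep <- SummarizedExperiment::assay(cohort@coverage)
    covPath <- writeTsv(
        data.frame(sample_id = colnames(dep), t(dep),
                   check.names = FALSE),
        file.path(outdir, "coverage.tsv"))
    truthPath <- writeTsv(v[, c("sample_id", "chrom", "pos", "ref",
                                "alt", "truth")],
                          file.path(outdir, "truth_labels.tsv"))
    evPath <- writeTsv(cohort@readEvidence,
                       file.path(outdir, "read_evidence.tsv"))
    invisible(list(vcf = vcfPaths, sample_sheet = sheetPath,
                   coverage = covPath, truth = truthPath,
                   evidence = evPath))
}
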