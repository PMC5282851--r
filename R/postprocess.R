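#' @include panel.R
NULL

#' Exclude variants supported only by primer footprints
#'
#' Amplicon primers are synthesised oligos: bases under a primer reflect
#' the primer sequence, not the template, so a call located only within
#' primer footprints carries no evidence. A variant is retained when at
#' least one covering amplicon's primer-free insert contains it (a primer
#' position of one amplicon may be honest insert of an overlapping
#' amplicon). Variants covered by no amplicon at all are routed to the
#' off-target log rather than treated as errors.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}.
#' @param panel an \code{AmpliconPanel}.
#' @return list with \code{kept}, \code{primerOnly} and \code{offTarget}
#'   data.frames.
#' @export
excludePrimerEvidence <- function(variants, panel) {
    if (!nrow(variants))
        return(list(kept = variants, primerOnly = variants,
                    offTarget = variants))
    vr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos,
                                                  variants$pos))
    # off-target chromosomes are expected; silence the seqlevel merge note
    onAmp <- suppressWarnings(GenomicRanges::countOverlaps(
        vr, amplicons(panel), ignore.strand = TRUE)) > 0
    onIns <- suppressWarnings(GenomicRanges::countOverlaps(
        vr, insertRegions(panel), ignore.strand = TRUE)) > 0
    list(kept = variants[onIns, , drop = FALSE],
         primerOnly = variants[onAmp & !onIns, , drop = FALSE],
         offTarget = variants[!onAmp, , drop = FALSE])
}

#' Assign panel genes to variant calls by position
#'
#' @param variants data.frame with \code{chrom}, \code{pos}.
#' @param panel an \code{AmpliconPanel}.
#' @return \code{variants} with a \code{gene} column (\code{NA} for
#'   off-target positions).
#' @export
assignGenes <- function(variants, panel) {
    gr <- amplicons(panel)
    vr <- GenomicRanges::GRanges(variants$chrom,
                                 IRanges::IRanges(variants$pos,
                                                  variants$pos))
    hit <- suppressWarnings(GenomicRanges::findOverlaps(
        vr, gr, ignore.strand = TRUE, select = "first"))
    variants$gene <- S4Vectors::mcols(gr)$gene[hit]
    variants
}

#' Build a recurrent-artifact blacklist from a cohort
#'
#' Systematic FFPE/panel artifacts recur at the same site across samples
#' at low allele frequency. A site (chrom, pos, ref, alt) enters the
#' blacklist when observed in at least \code{minSampleFraction} of cohort
#' samples with median AF below \code{maxMedianAF}. Recurrent sites with
#' high median AF are not artifacts but common-germline candidates: they
#' are excluded from the blacklist and flagged for germline
#' discrimination instead.
#'
#' @param variants cohort variant calls.
#' @param nSamples number of samples in the cohort (>= 3).
#' @param minSampleFraction recurrence threshold as a fraction of cohort
#'   samples (the required sample count is the rounded fraction).
#' @param maxMedianAF median-AF ceiling for blacklisting.
#' @return data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{n_samples}, \code{median_af}, \code{blacklisted},
#'   \code{germline_candidate}; blacklist membership is invariant to
#'   sample and record order.
#' @export
buildBlacklist <- function(variants, nSamples,
                           minSampleFraction = 0.4, maxMedianAF = 0.10) {
    if (nSamples < 3L) stop("need >= 3 samples to define recurrence")
    key <- variantKey(variants)
    nSeen <- vapply(split(variants$sample_id, key), function(s)
        length(unique(s)), integer(1))
    medAF <- vapply(split(variants$af, key), stats::median, numeric(1))
    k <- sort(unique(key))
    parts <- do.call(rbind, strsplit(k, ":", fixed = TRUE))
    need <- max(2L, round(minSampleFraction * nSamples))
    recurrent <- nSeen[k] >= need
    out <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                      ref = parts[, 3], alt = parts[, 4],
                      n_samples = unname(nSeen[k]),
                      median_af = unname(medAF[k]),
                      blacklisted = unname(recurrent &
                                           medAF[k] < maxMedianAF),
                      germline_candidate = unname(recurrent &
                                                  medAF[k] >= maxMedianAF))
    rownames(out) <- NULL
    out
}

#' Discriminate germline from somatic variants
#'
#' Rule-based origin call from an offline population-frequency /
#' database-membership lookup: population frequency >= 0.01 is called
#' germline; a COSMIC member with population frequency < 0.001 is called
#' somatic; everything else -- including borderline population
#' frequencies around 0.5\% whose nature published reports resolve only by
#' judgment -- is surfaced as ambiguous rather than auto-resolved.
#' Variants absent from the lookup are treated as frequency 0.
#'
#' @param variants data.frame with \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @param db lookup from \code{\link{readGermlineDb}}.
#' @param germlineFreq population frequency above which a variant is
#'   germline.
#' @param somaticFreq population frequency below which a COSMIC member is
#'   somatic.
#' @return \code{variants} with added columns \code{pop_freq},
#'   \code{dbsnp}, \code{cosmic}, \code{origin}.
#' @export
discriminateGermline <- function(variants, db, germlineFreq = 0.01,
                                 somaticFreq = 0.001) {
    hit <- match(variantKey(variants), variantKey(db))
    popFreq <- ifelse(is.na(hit), 0, db$pop_freq[hit])
    dbsnp <- !is.na(hit) & db$dbsnp[hit] > 0
    cosmic <- !is.na(hit) & db$cosmic[hit] > 0
    origin <- ifelse(popFreq >= germlineFreq, "germline",
               ifelse(cosmic & popFreq < somaticFreq, "somatic",
                      "ambiguous"))
    variants$pop_freq <- popFreq
    variants$dbsnp <- dbsnp
    variants$cosmic <- cosmic
    variants$origin <- origin
    variants
}

#' Shared-read fraction of a variant pair
#'
#' From per-read joint observation counts, the fraction of mutant reads
#' carrying both variants:
#' \code{n_both / (n_both + n_a_only + n_b_only)}. The pair is phased when
#' the fraction reaches the threshold; a zero denominator leaves the
#' fraction undefined and the pair unphased.
#'
#' @param counts one-row data.frame (or list) with \code{n_both},
#'   \code{n_a_only}, \code{n_b_only}.
#' @param threshold minimum shared fraction to declare the pair phased.
#' @return list with \code{fraction} and \code{phased}.
#' @export
phaseFraction <- function(counts, threshold = 0.9) {
    denom <- counts$n_both + counts$n_a_only + counts$n_b_only
    if (denom <= 0)
        return(list(fraction = NA_real_, phased = FALSE))
    frac <- counts$n_both / denom
    list(fraction = frac, phased = frac >= threshold)
}

#' Flag indels whose strand bias is a read-geometry artifact
#'
#' An insertion or deletion lying close to an amplicon end can only be
#' spanned by one read orientation: reads from the near end terminate
#' inside the variant at final sequencing cycles, so their alignments
#' either stop or get soft-clipped, and all variant support comes from
#' the other orientation. Such calls fail naive strand-bias filters for
#' purely geometric reasons. The flag is raised when, for either amplicon
#' end, the distance \eqn{d} from that end satisfies \eqn{d <}
#' \code{readLength} and \eqn{d + L >} \code{readLength - margin} (with
#' \eqn{L} the inserted/deleted length), i.e. a read starting at that end
#' runs out inside the variant. Flagged calls are exempted from
#' strand-bias filtering and marked for realignment review.
#'
#' @param variant one-row data.frame with \code{pos}, \code{ref},
#'   \code{alt}.
#' @param amplicon one amplicon of the panel as a one-row subset of
#'   \code{amplicons(panel)}, or a list with \code{start}, \code{end}.
#' @param readLength sequencing read length in bases.
#' @param margin bases of slack at the read end (alignment of a read
#'   ending just past a variant is still unreliable).
#' @return \code{TRUE} when the call should be rescued.
#' @export
strandBiasRescue <- function(variant, amplicon, readLength = 150L,
                             margin = 20L) {
    len <- abs(nchar(variant$alt) - nchar(variant$ref))
    if (len == 0L) return(FALSE)            # SNVs are never rescued
    aStart <- if (methods::is(amplicon, "GRanges"))
        GenomicRanges::start(amplicon) else amplicon$start
    aEnd <- if (methods::is(amplicon, "GRanges"))
        GenomicRanges::end(amplicon) else amplicon$end
    d5 <- variant$pos - aStart
    d3 <- aEnd - variant$pos
    rescue <- function(d) d < readLength & d + len > readLength - margin
    isTRUE(rescue(d5) || rescue(d3))
}

#' Assemble the curated variant report
#'
#' Final filtering stage, applied after primer exclusion, blacklist
#' construction, germline discrimination, phasing/merging and protein
#' annotation. A variant is kept when its AF clears the sample-specific
#' concentration-informed cutoff (for target genes) or the fixed
#' non-target floor of 10\% (for genes whose mutations matter only in a
#' major clone). Blacklisted sites, synonymous and non-coding calls, and
#' non-recurrent variants surviving only in degraded samples are dropped.
#' The output is sorted by gene and position and carries the origin,
#' expression and rescue annotations. Running the filter on its own
#' output changes nothing.
#'
#' @param variants annotated calls: \code{sample_id}, \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}, \code{af}, \code{gene}, and
#'   optionally \code{effect}, \code{origin}, \code{expressed},
#'   \code{rescue}.
#' @param samples sample sheet with \code{af_cutoff} and \code{degraded}
#'   (run \code{\link{qcReport}} first).
#' @param blacklist output of \code{\link{buildBlacklist}}, or
#'   \code{NULL}.
#' @param targetGenes genes subject to the per-sample cutoff; all other
#'   genes use the non-target floor.
#' @param nonTargetFloor AF floor for non-target genes.
#' @return the curated report data.frame.
#' @export
filterReport <- function(variants, samples, blacklist = NULL,
                         targetGenes = "EGFR", nonTargetFloor = 0.10) {
    if (!all(c("af_cutoff", "degraded") %in% colnames(samples)))
        stop("sample sheet lacks af_cutoff/degraded: run qcReport() first")
    if (!nrow(variants)) return(variants)
    miss <- setdiff(unique(variants$sample_id), samples$sample_id)
    if (length(miss))
        stop("samples without QC cutoffs: ", paste(miss, collapse = ", "),
             "; run qcReport() first")
    v <- variants
    if (!is.null(blacklist)) {
        bl <- blacklist[blacklist$blacklisted, , drop = FALSE]
        v <- v[!variantKey(v) %in% variantKey(bl), , drop = FALSE]
    }
    if ("effect" %in% colnames(v))
        v <- v[!v$effect %in% c("synonymous", "non-coding"), ,
               drop = FALSE]
    s <- match(v$sample_id, samples$sample_id)
    cutoff <- ifelse(v$gene %in% targetGenes,
                     samples$af_cutoff[s], nonTargetFloor)
    v <- v[v$af >= cutoff, , drop = FALSE]
    # drop non-recurrent calls whose only surviving carriers are degraded
    if (nrow(v)) {
        key <- variantKey(v)
        nSeen <- table(key)[key]
        degr <- samples$degraded[match(v$sample_id, samples$sample_id)]
        allDegr <- vapply(split(degr, key), all, logical(1))[key]
        v <- v[!(nSeen < 2L & allDegr), , drop = FALSE]
    }
    v <- v[order(v$gene, v$chrom, v$pos, v$sample_id), , drop = FALSE]
    rownames(v) <- NULL
    v
}
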