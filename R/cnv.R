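#' @include io.R
NULL

#' Normalize an amplicon coverage matrix
#'
#' Two-step normalization before copy-number estimation: each sample is
#' scaled by a median-of-ratios size factor (the median, over amplicons,
#' of its depth relative to the across-sample per-amplicon median), then
#' each amplicon is divided by its across-sample median so every
#' amplicon's median normalized coverage is 1 and amplicon-specific PCR
#' efficiency cancels. The median-based size factor keeps library-size
#' correction robust when a minority of amplicons is genuinely amplified
#' -- an equal-totals scaling would absorb part of a strong amplification
#' into the size factor and bias the fold estimate downwards. Amplicons
#' with all-zero coverage (panel drop-out) are removed with a warning.
#'
#' @param se \code{SummarizedExperiment} from
#'   \code{\link{readCoverageMatrix}} or \code{\link{simulateCoverage}}.
#' @return \code{SummarizedExperiment} with assay \code{"norm"}.
#' @export
normalizeCoverage <- function(se) {
    m <- SummarizedExperiment::assay(se)
    zero <- rowSums(m) == 0
    if (any(zero)) {
        warning("dropping all-zero amplicon(s): ",
                paste(rownames(m)[zero], collapse = ", "))
        se <- se[!zero, ]
        m <- m[!zero, , drop = FALSE]
    }
    if (any(colSums(m) == 0)) stop("all-zero sample column")
    ref <- apply(m, 1L, stats::median)
    ok <- ref > 0
    sizeFactor <- apply(m[ok, , drop = FALSE], 2L, function(col)
        stats::median(col / ref[ok]))
    if (any(sizeFactor <= 0)) stop("non-positive size factor")
    m <- sweep(m, 2L, sizeFactor, "/")
    med <- apply(m, 1L, stats::median)
    m <- sweep(m, 1L, pmax(med, .Machine$double.eps), "/")
    out <- se
    SummarizedExperiment::assays(out) <- list(norm = m)
    out
}

#' Bootstrap gene-level copy-number fold without matched normals
#'
#' In a tumor-only amplicon panel there is no matched normal to supply a
#' coverage baseline. Instead, a pseudo-control background is built by
#' resampling the other samples of the run with replacement: for each of
#' \code{B} bootstrap replicates, the background mean of every amplicon
#' of the gene is recomputed from a resample of the other samples, and
#' the replicate fold is the mean over the gene's amplicons of
#' (sample depth / background mean). Amplicons with zero depth in the
#' tested sample are treated as drop-out (missing data) and excluded
#' from the mean rather than read as focal deletions. The reported fold
#' is the plug-in
#' estimate against the full background, the confidence interval the
#' 2.5/97.5 bootstrap percentiles, and the call significant when the CI
#' excludes 1 and the fold lies beyond the clinical gate (1.5x in either
#' direction by default).
#'
#' @param se normalized coverage (\code{\link{normalizeCoverage}}).
#' @param sample sample id to test.
#' @param gene gene symbol (>= 2 amplicons on the panel).
#' @param B bootstrap replicates.
#' @param seed integer seed for the resampling.
#' @param gate fold gate for clinical significance.
#' @param level CI level (percentile bootstrap).
#' @return one-row data.frame: \code{sample_id}, \code{gene},
#'   \code{n_amplicons}, \code{fold}, \code{ci_low}, \code{ci_high},
#'   \code{significant}.
#' @export
bootstrapGeneFold <- function(se, sample, gene, B = 1000L, seed = 1L,
                              gate = 1.5, level = 0.95) {
    if (B < 100L) warning("B < 100 gives unstable percentile intervals")
    m <- SummarizedExperiment::assay(se)
    genes <- SummarizedExperiment::rowData(se)$gene
    rows <- which(genes == gene)
    if (!length(rows)) stop("gene not on the panel: ", gene)
    if (length(rows) < 2L)
        stop("gene ", gene, " has fewer than 2 amplicons")
    sCol <- match(sample, colnames(m))
    if (is.na(sCol)) stop("unknown sample: ", sample)
    others <- setdiff(seq_len(ncol(m)), sCol)
    if (length(others) < 4L)
        stop("need >= 4 other samples as bootstrap background")
    # amplicon drop-out in this sample is missing data, not copy zero:
    # zero cells would masquerade as focal deletions
    x <- m[rows, sCol]
    if (any(x == 0)) {
        rows <- rows[x > 0]
        if (length(rows) < 2L)
            stop("gene ", gene, " has < 2 covered amplicons in ", sample)
        x <- m[rows, sCol]
    }
    A <- m[rows, others, drop = FALSE]
    fold <- mean(x / rowMeans(A))
    set.seed(seed)
    idx <- matrix(sample.int(length(others), length(others) * B,
                             replace = TRUE), ncol = B)
    folds <- vapply(seq_len(B), function(b) {
        bg <- rowMeans(A[, idx[, b], drop = FALSE])
        mean(x / bg)
    }, numeric(1))
    alpha <- (1 - level) / 2
    ci <- unname(stats::quantile(folds, c(alpha, 1 - alpha)))
    sig <- (ci[1] > 1 || ci[2] < 1) && (fold > gate || fold < 1 / gate)
    data.frame(sample_id = sample, gene = gene,
               n_amplicons = length(rows), fold = fold,
               ci_low = ci[1], ci_high = ci[2], significant = sig)
}

#' Within-chromosome reference-gene normalized fold
#'
#' Whole-chromosome gains (or sample-wide effects) inflate the raw
#' bootstrap fold of every gene on the chromosome. To isolate a focal
#' amplification, the target gene's mean depth is divided by the pooled
#' mean depth of reference genes on the same chromosome in the same
#' sample, and that ratio is divided by its median across the other
#' samples. A uniform whole-chromosome doubling cancels exactly.
#'
#' @param se normalized coverage.
#' @param sample sample id.
#' @param targetGene gene being assessed.
#' @param referenceGenes same-chromosome genes forming the baseline; must
#'   not include the target.
#' @return the normalized fold (numeric). A warning is raised when a
#'   reference gene itself looks amplified in this sample (> 2x its
#'   across-sample median), since it contaminates the baseline.
#' @export
withinChromosomeFold <- function(se, sample, targetGene,
                                 referenceGenes) {
    if (!length(referenceGenes)) stop("reference gene set is empty")
    if (targetGene %in% referenceGenes)
        stop("reference set must not contain the target gene")
    rd <- SummarizedExperiment::rowData(se)
    chromOf <- function(g) unique(rd$chrom[rd$gene == g])
    tc <- chromOf(targetGene)
    for (g in referenceGenes) {
        if (!any(rd$gene == g)) stop("gene not on the panel: ", g)
        if (!identical(chromOf(g), tc))
            stop("reference gene ", g, " is not on chromosome ", tc)
    }
    m <- SummarizedExperiment::assay(se)
    sCol <- match(sample, colnames(m))
    if (is.na(sCol)) stop("unknown sample: ", sample)
    tRows <- which(rd$gene == targetGene)
    rRows <- which(rd$gene %in% referenceGenes)
    for (g in referenceGenes) {
        gr <- which(rd$gene == g)
        relative <- mean(m[gr, sCol]) /
            stats::median(colMeans(m[gr, -sCol, drop = FALSE]))
        if (is.finite(relative) && relative > 2)
            warning("reference gene ", g, " looks amplified in ",
                    sample, " (contaminated baseline)")
    }
    ratio <- function(col) mean(m[tRows, col]) / mean(m[rRows, col])
    rSample <- ratio(sCol)
    rOthers <- vapply(setdiff(seq_len(ncol(m)), sCol), ratio, numeric(1))
    rSample / stats::median(rOthers)
}

#' Gene-level CNV report for a cohort
#'
#' Runs \code{\link{bootstrapGeneFold}} for every (sample, gene) pair --
#' restricted to genes with at least \code{minAmplicons} amplicons -- and
#' optionally adds the within-chromosome normalized fold for configured
#' target genes.
#'
#' @param se raw coverage \code{SummarizedExperiment}; normalized
#'   internally.
#' @param B,seed,gate passed to \code{\link{bootstrapGeneFold}}.
#' @param minAmplicons minimum amplicons per gene to attempt a call.
#' @param normalizeChrom named list mapping a target gene to its
#'   same-chromosome reference genes, e.g.
#'   \code{list(MET = c("EGFR", "BRAF", "SMO"))}.
#' @param samples restrict to these samples (default all).
#' @return data.frame of CNV calls.
#' @export
cnvReport <- function(se, B = 1000L, seed = 1L, gate = 1.5,
                      minAmplicons = 2L, normalizeChrom = list(),
                      samples = NULL) {
    nm <- normalizeCoverage(se)
    genes <- unique(SummarizedExperiment::rowData(nm)$gene)
    keep <- vapply(genes, function(g)
        sum(SummarizedExperiment::rowData(nm)$gene == g) >= minAmplicons,
        logical(1))
    genes <- genes[keep]
    ids <- samples %||% colnames(SummarizedExperiment::assay(nm))
    rows <- list()
    for (s in ids) {
        for (g in genes) {
            call <- bootstrapGeneFold(nm, s, g, B = B,
                seed = seed + match(s, ids) * 1000L +
                    match(g, genes), gate = gate)
            call$normalized_fold <- NA_real_
            if (g %in% names(normalizeChrom))
                call$normalized_fold <- suppressWarnings(
                    withinChromosomeFold(nm, s, g, normalizeChrom[[g]]))
            rows[[length(rows) + 1L]] <- call
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}
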