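#' @include AllClasses.R
NULL

# the 12 strand-specific single-nucleotide substitution classes
SUB_CLASSES <- c("A>C", "A>G", "A>T", "C>A", "C>G", "C>T",
                 "G>A", "G>C", "G>T", "T>A", "T>C", "T>G")

# strand-symmetric (pyrimidine/purine-paired) 6-class view
COLLAPSE_MAP <- c("C>A" = "C:G>A:T", "G>T" = "C:G>A:T",
                  "C>G" = "C:G>G:C", "G>C" = "C:G>G:C",
                  "C>T" = "C:G>T:A", "G>A" = "C:G>T:A",
                  "T>A" = "T:A>A:T", "A>T" = "T:A>A:T",
                  "T>C" = "T:A>C:G", "A>G" = "T:A>C:G",
                  "T>G" = "T:A>G:C", "A>C" = "T:A>G:C")

SPECTRUM_CLASSES <- c(SUB_CLASSES, "mnv", "indel")

#' Classify a substitution by its REF/ALT alleles
#'
#' Single-base substitutions map to one of the 12 raw strand-specific
#' classes (\code{"C>T"}, \code{"G>A"}, ...). Equal-length multi-base
#' alleles map to \code{"mnv"}, length-changing alleles to \code{"indel"}.
#' FFPE cytosine deamination manifests as the strand-symmetric pair
#' C>T / G>A, which the collapsed view (\code{collapsed = TRUE}) reports
#' jointly as \code{"C:G>T:A"}.
#'
#' @param ref,alt allele strings (vectorised).
#' @param collapsed return the 6 strand-symmetric classes instead of the
#'   12 raw ones (mnv/indel unchanged).
#' @return character vector of class labels.
#' @examples
#' classifySubstitution("C", "T")
#' classifySubstitution("G", "A", collapsed = TRUE)
#' classifySubstitution("AT", "A")
#' @export
classifySubstitution <- function(ref, alt, collapsed = FALSE) {
    ref <- as.character(ref); alt <- as.character(alt)
    if (any(!nzchar(ref)) || any(!nzchar(alt)) || anyNA(ref) || anyNA(alt))
        stop("empty allele")
    if (any(ref == alt)) stop("ref and alt must differ")
    cls <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L,
                  paste0(ref, ">", alt),
                  ifelse(nchar(ref) == nchar(alt), "mnv", "indel"))
    bad <- !(cls %in% SPECTRUM_CLASSES)
    if (any(bad)) stop("unrecognised alleles: ",
                       paste(ref[bad], alt[bad], sep = ">", collapse = ", "))
    if (collapsed) {
        snv <- cls %in% SUB_CLASSES
        cls[snv] <- COLLAPSE_MAP[cls[snv]]
    }
    cls
}

#' Tabulate the mutation spectrum by allele-frequency bin
#'
#' Counts each variant call into exactly one half-open AF bin
#' \code{(low, high]} and one substitution class, giving the class-by-bin
#' spectrum used for FFPE artifact assessment. The default bins
#' \code{(0, 0.10]} and \code{(0.10, 1]} separate the low-AF regime where
#' deamination artifacts concentrate from the high-AF regime.
#'
#' @param variants data.frame with columns \code{ref}, \code{alt},
#'   \code{af}.
#' @param binEdges strictly increasing AF bin edges from 0 to 1.
#' @param pooled mark the table as cohort-pooled.
#' @return a \code{\linkS4class{SpectrumTable}}.
#' @export
spectrumByAF <- function(variants, binEdges = c(0, 0.10, 1), pooled = TRUE) {
    if (is.unsorted(binEdges, strictly = TRUE) ||
        binEdges[1] != 0 || binEdges[length(binEdges)] != 1)
        stop("binEdges must increase strictly from 0 to 1")
    nbin <- length(binEdges) - 1L
    binNames <- paste0("(", binEdges[-length(binEdges)], ",",
                       binEdges[-1], "]")
    counts <- matrix(0L, length(SPECTRUM_CLASSES), nbin,
                     dimnames = list(SPECTRUM_CLASSES, binNames))
    if (nrow(variants)) {
        if (any(variants$af <= 0 | variants$af > 1))
            stop("variant AF outside (0, 1]")
        cls <- classifySubstitution(variants$ref, variants$alt)
        bin <- cut(variants$af, breaks = binEdges, labels = binNames,
                   right = TRUE)
        tab <- table(factor(cls, levels = SPECTRUM_CLASSES), bin)
        counts[] <- as.integer(tab)
    }
    methods::new("SpectrumTable", counts = counts, binEdges = binEdges,
                 pooled = pooled)
}

#' Collapse a spectrum to the 6 strand-symmetric classes
#'
#' @param spectrum a \code{SpectrumTable} with the 12 raw classes.
#' @return numeric matrix with rows \code{C:G>T:A} etc. plus mnv/indel.
#' @export
collapseSpectrum <- function(spectrum) {
    counts <- spectrumCounts(spectrum)
    grp <- c(COLLAPSE_MAP[SUB_CLASSES], mnv = "mnv", indel = "indel")
    rowsum(counts, grp[rownames(counts)])
}

#' Spearman correlation of artifact burden with library concentration
#'
#' Rank correlation (Pearson on midranks) between per-sample
#' pre-normalization library concentration and per-sample mutation count.
#' Degraded FFPE input yields low-concentration libraries and many
#' deamination artifacts, so a strongly negative rho is the expected
#' signature. The two-sided p-value uses the exact permutation null (all
#' \eqn{n!} orderings) for \eqn{n < 10} and the t approximation otherwise.
#'
#' @param concentrations per-sample concentrations (ng/ul).
#' @param counts per-sample variant counts, aligned to
#'   \code{concentrations}.
#' @return list with \code{rho}, \code{p}, \code{n} and \code{method}.
#' @export
concentrationCorrelation <- function(concentrations, counts) {
    n <- length(concentrations)
    if (n < 2L || length(counts) != n)
        stop("need >= 2 aligned (concentration, count) pairs")
    if (length(unique(concentrations)) < 2L ||
        length(unique(counts)) < 2L) {
        warning("constant concentrations or counts: rho undefined")
        return(list(rho = NA_real_, p = NA_real_, n = n,
                    method = "undefined"))
    }
    rx <- rank(concentrations); ry <- rank(counts)
    rho <- stats::cor(rx, ry)
    if (n < 10L) {
        P <- allPermutations(n)
        Rp <- matrix(ry[P], nrow(P))           # permuted count ranks
        sp <- as.vector(Rp %*% rx)
        mx <- mean(rx); my <- mean(ry)
        denom <- (n - 1) * stats::sd(rx) * stats::sd(ry)
        rhos <- (sp - n * mx * my) / denom
        p <- mean(abs(rhos) >= abs(rho) - 1e-12)
        method <- "exact permutation"
    } else {
        tstat <- rho * sqrt((n - 2) / max(1 - rho^2,
                                          .Machine$double.eps))
        p <- 2 * stats::pt(-abs(tstat), df = n - 2)
        method <- "t approximation"
    }
    list(rho = rho, p = p, n = n, method = method)
}

#' Flag degraded samples by high-AF artifact burden and concentration
#'
#' A sample is flagged \code{degraded} when its count of variants above
#' the high-AF threshold exceeds \code{max(median + k * MAD, floor)} of the
#' cohort counts, or when its pre-normalization library concentration
#' falls below the concentration trigger. The robust count rule captures
#' the outlier samples carrying tens of 9--20\% AF artifacts; the
#' concentration trigger catches degraded input even before artifacts are
#' counted.
#'
#' @param samples data.frame with \code{sample_id} and
#'   \code{pre_norm_conc}.
#' @param variants data.frame of calls with \code{sample_id} and \code{af}.
#' @param highAFThreshold AF above which a call counts as high-AF.
#' @param k MAD multiplier of the outlier rule.
#' @param countFloor absolute floor of the count threshold, so that
#'   near-zero cohort MADs cannot flag ordinary samples.
#' @param concTrigger concentration (ng/ul) below which a sample is
#'   flagged regardless of counts.
#' @return \code{samples} with added columns \code{high_af_count} and
#'   \code{degraded}.
#' @export
flagDegraded <- function(samples, variants, highAFThreshold = 0.10,
                         k = 3, countFloor = 5, concTrigger = 1.5) {
    if (nrow(variants) && !all(variants$sample_id %in% samples$sample_id))
        stop("variants reference samples missing from the sample sheet")
    hi <- variants[variants$af > highAFThreshold, , drop = FALSE]
    cnt <- table(factor(hi$sample_id, levels = samples$sample_id))
    counts <- as.integer(cnt)
    thr <- max(stats::median(counts) + k * stats::mad(counts), countFloor)
    samples$high_af_count <- counts
    samples$degraded <- counts > thr | samples$pre_norm_conc < concTrigger
    samples
}

#' Substitution-class enrichment between two AF bins
#'
#' For every raw substitution class, Fisher's exact test on the 2x2 table
#' [class vs all other classes] x [low AF bin vs high AF bin] of a pooled
#' cohort spectrum, asking which substitution types are over-represented
#' in the low-AF (artifact-dominated) regime. Two-sided p-values by
#' hypergeometric summation; Benjamini-Hochberg q-values across the 12
#' classes.
#'
#' @param spectrum a cohort-pooled \code{SpectrumTable}.
#' @param lowBin,highBin column indices (or names) of the two bins.
#' @return data.frame with one row per raw class: counts in each bin,
#'   \code{odds_ratio}, \code{p}, \code{q}.
#' @export
enrichmentTest <- function(spectrum, lowBin = 1L, highBin = 2L) {
    counts <- spectrumCounts(spectrum)[SUB_CLASSES, , drop = FALSE]
    lo <- counts[, lowBin]; hi <- counts[, highBin]
    totLo <- sum(lo); totHi <- sum(hi)
    res <- lapply(SUB_CLASSES, function(cl) {
        a <- lo[cl]; b <- hi[cl]
        cc <- totLo - a; d <- totHi - b
        tab <- matrix(c(a, cc, b, d), 2L)
        if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
            orr <- NA_real_; p <- 1
        } else {
            p <- stats::fisher.test(tab)$p.value
            orr <- (a * d) / (b * cc)
            if (!is.finite(orr)) orr <- NA_real_
        }
        data.frame(class = cl, low = a, high = b,
                   odds_ratio = unname(orr), p = unname(p))
    })
    out <- do.call(rbind, res)
    out$q <- stats::p.adjust(out$p, method = "BH")
    rownames(out) <- NULL
    out
}

#' Fit the artifact-rate model to a cohort
#'
#' Fits \eqn{\lambda(c) = \exp(a - b \log c)} -- expected artifact count
#' given pre-normalization concentration \eqn{c} -- by negative-binomial
#' regression of per-sample counts on log concentration, using only
#' non-degraded samples. Falls back to Poisson regression when the NB fit
#' does not converge, and to a concentration-constant mean rate (with a
#' warning) when concentrations are degenerate.
#'
#' @param samples sample sheet with \code{pre_norm_conc} and, if present,
#'   \code{degraded} (degraded samples are excluded from the fit).
#' @param counts per-sample artifact-candidate counts aligned to
#'   \code{samples}.
#' @return object of class \code{artifactRateFit} with a
#'   \code{\link{predictArtifactRate}} method.
#' @export
fitArtifactRate <- function(samples, counts) {
    keep <- if ("degraded" %in% colnames(samples)) !samples$degraded
            else rep(TRUE, nrow(samples))
    conc <- samples$pre_norm_conc[keep]
    cnt <- counts[keep]
    if (length(cnt) < 3L)
        stop("need >= 3 non-degraded samples to fit the rate model")
    if (length(unique(conc)) < 2L) {
        warning("degenerate concentrations: falling back to a ",
                "concentration-constant artifact rate")
        fit <- list(type = "constant", lambda = mean(cnt))
    } else {
        m <- tryCatch(
            suppressWarnings(MASS::glm.nb(cnt ~ log(conc))),
            error = function(e) NULL)
        if (is.null(m))
            m <- stats::glm(cnt ~ log(conc), family = stats::poisson())
        fit <- list(type = "loglinear", model = m)
    }
    class(fit) <- "artifactRateFit"
    fit
}

#' Predict the expected artifact count at a concentration
#'
#' @param fit an \code{artifactRateFit} from \code{\link{fitArtifactRate}},
#'   or a single non-negative number used directly as \eqn{\lambda}.
#' @param conc concentration(s) in ng/ul.
#' @return expected artifact count(s).
#' @export
predictArtifactRate <- function(fit, conc) {
    if (is.numeric(fit)) return(rep_len(fit, length(conc)))
    switch(fit$type,
        constant = rep_len(fit$lambda, length(conc)),
        loglinear = unname(stats::predict(fit$model,
            newdata = data.frame(conc = conc), type = "response")))
}

#' Artifact allele-frequency model
#'
#' The AF distribution of low-AF FFPE artifacts: a Beta(shape1, shape2)
#' truncated to \code{(0, max]}. The default Beta(1.2, 30) truncated at
#' 0.10 concentrates mass well below 10\% AF, matching the artifact
#' regime.
#'
#' @param shape1,shape2 Beta shape parameters.
#' @param max truncation point.
#' @return list with the three parameters, class \code{artifactAFModel}.
#' @export
artifactAFModel <- function(shape1 = 1.2, shape2 = 30, max = 0.10) {
    structure(list(shape1 = shape1, shape2 = shape2, max = max),
              class = "artifactAFModel")
}

# survival P(AF >= f) under the truncated Beta artifact AF model
artifactAFSurvival <- function(model, f) {
    ptr <- stats::pbeta(model$max, model$shape1, model$shape2)
    pmax(0, (ptr - stats::pbeta(pmin(f, model$max), model$shape1,
                                model$shape2)) / ptr)
}

#' Concentration-informed per-sample allele-frequency cutoff
#'
#' The reporting cutoff for a sample is the smallest AF \eqn{f} such that
#' the expected number of artifact calls at or above \eqn{f} --
#' \eqn{\lambda(c) \cdot P(\mathrm{AF} \ge f)} under the fitted artifact
#' rate and AF models -- does not exceed \code{alpha}, and never below the
#' clinical floor for the variant category (5\% of covering reads for
#' response-associated mutations, 2.5\% for resistance-associated ones).
#' Because \eqn{\lambda} falls with concentration, the cutoff is monotone
#' non-increasing in concentration: cleaner input earns a lower reporting
#' threshold.
#'
#' @param conc the sample's pre-normalization concentration (ng/ul).
#' @param fit an \code{artifactRateFit} or a bare \eqn{\lambda} value.
#' @param afModel an \code{\link{artifactAFModel}}.
#' @param alpha tolerated expected number of artifact calls above the
#'   cutoff (default 1).
#' @param floors named clinical floors per variant category.
#' @param category which floor applies.
#' @return the AF cutoff (fraction).
#' @examples
#' estimateCutoff(5, fit = 0)     # no artifacts: clinical floor
#' @export
estimateCutoff <- function(conc, fit, afModel = artifactAFModel(),
                           alpha = 1,
                           floors = c(response = 0.05, resistance = 0.025),
                           category = "resistance") {
    stopifnot(category %in% names(floors))
    lam <- predictArtifactRate(fit, conc)
    floorAF <- unname(floors[[category]])
    f <- ifelse(lam <= alpha, 0, {
        ptr <- stats::pbeta(afModel$max, afModel$shape1, afModel$shape2)
        stats::qbeta((1 - alpha / lam) * ptr, afModel$shape1,
                     afModel$shape2)
    })
    pmax(f, floorAF)
}

#' Per-sample QC report for a cohort of variant calls
#'
#' Runs the artifact QC stage end to end: per-sample counts by AF bin and
#' C:G>T:A proportion, concentration-count rank correlation,
#' degraded-sample flags, the fitted artifact-rate model, and
#' concentration-informed per-sample AF cutoffs.
#'
#' @param variants cohort variant calls (data.frame).
#' @param samples sample sheet with \code{sample_id}, \code{pre_norm_conc}.
#' @param binEdges AF bin edges for the spectrum.
#' @param afModel artifact AF model used for cutoffs.
#' @param alpha cutoff tolerance (expected artifacts above cutoff).
#' @param ... further arguments to \code{\link{flagDegraded}}.
#' @return list with \code{samples} (augmented sheet: counts, C:G>T:A
#'   proportion, \code{degraded}, \code{af_cutoff}), \code{spectrum}
#'   (pooled \code{SpectrumTable}), \code{correlation} and \code{fit}.
#' @export
qcReport <- function(variants, samples, binEdges = c(0, 0.10, 1),
                     afModel = artifactAFModel(), alpha = 1, ...) {
    samples <- flagDegraded(samples, variants, ...)
    perSample <- split(variants, factor(variants$sample_id,
                                        levels = samples$sample_id))
    lowCount <- vapply(perSample, function(v)
        sum(v$af <= 0.10), integer(1))
    total <- vapply(perSample, nrow, integer(1))
    ctProp <- vapply(perSample, function(v) {
        if (!nrow(v)) return(NA_real_)
        snv <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
        if (!any(snv)) return(NA_real_)
        mean(classifySubstitution(v$ref[snv], v$alt[snv],
                                  collapsed = TRUE) == "C:G>T:A")
    }, numeric(1))
    samples$n_variants <- unname(total)
    samples$n_low_af <- unname(lowCount)
    samples$ctta_proportion <- unname(ctProp)
    corr <- concentrationCorrelation(samples$pre_norm_conc, total)
    fit <- fitArtifactRate(samples, samples$n_low_af)
    samples$af_cutoff <- vapply(samples$pre_norm_conc, function(cc)
        estimateCutoff(cc, fit, afModel = afModel, alpha = alpha),
        numeric(1))
    spectrum <- spectrumByAF(variants, binEdges = binEdges, pooled = TRUE)
    list(samples = samples, spectrum = spectrum, correlation = corr,
         fit = fit)
}

#' Write a QC report to JSON + spectrum TSV
#'
#' @param report output of \code{\link{qcReport}}.
#' @param jsonPath path of the JSON report.
#' @param spectrumPath optional path of the spectrum TSV.
#' @return invisibly, \code{jsonPath}.
#' @export
writeQcReport <- function(report, jsonPath, spectrumPath = NULL) {
    out <- list(samples = report$samples,
                correlation = report$correlation[c("rho", "p", "n",
                                                   "method")])
    jsonlite::write_json(out, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
    if (!is.null(spectrumPath)) {
        counts <- spectrumCounts(report$spectrum)
        writeTsv(data.frame(class = rownames(counts), counts,
                            check.names = FALSE), spectrumPath)
    }
    invisible(jsonPath)
}
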