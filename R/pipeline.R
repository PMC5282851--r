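#' @include simulate.R postprocess.R cnv.R
NULL

#' Demo pipeline configuration
#'
#' A complete run configuration on the default 48-gene / 212-amplicon
#' panel: a 26-sample synthetic cohort with four degraded samples, a
#' handful of planted somatic and germline variants, one phased compound
#' pair, and two gene amplifications (EGFR 5.7x in one sample, MET 1.6x
#' in another, the latter assessed against EGFR/BRAF/SMO on chromosome
#' 7).
#'
#' @param outdir output directory of the run.
#' @param seed integer seed; the entire run derives from it.
#' @param B bootstrap replicates for the CNV stage.
#' @return a run-configuration list for \code{\link{runPipeline}}.
#' @export
demoConfig <- function(outdir, seed = 17L, B = 250L) {
    panel <- defaultPanel()
    ins <- insertRegions(panel)
    posIn <- function(ampName, offset) {
        i <- match(ampName, S4Vectors::mcols(ins)$name)
        GenomicRanges::start(ins)[i] + offset
    }
    tv <- data.frame(
        sample_id = c("S07", "S07", "S12", "S15", "S20", "S20", "S04"),
        gene = c("EGFR", "TP53", "KRAS", "TP53", "PIK3CA", "KDR",
                 "AKT1"),
        chrom = c("chr7", "chr17", "chr12", "chr17", "chr3", "chr4",
                  "chr14"),
        pos = c(posIn("EGFR_amp03", 40), posIn("TP53_amp01", 60),
                posIn("KRAS_amp02", 25), posIn("TP53_amp02", 80),
                posIn("PIK3CA_amp01", 33), posIn("KDR_amp01", 50),
                posIn("AKT1_amp01", 12)),
        ref = c("T", "G", "G", "C", "G", "T", "G"),
        alt = c("G", "A", "T", "T", "A", "A", "A"),
        af = c(0.35, 0.44, 0.31, 0.17, 0.15, 0.48, 0.04),
        origin = c("somatic", "somatic", "somatic", "somatic",
                   "somatic", "germline", "somatic"))
    ce <- data.frame(
        sample_id = "S09", chrom = "chr7",
        pos_a = posIn("EGFR_amp05", 20), ref_a = "C", alt_a = "CA",
        pos_b = posIn("EGFR_amp05", 30), ref_b = "G", alt_b = "T",
        af = 0.28, shared_fraction = 1.0)
    cnv <- data.frame(sample_id = c("S05", "S11"),
                      gene = c("EGFR", "MET"), fold = c(5.7, 1.6))
    sim <- simulationConfig(trueVariants = tv, compoundEvents = ce,
                            cnvEvents = cnv, seed = seed)
    list(outdir = outdir, seed = as.integer(seed), sim = sim,
         panel = panel,
         dbPath = system.file("extdata", "germline_db.tsv",
                              package = "ffpeQC"),
         targetGenes = "EGFR",
         normalizeChrom = list(MET = c("EGFR", "BRAF", "SMO")),
         B = as.integer(B))
}

validateRunConfig <- function(config) {
    if (is.null(config$outdir)) stop("config needs an outdir")
    if (is.null(config$seed) || config$seed < 0)
        stop("config needs a non-negative integer seed")
    if (is.null(config$sim)) {
        if (is.null(config$vcfDir) || !dir.exists(config$vcfDir))
            stop("config without a simulation stage needs an existing ",
                 "vcfDir")
        if (is.null(config$sampleSheet) ||
            !file.exists(config$sampleSheet))
            stop("config without a simulation stage needs an existing ",
                 "sample sheet")
    }
    if (!is.null(config$dbPath) && nzchar(config$dbPath) &&
        !file.exists(config$dbPath))
        stop("germline db not found: ", config$dbPath)
    invisible(TRUE)
}

#' Run the full pipeline: simulate, QC, post-process, CNV
#'
#' Stages run in fixed order, each consuming the previous stage's
#' on-disk outputs; a manifest JSON records the seed, the key parameters
#' and md5 checksums of the stage outputs. Re-running with an identical
#' configuration and seed reproduces every report byte for byte.
#'
#' @param config a run-configuration list (see \code{\link{demoConfig}});
#'   either \code{sim} (a \code{SimulationConfig}) for a synthetic run,
#'   or \code{vcfDir} + \code{sampleSheet} (+ \code{coverage}) paths for
#'   existing data.
#' @return invisibly, a list with the stage outputs and written paths.
#' @export
runPipeline <- function(config) {
    validateRunConfig(config)
    outdir <- config$outdir
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    panel <- config$panel %||% defaultPanel()

    if (!is.null(config$sim)) {
        cohort <- simulateCohort(config$sim, panel)
        simPaths <- writeCohort(cohort, file.path(outdir, "sim"))
        vcfDir <- file.path(outdir, "sim", "vcf")
        sheetPath <- simPaths$sample_sheet
        covPath <- simPaths$coverage
        evidence <- cohort@readEvidence
    } else {
        vcfDir <- config$vcfDir
        sheetPath <- config$sampleSheet
        covPath <- config$coverage
        evidence <- if (!is.null(config$evidence))
            readTsv(config$evidence) else NULL
    }

    variants <- readVcfDir(vcfDir)
    sheet <- readTsv(sheetPath)
    qc <- qcReport(variants, sheet)
    qcPath <- file.path(outdir, "qc_report.json")
    writeQcReport(qc, qcPath, file.path(outdir, "spectrum.tsv"))

    pe <- excludePrimerEvidence(variants, panel)
    kept <- assignGenes(pe$kept, panel)
    bl <- buildBlacklist(kept, nSamples = nrow(sheet))
    if (!is.null(config$dbPath) && nzchar(config$dbPath)) {
        db <- readGermlineDb(config$dbPath)
        kept <- discriminateGermline(kept, db)
    } else kept$origin <- "ambiguous"
    amp <- amplicons(panel)
    kept$rescue <- vapply(seq_len(nrow(kept)), function(i) {
        hits <- ampliconsAt(panel, kept$chrom[i], kept$pos[i])
        any(vapply(hits, function(h)
            strandBiasRescue(kept[i, ], amp[h]), logical(1)))
    }, logical(1))
    curated <- filterReport(kept, qc$samples, bl,
                            targetGenes = config$targetGenes %||% "EGFR")
    curatedPath <- writeTsv(curated,
                            file.path(outdir, "curated_report.tsv"))

    cnv <- NULL
    cnvPath <- NULL
    if (!is.null(covPath)) {
        se <- readCoverageMatrix(covPath, panel)
        cnv <- cnvReport(se, B = config$B %||% 1000L,
                         seed = config$seed,
                         normalizeChrom = config$normalizeChrom %||%
                             list())
        cnvPath <- writeTsv(cnv, file.path(outdir, "cnv_report.tsv"))
    }

    summaryPath <- file.path(outdir, "summary.txt")
    writeLines(renderReport(qc, curated, cnv), summaryPath)

    manifest <- list(
        seed = config$seed,
        n_samples = nrow(sheet),
        n_variant_calls = nrow(variants),
        n_curated = nrow(curated),
        parameters = list(
            target_genes = config$targetGenes %||% "EGFR",
            bootstrap_B = config$B %||% 1000L),
        checksums = {
            paths <- stats::na.omit(c(qcPath, curatedPath, cnvPath))
            md5 <- tools::md5sum(paths)
            names(md5) <- basename(paths)
            as.list(md5)
        })
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)

    invisible(list(qc = qc, curated = curated, cnv = cnv,
                   evidence = evidence,
                   paths = list(qc = qcPath, curated = curatedPath,
                                cnv = cnvPath, summary = summaryPath)))
}

#' Render a human-readable cohort summary
#'
#' One text document per cohort: the per-sample QC table (variant counts
#' by AF regime, C:G>T:A proportion, concentration, degraded flag,
#' reporting cutoff), the curated variant table grouped by gene, and the
#' significant CNV calls.
#'
#' @param qc output of \code{\link{qcReport}}.
#' @param curated curated report from \code{\link{filterReport}} (or a
#'   curated table read via \code{\link{readCuratedTable}}).
#' @param cnv CNV report data.frame, or \code{NULL}.
#' @return character vector of report lines.
#' @export
renderReport <- function(qc, curated, cnv = NULL) {
    lines <- c("FFPE amplicon panel cohort report",
               strrep("=", 60), "", "Per-sample QC", strrep("-", 60))
    s <- qc$samples
    lines <- c(lines, sprintf(
        "%-6s conc=%6.2f ng/ul  calls=%5d  lowAF=%5d  C:G>T:A=%5s  %s  cutoff=%.3f",
        s$sample_id, s$pre_norm_conc, s$n_variants, s$n_low_af,
        ifelse(is.na(s$ctta_proportion), "NA",
               sprintf("%.2f", s$ctta_proportion)),
        ifelse(s$degraded, "DEGRADED", "ok      "), s$af_cutoff))
    corr <- qc$correlation
    lines <- c(lines, "", sprintf(
        "Concentration vs mutation count: Spearman rho = %.3f (p = %.3g, %s)",
        corr$rho, corr$p, corr$method))
    lines <- c(lines, "", "Curated variants", strrep("-", 60))
    if (is.null(curated) || !nrow(curated)) {
        lines <- c(lines, "No reportable variants.")
    } else if (all(c("gene", "hgvs_p", "af_percent") %in%
                   colnames(curated))) {
        for (g in unique(curated$gene)) {
            sub <- curated[curated$gene == g, , drop = FALSE]
            lines <- c(lines, sprintf("%s (%d)", g, nrow(sub)),
                       sprintf("  %-28s %-8s AF=%s%%  %s", sub$hgvs_p,
                               sub$patient, sub$af_percent, sub$impact))
        }
    } else {
        for (g in unique(curated$gene)) {
            sub <- curated[curated$gene == g, , drop = FALSE]
            lines <- c(lines, sprintf("%s (%d)", g, nrow(sub)),
                       sprintf("  %s:%d %s>%s  %s  AF=%.3f  %s", sub$chrom,
                               sub$pos, sub$ref, sub$alt, sub$sample_id,
                               sub$af,
                               if (!is.null(sub$origin)) sub$origin
                               else ""))
        }
    }
    lines <- c(lines, "", "Copy number", strrep("-", 60))
    if (is.null(cnv) || !nrow(cnv)) {
        lines <- c(lines, "No CNV analysis performed.")
    } else {
        sig <- cnv[cnv$significant, , drop = FALSE]
        if (!nrow(sig)) lines <- c(lines, "No significant CNV calls.")
        else lines <- c(lines, sprintf(
            "%s %s fold=%.2f [%.2f, %.2f]%s", sig$sample_id, sig$gene,
            sig$fold, sig$ci_low, sig$ci_high,
            ifelse(is.na(sig$normalized_fold), "",
                   sprintf(" (within-chromosome %.2f)",
                           sig$normalized_fold))))
    }
    lines
}
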