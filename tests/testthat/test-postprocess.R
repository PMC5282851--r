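test_that("primer-only evidence is excluded, multi-amplicon geometry respected", {
    # A1 chr1:100-250 (insert 125-225), A2 chr1:200-350 (insert 225-325)
    p <- tinyPanel()
    v <- data.frame(sample_id = "S1", chrom = c("chr1", "chr1", "chr1",
                                                "chr3"),
                    pos = c(110L, 170L, 240L, 999L),
                    ref = "C", alt = "T", af = 0.2)
    out <- excludePrimerEvidence(v, p)
    # 110: primer of A1 only -> removed; 170: mid-insert -> kept;
    # 240: primer of A1 (rev) but insert of A2 -> kept; 999: off-target
    expect_equal(out$kept$pos, c(170L, 240L))
    expect_equal(out$primerOnly$pos, 110L)
    expect_equal(out$offTarget$pos, 999L)
})

test_that("recurrent low-AF sites are blacklisted, high-AF routed to germline", {
    mkCohort <- function() {
        rows <- list()
        # site X: 10 / 26 samples, median AF 0.03 -> blacklisted
        for (s in 1:10)
            rows[[length(rows) + 1]] <- makeVariants(
                sprintf("S%02d", s), af = 0.03, pos = 1500L)
        # site Y: 1 / 26 samples -> untouched
        rows[[length(rows) + 1]] <- makeVariants("S01", af = 0.04,
                                                 pos = 1600L)
        # site Z: 20 / 26 samples, median AF 0.45 -> germline candidate
        for (s in 1:20)
            rows[[length(rows) + 1]] <- makeVariants(
                sprintf("S%02d", s), af = 0.45, pos = 1700L)
        do.call(rbind, rows)
    }
    bl <- buildBlacklist(mkCohort(), nSamples = 26L)
    expect_true(bl$blacklisted[bl$pos == 1500])
    expect_false(bl$blacklisted[bl$pos == 1600])
    expect_false(bl$germline_candidate[bl$pos == 1600])
    expect_false(bl$blacklisted[bl$pos == 1700])
    expect_true(bl$germline_candidate[bl$pos == 1700])

    # invariant to record order
    v <- mkCohort()
    blShuf <- buildBlacklist(v[rev(seq_len(nrow(v))), ], nSamples = 26L)
    expect_identical(bl, blShuf)

    expect_error(buildBlacklist(v, nSamples = 2L), ">= 3")
})

test_that("germline discrimination follows frequency and database rules", {
    db <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                     ref = "C", alt = "T",
                     pop_freq = c(0.25, 0, 0.005),
                     dbsnp = c(1L, 0L, 0L), cosmic = c(0L, 1L, 0L))
    v <- makeVariants("S1", af = c(0.5, 0.3, 0.45, 0.2),
                      pos = c(10L, 20L, 30L, 40L))
    out <- discriminateGermline(v, db)
    expect_equal(out$origin, c("germline", "somatic", "ambiguous",
                               "ambiguous"))
    expect_equal(out$pop_freq[4], 0)    # absent from db -> frequency 0
})

test_that("phase fraction and threshold behave at the boundaries", {
    expect_equal(phaseFraction(list(n_both = 200, n_a_only = 0,
                                    n_b_only = 0)),
                 list(fraction = 1.0, phased = TRUE))
    expect_equal(phaseFraction(list(n_both = 0, n_a_only = 100,
                                    n_b_only = 100)),
                 list(fraction = 0.0, phased = FALSE))
    pf <- phaseFraction(list(n_both = 85, n_a_only = 10, n_b_only = 5))
    expect_equal(pf$fraction, 0.85)
    expect_false(pf$phased)
    expect_true(phaseFraction(list(n_both = 85, n_a_only = 10,
                                   n_b_only = 5),
                              threshold = 0.8)$phased)
    und <- phaseFraction(list(n_both = 0, n_a_only = 0, n_b_only = 0))
    expect_true(is.na(und$fraction))
    expect_false(und$phased)
})

test_that("indels near amplicon ends are rescued from strand-bias filters", {
    a <- list(start = 1000L, end = 1250L)
    # 18 bp insertion 138 bp from the 3' end with 150 bp reads
    ins18 <- data.frame(pos = 1250L - 138L, ref = "A",
                        alt = paste0("A", strrep("T", 18)))
    expect_true(strandBiasRescue(ins18, a, readLength = 150L))
    # SNV at the amplicon centre: never rescued
    snv <- data.frame(pos = 1125L, ref = "C", alt = "T")
    expect_false(strandBiasRescue(snv, a))
    # same insertion only 10 bp from the end: both orientations span it
    insNear <- data.frame(pos = 1240L, ref = "A",
                          alt = paste0("A", strrep("T", 18)))
    expect_false(strandBiasRescue(insNear, a, readLength = 150L))
})

test_that("the curated report applies cutoffs, blacklist and origin logic", {
    samples <- data.frame(sample_id = c("S1", "S2", "S3"),
                          pre_norm_conc = c(5, 8, 1.0),
                          af_cutoff = c(0.025, 0.05, 0.09),
                          degraded = c(FALSE, FALSE, TRUE))
    v <- rbind(
        cbind(makeVariants("S1", af = 0.04, pos = 100L), gene = "EGFR"),
        cbind(makeVariants("S2", af = 0.04, pos = 100L), gene = "EGFR"),
        cbind(makeVariants("S1", af = 0.04, pos = 200L), gene = "KRAS"),
        cbind(makeVariants("S1", af = 0.30, pos = 300L), gene = "KRAS"),
        cbind(makeVariants("S3", af = 0.15, pos = 400L), gene = "TP53"))
    out <- filterReport(v, samples, blacklist = NULL,
                        targetGenes = "EGFR")
    # EGFR at 4%: kept under the 2.5% cutoff (S1), dropped under 5% (S2)
    expect_true(any(out$sample_id == "S1" & out$pos == 100))
    expect_false(any(out$sample_id == "S2" & out$pos == 100))
    # KRAS (non-target) at 4% fails the 10% floor; at 30% passes
    expect_false(any(out$pos == 200))
    expect_true(any(out$pos == 300))
    # TP53 seen only in the degraded sample and non-recurrent: dropped
    expect_false(any(out$pos == 400))

    # blacklisted site removed
    bl <- data.frame(chrom = "chr1", pos = 300L, ref = "C", alt = "T",
                     blacklisted = TRUE)
    out2 <- filterReport(v, samples, blacklist = bl, targetGenes = "EGFR")
    expect_false(any(out2$pos == 300))

    # synonymous calls are discarded when effects are present
    v2 <- cbind(makeVariants("S1", af = 0.30, pos = 500L), gene = "KRAS",
                effect = "synonymous")
    expect_equal(nrow(filterReport(v2, samples, targetGenes = "EGFR")), 0L)

    # empty input passes through
    expect_equal(nrow(filterReport(v[0, ], samples)), 0L)

    # sample without cutoffs is an instructive error
    expect_error(filterReport(cbind(makeVariants("S9", 0.5), gene = "X"),
                              samples), "qcReport")
})

test_that("the curated report filter is idempotent", {
    samples <- data.frame(sample_id = c("S1", "S2", "S3"),
                          pre_norm_conc = c(5, 8, 1.0),
                          af_cutoff = c(0.025, 0.05, 0.09),
                          degraded = c(FALSE, FALSE, TRUE))
    set.seed(3)
    v <- do.call(rbind, lapply(c("S1", "S2", "S3"), function(s)
        cbind(makeVariants(s, af = runif(40, 0.01, 0.9),
                           pos = sample(1000:1100, 40)),
              gene = sample(c("EGFR", "KRAS", "TP53"), 40,
                            replace = TRUE))))
    once <- filterReport(v, samples, targetGenes = "EGFR")
    twice <- filterReport(once, samples, targetGenes = "EGFR")
    expect_identical(once, twice)
})

test_that("the bundled curated table fixture parses with the published shape", {
    path <- system.file("extdata", "table1_variants.tsv",
                        package = "ffpeQC")
    tab <- readCuratedTable(path)
    expect_equal(nrow(tab), 25L)
    expect_equal(sum(tab$gene == "TP53"), 11L)
    expect_equal(max(tab$af_percent), 82)
    expect_equal(min(tab$af_percent), 4)
})
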