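test_that("substitution classification maps raw and collapsed classes", {
    expect_equal(classifySubstitution("C", "T"), "C>T")
    expect_equal(classifySubstitution("C", "T", collapsed = TRUE),
                 "C:G>T:A")
    expect_equal(classifySubstitution("G", "A", collapsed = TRUE),
                 "C:G>T:A")
    expect_equal(classifySubstitution("AT", "A"), "indel")
    expect_equal(classifySubstitution("A", "ATT"), "indel")
    expect_equal(classifySubstitution("AC", "GT"), "mnv")
    expect_equal(classifySubstitution(c("C", "G", "T"),
                                      c("A", "T", "G"),
                                      collapsed = TRUE),
                 c("C:G>A:T", "C:G>A:T", "T:A>G:C"))
    expect_error(classifySubstitution("", "T"), "empty")
    expect_error(classifySubstitution("C", "C"), "differ")
})

test_that("AF spectrum counts each variant into exactly one bin", {
    v <- makeVariants("S1", af = c(0.02, 0.05, 0.15))
    sp <- spectrumByAF(v, binEdges = c(0, 0.10, 1))
    counts <- spectrumCounts(sp)
    expect_equal(unname(colSums(counts)), c(2L, 1L))
    expect_equal(sum(counts), 3L)

    # empty input: all-zero table
    expect_equal(sum(spectrumCounts(spectrumByAF(v[0, ]))), 0L)

    # pure C>T low bin
    v2 <- makeVariants("S1", af = rep(0.05, 10))
    cc <- collapseSpectrum(spectrumByAF(v2))
    expect_equal(unname(cc["C:G>T:A", 1]), 10)
    expect_equal(cc["C:G>T:A", 1] /
                     sum(cc[setdiff(rownames(cc), c("mnv", "indel")), 1]),
                 1.0)

    expect_error(spectrumByAF(makeVariants("S1", af = 1.2)), "AF")
    expect_error(spectrumByAF(v, binEdges = c(0, 0.5, 0.4, 1)),
                 "strictly")
})

test_that("spectrum totals are conserved for arbitrary bin edges", {
    set.seed(42)
    for (i in 1:5) {
        n <- sample(5:80, 1)
        v <- makeVariants("S1", af = runif(n, 0.001, 1))
        inner <- sort(runif(sample(1:5, 1), 0.01, 0.99))
        sp <- spectrumByAF(v, binEdges = c(0, inner, 1))
        expect_equal(sum(spectrumCounts(sp)), n)
    }
})

test_that("rank correlation matches the exhaustive permutation oracle", {
    # perfect monotone decrease
    r <- concentrationCorrelation(c(1, 1.3, 1.9, 3, 5, 8),
                                  c(60, 50, 40, 30, 20, 10))
    expect_equal(r$rho, -1)

    x <- c(1, 2, 3, 4, 5); y <- c(10, 8, 9, 5, 1)
    got <- concentrationCorrelation(x, y)
    want <- oracleSpearman(x, y)
    expect_equal(got$rho, want$rho)
    expect_equal(got$p, want$p)
    expect_equal(got$method, "exact permutation")

    # midranks under ties still agree with the oracle
    xt <- c(1, 1, 2, 3, 4); yt <- c(5, 7, 6, 2, 1)
    gotT <- concentrationCorrelation(xt, yt)
    wantT <- oracleSpearman(xt, yt)
    expect_equal(gotT$rho, wantT$rho)
    expect_equal(gotT$p, wantT$p)

    # constant input is undefined, with a warning
    expect_warning(rc <- concentrationCorrelation(rep(2, 5), 1:5))
    expect_true(is.na(rc$rho))
})

test_that("large-n correlation uses the t approximation", {
    set.seed(1)
    x <- runif(30, 1, 30); y <- 100 - 2 * x + rnorm(30, 0, 5)
    r <- concentrationCorrelation(x, y)
    expect_equal(r$method, "t approximation")
    ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
    expect_equal(r$rho, unname(ref$estimate))
    expect_lt(r$p, 0.001)
})

test_that("Fisher enrichment matches closed forms and the enumeration oracle", {
    mk <- function(tab) {
        # build a spectrum whose C>T row and pooled others reproduce tab
        counts <- matrix(0L, length(ffpeQC:::SPECTRUM_CLASSES), 2,
                         dimnames = list(ffpeQC:::SPECTRUM_CLASSES,
                                         c("(0,0.1]", "(0.1,1]")))
        counts["C>T", ] <- tab[1, ]
        counts["A>G", ] <- tab[2, ]
        methods::new("SpectrumTable", counts = counts,
                     binEdges = c(0, 0.1, 1), pooled = TRUE)
    }
    # [[10, 0], [0, 10]]: two-sided p = 2 / choose(20, 10)
    et <- enrichmentTest(mk(matrix(c(10, 0, 0, 10), 2, byrow = TRUE)))
    expect_equal(et$p[et$class == "C>T"], 2 / choose(20, 10),
                 tolerance = 1e-10)
    # balanced table: OR 1, p 1
    et2 <- enrichmentTest(mk(matrix(c(5, 5, 5, 5), 2, byrow = TRUE)))
    expect_equal(et2$odds_ratio[et2$class == "C>T"], 1)
    expect_equal(et2$p[et2$class == "C>T"], 1)
    # random small tables vs exhaustive enumeration
    set.seed(7)
    for (i in 1:20) {
        tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
        while (sum(tab) == 0 || sum(tab) > 20 ||
               any(rowSums(tab) == 0) || any(colSums(tab) == 0))
            tab <- matrix(sample(0:10, 4, replace = TRUE), 2)
        et <- enrichmentTest(mk(tab))
        expect_equal(et$p[et$class == "C>T"],
                     oracleFisherP(tab[1, 1], tab[1, 2],
                                   tab[2, 1], tab[2, 2]),
                     tolerance = 1e-9)
    }
    # empty margin: undefined OR, p = 1
    et3 <- enrichmentTest(mk(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)))
    expect_true(is.na(et3$odds_ratio[et3$class == "C>T"]))
    expect_equal(et3$p[et3$class == "C>T"], 1)
})

test_that("degraded samples are flagged by count outliers and concentration", {
    sheet <- data.frame(sample_id = sprintf("S%02d", 1:26),
                        pre_norm_conc = c(1.0, 1.0, 1.3, 1.3,
                                          seq(1.9, 30, length.out = 22)))
    hiCounts <- c(8, 17, 40, 56, sample(0:2, 22, replace = TRUE))
    set.seed(11)
    v <- do.call(rbind, lapply(seq_len(26), function(i) {
        n <- hiCounts[i]
        if (n == 0) return(NULL)
        makeVariants(sheet$sample_id[i], af = runif(n, 0.12, 0.20),
                     pos = seq_len(n) + 5000L)
    }))
    out <- flagDegraded(sheet, v)
    expect_equal(out$sample_id[out$degraded], sprintf("S%02d", 1:4))

    # all samples identical: none flagged (count rule), none by conc
    sheet2 <- data.frame(sample_id = c("A", "B", "C"),
                         pre_norm_conc = c(5, 5, 5))
    v2 <- rbind(makeVariants("A", rep(0.2, 3), pos = 1:3 + 100L),
                makeVariants("B", rep(0.2, 3), pos = 1:3 + 100L),
                makeVariants("C", rep(0.2, 3), pos = 1:3 + 100L))
    expect_false(any(flagDegraded(sheet2, v2)$degraded))

    # low concentration flags even with zero high-AF variants
    sheet3 <- data.frame(sample_id = c("A", "B", "C"),
                         pre_norm_conc = c(1.4, 5, 8))
    out3 <- flagDegraded(sheet3, v2[0, ])
    expect_equal(out3$degraded, c(TRUE, FALSE, FALSE))

    expect_error(flagDegraded(sheet3, makeVariants("ZZ", 0.5)),
                 "missing")
})

test_that("per-sample AF cutoffs follow the artifact rate and clinical floors", {
    # no artifacts expected: cutoff is the resistance floor
    expect_equal(estimateCutoff(5, fit = 0), 0.025)
    expect_equal(estimateCutoff(5, fit = 0, category = "response"), 0.05)

    # monotone non-increasing in concentration under a fitted model
    sheet <- data.frame(sample_id = sprintf("S%d", 1:8),
                        pre_norm_conc = c(1.9, 2.5, 3.5, 5, 8, 12, 20, 30),
                        degraded = FALSE)
    counts <- c(200, 160, 120, 90, 60, 40, 25, 15)
    fit <- fitArtifactRate(sheet, counts)
    cuts <- vapply(sheet$pre_norm_conc, estimateCutoff, numeric(1),
                   fit = fit)
    expect_true(all(diff(cuts) <= 1e-12))
    expect_true(all(cuts >= 0.025))

    # lambda = 200: cutoff equals the truncated Beta (1 - 1/200) quantile,
    # checked against numeric inversion of the survival function
    m <- artifactAFModel()
    cut <- estimateCutoff(1, fit = 200, afModel = m)
    inv <- uniroot(function(f) 200 * ffpeQC:::artifactAFSurvival(m, f) - 1,
                   c(1e-6, m$max - 1e-9), tol = 1e-12)$root
    expect_equal(cut, inv, tolerance = 1e-6)

    # degenerate concentrations fall back to a constant rate with warning
    sheetC <- data.frame(sample_id = c("A", "B", "C"),
                         pre_norm_conc = c(2, 2, 2), degraded = FALSE)
    expect_warning(fitC <- fitArtifactRate(sheetC, c(10, 12, 14)),
                   "constant")
    expect_equal(predictArtifactRate(fitC, 99), 12)
})

test_that("qcReport assembles counts, flags, correlation and cutoffs", {
    co <- simulateCohort(simulationConfig(seed = 21L))
    qc <- qcReport(cohortVariants(co), sampleSheet(co))
    expect_equal(nrow(qc$samples), 26L)
    expect_lt(qc$correlation$rho, -0.5)
    expect_lt(qc$correlation$p, 0.01)
    expect_true(all(qc$samples$af_cutoff >= 0.025))
    expect_equal(sum(spectrumCounts(qc$spectrum)),
                 nrow(cohortVariants(co)))
    td <- withr::local_tempdir()
    writeQcReport(qc, file.path(td, "qc.json"), file.path(td, "sp.tsv"))
    parsed <- jsonlite::read_json(file.path(td, "qc.json"))
    expect_length(parsed$samples, 26L)
    expect_true(file.exists(file.path(td, "sp.tsv")))
})
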