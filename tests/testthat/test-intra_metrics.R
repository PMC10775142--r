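test_that("identification counting follows presence per replicate", {
    runs <- toyRuns(3)
    # group A in runs 1,2,3; group B in runs 1,3
    m <- matrix(c(100, 100,
                  100, NA,
                  100, 100), 2, 3,
                dimnames = list(NULL, runs))
    b <- makeBundle(runs, pg_int = m)
    res <- countIdentifications(b, "protein_group")
    expect_equal(unname(res$counts), c(2L, 1L, 2L))
    expect_equal(res$median, 2)
    expect_equal(res$n_features, 2L)
    expect_error(countIdentifications(b, "proteins"), "unknown level")
})

test_that("a sequence at two charges is two precursors but one peptide", {
    runs <- toyRuns(2)
    ev <- data.frame(modified_sequence = c("_AAAAK_", "_AAAAK_"),
                     charge = c(2L, 3L), run = runs[1],
                     retention_time = 10, intensity = 100,
                     stringsAsFactors = FALSE)
    b <- makeBundle(runs, pep_int = matrix(c(100, NA), 1, 2),
                    pep_seq = "AAAAK", ev = ev)
    expect_equal(countIdentifications(b, "precursor")$counts[[runs[1]]], 2L)
    expect_equal(countIdentifications(b, "peptide")$counts[[runs[1]]], 1L)
})

test_that("missed-cleavage summary counts distinct peptides", {
    runs <- toyRuns(2)
    b <- makeBundle(runs, pep_int = matrix(100, 4, 2),
                    pep_mc = c(0L, 0L, 1L, 2L))
    mc <- missedCleavageSummary(b)
    expect_equal(unname(mc$counts), c(2L, 1L, 1L))
    expect_equal(mc$percent_zero, 50)

    b2 <- makeBundle(runs, pep_int = matrix(100, 3, 2), pep_mc = 0L)
    expect_equal(missedCleavageSummary(b2)$percent_zero, 100)

    empty <- makeBundle(runs)
    expect_true(is.na(missedCleavageSummary(empty)$percent_zero))
})

test_that("completeness profile counts features by replicate presence", {
    runs <- toyRuns(3)
    m <- matrix(c(1, 1, NA,
                  1, 1, NA,
                  1, NA, NA), 3, 3, byrow = FALSE,
                dimnames = list(NULL, runs))
    # A present 3x, B 2x, C 1x (columns are runs)
    m <- matrix(c(100, 100, 100,
                  100, 100, NA,
                  100, NA, NA), 3, 3, byrow = TRUE,
                dimnames = list(NULL, runs))
    b <- makeBundle(runs, pg_int = m)
    p <- completenessProfile(b, "protein_group")
    expect_equal(p$count_by_k, c("1" = 1L, "2" = 1L, "3" = 1L))
    expect_equal(percentCompleteProfiles(p), 100 / 3)

    full <- makeBundle(runs, pg_int = matrix(100, 5, 3))
    pf <- completenessProfile(full)
    expect_equal(unname(pf$count_by_k), c(0L, 0L, 5L))
    expect_equal(percentCompleteProfiles(pf), 100)

    empty <- makeBundle(runs)
    expect_true(is.na(percentCompleteProfiles(completenessProfile(empty))))
})

test_that("feature CV uses the sample standard deviation", {
    expect_equal(featureCV(c(90, 100, 110)), 10)
    expect_equal(featureCV(c(5, 5, 5, 5)), 0)
    expect_true(is.na(featureCV(100)))
    expect_true(is.na(featureCV(c(100, NA))))
    # scale invariance
    v <- c(13.5, 19.2, 15.8, 14.1)
    expect_equal(featureCV(v * 1000), featureCV(v))
})

test_that("retention-time precision counts precursors strictly below threshold", {
    runs <- toyRuns(3)
    ev <- data.frame(
        modified_sequence = rep(c("_AAAAK_", "_CCCCR_"), each = 3),
        charge = 2L, run = rep(runs, 2),
        retention_time = c(20, 20, 20,      # CV 0 -> below
                           10, 10, 14),     # CV 20.38% -> above
        intensity = 100, stringsAsFactors = FALSE)
    b <- makeBundle(runs, ev = ev)
    rt <- rtPrecision(b, cv_threshold = 5)
    expect_equal(rt$n_evaluable, 2L)
    expect_equal(rt$n_below_threshold, 1L)
    expect_equal(rt$percent_below, 50)
    # hand value: sd(10,10,14)/mean = 2.3094/11.333
    expect_equal(featureCV(c(10, 10, 14)), 20.3771, tolerance = 1e-4)
})

test_that("replicate RT is the median over a precursor's evidence rows", {
    runs <- toyRuns(2)
    ev <- data.frame(
        modified_sequence = "_AAAAK_", charge = 2L,
        run = c(runs[1], runs[1], runs[1], runs[2]),
        retention_time = c(10, 10.2, 55, 10.1),  # split-peak artifact 55
        intensity = 100, stringsAsFactors = FALSE)
    b <- makeBundle(runs, ev = ev)
    rt <- rtPrecision(b, cv_threshold = 5)
    expect_equal(rt$n_evaluable, 1L)
    expect_equal(rt$n_below_threshold, 1L)   # median 10.2 vs 10.1
})

test_that("quantitative precision classifies CVs at the chosen level", {
    runs <- toyRuns(3)
    m <- matrix(c(100, 100, 100,      # CV 0
                  100, 150, 50),      # CV 50 -> above 20
                2, 3, byrow = TRUE, dimnames = list(NULL, runs))
    b <- makeBundle(runs, pg_int = m)
    qp <- quantPrecision(b, "protein_group", 20)
    expect_equal(qp$n_evaluable, 2L)
    expect_equal(qp$n_below_threshold, 1L)
    expect_equal(qp$percent_below, 50)
    expect_equal(featureCV(c(100, 150, 50)), 50)
})

test_that("features with fewer than two values are excluded, not failed", {
    runs <- toyRuns(3)
    m <- matrix(c(100, NA, NA,
                  100, 110, NA), 2, 3, byrow = TRUE,
                dimnames = list(NULL, runs))
    b <- makeBundle(runs, pg_int = m)
    qp <- quantPrecision(b, "protein_group", 20)
    expect_equal(qp$n_evaluable, 1L)
    b0 <- makeBundle(runs, pg_int = matrix(c(100, NA, NA), 1, 3,
                                           dimnames = list(NULL, runs)))
    expect_true(is.na(quantPrecision(b0)$percent_below))
})

test_that("lowering the CV threshold never increases percent below", {
    for (seed in c(21, 22, 23)) {
        b <- randomSmallBundle(seed)
        prev <- Inf
        for (thr in c(50, 20, 10, 5, 1)) {
            qp <- quantPrecision(b, "protein_group", thr)
            if (!is.na(qp$percent_below)) {
                expect_lte(qp$percent_below, prev)
                prev <- qp$percent_below
            }
        }
    }
})

test_that("duplicating a replicate never lowers the full-profile percentage", {
    for (seed in c(31, 32)) {
        b <- randomSmallBundle(seed)
        pct <- percentCompleteProfiles(completenessProfile(b))
        a <- SummarizedExperiment::assay(proteinGroups(b))
        runs2 <- c(runLabels(b),
                   sub("_R1$", paste0("_R", ncol(a) + 1), runLabels(b)[1]))
        a2 <- cbind(a, a[, 1])
        colnames(a2) <- runs2
        b2 <- makeBundle(runs2, pg_int = a2)
        pct2 <- percentCompleteProfiles(completenessProfile(b2))
        # full profiles include run 1, so duplicating run 1 keeps them full
        expect_gte(pct2, pct)
    }
})

test_that("every metric equals its brute-force oracle on random small bundles", {
    for (seed in 101:130) {
        b <- randomSmallBundle(seed)
        for (lv in c("protein_group", "peptide", "precursor")) {
            fast <- countIdentifications(b, lv)
            slow <- oracleCounts(b, lv)
            expect_equal(unname(fast$counts[runLabels(b)]),
                         unname(slow$counts[runLabels(b)]),
                         info = paste(seed, lv))
            expect_equal(fast$median, slow$median)
            expect_equal(fast$n_features, slow$n_features)
            expect_equal(completenessProfile(b, lv)$count_by_k,
                         oracleCompleteness(b, lv), info = paste(seed, lv))
            fq <- quantPrecision(b, lv, 20)
            sq <- oracleQuantPrecision(b, lv, 20)
            expect_equal(fq$n_evaluable, sq$n_evaluable)
            expect_equal(fq$n_below_threshold, sq$n_below)
            expect_equal(fq$percent_below, sq$percent_below)
        }
        fr <- rtPrecision(b, 5)
        sr <- oracleRTPrecision(b, 5)
        expect_equal(fr$n_evaluable, sr$n_evaluable)
        expect_equal(fr$n_below_threshold, sr$n_below)
    }
})

test_that("completeness conservation: profile sums to the distinct-feature union", {
    for (seed in 141:145) {
        b <- randomSmallBundle(seed)
        for (lv in c("protein_group", "peptide", "precursor")) {
            expect_equal(sum(completenessProfile(b, lv)$count_by_k),
                         countIdentifications(b, lv)$n_features)
        }
    }
})

test_that("dataset summary is composition-consistent and deterministic", {
    b <- applyStandardFilters(randomSmallBundle(55))
    s <- summarizeDataset(b)
    expect_equal(s$median_protein_group_ids,
                 countIdentifications(b, "protein_group")$median)
    expect_equal(s$percent_zero_missed_cleavages,
                 missedCleavageSummary(b)$percent_zero)
    expect_equal(s$percent_full_profiles_protein_group,
                 percentCompleteProfiles(completenessProfile(b)))
    expect_equal(s$rt_percent_below, rtPrecision(b)$percent_below)
    expect_equal(s$lfq_pg_percent_below, quantPrecision(b)$percent_below)
    expect_identical(s, summarizeDataset(applyStandardFilters(
        randomSmallBundle(55))))
})
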