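test_that("config validation rejects inconsistent parameters", {
    expect_error(simConfig(missed_cleavage_probs = c(0.9, 0.2, 0.1)),
                 "sum to 1")
    expect_error(simConfig(shared_core_size = 500, n_proteins = 100),
                 "shared_core_size")
    expect_error(simConfig(p_det = 1.2), "probabilities")
    expect_error(simConfig(rt_jitter_sd = -1), "spread")
    expect_error(simConfig(acquisitions = "SRM"), "acquisitions")
})

test_that("ground truth and measurements regenerate identically from a seed", {
    cfg <- simConfig(n_proteins = 40, shared_core_size = 20, seed = 9)
    t1 <- sampleGroundTruth(cfg)
    t2 <- sampleGroundTruth(cfg)
    expect_identical(t1$proteins, t2$proteins)
    expect_identical(t1$precursors, t2$precursors)
    m1 <- simulateMeasurements(t1)
    m2 <- simulateMeasurements(t2)
    expect_identical(m1, m2)
})

test_that("peptide/precursor/protein linkage is one-to-one upward", {
    truth <- sampleGroundTruth(simConfig(n_proteins = 50,
                                         shared_core_size = 25, seed = 3))
    expect_true(all(truth$peptides$parent %in%
                    seq_len(nrow(truth$proteins))))
    expect_true(all(truth$precursors$peptide %in%
                    seq_len(nrow(truth$peptides))))
    expect_false(anyDuplicated(truth$peptides$sequence) > 0)
    # every precursor maps to exactly one peptide by construction
    key <- paste(truth$precursors$modified_sequence,
                 truth$precursors$charge)
    expect_false(anyDuplicated(key) > 0)
})

test_that("missed-cleavage classes follow the configured multinomial", {
    cfg <- simConfig(n_proteins = 500, shared_core_size = 250,
                     peptides_per_protein_lambda = 4,
                     missed_cleavage_probs = c(0.8, 0.15, 0.05), seed = 5)
    truth <- sampleGroundTruth(cfg)
    mc <- truth$peptides$missed_cleavages
    n <- length(mc)
    expect_gt(n, 1500)
    # simultaneous 99% bounds over the three classes (Bonferroni split)
    for (k in 0:2) {
        p <- cfg$missed_cleavage_probs[k + 1]
        bounds <- qbinom(c(0.005 / 3, 1 - 0.005 / 3), n, p)
        expect_gte(sum(mc == k), bounds[1])
        expect_lte(sum(mc == k), bounds[2])
    }
})

test_that("boundary configs produce valid studies", {
    # all proteins shared: every lab sees the same inventory
    cfg <- simConfig(n_proteins = 30, shared_core_size = 30,
                     contaminant_fraction = 0, reverse_fraction = 0,
                     only_by_site_fraction = 0, spike_in_count = 0,
                     time_points = "T1", seed = 2)
    truth <- sampleGroundTruth(cfg)
    expect_true(all(truth$visibility))
    # degenerate: single protein, single replicate
    cfg1 <- simConfig(labs = "LabA", time_points = "T1", n_proteins = 1,
                      shared_core_size = 1, n_replicates = 1,
                      contaminant_fraction = 0, reverse_fraction = 0,
                      only_by_site_fraction = 0, spike_in_count = 0,
                      p_det = 1, seed = 4)
    st <- simulateStudy(cfg1, withr::local_tempdir())
    d <- readStudyDesign(st$design_path)
    e <- d$datasets[[1]]
    b <- readDataset(e$protein_groups, e$peptides, e$evidence,
                     e$run_labels, e$dataset_id)
    expect_equal(nrow(proteinGroups(b)), 1L)
})

test_that("written files round-trip bit-exactly through the readers", {
    cfg <- simConfig(n_proteins = 40, shared_core_size = 20,
                     labs = c("LabA", "LabB"), time_points = "T1",
                     n_replicates = 4, seed = 11)
    dir1 <- withr::local_tempdir()
    st <- simulateStudy(cfg, dir1)
    # read every data set back and re-write: byte-identical files
    dir2 <- withr::local_tempdir()
    for (tab in st$tables) {
        b <- readDataset(st$paths[[tab$dataset_id]]$protein_groups,
                         st$paths[[tab$dataset_id]]$peptides,
                         st$paths[[tab$dataset_id]]$evidence,
                         tab$run_labels, tab$dataset_id)
        # reader values equal the in-memory tables (0 -> NA convention)
        lfq_cols <- paste("LFQ intensity", tab$run_labels)
        mem <- as.matrix(tab$protein_groups[, lfq_cols])
        mem[mem == 0] <- NA
        got <- SummarizedExperiment::assay(proteinGroups(b))
        dimnames(got) <- NULL; dimnames(mem) <- NULL
        expect_equal(got, mem)
        expect_equal(evidence(b)$retention_time,
                     tab$evidence[["Retention time"]])
    }
    st2 <- simulateStudy(cfg, dir2)
    for (id in names(st$paths)) {
        for (f in names(st$paths[[id]])) {
            expect_identical(readLines(st$paths[[id]][[f]]),
                             readLines(st2$paths[[id]][[f]]))
        }
    }
})

test_that("spike-in rows carry PROCAL identifiers and filter out fully", {
    cfg <- simConfig(n_proteins = 30, shared_core_size = 15,
                     labs = "LabA", time_points = "T1", n_replicates = 3,
                     spike_in_count = 8, seed = 13)
    st <- simulateStudy(cfg, withr::local_tempdir())
    e <- readStudyDesign(st$design_path)$datasets[[1]]
    b <- readDataset(e$protein_groups, e$peptides, e$evidence,
                     e$run_labels, e$dataset_id)
    # spike-ins are always detected, so all 8 peptides appear
    rd <- SummarizedExperiment::rowData(peptides(b))
    expect_equal(sum(grepl("PROCAL", rd$sequence)), 8L)
    f <- applyStandardFilters(b)
    expect_equal(sum(grepl("PROCAL", SummarizedExperiment::rowData(
        peptides(f))$sequence)), 0L)
    expect_equal(sum(grepl("PROCAL", SummarizedExperiment::rowData(
        proteinGroups(f))$majority_ids)), 0L)
    expect_equal(sum(grepl("PROCAL", evidence(f)$modified_sequence)), 0L)
    rep_ <- filterReport(f)
    expect_equal(rep_$removed_spike_in[rep_$level == "peptide"], 8L)
})

test_that("zero RT jitter yields perfect retention-time precision", {
    cfg <- simConfig(n_proteins = 30, shared_core_size = 15,
                     labs = "LabA", time_points = "T1", n_replicates = 5,
                     rt_jitter_sd = 0, p_det = 0.9, seed = 17)
    st <- simulateStudy(cfg, withr::local_tempdir())
    e <- readStudyDesign(st$design_path)$datasets[[1]]
    b <- applyStandardFilters(readDataset(e$protein_groups, e$peptides,
        e$evidence, e$run_labels, e$dataset_id))
    expect_equal(rtPrecision(b, 5)$percent_below, 100)
})

test_that("full detection probability yields 100% complete profiles", {
    cfg <- simConfig(n_proteins = 25, shared_core_size = 25,
                     labs = "LabA", time_points = "T1", n_replicates = 4,
                     contaminant_fraction = 0, reverse_fraction = 0,
                     only_by_site_fraction = 0, p_det = 1, seed = 19)
    st <- simulateStudy(cfg, withr::local_tempdir())
    e <- readStudyDesign(st$design_path)$datasets[[1]]
    b <- applyStandardFilters(readDataset(e$protein_groups, e$peptides,
        e$evidence, e$run_labels, e$dataset_id))
    for (lv in c("protein_group", "peptide", "precursor"))
        expect_equal(percentCompleteProfiles(completenessProfile(b, lv)),
                     100)
})

test_that("DIA data sets are more complete than DDA under the default laws", {
    cfg <- simConfig(n_proteins = 150, shared_core_size = 150,
                     labs = "LabA", time_points = "T1",
                     acquisitions = c("DDA", "DIA"), n_replicates = 6,
                     seed = 23)
    st <- simulateStudy(cfg, withr::local_tempdir())
    pct <- vapply(readStudyDesign(st$design_path)$datasets, function(e) {
        b <- applyStandardFilters(readDataset(e$protein_groups,
            e$peptides, e$evidence, e$run_labels, e$dataset_id))
        percentCompleteProfiles(completenessProfile(b, "precursor"))
    }, 0)
    ids <- vapply(readStudyDesign(st$design_path)$datasets,
                  `[[`, "", "dataset_id")
    expect_gt(pct[grepl("DIA", ids)], pct[grepl("DDA", ids)])
})
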