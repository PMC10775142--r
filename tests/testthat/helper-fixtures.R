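# In-code fixture builders: small MQDataset objects assembled directly,
# plus hand-written MaxQuant-dialect files for the reader tests.

emptyEvidence <- function() {
    S4Vectors::DataFrame(
        modified_sequence = character(), sequence = character(),
        charge = integer(), run = character(),
        retention_time = numeric(), intensity = numeric(),
        reverse = logical(), contaminant = logical())
}

makeBundle <- function(runs,
                       pg_int = NULL, pg_ids = NULL,
                       pg_rev = FALSE, pg_con = FALSE, pg_obs = FALSE,
                       pep_int = NULL, pep_seq = NULL, pep_mc = 0L,
                       pep_rev = FALSE, pep_con = FALSE,
                       ev = NULL, id = "DS1") {
    n <- length(runs)
    if (is.null(pg_int)) pg_int <- matrix(NA_real_, 0L, n)
    colnames(pg_int) <- runs
    npg <- nrow(pg_int)
    if (is.null(pg_ids)) pg_ids <- sprintf("P%03d", seq_len(npg))
    pg <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = pg_int),
        rowData = S4Vectors::DataFrame(
            group_id = as.character(seq_len(npg)),
            majority_ids = pg_ids,
            reverse = rep_len(pg_rev, npg),
            contaminant = rep_len(pg_con, npg),
            only_by_site = rep_len(pg_obs, npg)))
    if (is.null(pep_int)) pep_int <- matrix(NA_real_, 0L, n)
    colnames(pep_int) <- runs
    npep <- nrow(pep_int)
    if (is.null(pep_seq)) pep_seq <- sprintf("PEPTIDE%03dK", seq_len(npep))
    pep <- SummarizedExperiment::SummarizedExperiment(
        assays = list(intensity = pep_int),
        rowData = S4Vectors::DataFrame(
            sequence = pep_seq,
            missed_cleavages = rep_len(as.integer(pep_mc), npep),
            reverse = rep_len(pep_rev, npep),
            contaminant = rep_len(pep_con, npep)))
    if (is.null(ev)) ev <- emptyEvidence()
    if (is.data.frame(ev)) {
        ev$sequence <- ev$sequence %||% gsub("_", "", ev$modified_sequence)
        ev$reverse <- ev$reverse %||% FALSE
        ev$contaminant <- ev$contaminant %||% FALSE
        ev$intensity <- ev$intensity %||% NA_real_
        ev <- S4Vectors::DataFrame(
            modified_sequence = ev$modified_sequence,
            sequence = ev$sequence,
            charge = as.integer(ev$charge), run = ev$run,
            retention_time = as.numeric(ev$retention_time),
            intensity = as.numeric(ev$intensity),
            reverse = rep_len(ev$reverse, nrow(ev)),
            contaminant = rep_len(ev$contaminant, nrow(ev)))
    }
    rl <- mqbench::parseRunLabel(runs)
    methods::new("MQDataset", datasetId = id, runs = rl,
                 proteinGroups = pg, peptides = pep, evidence = ev,
                 metadata = list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toyRuns <- function(n = 3, tp = "T1", lab = "LabA", acq = "DDA")
    sprintf("%s_%s_lcx_msx_%s_R%d", tp, lab, acq, seq_len(n))

# random small bundle for oracle-equivalence checks (base R only, built
# independently of the synthetic_data module)
randomSmallBundle <- function(seed) {
    set.seed(seed)
    n <- sample(2:5, 1)
    runs <- toyRuns(n)
    npg <- sample(1:20, 1)
    pg_int <- matrix(ifelse(runif(npg * n) < 0.7,
                            round(runif(npg * n, 10, 1000), 2), NA),
                     npg, n)
    # guarantee every group appears somewhere
    for (i in which(rowSums(!is.na(pg_int)) == 0))
        pg_int[i, sample(n, 1)] <- round(runif(1, 10, 1000), 2)
    pg_ids <- sprintf("P%03d", seq_len(npg))
    pair <- runif(npg) < 0.2
    pg_ids[pair] <- paste0(pg_ids[pair], ";X", seq_len(sum(pair)))
    npep <- sample(1:20, 1)
    pep_int <- matrix(ifelse(runif(npep * n) < 0.6,
                             round(runif(npep * n, 10, 1000), 2), NA),
                      npep, n)
    nev <- sample(0:40, 1)
    ev <- if (nev > 0) data.frame(
        modified_sequence = paste0("_SEQ", sample(1:8, nev, TRUE), "_"),
        charge = sample(2:3, nev, TRUE),
        run = sample(runs, nev, TRUE),
        retention_time = round(runif(nev, 5, 60), 3),
        intensity = ifelse(runif(nev) < 0.8,
                           round(runif(nev, 10, 1000), 2), NA),
        stringsAsFactors = FALSE) else NULL
    makeBundle(runs, pg_int = pg_int, pg_ids = pg_ids,
               pep_int = pep_int, pep_mc = sample(0:2, npep, TRUE),
               ev = ev, id = paste0("RB", seed))
}

# hand-written MaxQuant-dialect files for the readers
writeToyMQFiles <- function(dir, runs = toyRuns(2)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    pg <- data.frame(
        id = c("0", "1", "2", "3"),
        "Majority protein IDs" = c("P02768;A0A024R6I7", "P00738",
                                   "REV__P11111", "CON__P22222"),
        Reverse = c("", "", "+", ""),
        "Potential contaminant" = c("", "", "", "+"),
        "Only identified by site" = c("", "", "", ""),
        check.names = FALSE, stringsAsFactors = FALSE)
    pg[[paste("LFQ intensity", runs[1])]] <- c("1000.5", "0", "50", "60")
    pg[[paste("LFQ intensity", runs[2])]] <- c("1100.25", "900", "0", "70")
    pep <- data.frame(
        Sequence = c("AAAAK", "CCCCR", "DDDDK"),
        "Missed cleavages" = c(0L, 1L, 2L),
        Reverse = c("", "", ""),
        "Potential contaminant" = c("", "", ""),
        check.names = FALSE, stringsAsFactors = FALSE)
    pep[[paste("Intensity", runs[1])]] <- c("500", "0", "0")
    pep[[paste("Intensity", runs[2])]] <- c("600", "700", "0")
    ev <- data.frame(
        "Modified sequence" = c("_AAAAK_", "_AAAAK_", "_CCCCR_"),
        Charge = c(2L, 3L, 2L),
        "Raw file" = c(runs[1], runs[1], runs[2]),
        "Retention time" = c(10.5, 10.6, 63.2),
        Intensity = c("100", "0", "300"),
        Reverse = c("", "", ""),
        "Potential contaminant" = c("", "", ""),
        check.names = FALSE, stringsAsFactors = FALSE)
    paths <- list(pg = file.path(dir, "proteinGroups.txt"),
                  pep = file.path(dir, "peptides.txt"),
                  ev = file.path(dir, "evidence.txt"))
    write.table(pg, paths$pg, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(pep, paths$pep, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(ev, paths$ev, sep = "\t", quote = FALSE, row.names = FALSE)
    paths
}
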