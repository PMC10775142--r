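#' Configuration for the multicenter study simulator
#'
#' Builds and validates the parameter set for a synthetic round-robin
#' study: a set of laboratories, each measuring the same sample in
#' technical replicates at one or more time points and acquisition modes,
#' emitted in the MaxQuant table dialect with known ground truth.
#'
#' Proteins are partitioned into a shared core detected by every
#' laboratory plus lab-private sets, which drives the interlaboratory
#' overlap structure. Detection is independent across replicates with a
#' per-precursor probability drawn from an acquisition-specific Beta law
#' (DIA tighter and higher than DDA, mirroring the completeness contrast
#' between the modes) unless a fixed \code{p_det} is given. Replicate
#' intensity noise is lognormal with sigma chosen so the intensity CV
#' equals \code{intensity_cv} (CV = sqrt(exp(sigma^2) - 1)); retention
#' times get homoscedastic Gaussian jitter on a fixed gradient.
#'
#' @param labs character vector of laboratory identifiers.
#' @param time_points character vector, e.g. \code{c("T1", "T2")}.
#' @param acquisitions acquisition modes per lab, \code{"DDA"} and/or
#'   \code{"DIA"}.
#' @param n_replicates technical replicates per data set (default 10).
#' @param n_proteins number of true sample proteins.
#' @param shared_core_size proteins visible to every laboratory; the rest
#'   are divided among labs as lab-private proteins.
#' @param contaminant_fraction,reverse_fraction,only_by_site_fraction
#'   fractions of \code{n_proteins} added as flagged contaminant, decoy
#'   and only-by-site rows.
#' @param peptides_per_protein_lambda Poisson mean for peptides per
#'   protein (at least 1).
#' @param missed_cleavage_probs probabilities for 0/1/2 missed cleavages
#'   (must sum to 1).
#' @param charge_probs named probabilities for precursor charge states.
#' @param extra_charge_prob probability a peptide yields a second charge
#'   state.
#' @param p_det fixed detection probability overriding the Beta laws
#'   (\code{NULL} to use them).
#' @param beta_dda,beta_dia shape parameters \code{c(a, b)} of the
#'   detection-probability Beta law per acquisition mode.
#' @param core_p_det optional fixed detection probability for shared-core
#'   precursors (e.g. 1 to plant an always-detected core).
#' @param log_intensity_location,log_intensity_spread normal parameters of
#'   per-precursor base log-intensity.
#' @param intensity_cv target replicate intensity CV (fraction, not
#'   percent).
#' @param gradient_length LC gradient length in minutes.
#' @param rt_jitter_sd retention-time jitter SD in minutes.
#' @param spike_in_count number of PROCAL iRT spike-in peptides.
#' @param group_pair_fraction fraction of protein groups reported with a
#'   second, semicolon-joined majority accession.
#' @param sample_matrix sample matrix label recorded in the design.
#' @param seed integer seed; the full study regenerates bit-identically
#'   from (config, seed).
#' @return validated config list of class \code{"mq_sim_config"}.
#' @export
simConfig <- function(labs = c("LabA", "LabB"),
                      time_points = c("T1", "T2"),
                      acquisitions = "DDA",
                      n_replicates = 10L,
                      n_proteins = 200L,
                      shared_core_size = 100L,
                      contaminant_fraction = 0.05,
                      reverse_fraction = 0.05,
                      only_by_site_fraction = 0.02,
                      peptides_per_protein_lambda = 4,
                      missed_cleavage_probs = c(0.80, 0.15, 0.05),
                      charge_probs = c("2" = 0.7, "3" = 0.25, "4" = 0.05),
                      extra_charge_prob = 0.2,
                      p_det = NULL,
                      beta_dda = c(4, 2),
                      beta_dia = c(12, 2),
                      core_p_det = NULL,
                      log_intensity_location = log(1e6),
                      log_intensity_spread = 1.5,
                      intensity_cv = 0.10,
                      gradient_length = 60,
                      rt_jitter_sd = 0.15,
                      spike_in_count = 10L,
                      group_pair_fraction = 0.05,
                      sample_matrix = "plasma",
                      seed = 1L) {
    cfg <- list(labs = labs, time_points = time_points,
                acquisitions = acquisitions,
                n_replicates = as.integer(n_replicates),
                n_proteins = as.integer(n_proteins),
                shared_core_size = as.integer(shared_core_size),
                contaminant_fraction = contaminant_fraction,
                reverse_fraction = reverse_fraction,
                only_by_site_fraction = only_by_site_fraction,
                peptides_per_protein_lambda = peptides_per_protein_lambda,
                missed_cleavage_probs = missed_cleavage_probs,
                charge_probs = charge_probs,
                extra_charge_prob = extra_charge_prob,
                p_det = p_det, beta_dda = beta_dda, beta_dia = beta_dia,
                core_p_det = core_p_det,
                log_intensity_location = log_intensity_location,
                log_intensity_spread = log_intensity_spread,
                intensity_cv = intensity_cv,
                gradient_length = gradient_length,
                rt_jitter_sd = rt_jitter_sd,
                spike_in_count = as.integer(spike_in_count),
                group_pair_fraction = group_pair_fraction,
                sample_matrix = sample_matrix,
                seed = as.integer(seed))
    probs <- c(cfg$missed_cleavage_probs, cfg$charge_probs,
               cfg$extra_charge_prob, cfg$contaminant_fraction,
               cfg$reverse_fraction, cfg$only_by_site_fraction,
               cfg$group_pair_fraction, cfg$p_det, cfg$core_p_det)
    if (any(probs < 0 | probs > 1))
        stop("all probabilities must lie in [0, 1]", call. = FALSE)
    if (abs(sum(cfg$missed_cleavage_probs) - 1) > 1e-8)
        stop("missed_cleavage_probs must sum to 1", call. = FALSE)
    if (abs(sum(cfg$charge_probs) - 1) > 1e-8)
        stop("charge_probs must sum to 1", call. = FALSE)
    if (cfg$shared_core_size > cfg$n_proteins)
        stop("shared_core_size must be <= n_proteins", call. = FALSE)
    if (cfg$n_replicates < 1L || cfg$n_proteins < 1L)
        stop("n_replicates and n_proteins must be >= 1", call. = FALSE)
    if (cfg$rt_jitter_sd < 0 || cfg$intensity_cv < 0 ||
        cfg$log_intensity_spread < 0)
        stop("spread parameters must be >= 0", call. = FALSE)
    if (!all(cfg$acquisitions %in% c("DDA", "DIA")))
        stop("acquisitions must be 'DDA' and/or 'DIA'", call. = FALSE)
    class(cfg) <- "mq_sim_config"
    cfg
}

.randomPeptideSequence <- function(n) {
    aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]  # no K/R internally
    vapply(seq_len(n), function(i) {
        len <- sample(7:15, 1L)
        paste0(paste(sample(aa, len, replace = TRUE), collapse = ""),
               sample(c("K", "R"), 1L))
    }, "")
}

#' Sample the ground truth of a synthetic study
#'
#' Draws the protein inventory (shared core, lab-private proteins,
#' flagged contaminant/decoy/only-by-site and PROCAL spike-in entries),
#' the peptides with their missed-cleavage classes, and the precursors
#' with charge, true retention time, base log-intensity and per-mode
#' detection probabilities. Fully deterministic given the config seed.
#'
#' @param config an \code{\link{simConfig}} object.
#' @return list of class \code{"mq_ground_truth"} with data frames
#'   \code{proteins}, \code{peptides}, \code{precursors}, the data-set
#'   grid \code{datasets}, and the \code{config}.
#' @export
sampleGroundTruth <- function(config) {
    stopifnot(inherits(config, "mq_sim_config"))
    set.seed(config$seed)
    np <- config$n_proteins
    n_con <- round(config$contaminant_fraction * np)
    n_rev <- round(config$reverse_fraction * np)
    n_obs <- round(config$only_by_site_fraction * np)

    acc <- sprintf("P%05d", seq_len(np + n_obs))
    proteins <- data.frame(
        accession = c(acc,
                      if (n_con) paste0("CON__", sprintf("Q%05d", seq_len(n_con))),
                      if (n_rev) paste0("REV__", sprintf("P%05d", seq_len(n_rev))),
                      if (config$spike_in_count) "PROCAL_iRT"),
        is_contaminant = c(rep(FALSE, np + n_obs), rep(TRUE, n_con),
                           rep(FALSE, n_rev),
                           rep(FALSE, config$spike_in_count > 0L)),
        is_reverse = c(rep(FALSE, np + n_obs + n_con), rep(TRUE, n_rev),
                       rep(FALSE, config$spike_in_count > 0L)),
        is_spike_in = c(rep(FALSE, np + n_obs + n_con + n_rev),
                        rep(TRUE, config$spike_in_count > 0L)),
        only_by_site = c(rep(FALSE, np), rep(TRUE, n_obs),
                         rep(FALSE, n_con + n_rev),
                         rep(FALSE, config$spike_in_count > 0L)),
        stringsAsFactors = FALSE)
    nprot <- nrow(proteins)
    proteins$is_core <- c(seq_len(np) <= config$shared_core_size,
                          rep(TRUE, nprot - np))

    # lab visibility: core + auxiliaries everywhere, privates round-robin
    vis <- matrix(TRUE, nprot, length(config$labs),
                  dimnames = list(proteins$accession, config$labs))
    private <- which(seq_len(nprot) <= np & !proteins$is_core)
    if (length(private) && length(config$labs) > 1L) {
        owner <- rep_len(seq_along(config$labs), length(private))
        vis[private, ] <- FALSE
        vis[cbind(private, owner)] <- TRUE
    }

    # a fraction of groups carries a second, indistinguishable accession
    second <- stats::runif(nprot) < config$group_pair_fraction &
        !proteins$is_reverse & !proteins$is_spike_in
    proteins$majority_ids <- ifelse(second,
        paste0(proteins$accession, ";", proteins$accession, "b"),
        proteins$accession)

    # peptides per protein; spike-in sequences carry the PROCAL identifier
    n_pep <- pmax(1L, stats::rpois(nprot, config$peptides_per_protein_lambda))
    if (proteins$is_spike_in[nprot]) n_pep[nprot] <- config$spike_in_count
    parent <- rep(seq_len(nprot), n_pep)
    n_total <- length(parent)
    seqs <- .randomPeptideSequence(n_total)
    spike_pep <- proteins$is_spike_in[parent]
    seqs[spike_pep] <- sprintf("PROCAL%02dSEQ%s", seq_len(sum(spike_pep)),
                               substr(seqs[spike_pep], 1, 6))
    peptides <- data.frame(
        sequence = seqs,
        accession = proteins$accession[parent],
        parent = parent,
        missed_cleavages = sample(0:2, n_total, replace = TRUE,
                                  prob = config$missed_cleavage_probs),
        stringsAsFactors = FALSE)
    # uniqueness of sequences (collisions are astronomically rare, but the
    # one-peptide-one-protein invariant must hold exactly)
    while (anyDuplicated(peptides$sequence)) {
        dup <- duplicated(peptides$sequence)
        peptides$sequence[dup] <- .randomPeptideSequence(sum(dup))
    }

    # precursors: each peptide at one charge, a second state with prob
    charges <- as.integer(names(config$charge_probs))
    c1 <- sample(charges, n_total, replace = TRUE,
                 prob = config$charge_probs)
    extra <- stats::runif(n_total) < config$extra_charge_prob &
        length(charges) > 1L
    c2 <- vapply(seq_len(n_total), function(i) {
        if (!extra[i]) return(NA_integer_)
        sample(setdiff(charges, c1[i]), 1L)
    }, 0L)
    pep_idx <- c(seq_len(n_total), which(extra))
    charge <- c(c1, c2[extra])
    n_prec <- length(pep_idx)
    beta_draw <- function(ab) stats::rbeta(n_prec, ab[1], ab[2])
    precursors <- data.frame(
        peptide = pep_idx,
        modified_sequence = paste0("_", peptides$sequence[pep_idx], "_"),
        charge = charge,
        true_rt = round(stats::runif(n_prec, 0.05, 0.95) *
                        config$gradient_length, 4),
        log_intensity = stats::rnorm(n_prec, config$log_intensity_location,
                                     config$log_intensity_spread),
        p_dda = if (is.null(config$p_det)) beta_draw(config$beta_dda)
                else rep(config$p_det, n_prec),
        p_dia = if (is.null(config$p_det)) beta_draw(config$beta_dia)
                else rep(config$p_det, n_prec),
        stringsAsFactors = FALSE)
    prot_of_prec <- peptides$parent[precursors$peptide]
    if (!is.null(config$core_p_det)) {
        core_prec <- proteins$is_core[prot_of_prec] &
            seq_len(nprot)[prot_of_prec] <= np
        precursors$p_dda[core_prec] <- config$core_p_det
        precursors$p_dia[core_prec] <- config$core_p_det
    }
    # decoy hits are rare; spike-ins are always detected
    rev_prec <- proteins$is_reverse[prot_of_prec]
    precursors$p_dda[rev_prec] <- pmin(precursors$p_dda[rev_prec], 0.1)
    precursors$p_dia[rev_prec] <- pmin(precursors$p_dia[rev_prec], 0.1)
    spike_prec <- proteins$is_spike_in[prot_of_prec]
    precursors$p_dda[spike_prec] <- 1
    precursors$p_dia[spike_prec] <- 1

    grid <- expand.grid(acquisition = config$acquisitions,
                        lab = config$labs,
                        time_point = config$time_points,
                        stringsAsFactors = FALSE)
    lab_idx <- match(grid$lab, config$labs)
    datasets <- data.frame(
        dataset_id = sprintf("%s_%s_lc%d_ms%d_%s", grid$time_point,
                             grid$lab, lab_idx, lab_idx, grid$acquisition),
        time_point = grid$time_point, lab = grid$lab,
        lc_system = paste0("lc", lab_idx),
        ms_instrument = paste0("ms", lab_idx),
        acquisition = grid$acquisition,
        stringsAsFactors = FALSE)

    structure(list(proteins = proteins, visibility = vis,
                   peptides = peptides, precursors = precursors,
                   datasets = datasets, config = config),
              class = "mq_ground_truth")
}

#' Simulate the measurement tables of a synthetic study
#'
#' Realizes every data set of the ground truth: each visible precursor is
#' detected independently per replicate with its detection probability;
#' detected precursors get jittered retention times and lognormal
#' intensity noise; peptide intensities are the sums of their detected
#' precursors and protein LFQ values the sums of their peptides.
#' Undetected features carry intensity 0, the MaxQuant convention for
#' absent quantification.
#'
#' @param truth ground truth from [sampleGroundTruth()].
#' @return named list (one element per data set) of lists with
#'   \code{dataset_id}, \code{run_labels}, and data frames
#'   \code{protein_groups}, \code{peptides}, \code{evidence} in the exact
#'   column dialect the readers consume.
#' @export
simulateMeasurements <- function(truth) {
    stopifnot(inherits(truth, "mq_ground_truth"))
    cfg <- truth$config
    set.seed(cfg$seed + 1L)
    sigma_ln <- sqrt(log(1 + cfg$intensity_cv^2))
    prec <- truth$precursors
    pep <- truth$peptides
    prot <- truth$proteins
    prot_of_prec <- pep$parent[prec$peptide]
    nrep <- cfg$n_replicates

    out <- list()
    for (d in seq_len(nrow(truth$datasets))) {
        ds <- truth$datasets[d, ]
        run_labels <- sprintf("%s_%s_%s_%s_%s_R%d", ds$time_point, ds$lab,
                              ds$lc_system, ds$ms_instrument,
                              ds$acquisition, seq_len(nrep))
        visible <- truth$visibility[, ds$lab]
        vis_prec <- which(visible[prot_of_prec])
        p <- if (ds$acquisition == "DIA") prec$p_dia[vis_prec]
             else prec$p_dda[vis_prec]
        nv <- length(vis_prec)
        det <- matrix(stats::runif(nv * nrep), nv, nrep) < p
        rt <- round(matrix(prec$true_rt[vis_prec], nv, nrep) +
                    matrix(stats::rnorm(nv * nrep, 0, cfg$rt_jitter_sd),
                           nv, nrep), 4)
        rt[rt < 0] <- 0
        inten <- round(exp(matrix(prec$log_intensity[vis_prec], nv, nrep) +
                           matrix(stats::rnorm(nv * nrep, 0, sigma_ln),
                                  nv, nrep)), 2)

        hit <- which(det, arr.ind = TRUE)
        gi <- vis_prec[hit[, 1]]
        ord <- order(hit[, 2], gi)
        hit <- hit[ord, , drop = FALSE]
        gi <- gi[ord]
        evidence <- data.frame(
            "Modified sequence" = prec$modified_sequence[gi],
            "Charge" = prec$charge[gi],
            "Raw file" = run_labels[hit[, 2]],
            "Retention time" = rt[hit],
            "Intensity" = inten[hit],
            "Reverse" = ifelse(prot$is_reverse[prot_of_prec[gi]], "+", ""),
            "Potential contaminant" =
                ifelse(prot$is_contaminant[prot_of_prec[gi]], "+", ""),
            check.names = FALSE, stringsAsFactors = FALSE)

        # peptide intensities: sum of detected precursors per run
        pval <- inten * det
        pep_run <- rowsum(pval, group = pep$sequence[prec$peptide[vis_prec]])
        pep_seqs <- rownames(pep_run)
        pep_row <- match(pep_seqs, pep$sequence)
        keep <- rowSums(pep_run) > 0
        pep_run <- round(pep_run[keep, , drop = FALSE], 2)
        pep_row <- pep_row[keep]
        peptides_df <- data.frame(
            "Sequence" = pep$sequence[pep_row],
            "Missed cleavages" = pep$missed_cleavages[pep_row],
            "Reverse" = ifelse(prot$is_reverse[pep$parent[pep_row]], "+", ""),
            "Potential contaminant" =
                ifelse(prot$is_contaminant[pep$parent[pep_row]], "+", ""),
            check.names = FALSE, stringsAsFactors = FALSE)
        colnames(pep_run) <- paste("Intensity", run_labels)
        peptides_df <- cbind(peptides_df, as.data.frame(pep_run,
            check.names = FALSE, row.names = NULL))

        # protein LFQ: sum of member peptides per run
        prot_run <- rowsum(pep_run, group = pep$parent[pep_row])
        prot_idx <- as.integer(rownames(prot_run))
        prot_run <- round(prot_run, 2)
        pg_df <- data.frame(
            "id" = as.character(seq_along(prot_idx)),
            "Majority protein IDs" = prot$majority_ids[prot_idx],
            "Reverse" = ifelse(prot$is_reverse[prot_idx], "+", ""),
            "Potential contaminant" =
                ifelse(prot$is_contaminant[prot_idx], "+", ""),
            "Only identified by site" =
                ifelse(prot$only_by_site[prot_idx], "+", ""),
            check.names = FALSE, stringsAsFactors = FALSE)
        colnames(prot_run) <- paste("LFQ intensity", run_labels)
        pg_df <- cbind(pg_df, as.data.frame(prot_run, check.names = FALSE,
                                            row.names = NULL))

        out[[ds$dataset_id]] <- list(
            dataset_id = ds$dataset_id,
            sample_matrix = cfg$sample_matrix,
            run_labels = run_labels,
            protein_groups = pg_df,
            peptides = peptides_df,
            evidence = evidence)
    }
    out
}

#' Write simulated tables as MaxQuant-dialect files
#'
#' One directory per data set containing \code{proteinGroups.txt},
#' \code{peptides.txt} and \code{evidence.txt} exactly as the readers
#' expect them (tab-separated, \code{"+"} flags, 0 for undetected).
#'
#' @param tables output of [simulateMeasurements()].
#' @param out_dir output directory (created if needed).
#' @return named list of per-data-set file path lists, invisibly.
#' @export
writeMaxQuantFiles <- function(tables, out_dir) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(out_dir))
        stop("cannot create output directory ", out_dir, call. = FALSE)
    paths <- lapply(tables, function(tab) {
        d <- file.path(out_dir, tab$dataset_id)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        p <- list(protein_groups = file.path(d, "proteinGroups.txt"),
                  peptides = file.path(d, "peptides.txt"),
                  evidence = file.path(d, "evidence.txt"))
        utils::write.table(tab$protein_groups, p$protein_groups,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(tab$peptides, p$peptides,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(tab$evidence, p$evidence,
                           sep = "\t", quote = FALSE, row.names = FALSE)
        p
    })
    invisible(paths)
}

#' Generate and write a complete synthetic study
#'
#' Convenience wrapper: samples the ground truth, simulates the
#' measurements, writes the MaxQuant-dialect files, a study design YAML
#' and a ground-truth JSON.
#'
#' @param config an \code{\link{simConfig}} object.
#' @param out_dir output directory.
#' @return list with \code{design_path}, \code{truth_path}, \code{truth},
#'   \code{tables} and per-data-set \code{paths}.
#' @export
simulateStudy <- function(config, out_dir) {
    truth <- sampleGroundTruth(config)
    tables <- simulateMeasurements(truth)
    paths <- writeMaxQuantFiles(tables, out_dir)
    design <- list(
        datasets = lapply(tables, function(tab) list(
            dataset_id = tab$dataset_id,
            sample_matrix = tab$sample_matrix,
            protein_groups = file.path(tab$dataset_id, "proteinGroups.txt"),
            peptides = file.path(tab$dataset_id, "peptides.txt"),
            evidence = file.path(tab$dataset_id, "evidence.txt"),
            run_labels = as.list(tab$run_labels))),
        options = list()
    )
    names(design$datasets) <- NULL
    design_path <- file.path(out_dir, "design.yaml")
    yaml::write_yaml(design, design_path)
    truth_path <- file.path(out_dir, "ground_truth.json")
    jsonlite::write_json(list(
        proteins = truth$proteins,
        peptides = truth$peptides,
        precursors = truth$precursors,
        datasets = truth$datasets), truth_path, digits = NA)
    list(design_path = design_path, truth_path = truth_path,
         truth = truth, tables = tables, paths = paths)
}
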