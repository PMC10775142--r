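#' Parse technical-replicate run labels
#'
#' Run labels follow the underscore-delimited convention
#' \code{<T#>_<Lab>_<LC>_<MS>[_<DDA|DIA>]_R<n>}, e.g.
#' \code{"T2_LabD_nanoElute_timspro_DIA_R10"}. The acquisition segment is
#' optional and defaults to \code{"DDA"} when absent.
#'
#' @param x character vector of run labels.
#' @return \code{DataFrame} with one row per label and columns
#'   \code{label}, \code{time_point}, \code{lab}, \code{lc_system},
#'   \code{ms_instrument}, \code{acquisition}, \code{replicate_index}.
#' @examples
#' parseRunLabel("T2_LabF_ultimate_qexachf_R10")
#' @export
parseRunLabel <- function(x) {
    x <- as.character(x)
    parse1 <- function(lab) {
        parts <- strsplit(lab, "_", fixed = TRUE)[[1]]
        if (length(parts) < 2L)
            stop("malformed run label '", lab, "': too few segments",
                 call. = FALSE)
        if (!grepl("^T[0-9]+$", parts[1]))
            stop("malformed run label '", lab,
                 "': leading segment '", parts[1],
                 "' is not a time point (expected T1, T2, ...)",
                 call. = FALSE)
        last <- parts[length(parts)]
        if (!grepl("^R[0-9]+$", last))
            stop("malformed run label '", lab,
                 "': trailing segment '", last,
                 "' is not a replicate token (expected R<n>)", call. = FALSE)
        mid <- parts[-c(1L, length(parts))]
        if (length(mid) == 4L && mid[4] %in% c("DDA", "DIA")) {
            acq <- mid[4]; mid <- mid[1:3]
        } else {
            acq <- "DDA"
        }
        if (length(mid) != 3L)
            stop("malformed run label '", lab,
                 "': expected <lab>_<lc>_<ms> between time point and ",
                 "replicate token, got '", paste(mid, collapse = "_"), "'",
                 call. = FALSE)
        list(label = lab, time_point = parts[1], lab = mid[1],
             lc_system = mid[2], ms_instrument = mid[3], acquisition = acq,
             replicate_index = as.integer(sub("^R", "", last)))
    }
    rows <- lapply(x, parse1)
    DataFrame(
        label           = vapply(rows, `[[`, "", "label"),
        time_point      = vapply(rows, `[[`, "", "time_point"),
        lab             = vapply(rows, `[[`, "", "lab"),
        lc_system       = vapply(rows, `[[`, "", "lc_system"),
        ms_instrument   = vapply(rows, `[[`, "", "ms_instrument"),
        acquisition     = vapply(rows, `[[`, "", "acquisition"),
        replicate_index = vapply(rows, `[[`, 0L, "replicate_index")
    )
}

#' Render parsed run labels back to text
#'
#' Inverse of [parseRunLabel()]. The acquisition segment is always written
#' explicitly, so \code{parseRunLabel(renderRunLabel(r))} reproduces
#' \code{r} field-for-field.
#'
#' @param runs \code{DataFrame}/data.frame as returned by [parseRunLabel()].
#' @return character vector of labels.
#' @export
renderRunLabel <- function(runs) {
    sprintf("%s_%s_%s_%s_%s_R%d", runs$time_point, runs$lab,
            runs$lc_system, runs$ms_instrument, runs$acquisition,
            as.integer(runs$replicate_index))
}

# -- shared reader internals --------------------------------------------------

.readMQTable <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path, call. = FALSE)
    utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
}

.requireColumns <- function(tab, cols, path) {
    missing <- setdiff(cols, colnames(tab))
    if (length(missing))
        stop("format error in ", path, ": missing mandatory column(s): ",
             paste(sQuote(missing), collapse = ", "), call. = FALSE)
}

# MaxQuant version drift: "Potential contaminant" vs "Contaminant"
.contaminantColumn <- function(tab, path) {
    for (nm in c("Potential contaminant", "Contaminant"))
        if (nm %in% colnames(tab)) return(nm)
    stop("format error in ", path,
         ": missing mandatory column 'Potential contaminant' ",
         "(or legacy alias 'Contaminant')", call. = FALSE)
}

.flagColumn <- function(tab, nm) {
    v <- tab[[nm]]
    if (is.null(v)) return(rep(FALSE, nrow(tab)))
    v <- as.character(v)
    v[is.na(v)] <- ""
    v == "+"
}

# per-run quantification columns: "LFQ intensity <label>" preferred,
# plain "Intensity <label>" as fallback; zero or empty means not detected
.quantMatrix <- function(tab, run_labels, path) {
    pick <- function(prefix) {
        cols <- grep(paste0("^", prefix, " "), colnames(tab), value = TRUE)
        suff <- sub(paste0("^", prefix, " "), "", cols)
        list(cols = cols, suff = suff)
    }
    lfq <- pick("LFQ intensity")
    plain <- pick("Intensity")
    use <- if (all(run_labels %in% lfq$suff)) lfq
           else if (all(run_labels %in% plain$suff)) plain
           else {
        have <- union(lfq$suff, plain$suff)
        stop("format error in ", path,
             ": no per-run quantification columns for run label(s): ",
             paste(sQuote(setdiff(run_labels, have)), collapse = ", "),
             call. = FALSE)
    }
    unknown <- setdiff(use$suff, run_labels)
    if (length(unknown))
        stop("run label(s) in ", path, " not in the declared replicate set: ",
             paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    prefix <- if (identical(use, lfq)) "LFQ intensity" else "Intensity"
    m <- matrix(NA_real_, nrow = nrow(tab), ncol = length(run_labels),
                dimnames = list(NULL, run_labels))
    for (lab in run_labels) {
        v <- suppressWarnings(as.numeric(tab[[paste0(prefix, " ", lab)]]))
        v[!is.na(v) & v <= 0] <- NA_real_
        m[, lab] <- v
    }
    attr(m, "quant_column") <- prefix
    m
}

#' Read a MaxQuant proteinGroups table
#'
#' Reads a tab-separated \code{proteinGroups.txt}-dialect file into a
#' \code{SummarizedExperiment} (one row per protein group, one column per
#' run). Flag columns holding \code{"+"} become \code{TRUE}; zero or empty
#' per-run intensities become \code{NA} (not detected). "Majority protein
#' IDs" are kept semicolon-joined in \code{rowData} in their original order.
#'
#' @param path path to the tab-separated table.
#' @param run_labels character vector of expected run labels; per-run
#'   quantification columns are \code{"LFQ intensity <label>"} with
#'   \code{"Intensity <label>"} as fallback.
#' @return \code{SummarizedExperiment} with assay \code{"intensity"}.
#' @export
readProteinGroups <- function(path, run_labels) {
    tab <- .readMQTable(path)
    .requireColumns(tab, c("Majority protein IDs", "Reverse",
                           "Only identified by site"), path)
    ccol <- .contaminantColumn(tab, path)
    m <- .quantMatrix(tab, run_labels, path)
    maj <- as.character(tab[["Majority protein IDs"]])
    if (any(is.na(maj) | maj == ""))
        stop("format error in ", path,
             ": empty 'Majority protein IDs' entry", call. = FALSE)
    rd <- DataFrame(
        group_id     = if ("id" %in% colnames(tab)) as.character(tab[["id"]])
                       else as.character(seq_len(nrow(tab))),
        majority_ids = maj,
        reverse      = .flagColumn(tab, "Reverse"),
        contaminant  = .flagColumn(tab, ccol),
        only_by_site = .flagColumn(tab, "Only identified by site")
    )
    se <- SummarizedExperiment(assays = list(intensity = m), rowData = rd)
    metadata(se)$quant_column <- attr(m, "quant_column")
    se
}

#' Read a MaxQuant peptides table
#'
#' As [readProteinGroups()], for the \code{peptides.txt} dialect. The
#' \code{"Missed cleavages"} column must hold integers 0-2 (the tryptic
#' search maximum); larger values are a format error.
#'
#' @inheritParams readProteinGroups
#' @return \code{SummarizedExperiment} with assay \code{"intensity"} and
#'   rowData columns \code{sequence}, \code{missed_cleavages},
#'   \code{reverse}, \code{contaminant}.
#' @export
readPeptides <- function(path, run_labels) {
    tab <- .readMQTable(path)
    .requireColumns(tab, c("Sequence", "Missed cleavages", "Reverse"), path)
    ccol <- .contaminantColumn(tab, path)
    mc <- suppressWarnings(as.integer(tab[["Missed cleavages"]]))
    bad <- is.na(mc) | mc < 0L | mc > 2L
    if (any(bad))
        stop("format error in ", path, ": 'Missed cleavages' outside 0-2 ",
             "(search maximum) in data row(s): ",
             paste(utils::head(which(bad), 5), collapse = ", "),
             call. = FALSE)
    m <- .quantMatrix(tab, run_labels, path)
    rd <- DataFrame(
        sequence         = as.character(tab[["Sequence"]]),
        missed_cleavages = mc,
        reverse          = .flagColumn(tab, "Reverse"),
        contaminant      = .flagColumn(tab, ccol)
    )
    se <- SummarizedExperiment(assays = list(intensity = m), rowData = rd)
    metadata(se)$quant_column <- attr(m, "quant_column")
    se
}

# strip MaxQuant modification annotations: leading/trailing "_" anchors and
# (possibly nested) parenthesised modification names
.stripModifiedSequence <- function(x) {
    x <- gsub("_", "", x, fixed = TRUE)
    while (any(grepl("\\([^()]*\\)", x)))
        x <- gsub("\\([^()]*\\)", "", x)
    x
}

#' Read a MaxQuant evidence table
#'
#' One row per precursor observation (modified sequence x charge x run).
#' The run of each row is resolved by parsing the \code{"Raw file"} column
#' as a run label; when \code{run_labels} is supplied, raw files outside
#' that set are an error.
#'
#' @param path path to the tab-separated table.
#' @param run_labels optional character vector of admissible run labels.
#' @return \code{DataFrame} with columns \code{modified_sequence},
#'   \code{sequence}, \code{charge}, \code{run}, \code{retention_time},
#'   \code{intensity}, \code{reverse}, \code{contaminant}.
#' @export
readEvidence <- function(path, run_labels = NULL) {
    tab <- .readMQTable(path)
    .requireColumns(tab, c("Modified sequence", "Charge", "Retention time",
                           "Intensity", "Raw file", "Reverse"), path)
    ccol <- .contaminantColumn(tab, path)
    raw <- as.character(tab[["Raw file"]])
    parseRunLabel(unique(raw))   # format check; errors name the label
    if (!is.null(run_labels)) {
        unknown <- setdiff(unique(raw), run_labels)
        if (length(unknown))
            stop("unresolvable raw-file label(s) in ", path, ": ",
                 paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    }
    charge <- suppressWarnings(as.integer(tab[["Charge"]]))
    if (any(is.na(charge) | charge < 1L))
        stop("format error in ", path, ": 'Charge' must be integer >= 1",
             call. = FALSE)
    rt <- suppressWarnings(as.numeric(tab[["Retention time"]]))
    if (any(!is.na(rt) & rt < 0))
        stop("format error in ", path, ": negative 'Retention time'",
             call. = FALSE)
    intensity <- suppressWarnings(as.numeric(tab[["Intensity"]]))
    intensity[!is.na(intensity) & intensity <= 0] <- NA_real_
    modseq <- as.character(tab[["Modified sequence"]])
    DataFrame(
        modified_sequence = modseq,
        sequence          = .stripModifiedSequence(modseq),
        charge            = charge,
        run               = raw,
        retention_time    = rt,
        intensity         = intensity,
        reverse           = .flagColumn(tab, "Reverse"),
        contaminant       = .flagColumn(tab, ccol)
    )
}

#' Assemble one data set's tables into an MQDataset
#'
#' Validates that the three tables reference one consistent replicate set,
#' orders runs by replicate index, and builds the container.
#'
#' @param protein_groups \code{SummarizedExperiment} from
#'   [readProteinGroups()].
#' @param peptides \code{SummarizedExperiment} from [readPeptides()].
#' @param evidence \code{DataFrame} from [readEvidence()].
#' @param dataset_id single character identifier.
#' @return validated \linkS4class{MQDataset}.
#' @export
assembleDataset <- function(protein_groups, peptides, evidence, dataset_id) {
    pg_runs <- colnames(protein_groups)
    pep_runs <- colnames(peptides)
    sdiff <- union(setdiff(pg_runs, pep_runs), setdiff(pep_runs, pg_runs))
    if (length(sdiff))
        stop("replicate sets disagree between proteinGroups and peptides; ",
             "symmetric difference: ", paste(sQuote(sdiff), collapse = ", "),
             call. = FALSE)
    ev_extra <- setdiff(unique(evidence$run), pg_runs)
    if (length(ev_extra))
        stop("replicate sets disagree: evidence references run(s) absent ",
             "from the quantification tables: ",
             paste(sQuote(ev_extra), collapse = ", "), call. = FALSE)
    runs <- parseRunLabel(pg_runs)
    runs <- runs[order(runs$replicate_index), , drop = FALSE]
    ord <- as.character(runs$label)
    obj <- new("MQDataset",
        datasetId     = as.character(dataset_id),
        runs          = runs,
        proteinGroups = protein_groups[, ord],
        peptides      = peptides[, ord],
        evidence      = evidence,
        metadata      = list(
            quant_column = metadata(protein_groups)$quant_column))
    validObject(obj)
    obj
}

#' Read one data set from its three MaxQuant files
#'
#' @param protein_groups,peptides,evidence file paths.
#' @param run_labels character vector of run labels for this data set.
#' @param dataset_id identifier for the assembled data set.
#' @return \linkS4class{MQDataset}.
#' @export
readDataset <- function(protein_groups, peptides, evidence, run_labels,
                        dataset_id) {
    assembleDataset(
        readProteinGroups(protein_groups, run_labels),
        readPeptides(peptides, run_labels),
        readEvidence(evidence, run_labels),
        dataset_id
    )
}

#' Read a study design file
#'
#' A study design is a YAML (or JSON) document listing the data sets of a
#' multicenter study:
#' \preformatted{
#' datasets:
#'   - dataset_id: T1_LabA_ultimate_qexachf_DDA
#'     sample_matrix: plasma
#'     protein_groups: T1_LabA/proteinGroups.txt
#'     peptides: T1_LabA/peptides.txt
#'     evidence: T1_LabA/evidence.txt
#'     run_labels: [T1_LabA_ultimate_qexachf_R1, ...]
#' biomarker_panel: panel.txt          # optional
#' options:                            # optional overrides
#'   rt_cv_threshold: 5
#'   lfq_cv_threshold: 20
#'   completeness_threshold: 100
#'   outlier_fraction: 0.5
#'   drop_outliers: false
#'   spike_patterns: [PROCAL]
#' }
#' Relative paths are resolved against the design file's directory.
#'
#' @param path path to the design file.
#' @return validated list with elements \code{datasets}, \code{options},
#'   and optionally \code{biomarker_panel}.
#' @export
readStudyDesign <- function(path) {
    design <- yaml::read_yaml(path)
    if (is.null(design$datasets) || !length(design$datasets))
        stop("study design has no 'datasets' entries", call. = FALSE)
    base <- dirname(normalizePath(path))
    resolve <- function(p)
        if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base, p)
    ids <- vapply(design$datasets, function(d) as.character(d$dataset_id), "")
    if (anyDuplicated(ids))
        stop("duplicate dataset_id in study design: ",
             paste(sQuote(unique(ids[duplicated(ids)])), collapse = ", "),
             call. = FALSE)
    design$datasets <- lapply(design$datasets, function(d) {
        for (f in c("dataset_id", "protein_groups", "peptides", "evidence",
                    "run_labels"))
            if (is.null(d[[f]]))
                stop("data set entry '", d$dataset_id %||% "?",
                     "' is missing field '", f, "'", call. = FALSE)
        for (f in c("protein_groups", "peptides", "evidence"))
            d[[f]] <- resolve(d[[f]])
        d$run_labels <- unlist(d$run_labels)
        d$sample_matrix <- d$sample_matrix %||% "other"
        d
    })
    if (!is.null(design$biomarker_panel))
        design$biomarker_panel <- resolve(design$biomarker_panel)
    design$options <- design$options %||% list()
    design
}

`%||%` <- function(a, b) if (is.null(a)) b else a
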