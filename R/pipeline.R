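.defaultOptions <- function() {
    list(rt_cv_threshold = 5,
         lfq_cv_threshold = 20,
         completeness_threshold = 100,
         outlier_level = "protein_group",
         outlier_fraction = 0.5,
         drop_outliers = FALSE,
         spike_patterns = "PROCAL",
         precursor_by = "modified")
}

# metrics entering the scaled time-point comparison
.ABSOLUTE_METRICS <- c("median_protein_group_ids", "median_peptide_ids",
                       "median_precursor_ids", "mc0_count",
                       "full_profiles_protein_group",
                       "full_profiles_peptide", "full_profiles_precursor",
                       "rt_n_below_threshold", "lfq_pg_n_below_threshold")
.RELATIVE_METRICS <- c("percent_zero_missed_cleavages",
                       "percent_full_profiles_protein_group",
                       "percent_full_profiles_peptide",
                       "percent_full_profiles_precursor",
                       "rt_percent_below", "lfq_pg_percent_below")

.stage <- function(dataset_id, stage, expr) {
    tryCatch(expr, error = function(e)
        stop("data set '", dataset_id, "' failed at stage '", stage, "': ",
             conditionMessage(e), call. = FALSE))
}

#' Run the full benchmarking pipeline
#'
#' Executes the complete analysis for a study design: read each data
#' set, apply standard filters, screen replicates for outliers
#' (optionally dropping them), compute per-data-set metric summaries,
#' then the cross-data-set comparisons per sample matrix — scaled
#' time-point comparison for absolute and relative metrics, overlap
#' saturation curves per time point and combined, and biomarker-panel
#' matching when a panel is given. All tables, a JSON report recording
#' every decision (filters, outliers, thresholds, design checksum) and a
#' plain log are written to \code{out_dir}. Deterministic: identical
#' inputs yield byte-identical reports.
#'
#' @param design path to a study design file (see [readStudyDesign()]) or
#'   an already-read design list.
#' @param out_dir output directory for the report bundle.
#' @param options named list overriding the design/default analysis
#'   options (\code{rt_cv_threshold}, \code{lfq_cv_threshold},
#'   \code{completeness_threshold}, \code{outlier_level},
#'   \code{outlier_fraction}, \code{drop_outliers},
#'   \code{spike_patterns}, \code{precursor_by}).
#' @return invisibly, a list with the metric summary, comparisons,
#'   overlap curves, biomarker results, outlier table and report paths.
#' @export
runPipeline <- function(design, out_dir, options = list()) {
    design_path <- NULL
    if (is.character(design)) {
        design_path <- design
        design <- readStudyDesign(design)
    }
    opts <- .defaultOptions()
    for (src in list(design$options, options))
        for (nm in names(src)) opts[[nm]] <- src[[nm]]
    log_lines <- c("mqbench analysis",
                   paste0("package version: ",
                          as.character(utils::packageVersion("mqbench"))),
                   paste0("data sets: ", length(design$datasets)),
                   paste0("options: ", jsonlite::toJSON(opts,
                          auto_unbox = TRUE)))

    bundles <- list()
    outlier_rows <- list()
    for (entry in design$datasets) {
        id <- entry$dataset_id
        b <- .stage(id, "read", readDataset(entry$protein_groups,
            entry$peptides, entry$evidence, entry$run_labels, id))
        b <- .stage(id, "filter",
                    applyStandardFilters(b, opts$spike_patterns))
        flagged <- character()
        if (length(runLabels(b)) >= 3L)
            flagged <- .stage(id, "outlier_screen", detectOutlierReplicates(
                b, opts$outlier_level, opts$outlier_fraction))
        dropped <- character()
        if (length(flagged) && isTRUE(opts$drop_outliers)) {
            b <- .stage(id, "outlier_removal", dropReplicates(b, flagged))
            dropped <- flagged
        }
        outlier_rows[[id]] <- data.frame(
            dataset_id = id,
            flagged = paste(flagged, collapse = ";"),
            dropped = paste(dropped, collapse = ";"),
            stringsAsFactors = FALSE)
        b@metadata$sample_matrix <- entry$sample_matrix
        bundles[[id]] <- b
        log_lines <- c(log_lines, sprintf(
            "%s: %d protein groups, %d peptides, %d evidence rows after filtering; outliers flagged: %s",
            id, nrow(proteinGroups(b)), nrow(peptides(b)),
            nrow(evidence(b)),
            if (length(flagged)) paste(flagged, collapse = ",") else "none"))
    }

    summary_tab <- do.call(rbind, lapply(names(bundles), function(id)
        .stage(id, "metrics", cbind(
            sample_matrix = bundles[[id]]@metadata$sample_matrix,
            summarizeDataset(bundles[[id]], opts$rt_cv_threshold,
                             opts$lfq_cv_threshold, opts$precursor_by)))))

    matrices <- unique(summary_tab$sample_matrix)
    scaled_abs <- scaled_rel <- overlap_tab <- list()
    for (mx in matrices) {
        sub <- summary_tab[summary_tab$sample_matrix == mx, , drop = FALSE]
        tps <- sort(unique(sub$time_point))
        if (length(tps) >= 2L) {
            a <- sub[sub$time_point == tps[1], , drop = FALSE]
            b <- sub[sub$time_point == tps[2], , drop = FALSE]
            mk <- function(metrics) do.call(rbind, lapply(metrics,
                function(m) {
                    va <- a[[m]]; vb <- b[[m]]
                    if (all(is.na(va)) || all(is.na(vb))) return(NULL)
                    cbind(sample_matrix = mx, group_a = tps[1],
                          group_b = tps[2],
                          scaledMedianComparison(va, vb, m))
                }))
            scaled_abs[[mx]] <- mk(.ABSOLUTE_METRICS)
            scaled_rel[[mx]] <- mk(.RELATIVE_METRICS)
        }
        ids_mx <- sub$dataset_id
        groups <- c(stats::setNames(lapply(tps, function(tp)
                        ids_mx[sub$time_point == tp]), tps),
                    list(all = ids_mx))
        for (g in names(groups)) {
            ids <- groups[[g]]
            if (length(ids) < 2L) next
            sets <- lapply(bundles[ids], fullProfileAccessions,
                           threshold = opts$completeness_threshold)
            overlap_tab[[paste(mx, g)]] <- cbind(
                sample_matrix = mx, group = g, overlapCurve(sets))
        }
    }
    scaled_abs <- do.call(rbind, unname(scaled_abs))
    scaled_rel <- do.call(rbind, unname(scaled_rel))
    overlap_tab <- do.call(rbind, unname(overlap_tab))

    biomarker <- NULL
    if (!is.null(design$biomarker_panel)) {
        panel <- readBiomarkerPanel(design$biomarker_panel)
        biomarker <- lapply(stats::setNames(matrices, matrices), function(mx) {
            ids <- summary_tab$dataset_id[summary_tab$sample_matrix == mx]
            biomarkerMatching(bundles[ids], panel)
        })
    }

    outliers <- do.call(rbind, unname(outlier_rows))

    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wtsv <- function(df, name) {
        p <- file.path(out_dir, name)
        utils::write.table(df, p, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        p
    }
    paths <- list(metric_summary = wtsv(summary_tab, "metric_summary.tsv"),
                  outliers = wtsv(outliers, "outlier_screen.tsv"))
    if (!is.null(scaled_abs))
        paths$scaled_absolute <- wtsv(scaled_abs,
                                      "scaled_comparison_absolute.tsv")
    if (!is.null(scaled_rel))
        paths$scaled_relative <- wtsv(scaled_rel,
                                      "scaled_comparison_relative.tsv")
    if (!is.null(overlap_tab))
        paths$overlap <- wtsv(overlap_tab, "overlap_curves.tsv")
    if (!is.null(biomarker)) {
        pres <- do.call(rbind, lapply(names(biomarker), function(mx)
            cbind(sample_matrix = mx, biomarker[[mx]]$presence)))
        paths$biomarker_presence <- wtsv(pres, "biomarker_presence.tsv")
        mat <- do.call(rbind, lapply(names(biomarker), function(mx) {
            m <- biomarker[[mx]]$matches
            if (is.null(m)) NULL else cbind(sample_matrix = mx, m)
        }))
        if (!is.null(mat))
            paths$biomarker_matches <- wtsv(mat, "biomarker_matches.tsv")
    }

    report <- list(
        tool = "mqbench",
        version = as.character(utils::packageVersion("mqbench")),
        design_checksum = if (!is.null(design_path))
            unname(tools::md5sum(design_path)) else NA,
        options = opts,
        datasets = lapply(bundles, function(b) list(
            dataset_id = datasetId(b),
            sample_matrix = b@metadata$sample_matrix,
            n_replicates = length(runLabels(b)),
            quant_column = b@metadata$quant_column,
            filter_report = filterReport(b),
            dropped_replicates = b@metadata$dropped_replicates %||%
                character())),
        outliers = outliers)
    report_path <- file.path(out_dir, "report.json")
    jsonlite::write_json(report, report_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
    paths$report <- report_path
    writeLines(log_lines, file.path(out_dir, "analysis.log"))
    paths$log <- file.path(out_dir, "analysis.log")

    invisible(list(summary = summary_tab,
                   scaled_absolute = scaled_abs,
                   scaled_relative = scaled_rel,
                   overlap = overlap_tab,
                   biomarker = biomarker,
                   outliers = outliers,
                   bundles = bundles,
                   options = opts,
                   paths = paths))
}
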