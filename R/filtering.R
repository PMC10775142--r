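#' Standard row filtering for benchmarking metrics
#'
#' Removes, at every table level, decoy hits (\code{Reverse}), potential
#' contaminants, protein groups only identified by modified-site evidence,
#' and retention-time spike-in identifications (by default anything
#' matching \code{"PROCAL"} in accessions or peptide sequences). Each
#' removed row is tallied once, under the first matching category in the
#' order reverse, contaminant, only-by-site, spike-in.
#'
#' Filtering is idempotent; applying it to an already-filtered data set
#' removes nothing further.
#'
#' @param x an \linkS4class{MQDataset}.
#' @param spike_patterns character vector of regular expressions matched
#'   against protein accessions and peptide/precursor sequences.
#' @return the filtered \code{MQDataset}; the removal tallies are stored in
#'   its metadata and retrievable with [filterReport()].
#' @export
applyStandardFilters <- function(x, spike_patterns = "PROCAL") {
    stopifnot(is(x, "MQDataset"))
    matchAny <- function(values, split = FALSE) {
        if (!length(spike_patterns)) return(rep(FALSE, length(values)))
        hit <- rep(FALSE, length(values))
        for (p in spike_patterns) {
            if (split) {
                hit <- hit | vapply(strsplit(values, ";", fixed = TRUE),
                                    function(a) any(grepl(p, a)), NA)
            } else hit <- hit | grepl(p, values)
        }
        hit
    }
    classify <- function(reverse, contaminant, only_by_site, spike) {
        cat <- rep("retained", length(reverse))
        only_by_site <- rep_len(only_by_site, length(reverse))
        cat[spike]        <- "spike_in"
        cat[only_by_site] <- "only_by_site"
        cat[contaminant]  <- "contaminant"
        cat[reverse]      <- "reverse"
        cat
    }
    tally <- function(cat) {
        c(input = length(cat),
          removed_reverse      = sum(cat == "reverse"),
          removed_contaminant  = sum(cat == "contaminant"),
          removed_only_by_site = sum(cat == "only_by_site"),
          removed_spike_in     = sum(cat == "spike_in"),
          retained             = sum(cat == "retained"))
    }

    pg <- x@proteinGroups
    pg_cat <- classify(rowData(pg)$reverse, rowData(pg)$contaminant,
                       rowData(pg)$only_by_site,
                       matchAny(rowData(pg)$majority_ids, split = TRUE))
    pep <- x@peptides
    pep_cat <- classify(rowData(pep)$reverse, rowData(pep)$contaminant,
                        FALSE, matchAny(rowData(pep)$sequence))
    ev <- x@evidence
    ev_cat <- classify(ev$reverse, ev$contaminant, FALSE,
                       matchAny(ev$modified_sequence) | matchAny(ev$sequence))

    report <- rbind(protein_group = tally(pg_cat),
                    peptide       = tally(pep_cat),
                    precursor     = tally(ev_cat))
    report <- data.frame(level = rownames(report), report,
                         row.names = NULL, check.names = FALSE)

    out <- x
    out@proteinGroups <- pg[pg_cat == "retained", ]
    out@peptides      <- pep[pep_cat == "retained", ]
    out@evidence      <- ev[ev_cat == "retained", , drop = FALSE]
    out@metadata$filter_report  <- report
    out@metadata$spike_patterns <- spike_patterns
    validObject(out)
    out
}

#' @rdname applyStandardFilters
#' @export
filterReport <- function(x) {
    stopifnot(is(x, "MQDataset"))
    x@metadata$filter_report
}

#' Flag low-identification replicates
#'
#' Screens the technical replicates of one data set for outliers by their
#' identification count: a replicate is flagged when its ID count at
#' \code{level} falls strictly below \code{min_fraction} of the median
#' count over all replicates. Detection never mutates the data set;
#' removal is a separate, explicit step ([dropReplicates()]), so the
#' decision is always reportable.
#'
#' @param x a standard-filtered \linkS4class{MQDataset} with at least three
#'   replicates.
#' @param level metric level for the counts: \code{"protein_group"}
#'   (default), \code{"peptide"} or \code{"precursor"}.
#' @param min_fraction fraction of the median ID count, in (0, 1), below
#'   which a replicate is an outlier.
#' @return character vector of flagged run labels (possibly empty).
#' @export
detectOutlierReplicates <- function(x, level = "protein_group",
                                    min_fraction = 0.5) {
    stopifnot(is(x, "MQDataset"))
    .checkLevel(level)
    if (!(min_fraction > 0 && min_fraction < 1))
        stop("'min_fraction' must lie in (0, 1)", call. = FALSE)
    if (length(runLabels(x)) < 3L)
        stop("outlier screening needs >= 3 replicates (median over ",
             length(runLabels(x)), " is not meaningful)", call. = FALSE)
    counts <- countIdentifications(x, level)$counts
    cutoff <- min_fraction * stats::median(counts)
    names(counts)[counts < cutoff]
}

#' Remove replicates from a data set
#'
#' @param x an \linkS4class{MQDataset}.
#' @param labels run labels to drop (e.g. from
#'   [detectOutlierReplicates()]).
#' @return the reduced \code{MQDataset}; dropped labels are recorded in its
#'   metadata.
#' @export
dropReplicates <- function(x, labels) {
    stopifnot(is(x, "MQDataset"))
    unknown <- setdiff(labels, runLabels(x))
    if (length(unknown))
        stop("cannot drop unknown run label(s): ",
             paste(sQuote(unknown), collapse = ", "), call. = FALSE)
    keep <- setdiff(runLabels(x), labels)
    if (!length(keep))
        stop("cannot drop all replicates", call. = FALSE)
    out <- x
    out@runs          <- x@runs[x@runs$label %in% keep, , drop = FALSE]
    out@proteinGroups <- x@proteinGroups[, keep]
    out@peptides      <- x@peptides[, keep]
    out@evidence      <- x@evidence[x@evidence$run %in% keep, , drop = FALSE]
    out@metadata$dropped_replicates <-
        c(x@metadata$dropped_replicates, labels)
    validObject(out)
    out
}
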