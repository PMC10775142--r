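#' Scaled median comparison of two measurement rounds
#'
#' For one metric, the medians over the data sets of each round are put on
#' a common percentage scale by dividing both by the larger of the two and
#' multiplying by 100; the difference is reported in percentage points
#' (round B minus round A). This makes improvements between rounds
#' comparable across metrics with very different absolute ranges.
#'
#' @param values_a numeric metric values, one per data set of round A
#'   (e.g. T1).
#' @param values_b numeric metric values, one per data set of round B
#'   (e.g. T2).
#' @param metric_name name recorded in the result.
#' @return one-row \code{data.frame} with \code{metric}, \code{median_a},
#'   \code{median_b}, \code{scaled_a}, \code{scaled_b}, \code{difference}.
#'   When both medians are 0 the scaled values and difference are
#'   \code{NA}.
#' @examples
#' scaledMedianComparison(613, 707, "protein_group_ids")
#' @export
scaledMedianComparison <- function(values_a, values_b, metric_name = "metric") {
    values_a <- values_a[!is.na(values_a)]
    values_b <- values_b[!is.na(values_b)]
    if (!length(values_a) || !length(values_b))
        stop("both value sets must be non-empty", call. = FALSE)
    if (any(values_a < 0) || any(values_b < 0))
        stop("metric values must be >= 0", call. = FALSE)
    med_a <- median(values_a)
    med_b <- median(values_b)
    top <- max(med_a, med_b)
    if (top == 0) {
        scaled_a <- scaled_b <- diff_ <- NA_real_
    } else {
        scaled_a <- 100 * med_a / top
        scaled_b <- 100 * med_b / top
        diff_ <- scaled_b - scaled_a
    }
    data.frame(metric = metric_name, median_a = med_a, median_b = med_b,
               scaled_a = scaled_a, scaled_b = scaled_b,
               difference = diff_, stringsAsFactors = FALSE)
}

#' Accessions with (near-)complete data completeness
#'
#' Expands the majority accessions of every protein group present in at
#' least \code{ceiling(threshold/100 * n)} of the n replicates. At the
#' default threshold of 100 this is the full-profile set used for
#' interlaboratory overlap; lowering the threshold relaxes the
#' completeness requirement (e.g. 80 with n = 10 requires 8 replicates).
#'
#' Accession expansion makes the overlap symmetric across laboratories
#' that grouped proteins differently: an accession is present whenever
#' any qualifying group lists it.
#'
#' @param x a standard-filtered \linkS4class{MQDataset}.
#' @param threshold completeness threshold in percent, in (0, 100].
#' @return character vector of accessions (unordered set).
#' @export
fullProfileAccessions <- function(x, threshold = 100) {
    stopifnot(is(x, "MQDataset"))
    if (!(threshold > 0 && threshold <= 100))
        stop("'threshold' must lie in (0, 100]", call. = FALSE)
    n <- length(runLabels(x))
    need <- ceiling(threshold / 100 * n)
    m <- !is.na(assay(x@proteinGroups, "intensity"))
    keep <- rowSums(m) >= need
    if (!any(keep)) return(character())
    unique(unlist(strsplit(rowData(x@proteinGroups)$majority_ids[keep],
                           ";", fixed = TRUE)))
}

#' Overlap saturation over an ordered sequence of data sets
#'
#' Running intersection, running union and relative overlap (100 x
#' intersection / union) of accession sets, in the caller-supplied order.
#' The absolute overlap declines as data sets are added while the union
#' saturates; the ordering changes the intermediate values but never the
#' terminal intersection or union.
#'
#' @param sets named list of accession character vectors, in curve order.
#' @return \code{data.frame} with one row per k: \code{k},
#'   \code{dataset_id}, \code{intersection}, \code{union},
#'   \code{relative_overlap}.
#' @examples
#' overlapCurve(list(a = c("A","B","C"), b = c("B","C","D"), c = "B"))
#' @export
overlapCurve <- function(sets) {
    if (!length(sets))
        stop("'sets' must contain at least one accession set", call. = FALSE)
    ids <- names(sets) %||% as.character(seq_along(sets))
    inter <- uni <- NULL
    out <- vector("list", length(sets))
    for (k in seq_along(sets)) {
        s <- unique(as.character(sets[[k]]))
        inter <- if (k == 1L) s else intersect(inter, s)
        uni <- union(uni, s)
        out[[k]] <- data.frame(
            k = k, dataset_id = ids[k],
            intersection = length(inter), union = length(uni),
            relative_overlap = if (length(uni)) 100 * length(inter) /
                length(uni) else NA_real_,
            stringsAsFactors = FALSE)
    }
    do.call(rbind, out)
}

#' Exact accession matching
#'
#' @param majority_accessions character vector of accessions (one protein
#'   group's majority IDs).
#' @param reference single accession to look for.
#' @return \code{TRUE} iff \code{reference} exactly equals one of the
#'   listed accessions; isoform suffixes are not stripped.
#' @export
matchAccession <- function(majority_accessions, reference) {
    reference %in% majority_accessions
}

#' Read a biomarker panel file
#'
#' Plain text, one UniProt accession per line; lines starting with
#' \code{"#"} and blank lines are ignored.
#'
#' @param path file path.
#' @return character vector of accessions.
#' @export
readBiomarkerPanel <- function(path) {
    lines <- trimws(readLines(path, warn = FALSE))
    panel <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(panel))
        stop("biomarker panel ", path, " contains no accessions",
             call. = FALSE)
    unique(panel)
}

#' Match a biomarker panel against full-profile detections
#'
#' For every data set, the panel accessions found in its full-profile
#' accession set (100 percent data completeness), each annotated with the
#' LFQ CV of the matched protein group. When several full-profile groups
#' list the same accession, the group quantified in the most replicates
#' (ties broken by higher median intensity) provides the CV and the
#' ambiguity is flagged. Per accession, presence is the percentage of
#' data sets with a full-profile match, overall and per time point; panel
#' accessions matched nowhere are reported with presence 0, never
#' dropped.
#'
#' @param bundles list of standard-filtered \linkS4class{MQDataset}
#'   objects.
#' @param panel character vector of accessions (see
#'   [readBiomarkerPanel()]).
#' @return list with \code{matches} (data.frame: dataset_id, time_point,
#'   accession, cv, ambiguous), \code{per_dataset} (matched counts) and
#'   \code{presence} (data.frame: accession, presence percentages overall
#'   and per time point).
#' @export
biomarkerMatching <- function(bundles, panel) {
    if (!length(panel)) stop("empty biomarker panel", call. = FALSE)
    if (!length(bundles)) stop("no data sets supplied", call. = FALSE)
    panel <- unique(as.character(panel))
    match1 <- function(x) {
        n <- length(runLabels(x))
        a <- assay(x@proteinGroups, "intensity")
        full <- rowSums(!is.na(a)) >= n
        rd <- rowData(x@proteinGroups)
        acc_lists <- strsplit(rd$majority_ids, ";", fixed = TRUE)
        rows <- lapply(panel, function(p) {
            hits <- which(full & vapply(acc_lists, matchAccession,
                                        NA, reference = p))
            if (!length(hits)) return(NULL)
            if (length(hits) > 1L) {
                nq <- rowSums(!is.na(a[hits, , drop = FALSE]))
                mi <- apply(a[hits, , drop = FALSE], 1L, median, na.rm = TRUE)
                hits <- hits[order(-nq, -mi)]
            }
            data.frame(dataset_id = datasetId(x),
                       time_point = x@runs$time_point[1],
                       accession = p,
                       cv = featureCV(a[hits[1L], ]),
                       ambiguous = length(hits) > 1L,
                       stringsAsFactors = FALSE)
        })
        do.call(rbind, rows)
    }
    matches <- do.call(rbind, lapply(bundles, match1))
    ids <- vapply(bundles, datasetId, "")
    tps <- vapply(bundles, function(b) b@runs$time_point[1], "")
    per_dataset <- data.frame(
        dataset_id = ids, time_point = tps,
        matched = vapply(ids, function(i)
            if (is.null(matches)) 0L else sum(matches$dataset_id == i), 0L),
        row.names = NULL, stringsAsFactors = FALSE)
    pres <- function(acc, keep_tp = NULL) {
        use_ids <- if (is.null(keep_tp)) ids else ids[tps == keep_tp]
        if (!length(use_ids)) return(NA_real_)
        hit <- if (is.null(matches)) 0L else
            sum(matches$accession == acc & matches$dataset_id %in% use_ids)
        100 * hit / length(use_ids)
    }
    presence <- data.frame(accession = panel,
                           presence = vapply(panel, pres, 0),
                           stringsAsFactors = FALSE, row.names = NULL)
    for (tp in sort(unique(tps)))
        presence[[paste0("presence_", tp)]] <-
            vapply(panel, pres, 0, keep_tp = tp)
    list(panel_size = length(panel), matches = matches,
         per_dataset = per_dataset, presence = presence)
}
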