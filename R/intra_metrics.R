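#' @importFrom stats median sd setNames
NULL

# precursor identity: peptide sequence including charge; the modified
# sequence is used by default, the stripped sequence is a documented switch
.precursorKey <- function(ev, precursor_by = c("modified", "stripped")) {
    precursor_by <- match.arg(precursor_by)
    seqs <- if (precursor_by == "modified") ev$modified_sequence
            else ev$sequence
    paste(seqs, ev$charge, sep = "/")
}

# logical features x runs presence matrix at one metric level; a feature is
# present in a run iff it has a non-missing quantification (protein group,
# peptide) or at least one evidence row (precursor) in that run
.presenceMatrix <- function(x, level, precursor_by = "modified") {
    runs <- runLabels(x)
    if (level == "protein_group") {
        m <- !is.na(assay(x@proteinGroups, "intensity"))
        rownames(m) <- rowData(x@proteinGroups)$group_id
    } else if (level == "peptide") {
        a <- !is.na(assay(x@peptides, "intensity"))
        seqs <- rowData(x@peptides)$sequence
        m <- rowsum(a + 0L, group = seqs) > 0L
    } else {
        ev <- x@evidence
        m <- matrix(FALSE, 0L, length(runs), dimnames = list(NULL, runs))
        if (nrow(ev) > 0L) {
            key <- .precursorKey(ev, precursor_by)
            feats <- unique(key)
            m <- matrix(FALSE, length(feats), length(runs),
                        dimnames = list(feats, runs))
            m[cbind(match(key, feats), match(ev$run, runs))] <- TRUE
        }
    }
    m[rowSums(m) > 0L, , drop = FALSE]
}

# numeric features x runs quantification matrix at one metric level
.quantValues <- function(x, level, precursor_by = "modified") {
    runs <- runLabels(x)
    if (level == "protein_group") {
        assay(x@proteinGroups, "intensity")
    } else if (level == "peptide") {
        a <- assay(x@peptides, "intensity")
        seqs <- rowData(x@peptides)$sequence
        if (anyDuplicated(seqs)) {
            s <- rowsum(ifelse(is.na(a), 0, a), group = seqs)
            n <- rowsum((!is.na(a)) + 0L, group = seqs)
            s[n == 0L] <- NA_real_
            s
        } else {
            rownames(a) <- seqs
            a
        }
    } else {
        ev <- x@evidence
        m <- matrix(NA_real_, 0L, length(runs), dimnames = list(NULL, runs))
        if (nrow(ev) > 0L) {
            key <- .precursorKey(ev, precursor_by)
            keep <- !is.na(ev$intensity)
            if (any(keep)) {
                s <- rowsum(ev$intensity[keep],
                            group = paste(key, ev$run, sep = "\r")[keep])
                parts <- strsplit(rownames(s), "\r", fixed = TRUE)
                feats <- unique(vapply(parts, `[[`, "", 1L))
                m <- matrix(NA_real_, length(feats), length(runs),
                            dimnames = list(feats, runs))
                m[cbind(match(vapply(parts, `[[`, "", 1L), feats),
                        match(vapply(parts, `[[`, "", 2L), runs))] <- s[, 1L]
            }
        }
        m
    }
}

#' Identification counts per replicate
#'
#' Counts identified features per technical replicate at one metric level.
#' A feature counts in a replicate iff it has a non-missing quantification
#' there (protein group, peptide) or at least one evidence row (precursor);
#' a precursor is a peptide sequence including its charge state.
#'
#' @param x a standard-filtered \linkS4class{MQDataset}.
#' @param level \code{"protein_group"}, \code{"peptide"} or
#'   \code{"precursor"}.
#' @param precursor_by precursor sequence identity: \code{"modified"}
#'   (default) or \code{"stripped"}.
#' @return list with \code{counts} (named integer vector, one entry per
#'   replicate), \code{median}, and \code{n_features} (distinct features
#'   identified in at least one replicate).
#' @export
countIdentifications <- function(x, level = "protein_group",
                                 precursor_by = "modified") {
    stopifnot(is(x, "MQDataset"))
    .checkLevel(level)
    m <- .presenceMatrix(x, level, precursor_by)
    counts <- setNames(as.integer(colSums(m)), colnames(m))
    list(counts = counts, median = median(counts), n_features = nrow(m))
}

#' Missed-cleavage summary over identified peptides
#'
#' Tallies the distinct identified peptide sequences (union over
#' replicates) by their number of missed tryptic cleavage sites and
#' reports the percentage with zero missed cleavages, the standard
#' digestion-efficiency readout.
#'
#' @param x a standard-filtered \linkS4class{MQDataset}.
#' @return list with \code{counts} (named vector for classes 0/1/2),
#'   \code{total}, and \code{percent_zero} (\code{NA} when no peptides).
#' @export
missedCleavageSummary <- function(x) {
    stopifnot(is(x, "MQDataset"))
    rd <- rowData(x@peptides)
    keep <- !duplicated(rd$sequence)
    mc <- rd$missed_cleavages[keep]
    counts <- setNames(vapply(0:2, function(k) sum(mc == k), 0L),
                       as.character(0:2))
    total <- length(mc)
    list(counts = counts, total = total,
         percent_zero = if (total > 0L) 100 * counts[["0"]] / total
                        else NA_real_)
}

#' Data-completeness profile
#'
#' For one metric level, counts features by the number of replicates k in
#' which they were observed. A feature seen in every replicate is a full
#' profile (100 percent data completeness).
#'
#' @inheritParams countIdentifications
#' @return list with \code{level}, \code{n_replicates}, and
#'   \code{count_by_k}, a named integer vector over k = 1..n_replicates.
#' @export
completenessProfile <- function(x, level = "protein_group",
                                precursor_by = "modified") {
    stopifnot(is(x, "MQDataset"))
    .checkLevel(level)
    n <- length(runLabels(x))
    m <- .presenceMatrix(x, level, precursor_by)
    k <- rowSums(m)
    count_by_k <- setNames(vapply(seq_len(n), function(i) sum(k == i), 0L),
                           as.character(seq_len(n)))
    list(level = level, n_replicates = n, count_by_k = count_by_k)
}

#' Percentage of full profiles
#'
#' The number of complete profiles divided by the total number of
#' identified features, times 100.
#'
#' @param profile a completeness profile from [completenessProfile()].
#' @return percentage in \code{[0, 100]}, or \code{NA} for an empty
#'   profile.
#' @export
percentCompleteProfiles <- function(profile) {
    total <- sum(profile$count_by_k)
    if (total == 0L) return(NA_real_)
    100 * profile$count_by_k[[as.character(profile$n_replicates)]] / total
}

#' Coefficient of variation of a feature's replicate values
#'
#' 100 times the sample (n-1) standard deviation divided by the mean,
#' over the non-missing values. Fewer than two non-missing values make the
#' feature non-evaluable (\code{NA}), never a zero.
#'
#' @param values numeric vector of positive replicate measurements
#'   (\code{NA} allowed).
#' @return CV in percent, or \code{NA} if fewer than 2 values.
#' @examples
#' featureCV(c(90, 100, 110))   # 10
#' @export
featureCV <- function(values) {
    v <- values[!is.na(values)]
    if (length(v) < 2L) return(NA_real_)
    100 * sd(v) / mean(v)
}

# row-wise CV on a features x runs matrix; NA where < 2 values
.rowCV <- function(m) {
    n <- rowSums(!is.na(m))
    mu <- rowMeans(m, na.rm = TRUE)
    ss <- rowSums((m - mu)^2, na.rm = TRUE)
    cv <- 100 * sqrt(ss / pmax(n - 1L, 1L)) / mu
    cv[n < 2L] <- NA_real_
    cv
}

.precisionResult <- function(cv, level, dimension, cv_threshold) {
    cv <- cv[!is.na(cv)]
    n_eval <- length(cv)
    n_below <- sum(cv < cv_threshold)
    list(level = level, dimension = dimension, cv_threshold = cv_threshold,
         n_evaluable = n_eval, n_below_threshold = n_below,
         percent_below = if (n_eval > 0L) 100 * n_below / n_eval
                         else NA_real_)
}

#' Retention-time precision of precursor identifications
#'
#' Per precursor, one retention time per replicate (the median over that
#' precursor's evidence rows in the replicate, robust to split peaks), a
#' CV over the replicates with an observation, and the percentage of
#' evaluable precursors whose CV falls strictly below the threshold.
#'
#' @param x a standard-filtered \linkS4class{MQDataset}.
#' @param cv_threshold CV threshold in percent (default 5).
#' @param precursor_by precursor sequence identity, see
#'   [countIdentifications()].
#' @return precision result list: \code{level}, \code{dimension},
#'   \code{cv_threshold}, \code{n_evaluable}, \code{n_below_threshold},
#'   \code{percent_below}.
#' @export
rtPrecision <- function(x, cv_threshold = 5, precursor_by = "modified") {
    stopifnot(is(x, "MQDataset"))
    ev <- x@evidence
    runs <- runLabels(x)
    m <- matrix(NA_real_, 0L, length(runs))
    if (nrow(ev) > 0L) {
        key <- .precursorKey(ev, precursor_by)
        ok <- !is.na(ev$retention_time)
        grp <- paste(key, ev$run, sep = "\r")[ok]
        med <- vapply(split(ev$retention_time[ok], grp), median, 0)
        parts <- strsplit(names(med), "\r", fixed = TRUE)
        feats <- unique(vapply(parts, `[[`, "", 1L))
        m <- matrix(NA_real_, length(feats), length(runs),
                    dimnames = list(feats, runs))
        m[cbind(match(vapply(parts, `[[`, "", 1L), feats),
                match(vapply(parts, `[[`, "", 2L), runs))] <- med
    }
    .precisionResult(.rowCV(m), "precursor", "retention_time", cv_threshold)
}

#' Quantitative precision at a metric level
#'
#' CV of the per-replicate quantification values (LFQ intensity for
#' protein groups, summed intensities for peptides/precursors) per
#' feature, and the percentage of evaluable features with CV strictly
#' below the threshold.
#'
#' @param x a standard-filtered \linkS4class{MQDataset}.
#' @param level \code{"protein_group"} (default), \code{"peptide"} or
#'   \code{"precursor"}.
#' @param cv_threshold CV threshold in percent (default 20).
#' @param precursor_by precursor sequence identity, see
#'   [countIdentifications()].
#' @return precision result list, see [rtPrecision()].
#' @export
quantPrecision <- function(x, level = "protein_group", cv_threshold = 20,
                           precursor_by = "modified") {
    stopifnot(is(x, "MQDataset"))
    .checkLevel(level)
    m <- .quantValues(x, level, precursor_by)
    .precisionResult(.rowCV(m), level, "lfq_intensity", cv_threshold)
}

#' One-row performance summary of a data set
#'
#' Aggregates every per-data-set metric (identification counts and
#' medians at the three levels, missed-cleavage classes, full-profile
#' percentages, retention-time and quantitative precision) into one row,
#' the building block of a study-wide summary table. Missing values are
#' propagated, never replaced by zeros.
#'
#' @param x a standard-filtered \linkS4class{MQDataset}.
#' @param rt_cv_threshold retention-time CV threshold in percent.
#' @param lfq_cv_threshold intensity CV threshold in percent.
#' @param precursor_by precursor sequence identity, see
#'   [countIdentifications()].
#' @return one-row \code{data.frame}.
#' @export
summarizeDataset <- function(x, rt_cv_threshold = 5, lfq_cv_threshold = 20,
                             precursor_by = "modified") {
    stopifnot(is(x, "MQDataset"))
    r <- x@runs
    ids <- lapply(setNames(.LEVELS, .LEVELS), function(lv)
        countIdentifications(x, lv, precursor_by))
    comp <- lapply(setNames(.LEVELS, .LEVELS), function(lv)
        percentCompleteProfiles(completenessProfile(x, lv, precursor_by)))
    full <- lapply(setNames(.LEVELS, .LEVELS), function(lv) {
        p <- completenessProfile(x, lv, precursor_by)
        p$count_by_k[[as.character(p$n_replicates)]]
    })
    mc <- missedCleavageSummary(x)
    rt <- rtPrecision(x, rt_cv_threshold, precursor_by)
    qp_pg <- quantPrecision(x, "protein_group", lfq_cv_threshold,
                            precursor_by)
    qp_pep <- quantPrecision(x, "peptide", lfq_cv_threshold, precursor_by)
    data.frame(
        dataset_id    = datasetId(x),
        time_point    = r$time_point[1],
        lab           = r$lab[1],
        lc_system     = r$lc_system[1],
        ms_instrument = r$ms_instrument[1],
        acquisition   = r$acquisition[1],
        n_replicates  = nrow(r),
        median_protein_group_ids = ids$protein_group$median,
        median_peptide_ids       = ids$peptide$median,
        median_precursor_ids     = ids$precursor$median,
        total_protein_groups     = ids$protein_group$n_features,
        total_peptides           = ids$peptide$n_features,
        total_precursors         = ids$precursor$n_features,
        mc0_count = mc$counts[["0"]],
        mc1_count = mc$counts[["1"]],
        mc2_count = mc$counts[["2"]],
        percent_zero_missed_cleavages = mc$percent_zero,
        full_profiles_protein_group = full$protein_group,
        full_profiles_peptide       = full$peptide,
        full_profiles_precursor     = full$precursor,
        percent_full_profiles_protein_group = comp$protein_group,
        percent_full_profiles_peptide       = comp$peptide,
        percent_full_profiles_precursor     = comp$precursor,
        rt_cv_threshold          = rt$cv_threshold,
        rt_n_evaluable           = rt$n_evaluable,
        rt_n_below_threshold     = rt$n_below_threshold,
        rt_percent_below         = rt$percent_below,
        lfq_cv_threshold         = qp_pg$cv_threshold,
        lfq_pg_n_evaluable       = qp_pg$n_evaluable,
        lfq_pg_n_below_threshold = qp_pg$n_below_threshold,
        lfq_pg_percent_below     = qp_pg$percent_below,
        lfq_pep_n_evaluable      = qp_pep$n_evaluable,
        lfq_pep_n_below_threshold = qp_pep$n_below_threshold,
        lfq_pep_percent_below    = qp_pep$percent_below,
        stringsAsFactors = FALSE
    )
}
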