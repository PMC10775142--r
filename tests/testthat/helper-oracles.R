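# Naive brute-force reimplementations of every metric, written with plain
# loops and independent of the package's vectorised code paths. Used to
# cross-check the main implementation on small random bundles.

oraclePresence <- function(b, level) {
    runs <- mqbench::runLabels(b)
    if (level == "protein_group") {
        a <- SummarizedExperiment::assay(mqbench::proteinGroups(b))
        feats <- as.character(seq_len(nrow(a)))
        present <- function(f, r) !is.na(a[as.integer(f), r])
    } else if (level == "peptide") {
        a <- SummarizedExperiment::assay(mqbench::peptides(b))
        seqs <- SummarizedExperiment::rowData(mqbench::peptides(b))$sequence
        feats <- unique(seqs)
        present <- function(f, r) {
            any(!is.na(a[seqs == f, r]))
        }
    } else {
        ev <- as.data.frame(mqbench::evidence(b))
        feats <- unique(paste(ev$modified_sequence, ev$charge, sep = "/"))
        present <- function(f, r) {
            key <- paste(ev$modified_sequence, ev$charge, sep = "/")
            any(key == f & ev$run == r)
        }
    }
    m <- matrix(FALSE, length(feats), length(runs),
                dimnames = list(feats, runs))
    for (f in feats) for (r in runs) m[f, r] <- present(f, r)
    m[apply(m, 1, any), , drop = FALSE]
}

oracleCounts <- function(b, level) {
    m <- oraclePresence(b, level)
    counts <- integer(0)
    for (r in colnames(m)) counts[r] <- sum(m[, r])
    list(counts = counts, median = median(as.numeric(counts)),
         n_features = nrow(m))
}

oracleCompleteness <- function(b, level) {
    m <- oraclePresence(b, level)
    n <- length(mqbench::runLabels(b))
    cbk <- integer(n); names(cbk) <- as.character(seq_len(n))
    for (i in seq_len(nrow(m))) {
        k <- sum(m[i, ])
        cbk[as.character(k)] <- cbk[as.character(k)] + 1L
    }
    cbk
}

oracleCV <- function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(NA_real_)
    mu <- sum(v) / length(v)
    ss <- 0
    for (x in v) ss <- ss + (x - mu)^2
    100 * sqrt(ss / (length(v) - 1)) / mu
}

oracleRTPrecision <- function(b, threshold = 5) {
    ev <- as.data.frame(mqbench::evidence(b))
    runs <- mqbench::runLabels(b)
    keys <- unique(paste(ev$modified_sequence, ev$charge, sep = "/"))
    cvs <- c()
    for (f in keys) {
        rts <- c()
        for (r in runs) {
            sel <- paste(ev$modified_sequence, ev$charge, sep = "/") == f &
                ev$run == r & !is.na(ev$retention_time)
            if (any(sel)) rts <- c(rts, median(ev$retention_time[sel]))
        }
        cvs <- c(cvs, oracleCV(rts))
    }
    cvs <- cvs[!is.na(cvs)]
    list(n_evaluable = length(cvs), n_below = sum(cvs < threshold),
         percent_below = if (length(cvs)) 100 * sum(cvs < threshold) /
             length(cvs) else NA_real_)
}

oracleQuantPrecision <- function(b, level, threshold = 20) {
    runs <- mqbench::runLabels(b)
    if (level == "protein_group") {
        a <- SummarizedExperiment::assay(mqbench::proteinGroups(b))
        rowsets <- as.list(seq_len(nrow(a)))
        val <- function(rows, r) {
            v <- a[rows, r]
            if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
        }
    } else if (level == "peptide") {
        a <- SummarizedExperiment::assay(mqbench::peptides(b))
        seqs <- SummarizedExperiment::rowData(mqbench::peptides(b))$sequence
        rowsets <- lapply(unique(seqs), function(s) which(seqs == s))
        val <- function(rows, r) {
            v <- a[rows, r]
            if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
        }
    } else {
        ev <- as.data.frame(mqbench::evidence(b))
        key <- paste(ev$modified_sequence, ev$charge, sep = "/")
        rowsets <- lapply(unique(key), function(k) which(key == k))
        val <- function(rows, r) {
            v <- ev$intensity[rows][ev$run[rows] == r]
            v <- v[!is.na(v)]
            if (!length(v)) NA_real_ else sum(v)
        }
    }
    cvs <- c()
    for (rows in rowsets) {
        v <- c()
        for (r in runs) v <- c(v, val(rows, r))
        cvs <- c(cvs, oracleCV(v))
    }
    cvs <- cvs[!is.na(cvs)]
    list(n_evaluable = length(cvs), n_below = sum(cvs < threshold),
         percent_below = if (length(cvs)) 100 * sum(cvs < threshold) /
             length(cvs) else NA_real_)
}

oracleOverlap <- function(sets) {
    K <- length(sets)
    res <- NULL
    for (k in seq_len(K)) {
        inter <- unique(sets[[1]])
        for (j in seq_len(k)) inter <- inter[inter %in% sets[[j]]]
        uni <- character()
        for (j in seq_len(k)) uni <- unique(c(uni, sets[[j]]))
        res <- rbind(res, data.frame(k = k, intersection = length(inter),
                                     union = length(uni)))
    }
    res
}

oracleFullProfileAccessions <- function(b, threshold = 100) {
    a <- SummarizedExperiment::assay(mqbench::proteinGroups(b))
    ids <- SummarizedExperiment::rowData(mqbench::proteinGroups(b))$majority_ids
    n <- ncol(a)
    need <- ceiling(threshold / 100 * n)
    accs <- character()
    for (i in seq_len(nrow(a))) {
        npres <- sum(!is.na(a[i, ]))
        if (npres >= need)
            accs <- c(accs, strsplit(ids[i], ";")[[1]])
    }
    unique(accs)
}
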