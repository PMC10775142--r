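#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
NULL

#' MQDataset: one workflow's technical-replicate set
#'
#' Container for a single data set of a multicenter benchmarking study,
#' i.e. one laboratory x LC-MS setup x acquisition mode x time point with
#' its technical replicates. Protein-group and peptide quantifications are
#' held as \linkS4class{SummarizedExperiment} objects (features x runs, one
#' \code{"intensity"} assay, \code{NA} = not detected); precursor-level
#' identifications are a long-format evidence \linkS4class{DataFrame} with
#' one row per (modified sequence, charge, run) observation.
#'
#' @slot datasetId single character identifier.
#' @slot runs \code{DataFrame} of parsed run labels (columns \code{label},
#'   \code{time_point}, \code{lab}, \code{lc_system}, \code{ms_instrument},
#'   \code{acquisition}, \code{replicate_index}), ordered by replicate index.
#' @slot proteinGroups \code{SummarizedExperiment}; rowData carries
#'   \code{group_id}, \code{majority_ids} (semicolon-joined accessions),
#'   \code{reverse}, \code{contaminant}, \code{only_by_site}.
#' @slot peptides \code{SummarizedExperiment}; rowData carries
#'   \code{sequence}, \code{missed_cleavages}, \code{reverse},
#'   \code{contaminant}.
#' @slot evidence \code{DataFrame} with columns \code{modified_sequence},
#'   \code{sequence}, \code{charge}, \code{run}, \code{retention_time},
#'   \code{intensity}, \code{reverse}, \code{contaminant}.
#' @slot metadata list of provenance (quantification column used, filter
#'   report once filtered, ...).
#'
#' @seealso [assembleDataset()], [readProteinGroups()],
#'   [applyStandardFilters()], [summarizeDataset()]
#' @exportClass MQDataset
setClass("MQDataset",
    slots = c(
        datasetId     = "character",
        runs          = "DataFrame",
        proteinGroups = "SummarizedExperiment",
        peptides      = "SummarizedExperiment",
        evidence      = "DataFrame",
        metadata      = "list"
    )
)

setValidity("MQDataset", function(object) {
    msg <- character()
    if (length(object@datasetId) != 1L || is.na(object@datasetId))
        msg <- c(msg, "'datasetId' must be a single non-NA string")
    runcols <- c("label", "time_point", "lab", "lc_system", "ms_instrument",
                 "acquisition", "replicate_index")
    if (!all(runcols %in% colnames(object@runs)))
        msg <- c(msg, paste0("'runs' must have columns: ",
                             paste(runcols, collapse = ", ")))
    labs <- object@runs$label
    if (anyDuplicated(labs))
        msg <- c(msg, "run labels must be pairwise distinct")
    if (length(labs) > 1L) {
        for (f in c("time_point", "lab", "lc_system", "ms_instrument",
                    "acquisition")) {
            if (length(unique(object@runs[[f]])) != 1L)
                msg <- c(msg, sprintf("all runs must share '%s'", f))
        }
    }
    for (nm in c("proteinGroups", "peptides")) {
        se <- slot(object, nm)
        if (!identical(colnames(se), as.character(labs)))
            msg <- c(msg, sprintf("colnames(%s) must equal the run labels", nm))
    }
    ev <- object@evidence
    if (nrow(ev) > 0L && !all(ev$run %in% labs))
        msg <- c(msg, sprintf("evidence references runs not in 'runs': %s",
                 paste(setdiff(unique(ev$run), labs), collapse = ", ")))
    if (nrow(ev) > 0L && any(!is.na(ev$retention_time) & ev$retention_time < 0))
        msg <- c(msg, "retention times must be >= 0")
    if (length(msg)) msg else TRUE
})

#' @rdname MQDataset-class
#' @param object,x an \code{MQDataset}.
#' @export
setGeneric("datasetId", function(x) standardGeneric("datasetId"))

#' @rdname MQDataset-class
#' @export
setMethod("datasetId", "MQDataset", function(x) x@datasetId)

#' @rdname MQDataset-class
#' @export
setGeneric("runInfo", function(x) standardGeneric("runInfo"))

#' @rdname MQDataset-class
#' @export
setMethod("runInfo", "MQDataset", function(x) x@runs)

#' @rdname MQDataset-class
#' @export
setGeneric("runLabels", function(x) standardGeneric("runLabels"))

#' @rdname MQDataset-class
#' @export
setMethod("runLabels", "MQDataset", function(x) as.character(x@runs$label))

#' @rdname MQDataset-class
#' @export
setGeneric("proteinGroups", function(x) standardGeneric("proteinGroups"))

#' @rdname MQDataset-class
#' @export
setMethod("proteinGroups", "MQDataset", function(x) x@proteinGroups)

#' @rdname MQDataset-class
#' @export
setGeneric("peptides", function(x) standardGeneric("peptides"))

#' @rdname MQDataset-class
#' @export
setMethod("peptides", "MQDataset", function(x) x@peptides)

#' @rdname MQDataset-class
#' @export
setGeneric("evidence", function(x) standardGeneric("evidence"))

#' @rdname MQDataset-class
#' @export
setMethod("evidence", "MQDataset", function(x) x@evidence)

#' @rdname MQDataset-class
#' @export
setMethod("show", "MQDataset", function(object) {
    cat("MQDataset:", object@datasetId, "\n")
    r <- object@runs
    cat(sprintf("  %d runs (%s, %s, %s/%s, %s)\n", nrow(r),
        r$time_point[1], r$lab[1], r$lc_system[1], r$ms_instrument[1],
        r$acquisition[1]))
    cat(sprintf("  protein groups: %d   peptides: %d   evidence rows: %d\n",
        nrow(object@proteinGroups), nrow(object@peptides),
        nrow(object@evidence)))
    if (!is.null(object@metadata$filter_report))
        cat("  standard filters applied\n")
    invisible(NULL)
})

# metric levels recognised throughout the package
.LEVELS <- c("protein_group", "peptide", "precursor")

.checkLevel <- function(level) {
    if (length(level) != 1L || !level %in% .LEVELS)
        stop("unknown level '", paste(level, collapse = ","),
             "'; must be one of: ", paste(.LEVELS, collapse = ", "),
             call. = FALSE)
    level
}
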