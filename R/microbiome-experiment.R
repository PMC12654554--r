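#' @include AllClasses.R AllGenerics.R
NULL

#' Assemble a MicrobiomeExperiment from its component tables
#'
#' Bundles an ASV count matrix, a sample-metadata table and (optionally) a
#' taxonomy table and an environmental table into a validated
#' [MicrobiomeExperiment-class].
#'
#' @param counts numeric matrix of non-negative counts, features as rows and
#'   samples as columns (both dimensions named).
#' @param sampleData data.frame keyed by `sample_id` with the required
#'   metadata columns (`host_id`, `day`, `trip_status`, `sunblock`,
#'   `cosmetics`, `outdoor`, `batch`).
#' @param taxonomy optional data.frame keyed by `feature_id` with rank
#'   columns `domain` ... `species`; features without a row are treated as
#'   unclassified downstream.
#' @param environment optional data.frame keyed by `sample_id` with the five
#'   [envVariables()] columns (may contain `NA`).
#'
#' @return A [MicrobiomeExperiment-class].
#' @export
#' @examples
#' d <- antarcticStudyDesign(seed = 1)
#' me <- generateStudy(d)
#' me2 <- makeExperiment(counts(me), sampleTable(me))
makeExperiment <- function(counts, sampleData, taxonomy = NULL,
                           environment = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have feature row names and sample column names")
  if (!"sample_id" %in% colnames(sampleData))
    stop("sampleData must contain a sample_id column")
  missing <- setdiff(colnames(counts), sampleData$sample_id)
  if (length(missing))
    stop("samples absent from metadata: ", paste(missing, collapse = ", "))
  sampleData <- sampleData[match(colnames(counts), sampleData$sample_id), ,
                           drop = FALSE]
  if (!is.null(environment)) {
    if (!"sample_id" %in% colnames(environment))
      stop("environment table must contain a sample_id column")
    idx <- match(colnames(counts), environment$sample_id)
    if (anyNA(idx))
      stop("environment table lacks sample(s): ",
           paste(colnames(counts)[is.na(idx)], collapse = ", "))
    for (v in .ENV_VARS) sampleData[[v]] <- environment[[v]][idx]
  }
  cd <- DataFrame(sampleData[setdiff(colnames(sampleData), "sample_id")],
                  row.names = sampleData$sample_id)
  rd <- NULL
  if (!is.null(taxonomy)) {
    if (!"feature_id" %in% colnames(taxonomy))
      stop("taxonomy must contain a feature_id column")
    idx <- match(rownames(counts), taxonomy$feature_id)
    rd <- DataFrame(taxonomy[idx, setdiff(colnames(taxonomy), "feature_id"),
                             drop = FALSE],
                    row.names = rownames(counts))
  }
  se <- SummarizedExperiment(assays = list(counts = counts), colData = cd,
                             rowData = if (is.null(rd)) NULL else rd)
  new("MicrobiomeExperiment", se)
}

#' Extract the count matrix
#'
#' @param object a [MicrobiomeExperiment-class].
#' @return Numeric matrix, features x samples.
#' @importFrom BiocGenerics counts
#' @export
#' @aliases counts,MicrobiomeExperiment-method
setMethod("counts", "MicrobiomeExperiment", function(object) {
  assay(object, "counts")
})

#' Per-sample accessors
#'
#' Convenience accessors over `colData`: trip phase (as an ordered factor),
#' host identifier, integer day offset and batch label.
#'
#' @param object a [MicrobiomeExperiment-class].
#' @return A vector with one entry per sample.
#' @export
tripStatus <- function(object) {
  factor(colData(object)$trip_status, levels = .PHASES, ordered = TRUE)
}

#' @rdname tripStatus
#' @export
hostId <- function(object) colData(object)$host_id

#' @rdname tripStatus
#' @export
sampleDay <- function(object) as.integer(colData(object)$day)

#' @rdname tripStatus
#' @export
batchLabel <- function(object) as.character(colData(object)$batch)

#' Sample metadata as a plain data.frame
#'
#' @param object a [MicrobiomeExperiment-class].
#' @return data.frame with a `sample_id` column followed by all `colData`
#'   columns.
#' @export
sampleTable <- function(object) {
  cd <- as.data.frame(colData(object))
  data.frame(sample_id = rownames(cd), cd, row.names = NULL,
             check.names = FALSE)
}

#' Environmental series of an experiment
#'
#' Extracts the per-sample weather table (with host, day and outdoor flag)
#' in the layout consumed by [imputeIndoorConstants()],
#' [interpolateMissing()] and [standardScale()].
#'
#' @param object a [MicrobiomeExperiment-class].
#' @return data.frame with columns `sample_id`, `host_id`, `day`, `outdoor`
#'   and the five [envVariables()].
#' @export
environmentTable <- function(object) {
  cd <- as.data.frame(colData(object))
  missing <- setdiff(.ENV_VARS, colnames(cd))
  for (v in missing) cd[[v]] <- NA_real_
  data.frame(sample_id = rownames(cd),
             cd[, c("host_id", "day", "outdoor", .ENV_VARS)],
             row.names = NULL, check.names = FALSE)
}

#' Taxonomy table of an experiment
#'
#' @param object a [MicrobiomeExperiment-class].
#' @return data.frame with `feature_id` and whatever rank columns are
#'   present in `rowData`, or NULL when no taxonomy is attached.
#' @export
taxonomyTable <- function(object) {
  rd <- as.data.frame(rowData(object))
  if (ncol(rd) == 0L) return(NULL)
  data.frame(feature_id = rownames(object), rd, row.names = NULL,
             check.names = FALSE)
}

setMethod("show", "MicrobiomeExperiment", function(object) {
  callNextMethod()
  cd <- colData(object)
  cat("hosts(", length(unique(cd$host_id)), "): ",
      paste(unique(cd$host_id), collapse = " "), "\n", sep = "")
  tab <- table(factor(cd$trip_status, levels = .PHASES))
  cat("samples per phase: ",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n", sep = "")
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign with", length(object@hosts), "host(s):",
      paste(object@hosts, collapse = ", "), "\n")
  for (h in object@hosts) {
    sched <- object@phaseSchedule[[h]]
    cat("  ", h, ": ",
        paste(names(sched), sched, sep = "=", collapse = " "),
        " (days)\n", sep = "")
  }
  cat("  features:", object@nFeatures,
      " depth:", object@sequencingDepth,
      " concentration:", object@concentration,
      " batches:", object@nBatches, "\n")
  cat("  sampling every", object@samplingInterval[1L], "-",
      object@samplingInterval[2L], "days; env missing rate",
      object@missingRate, "; seed", object@seed, "\n")
})
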