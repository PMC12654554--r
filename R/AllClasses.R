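#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   'assays<-' assayNames colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

## Canonical ordered expedition phases used throughout the package.
.PHASES <- c("BeforeTrip", "OnTheWay", "Staying", "OnTheWayBack", "AfterTrip")

## Environmental variables tracked per sample, in canonical column order.
.ENV_VARS <- c("temperature", "relative_humidity", "pressure",
               "wind_speed", "wind_direction")

## Lifestyle flags recorded in the daily log.
.LIFESTYLE <- c("sunblock", "cosmetics", "outdoor")

#' Ordered expedition phases
#'
#' The five canonical trip statuses, in chronological order. Every sample in
#' a study is labelled with exactly one of these.
#'
#' @return Character vector of length five.
#' @export
#' @examples
#' tripPhases()
tripPhases <- function() .PHASES

#' Environmental variable names
#'
#' Canonical names of the five per-sample weather variables: temperature
#' (degrees C), relative humidity (percent), atmospheric pressure (hPa),
#' wind speed (m/s) and wind direction (degrees, 0 = north, clockwise).
#'
#' @return Character vector of length five.
#' @export
envVariables <- function() .ENV_VARS

#' StudyDesign: parameters of the synthetic expedition generator
#'
#' An S4 class describing a two-host (or n-host) longitudinal skin-swab
#' sampling design with ordered trip phases, phase-dependent community
#' composition, sequencing batches, lifestyle logs and gappy environmental
#' series. [generateStudy()] turns a design into a
#' [MicrobiomeExperiment-class] with known ground truth.
#'
#' @slot hosts character, host identifiers.
#' @slot phaseSchedule named list, one named numeric vector per host giving
#'   phase durations in days (names from [tripPhases()], in order; a host
#'   may omit phases, e.g. no return-leg samples).
#' @slot samplingInterval integer length-2, inclusive range of days between
#'   consecutive swabs.
#' @slot nFeatures integer, number of ASVs.
#' @slot phaseComposition named list, one matrix per host (phases x features)
#'   of Dirichlet mean proportions; each row sums to 1.
#' @slot concentration numeric, Dirichlet concentration; `Inf` collapses the
#'   count model to a plain multinomial at the phase mean.
#' @slot sequencingDepth numeric, mean reads per sample (Poisson).
#' @slot nBatches integer, number of sequencing batches; samples are assigned
#'   to batches in contiguous blocks of processing order.
#' @slot batchShift matrix (batches x features) of additive log10 offsets
#'   applied to counts of each batch.
#' @slot lifestyleProbs matrix (phases x 3) of per-phase probabilities that
#'   sunblock / cosmetics / outdoor is TRUE.
#' @slot envParams named list, one 2 x 5 matrix per phase (rows "mean","sd";
#'   columns [envVariables()]) for outdoor-day weather draws.
#' @slot missingRate numeric in `[0,1]`, fraction of outdoor environmental
#'   entries blanked to simulate logging gaps.
#' @slot taxonomy data.frame or NULL, feature lineage table.
#' @slot seed integer, RNG seed making generation deterministic.
#'
#' @seealso [studyDesign()], [antarcticStudyDesign()], [generateStudy()]
#' @export
setClass("StudyDesign",
  representation(
    hosts = "character",
    phaseSchedule = "list",
    samplingInterval = "integer",
    nFeatures = "integer",
    phaseComposition = "list",
    concentration = "numeric",
    sequencingDepth = "numeric",
    nBatches = "integer",
    batchShift = "matrix",
    lifestyleProbs = "matrix",
    envParams = "list",
    missingRate = "numeric",
    taxonomy = "ANY",
    seed = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- character()
  if (length(object@hosts) < 1L || anyDuplicated(object@hosts))
    msg <- c(msg, "hosts must be a non-empty set of unique identifiers")
  if (!setequal(names(object@phaseSchedule), object@hosts))
    msg <- c(msg, "phaseSchedule must have one entry per host")
  for (h in names(object@phaseSchedule)) {
    sched <- object@phaseSchedule[[h]]
    if (!all(names(sched) %in% .PHASES))
      msg <- c(msg, sprintf("host %s: unknown phase in schedule", h))
    if (is.unsorted(match(names(sched), .PHASES)))
      msg <- c(msg, sprintf("host %s: phases out of canonical order", h))
    if (any(sched <= 0))
      msg <- c(msg, sprintf("host %s: zero- or negative-duration phase", h))
  }
  if (length(object@samplingInterval) != 2L ||
      any(object@samplingInterval < 1L) ||
      object@samplingInterval[1L] > object@samplingInterval[2L])
    msg <- c(msg, "samplingInterval must be an increasing positive range")
  if (object@nFeatures < 2L)
    msg <- c(msg, "nFeatures must be at least 2")
  for (h in names(object@phaseComposition)) {
    comp <- object@phaseComposition[[h]]
    if (ncol(comp) != object@nFeatures)
      msg <- c(msg, sprintf("host %s: composition has wrong feature count", h))
    if (any(comp < 0))
      msg <- c(msg, sprintf("host %s: negative composition entry", h))
    if (any(abs(rowSums(comp) - 1) > 1e-9))
      msg <- c(msg, sprintf(
        "host %s: composition rows must sum to 1 within 1e-9", h))
    if (!all(names(object@phaseSchedule[[h]]) %in% rownames(comp)))
      msg <- c(msg, sprintf("host %s: composition missing scheduled phase", h))
  }
  if (length(object@concentration) != 1L || object@concentration <= 0)
    msg <- c(msg, "concentration must be a single positive value (Inf allowed)")
  if (object@sequencingDepth <= 0)
    msg <- c(msg, "sequencingDepth must be positive")
  if (object@nBatches < 1L)
    msg <- c(msg, "nBatches must be at least 1")
  if (!all(dim(object@batchShift) == c(object@nBatches, object@nFeatures)))
    msg <- c(msg, "batchShift must be nBatches x nFeatures")
  if (any(!is.finite(object@batchShift)))
    msg <- c(msg, "batchShift offsets must be finite")
  if (!all(rownames(object@lifestyleProbs) %in% .PHASES) ||
      !identical(colnames(object@lifestyleProbs), .LIFESTYLE) ||
      any(object@lifestyleProbs < 0) || any(object@lifestyleProbs > 1))
    msg <- c(msg, "lifestyleProbs must be phases x (sunblock,cosmetics,outdoor) in [0,1]")
  for (ph in names(object@envParams)) {
    ep <- object@envParams[[ph]]
    if (!identical(rownames(ep), c("mean", "sd")) ||
        !identical(colnames(ep), .ENV_VARS) || any(ep["sd", ] < 0))
      msg <- c(msg, sprintf("envParams[%s] must be a 2 x 5 mean/sd matrix", ph))
  }
  if (object@missingRate < 0 || object@missingRate > 1)
    msg <- c(msg, "missingRate must lie in [0,1]")
  if (length(msg)) msg else TRUE
})

#' MicrobiomeExperiment: samples-by-features container for the pipeline
#'
#' An S4 class extending [SummarizedExperiment::SummarizedExperiment] that
#' holds an ASV count matrix (features as rows, samples as columns) in the
#' `"counts"` assay, per-sample metadata (host, day offset, trip status,
#' lifestyle flags, batch, weather) in `colData`, and taxonomy in `rowData`.
#'
#' Required `colData` columns: `host_id`, `day` (integer day offset from
#' study start), `trip_status` (one of [tripPhases()]), `sunblock`,
#' `cosmetics`, `outdoor` (logical) and `batch`. The five
#' [envVariables()] columns are optional and may contain `NA` (missing
#' weather log entries) until [imputeIndoorConstants()] /
#' [interpolateMissing()] are run.
#'
#' @seealso [makeExperiment()], [generateStudy()]
#' @export
setClass("MicrobiomeExperiment", contains = "SummarizedExperiment")

.REQUIRED_COLDATA <- c("host_id", "day", "trip_status",
                       "sunblock", "cosmetics", "outdoor", "batch")

setValidity("MicrobiomeExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    cts <- assay(object, "counts")
    if (anyNA(cts) || any(cts < 0))
      msg <- c(msg, "counts must be non-negative and complete")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate feature identifiers")
  cd <- colData(object)
  missing <- setdiff(.REQUIRED_COLDATA, colnames(cd))
  if (length(missing))
    msg <- c(msg, paste0("colData lacks required column(s): ",
                         paste(missing, collapse = ", ")))
  if ("trip_status" %in% colnames(cd) &&
      !all(cd$trip_status %in% .PHASES))
    msg <- c(msg, paste0("trip_status values must be among: ",
                         paste(.PHASES, collapse = ", ")))
  if ("day" %in% colnames(cd) && anyNA(cd$day))
    msg <- c(msg, "day offsets must be complete")
  if (length(msg)) msg else TRUE
})
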