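#' @include AllClasses.R
NULL

## Read a TSV with header, keeping blank fields as NA and never mangling
## column names. Ragged rows are reported with their line number.
.readTsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L)
    stop("file ", path, " has no data rows")
  ## count separators directly: strsplit would drop trailing blank fields
  nTabs <- nchar(lines) - nchar(gsub("\t", "", lines, fixed = TRUE))
  bad <- which(nTabs != nTabs[1L])
  if (length(bad))
    stop("ragged row(s) in ", path, " at line(s): ",
         paste(bad, collapse = ", "))
  utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

.writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

#' Read / write an ASV feature table
#'
#' Feature tables are tab-separated with a header row. By default samples
#' are rows and features columns (`orientation = "samples"`); set
#' `orientation = "features"` for the transposed layout. Either way the
#' returned matrix is in the package's canonical orientation, features as
#' rows and samples as columns. Duplicated identifiers, negative or
#' non-numeric entries are rejected with the offending row/column named.
#'
#' @param path file path.
#' @param orientation `"samples"` if rows of the file are samples,
#'   `"features"` if rows are features.
#' @return `readFeatureTable`: numeric matrix, features x samples.
#' @export
readFeatureTable <- function(path, orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  df <- .readTsv(path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated ", if (orientation == "samples") "sample" else "feature",
         " id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  other <- colnames(df)[-1L]
  if (anyDuplicated(other))
    stop("duplicated column id(s) in ", path, ": ",
         paste(unique(other[duplicated(other)]), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("invalid (negative or non-numeric) count at row '",
         ids[bad[1L, 1L]], "', column '", other[bad[1L, 2L]], "' in ", path)
  }
  rownames(m) <- ids
  if (orientation == "samples") m <- t(m)
  m
}

#' @param x feature count matrix, features x samples.
#' @rdname readFeatureTable
#' @export
writeFeatureTable <- function(x, path,
                              orientation = c("samples", "features")) {
  orientation <- match.arg(orientation)
  m <- if (orientation == "samples") t(x) else x
  idName <- if (orientation == "samples") "sample_id" else "feature_id"
  df <- data.frame(rownames(m), m, check.names = FALSE)
  colnames(df)[1L] <- idName
  .writeTsv(df, path)
  invisible(path)
}

.parseBool <- function(x, column, path) {
  low <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(low))
  out[low %in% c("yes", "true", "1")] <- TRUE
  out[low %in% c("no", "false", "0")] <- FALSE
  bad <- !is.na(x) & is.na(out)
  if (any(bad))
    stop("column '", column, "' in ", path,
         " has non-boolean value(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (accepted: Yes/No, true/false, 1/0)")
  out
}

#' Read / write the sample metadata table
#'
#' Required columns: `sample_id`, `host_id`, `day` (integer day offset),
#' `trip_status` (one of [tripPhases()]), `sunblock`, `cosmetics`,
#' `outdoor` (Yes/No or true/false, both dialects accepted) and `batch`.
#'
#' @param path file path.
#' @return `readSampleMetadata`: data.frame with canonical boolean and
#'   phase encodings.
#' @export
readSampleMetadata <- function(path) {
  df <- .readTsv(path)
  required <- c("sample_id", "host_id", "day", "trip_status",
                "sunblock", "cosmetics", "outdoor", "batch")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("metadata ", path, " lacks required column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in ", path)
  bad <- !df$trip_status %in% .PHASES
  if (any(bad))
    stop("unknown trip_status value(s) in ", path, ": ",
         paste(unique(df$trip_status[bad]), collapse = ", "),
         "; allowed values: ", paste(.PHASES, collapse = ", "))
  df$day <- as.integer(df$day)
  if (anyNA(df$day)) stop("non-integer day offset(s) in ", path)
  for (v in .LIFESTYLE) df[[v]] <- .parseBool(df[[v]], v, path)
  df$batch <- as.character(df$batch)
  df[order(df$host_id, df$day), , drop = FALSE]
}

#' @param metadata data.frame as returned by [readSampleMetadata()].
#' @rdname readSampleMetadata
#' @export
writeSampleMetadata <- function(metadata, path) {
  df <- metadata
  for (v in .LIFESTYLE) df[[v]] <- ifelse(df[[v]], "Yes", "No")
  .writeTsv(df, path)
  invisible(path)
}

#' Read / write the taxonomy table
#'
#' Tab-separated, `feature_id` plus the seven rank columns `domain`,
#' `phylum`, `class`, `order`, `family`, `genus`, `species`; unclassified
#' ranks are blank.
#'
#' @param path file path.
#' @return `readTaxonomyTable`: data.frame.
#' @export
readTaxonomyTable <- function(path) {
  df <- .readTsv(path)
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  missing <- setdiff(c("feature_id", ranks), colnames(df))
  if (length(missing))
    stop("taxonomy ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(df$feature_id))
    stop("duplicated feature_id in ", path)
  df[, c("feature_id", ranks)]
}

#' @param taxonomy data.frame as returned by [readTaxonomyTable()].
#' @rdname readTaxonomyTable
#' @export
writeTaxonomyTable <- function(taxonomy, path) {
  .writeTsv(taxonomy, path)
  invisible(path)
}

#' Read / write the environmental series table
#'
#' Tab-separated with columns `sample_id`, `host_id`, `day`, `outdoor` and
#' the five [envVariables()]. Blank fields are missing observations and are
#' preserved as `NA` for [imputeIndoorConstants()] and
#' [interpolateMissing()]; a sentinel number is never used because 0 is a
#' legitimate wind value. Range checks (humidity in `[0,100]`, wind direction
#' in `[0,360)`, wind speed >= 0) apply to present values only.
#'
#' @param path file path.
#' @return `readEnvironmentTable`: data.frame with `NA` for missing entries.
#' @export
readEnvironmentTable <- function(path) {
  df <- .readTsv(path)
  required <- c("sample_id", "host_id", "day", "outdoor", .ENV_VARS)
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("environment table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  df$day <- as.integer(df$day)
  df$outdoor <- .parseBool(df$outdoor, "outdoor", path)
  for (v in .ENV_VARS) df[[v]] <- as.numeric(df[[v]])
  chk <- function(cond, what) {
    if (any(cond, na.rm = TRUE))
      stop("out-of-range ", what, " in ", path, " for sample(s): ",
           paste(df$sample_id[which(cond)], collapse = ", "))
  }
  chk(df$relative_humidity < 0 | df$relative_humidity > 100,
      "relative_humidity (must be in [0,100])")
  chk(df$wind_speed < 0, "wind_speed (must be >= 0)")
  chk(df$wind_direction < 0 | df$wind_direction >= 360,
      "wind_direction (must be in [0,360))")
  df[order(df$host_id, df$day), , drop = FALSE]
}

#' @param env data.frame as returned by [readEnvironmentTable()].
#' @rdname readEnvironmentTable
#' @export
writeEnvironmentTable <- function(env, path) {
  df <- env
  df$outdoor <- ifelse(df$outdoor, "Yes", "No")
  .writeTsv(df, path)
  invisible(path)
}

#' Read / write a distance matrix
#'
#' Square, labelled, tab-separated. Symmetry is checked to 1e-12 and the
#' diagonal must be zero.
#'
#' @param path file path.
#' @return `readDistanceMatrix`: symmetric numeric matrix with matching
#'   dimnames.
#' @export
readDistanceMatrix <- function(path) {
  df <- .readTsv(path)
  ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (!identical(rownames(m), colnames(m)))
    stop("distance matrix ", path, " row and column labels differ")
  validateDistanceMatrix(m)
  m
}

#' @param dm symmetric distance matrix.
#' @rdname readDistanceMatrix
#' @export
writeDistanceMatrix <- function(dm, path) {
  df <- data.frame(sample_id = rownames(dm), dm, check.names = FALSE)
  .writeTsv(df, path)
  invisible(path)
}

#' Validate a distance matrix
#'
#' Checks squareness, label agreement, symmetry (to 1e-12), a zero diagonal
#' and non-negative entries. Called by every consumer of distance matrices.
#'
#' @param dm numeric matrix.
#' @return `dm`, invisibly, or an error.
#' @export
validateDistanceMatrix <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm))
    stop("distance matrix must be square")
  if (max(abs(dm - t(dm))) > 1e-12)
    stop("distance matrix is not symmetric within 1e-12")
  if (any(abs(diag(dm)) > 1e-12))
    stop("distance matrix diagonal must be zero")
  if (any(dm < 0))
    stop("distance matrix entries must be non-negative")
  invisible(dm)
}

#' Write or read all study tables of an experiment
#'
#' `writeStudyTables` writes the four canonical tab-separated tables
#' (feature table, sample metadata, taxonomy, environment) into a
#' directory; `readStudyTables` reads them back into a
#' [MicrobiomeExperiment-class].
#'
#' @param object a [MicrobiomeExperiment-class].
#' @param dir directory (created if absent).
#' @return `writeStudyTables`: the directory, invisibly;
#'   `readStudyTables`: a [MicrobiomeExperiment-class].
#' @export
writeStudyTables <- function(object, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFeatureTable(counts(object), file.path(dir, "feature_table.tsv"))
  md <- sampleTable(object)
  writeSampleMetadata(md[, c("sample_id", "host_id", "day", "trip_status",
                             "sunblock", "cosmetics", "outdoor", "batch")],
                      file.path(dir, "sample_metadata.tsv"))
  tax <- taxonomyTable(object)
  if (!is.null(tax))
    writeTaxonomyTable(tax, file.path(dir, "taxonomy.tsv"))
  writeEnvironmentTable(environmentTable(object),
                        file.path(dir, "environment.tsv"))
  invisible(dir)
}

#' @rdname writeStudyTables
#' @export
readStudyTables <- function(dir) {
  counts <- readFeatureTable(file.path(dir, "feature_table.tsv"))
  md <- readSampleMetadata(file.path(dir, "sample_metadata.tsv"))
  taxPath <- file.path(dir, "taxonomy.tsv")
  tax <- if (file.exists(taxPath)) readTaxonomyTable(taxPath) else NULL
  env <- readEnvironmentTable(file.path(dir, "environment.tsv"))
  makeExperiment(counts, md, taxonomy = tax, environment = env)
}
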