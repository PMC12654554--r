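#' @include AllClasses.R synthetic-data.R tables-io.R metadata-prep.R
#'   abundance-prep.R combat.R diversity.R resilience.R association.R
NULL

#' Default pipeline configuration
#'
#' Returns the configuration list [runPipeline()] consumes, filled with the
#' package defaults: the two-host Antarctic synthetic design, occurrence
#' strictly above 0.1 and total strictly above 5 feature filtering, covariate-protected batch
#' correction, Shannon base 2, 999 PERMANOVA permutations, the `"zero"`
#' resilience reference and successive-sample association shifts.
#'
#' @param seed integer seed; fans out to per-stage sub-seeds by fixed
#'   offsets so every stage is individually reproducible.
#' @param outDir optional output directory; `NULL` disables writing.
#' @return Named list; edit fields or pass a YAML file with the same keys
#'   to [runPipeline()].
#' @export
defaultRunConfig <- function(seed = 1L, outDir = NULL) {
  list(
    seed = as.integer(seed),
    inputDir = NULL,          # read the four tables from here instead of
                              # generating, when non-NULL
    outDir = outDir,
    minOccurrence = 0.1,
    minTotal = 5,
    combatTol = 1e-4,
    combatMaxIter = 500L,
    covariates = c("host_id", "trip_status"),
    multicollinearityThreshold = 0.9,
    shannonBase = 2,
    permutations = 999L,
    d0Mode = "zero",
    associationMode = "successive",
    aggregationRank = "phylum"
  )
}

.validateRunConfig <- function(config) {
  required <- c("seed", "minOccurrence", "minTotal", "permutations",
                "d0Mode", "associationMode", "shannonBase")
  missing <- required[!vapply(required, function(f)
    !is.null(config[[f]]), logical(1L))]
  if (length(missing))
    stop("run config lacks required field(s): ",
         paste(missing, collapse = ", "))
  if (!config$d0Mode %in% c("zero", "baseline_self", "global_max"))
    stop("d0Mode must be one of: zero, baseline_self, global_max")
  if (!config$associationMode %in% c("successive", "from_baseline"))
    stop("associationMode must be 'successive' or 'from_baseline'")
  if (config$minOccurrence < 0 || config$minTotal < 0 ||
      config$permutations < 1L)
    stop("thresholds must be positive")
  invisible(config)
}

#' Run the full longitudinal microbiome pipeline
#'
#' Orchestrates every stage in order: synthetic generation (or table
#' ingest), environmental preparation (indoor constants, interpolation,
#' scaling), feature filtering, log10 transform, empirical-Bayes batch
#' correction with covariate protection, back-transform and relative
#' abundance, alpha diversity with per-host phase tests, Bray-Curtis /
#' PCoA / PERMANOVA per host, baseline trajectories with per-phase
#' resilience indices, and environment/lifestyle associations. With the
#' same config (including seed) the run is fully deterministic; when
#' `outDir` is set every intermediate table plus a JSON manifest is
#' written.
#'
#' @param config a list as from [defaultRunConfig()], or the path of a YAML
#'   file with the same keys (missing keys take the defaults; `seed`,
#'   `d0Mode` and the other required keys must resolve to valid values
#'   before any computation starts).
#' @return Invisibly, a list of results: `experiment`, `environment`,
#'   `alpha`, `alphaTests`, `distance`, `pcoa`, `permanova`, `trajectory`,
#'   `resilience`, `associations`, `screen`, `phylum`, and `manifest`.
#' @export
#' @examples
#' res <- runPipeline(defaultRunConfig(seed = 7))
#' res$resilience$A
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config) && length(config) == 1L) {
    user <- yaml::read_yaml(config)
    config <- utils::modifyList(defaultRunConfig(), user,
                                keep.null = TRUE)
    if (!"seed" %in% names(user))
      stop("run config file must set a seed")
  }
  .validateRunConfig(config)
  warnings <- character()

  ## stage 1: inputs (sub-seed offset 0)
  if (!is.null(config$inputDir)) {
    me <- readStudyTables(config$inputDir)
  } else {
    me <- generateStudy(antarcticStudyDesign(seed = config$seed))
  }

  ## stage 2: environmental preparation
  env <- environmentTable(me)
  envScaled <- prepareEnvironment(env)

  ## stage 3: abundance preparation
  filtered <- filterFeatures(counts(me),
                             minOccurrence = config$minOccurrence,
                             minTotal = config$minTotal)
  logm <- logTransform(filtered)
  md <- sampleTable(me)
  cov <- md[, intersect(config$covariates, colnames(md)), drop = FALSE]
  covKept <- removeMulticollinear(cov,
                                  threshold =
                                    config$multicollinearityThreshold)
  adj <- combatAdjust(logm, batchLabel(me), covKept$covariates,
                      tol = config$combatTol,
                      maxIter = config$combatMaxIter)
  corrected <- delog(adj$adjusted)
  relab <- relativeAbundance(corrected)

  tax <- taxonomyTable(me)
  phylum <- if (is.null(tax)) NULL else
    relativeAbundance(aggregateTaxa(corrected, tax, "phylum"))

  ## stage 4: diversity (counts feed alpha; corrected abundances feed beta)
  alpha <- alphaDiversity(filtered, base = config$shannonBase)
  hosts <- unique(md$host_id)
  alphaTests <- list(); dms <- list(); ords <- list(); perms <- list()
  for (h in hosts) {
    sel <- md$sample_id[md$host_id == h]
    phases <- md$trip_status[match(sel, md$sample_id)]
    a <- alpha[match(sel, alpha$sample_id), ]
    alphaTests[[h]] <- lapply(
      stats::setNames(c("shannon", "simpson", "chao1",
                        "observed_features"),
                      c("shannon", "simpson", "chao1",
                        "observed_features")),
      function(metric) kruskalWallisPosthoc(a[[metric]], phases))
    dms[[h]] <- brayCurtis(relab[, sel, drop = FALSE])
    ords[[h]] <- pcoaOrdination(dms[[h]], nAxes = 2L)
    perms[[h]] <- permanova(dms[[h]], phases,
                            nPermutations = config$permutations,
                            seed = config$seed + 11L)
  }

  ## stage 5: resilience
  traj <- lapply(stats::setNames(hosts, hosts), function(h)
    baselineTrajectory(dms[[h]], md, h))
  resil <- lapply(stats::setNames(hosts, hosts), function(h)
    perPhaseResilience(dms[[h]], md, h, d0Mode = config$d0Mode))

  ## stage 6: associations
  assoc <- list()
  for (h in hosts) {
    shift <- betaShiftSeries(dms[[h]], md, h,
                             mode = config$associationMode)
    envH <- envScaled[envScaled$host_id == h, , drop = FALSE]
    reg <- regressShiftOnEnv(shift, envH)
    life <- md[md$host_id == h,
               c("sample_id", "sunblock", "cosmetics", "outdoor")]
    shiftLife <- lapply(c("sunblock", "cosmetics", "outdoor"), function(v) {
      b <- life[[v]][match(shift$sample_id, life$sample_id)]
      if (length(unique(b)) < 2L)
        return(data.frame(factor = v, method = "point_biserial",
                          coefficient = NA_real_, pValue = NA_real_,
                          n = length(b), flag = "single level"))
      r <- pointBiserialCorrelation(b, shift$shift)
      data.frame(factor = v, r[, c("method", "coefficient", "pValue", "n",
                                   "flag")])
    })
    selH <- md$sample_id[md$host_id == h]
    matH <- taxonFactorMatrix(relab[, selH, drop = FALSE],
                              envH, life)
    assoc[[h]] <- list(shift = shift, regression = reg,
                       lifestyle = do.call(rbind, shiftLife),
                       matrix = matH)
  }
  screen <- taxonPhaseScreen(relab, md$trip_status)

  manifest <- list(
    package = "microtraj",
    version = as.character(utils::packageVersion("microtraj")),
    seed = config$seed,
    parameters = config[c("minOccurrence", "minTotal", "shannonBase",
                          "permutations", "d0Mode", "associationMode")],
    pseudocount = attr(logm, "pseudocount"),
    droppedFeatures = length(attr(filtered, "dropped")),
    droppedCovariates = covKept$dropped,
    combatIterations = adj$model$iterations,
    stages = list(
      input = dim(counts(me)),
      filtered = dim(filtered),
      corrected = dim(corrected)),
    warnings = warnings)

  results <- list(experiment = me, environment = envScaled,
                  covariateLog = covKept$log, batchModel = adj$model,
                  corrected = corrected, relabund = relab,
                  phylum = phylum, alpha = alpha, alphaTests = alphaTests,
                  distance = dms, pcoa = ords, permanova = perms,
                  trajectory = traj, resilience = resil,
                  associations = assoc, screen = screen,
                  manifest = manifest)

  if (!is.null(config$outDir)) .writePipelineOutputs(results, config)
  invisible(results)
}

.writePipelineOutputs <- function(results, config) {
  dir <- config$outDir
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeStudyTables(results$experiment, file.path(dir, "input"))
  writeEnvironmentTable(results$environment,
                        file.path(dir, "environment_scaled.tsv"))
  writeFeatureTable(results$corrected,
                    file.path(dir, "corrected_abundance.tsv"))
  writeFeatureTable(results$relabund,
                    file.path(dir, "relative_abundance.tsv"))
  .writeTsv(results$alpha, file.path(dir, "alpha_diversity.tsv"))
  for (h in names(results$distance)) {
    writeDistanceMatrix(results$distance[[h]],
                        file.path(dir, paste0("bray_curtis_", h, ".tsv")))
    .writeTsv(results$trajectory[[h]],
              file.path(dir, paste0("trajectory_", h, ".tsv")))
    .writeTsv(results$resilience[[h]],
              file.path(dir, paste0("resilience_", h, ".tsv")))
    .writeTsv(results$associations[[h]]$matrix,
              file.path(dir, paste0("associations_", h, ".tsv")))
  }
  .writeTsv(results$screen, file.path(dir, "taxon_phase_screen.tsv"))
  jsonlite::write_json(results$manifest,
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
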