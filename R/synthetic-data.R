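#' @include AllClasses.R AllGenerics.R microbiome-experiment.R
NULL

## Phase-averaged phylum-level relative abundances (percent) observed on the
## cheek of two hosts during Antarctic expeditions; used as the generator's
## default ground-truth composition. Host B returned without usable
## return-leg samples, so its OnTheWayBack profile is reconstructed as the
## midpoint of Staying and AfterTrip.
.PHYLUM_PROFILES <- local({
  phyla <- c("Actinomycetota", "Pseudomonadota", "Bacillota_D",
             "Bacteroidota", "Bacillota_A", "Bacillota_C", "Cyanobacteria",
             "Deinococcota", "Fusobacteriota", "Planctomycetota",
             "Eremiobacterota", "Gemmatimonadota", "Unclassified")
  A <- rbind(
    BeforeTrip   = c(91.97, 2.65, 3.27, 1.06, 0.44, 0.11, 0.02, 0.00, 0.01, 0, 0, 0, 0.47),
    OnTheWay     = c(91.70, 2.50, 3.48, 0.71, 0.85, 0.29, 0.02, 0.00, 0.01, 0, 0, 0, 0.43),
    Staying      = c(76.12, 10.37, 8.25, 2.86, 0.89, 0.62, 0.29, 0.18, 0.06, 0, 0, 0, 0.36),
    OnTheWayBack = c(80.52, 8.57, 7.61, 1.83, 0.49, 0.30, 0.01, 0.17, 0.05, 0, 0, 0, 0.45),
    AfterTrip    = c(61.68, 11.90, 17.54, 5.51, 2.39, 0.44, 0.02, 0.13, 0.12, 0, 0, 0, 0.28))
  B4 <- rbind(
    BeforeTrip = c(74.58, 9.85, 12.90, 0.87, 1.29, 0.19, 0.00, 0.04, 0.00, 0.00, 0.00, 0.00, 0.29),
    OnTheWay   = c(83.93, 5.44, 6.79, 1.58, 1.14, 0.43, 0.00, 0.03, 0.20, 0.00, 0.00, 0.00, 0.45),
    Staying    = c(80.51, 8.67, 5.98, 2.46, 0.91, 0.39, 0.44, 0.23, 0.06, 0.05, 0.02, 0.02, 0.28),
    AfterTrip  = c(68.66, 14.41, 7.34, 4.96, 4.39, 0.24, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00, 0.00))
  B <- rbind(B4[c("BeforeTrip", "OnTheWay", "Staying"), , drop = FALSE],
             OnTheWayBack = (B4["Staying", ] + B4["AfterTrip", ]) / 2,
             AfterTrip = B4["AfterTrip", ])
  colnames(A) <- colnames(B) <- phyla
  list(A = A / rowSums(A) * 100, B = B / rowSums(B) * 100)
})

#' Reference phylum profiles of the Antarctic expedition design
#'
#' Per-phase mean phylum-level relative abundances (percent) for the two
#' expedition hosts that the default synthetic design emulates. Rows are
#' trip phases, columns phyla (plus an `Unclassified` column).
#'
#' @return Named list of two matrices (`A`, `B`), rows summing to 100.
#' @export
#' @examples
#' rowSums(antarcticPhylumProfiles()$A)
antarcticPhylumProfiles <- function() .PHYLUM_PROFILES

#' Construct a StudyDesign
#'
#' Low-level constructor with full control over every generator parameter;
#' most users want [antarcticStudyDesign()], which fills in the two-host
#' expedition defaults.
#'
#' @param hosts character, host identifiers.
#' @param phaseSchedule named list of named numeric vectors (phase -> days).
#' @param phaseComposition named list of phases x features proportion
#'   matrices, one per host.
#' @param samplingInterval integer length-2 range of days between swabs.
#' @param concentration Dirichlet concentration (Inf = no overdispersion).
#' @param sequencingDepth mean reads per sample.
#' @param nBatches number of sequencing batches.
#' @param batchShift batches x features matrix of log10 offsets (defaults to
#'   no batch effect).
#' @param lifestyleProbs phases x 3 matrix of P(sunblock), P(cosmetics),
#'   P(outdoor).
#' @param envParams named list of 2 x 5 mean/sd matrices per phase.
#' @param missingRate fraction of outdoor weather entries blanked.
#' @param taxonomy optional feature_id + rank data.frame.
#' @param seed integer RNG seed.
#'
#' @return A validated [StudyDesign-class].
#' @export
studyDesign <- function(hosts, phaseSchedule, phaseComposition,
                        samplingInterval = c(2L, 3L),
                        concentration = 200, sequencingDepth = 20000,
                        nBatches = 1L, batchShift = NULL,
                        lifestyleProbs = NULL, envParams = NULL,
                        missingRate = 0.15, taxonomy = NULL, seed = 1L) {
  nFeatures <- ncol(phaseComposition[[1L]])
  if (is.null(batchShift))
    batchShift <- matrix(0, nBatches, nFeatures)
  if (is.null(lifestyleProbs)) {
    lifestyleProbs <- matrix(rep(c(0.3, 0.3, 0.6), each = length(.PHASES)),
                             ncol = 3,
                             dimnames = list(.PHASES, .LIFESTYLE))
  }
  if (is.null(envParams)) {
    envParams <- lapply(stats::setNames(.PHASES, .PHASES), function(ph)
      matrix(c(10, 5, 50, 10, 1010, 5, 3, 1, 180, 60), nrow = 2,
             dimnames = list(c("mean", "sd"), .ENV_VARS)))
  }
  new("StudyDesign",
      hosts = hosts,
      phaseSchedule = phaseSchedule,
      samplingInterval = as.integer(samplingInterval),
      nFeatures = as.integer(nFeatures),
      phaseComposition = phaseComposition,
      concentration = as.numeric(concentration),
      sequencingDepth = as.numeric(sequencingDepth),
      nBatches = as.integer(nBatches),
      batchShift = batchShift,
      lifestyleProbs = lifestyleProbs,
      envParams = envParams,
      missingRate = as.numeric(missingRate),
      taxonomy = taxonomy,
      seed = as.integer(seed))
}

## Deterministic within-phylum ASV weights: a geometric series, so a few
## ASVs dominate each phylum as in real skin communities.
.withinWeights <- function(n, ratio = 0.6) {
  w <- ratio^(seq_len(n) - 1L)
  w / sum(w)
}

#' Default two-host Antarctic expedition design
#'
#' Builds the [StudyDesign-class] the package's tests and acceptance runs
#' use: two hosts sampled every 2-3 days across the five ordered trip
#' phases, with phase composition anchored to the reference phylum profiles
#' of [antarcticPhylumProfiles()], a three-batch structure with
#' feature-level log10 shifts, phase-dependent lifestyle logs, and gappy
#' Antarctic/temperate weather series. Host A's itinerary (two-week transit,
#' ten-week polar stay) is longer than Host B's (short flights, seven-week
#' stay).
#'
#' @param seed integer seed; the design (batch shifts) and the downstream
#'   generation are deterministic functions of it.
#' @param asvPerPhylum named integer vector, number of ASVs assigned to each
#'   phylum column of the reference profiles.
#' @param concentration Dirichlet concentration controlling sample-to-sample
#'   compositional noise around the phase mean.
#' @param sequencingDepth mean reads per sample.
#' @param batchShiftSd standard deviation of the per-feature log10 batch
#'   offsets (batch 1 is the unshifted reference).
#' @param missingRate fraction of outdoor weather entries blanked.
#'
#' @return A [StudyDesign-class].
#' @export
#' @examples
#' d <- antarcticStudyDesign(seed = 7)
#' me <- generateStudy(d)
antarcticStudyDesign <- function(seed = 1L,
                                 asvPerPhylum = NULL,
                                 concentration = 200,
                                 sequencingDepth = 20000,
                                 batchShiftSd = 0.2,
                                 missingRate = 0.15) {
  profiles <- .PHYLUM_PROFILES
  phyla <- colnames(profiles$A)
  if (is.null(asvPerPhylum)) {
    asvPerPhylum <- stats::setNames(
      c(40L, 20L, 15L, 10L, 8L, 6L, 4L, 4L, 3L, 2L, 2L, 2L, 4L), phyla)
  }
  stopifnot(setequal(names(asvPerPhylum), phyla))
  asvPerPhylum <- asvPerPhylum[phyla]
  nFeatures <- sum(asvPerPhylum)
  featPhylum <- rep(phyla, asvPerPhylum)
  featIds <- sprintf("ASV%03d", seq_len(nFeatures))
  weights <- unlist(lapply(asvPerPhylum, .withinWeights), use.names = FALSE)

  compose <- function(profile) {
    comp <- matrix(0, nrow(profile), nFeatures,
                   dimnames = list(rownames(profile), featIds))
    for (ph in rownames(profile)) {
      p <- (profile[ph, ] / 100)[featPhylum] * weights
      comp[ph, ] <- p / sum(p)
    }
    comp
  }
  phaseComposition <- list(A = compose(profiles$A), B = compose(profiles$B))

  phaseSchedule <- list(
    A = c(BeforeTrip = 14, OnTheWay = 17, Staying = 70,
          OnTheWayBack = 21, AfterTrip = 14),
    B = c(BeforeTrip = 14, OnTheWay = 3, Staying = 49,
          OnTheWayBack = 3, AfterTrip = 14))

  lifestyleProbs <- rbind(
    BeforeTrip   = c(0.2, 0.3, 0.4),
    OnTheWay     = c(0.4, 0.3, 0.5),
    Staying      = c(0.7, 0.4, 0.8),
    OnTheWayBack = c(0.4, 0.3, 0.5),
    AfterTrip    = c(0.2, 0.3, 0.4))
  colnames(lifestyleProbs) <- .LIFESTYLE

  envRow <- function(tm, ts, hm, hs, pm, ps, wm, ws, dm, ds)
    matrix(c(tm, ts, hm, hs, pm, ps, wm, ws, dm, ds), nrow = 2,
           dimnames = list(c("mean", "sd"), .ENV_VARS))
  envParams <- list(
    BeforeTrip   = envRow(15, 5, 50, 10, 1015, 5, 2, 1, 180, 60),
    OnTheWay     = envRow(8, 6, 60, 12, 1008, 6, 5, 2, 200, 70),
    Staying      = envRow(-2, 5, 45, 12, 990, 8, 5, 2, 260, 60),
    OnTheWayBack = envRow(8, 6, 60, 12, 1008, 6, 5, 2, 200, 70),
    AfterTrip    = envRow(15, 5, 50, 10, 1015, 5, 2, 1, 180, 60))

  nBatches <- 3L
  ## batch shifts are part of the design, derived deterministically from the
  ## seed without disturbing the caller's RNG stream
  batchShift <- local({
    state <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (is.null(state)) {
      if (exists(".Random.seed", .GlobalEnv))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", state, .GlobalEnv))
    set.seed(seed + 101L)
    rbind(0, matrix(stats::rnorm((nBatches - 1L) * nFeatures,
                                 sd = batchShiftSd),
                    nBatches - 1L, nFeatures))
  })
  colnames(batchShift) <- featIds

  taxonomy <- .defaultTaxonomy(featIds, featPhylum)

  studyDesign(hosts = c("A", "B"),
              phaseSchedule = phaseSchedule,
              phaseComposition = phaseComposition,
              concentration = concentration,
              sequencingDepth = sequencingDepth,
              nBatches = nBatches,
              batchShift = batchShift,
              lifestyleProbs = lifestyleProbs,
              envParams = envParams,
              missingRate = missingRate,
              taxonomy = taxonomy,
              seed = seed)
}

## Seven-rank placeholder lineages keyed to the phylum assignment; features
## in the Unclassified pool carry no lineage at all.
.defaultTaxonomy <- function(featIds, featPhylum) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  tax <- data.frame(feature_id = featIds)
  for (r in ranks) tax[[r]] <- NA_character_
  classified <- featPhylum != "Unclassified"
  idxWithin <- stats::ave(seq_along(featIds), featPhylum,
                          FUN = seq_along)
  tax$domain[classified] <- "d__Bacteria"
  tax$phylum[classified] <- paste0("p__", featPhylum[classified])
  tax$class[classified] <- paste0("c__", featPhylum[classified], "_c")
  tax$order[classified] <- paste0("o__", featPhylum[classified], "_o")
  tax$family[classified] <- paste0("f__", featPhylum[classified], "_f")
  tax$genus[classified] <- paste0("g__", featPhylum[classified], "_g",
                                  1L + (idxWithin[classified] - 1L) %/% 3L)
  tax$species[classified] <- paste0("s__", featPhylum[classified], "_sp",
                                    idxWithin[classified])
  tax
}

## Sampling days for one host: swab at day 0, then every 2-3 (interval
## range) days until the schedule ends. Returns day offsets and phase labels.
.sampleSchedule <- function(sched, interval) {
  total <- sum(sched)
  bounds <- cumsum(sched)
  days <- integer()
  d <- 0L
  steps <- seq(interval[1L], interval[2L])
  while (d < total) {
    days <- c(days, d)
    d <- d + if (length(steps) == 1L) steps else sample(steps, 1L)
  }
  phase <- names(sched)[findInterval(days, c(0, bounds), rightmost.closed =
                                       TRUE)]
  list(days = days, phase = phase)
}

## One Dirichlet-multinomial draw: proportions from a Dirichlet with mean
## `m` and concentration `conc`, counts multinomial at `depth`.
.rdirmult <- function(m, conc, depth) {
  if (is.infinite(conc)) {
    p <- m
  } else {
    g <- stats::rgamma(length(m), shape = m * conc)
    if (sum(g) == 0) g[which.max(m)] <- 1
    p <- g / sum(g)
  }
  stats::rmultinom(1L, depth, p)[, 1L]
}

#' Generate a synthetic expedition study
#'
#' Simulates the full set of study inputs from a [StudyDesign-class]:
#' Dirichlet-multinomial ASV counts with phase-dependent mean composition,
#' per-sample lifestyle logs, contiguous-block sequencing batches with
#' log10-scale count shifts, and phase-specific weather draws for outdoor
#' days (indoor days have no weather record; a fraction of outdoor entries
#' is additionally blanked). The result is deterministic given the design's
#' seed.
#'
#' @param design a [StudyDesign-class].
#' @return A [MicrobiomeExperiment-class] with counts, metadata, taxonomy
#'   and (gappy) environmental columns.
#' @export
generateStudy <- function(design) {
  validObject(design)
  set.seed(design@seed)
  featIds <- colnames(design@phaseComposition[[1L]])
  if (is.null(featIds)) featIds <- sprintf("ASV%03d",
                                           seq_len(design@nFeatures))

  meta <- list(); countCols <- list()
  for (h in design@hosts) {
    sched <- design@phaseSchedule[[h]]
    ss <- .sampleSchedule(sched, design@samplingInterval)
    comp <- design@phaseComposition[[h]]
    for (k in seq_along(ss$days)) {
      day <- ss$days[k]; ph <- ss$phase[k]
      depth <- max(1L, stats::rpois(1L, design@sequencingDepth))
      cts <- .rdirmult(comp[ph, ], design@concentration, depth)
      sid <- sprintf("%s_D%03d", h, day)
      countCols[[sid]] <- cts
      pr <- design@lifestyleProbs[ph, ]
      outdoor <- stats::runif(1L) < pr["outdoor"]
      ep <- design@envParams[[ph]]
      if (outdoor) {
        env <- stats::rnorm(5L, ep["mean", ], ep["sd", ])
        env[2L] <- min(max(env[2L], 0), 100)     # relative humidity
        env[4L] <- max(env[4L], 0)               # wind speed
        env[5L] <- env[5L] %% 360                # wind direction
        blank <- stats::runif(5L) < design@missingRate
        env[blank] <- NA_real_
      } else {
        env <- rep(NA_real_, 5L)                 # indoor: no weather record
      }
      meta[[sid]] <- data.frame(
        sample_id = sid, host_id = h, day = day, trip_status = ph,
        sunblock = stats::runif(1L) < pr["sunblock"],
        cosmetics = stats::runif(1L) < pr["cosmetics"],
        outdoor = outdoor,
        temperature = env[1L], relative_humidity = env[2L],
        pressure = env[3L], wind_speed = env[4L],
        wind_direction = env[5L])
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  counts <- do.call(cbind, countCols)
  rownames(counts) <- featIds

  ## sequencing batches: contiguous blocks of processing order (host, day)
  n <- nrow(meta)
  meta$batch <- if (design@nBatches == 1L) "batch1" else
    paste0("batch", cut(seq_len(n), breaks = design@nBatches,
                        labels = FALSE))
  shift <- design@batchShift
  rownames(shift) <- paste0("batch", seq_len(design@nBatches))
  me <- makeExperiment(counts, meta, taxonomy = design@taxonomy)
  me <- injectBatchEffect(me, batchLabel(me), shift)
  S4Vectors::metadata(me)$design <- list(seed = design@seed,
                                         concentration = design@concentration,
                                         sequencingDepth = design@sequencingDepth,
                                         nBatches = design@nBatches)
  me
}

#' Apply a multiplicative (log10-scale) batch effect to counts
#'
#' Multiplies each feature's counts in batch `b` by `10^shift[b, feature]`
#' and rounds back to integers; zero counts stay zero. This creates the
#' technical confounding that [combatAdjust()] is designed to remove.
#'
#' @param x count matrix (features x samples) or
#'   [MicrobiomeExperiment-class].
#' @param batches character vector of batch labels, one per sample.
#' @param shift matrix of finite log10 offsets with one row per batch label
#'   (row names must cover every label) and one column per feature.
#' @param ... unused.
#'
#' @return Object of the same class as `x` with shifted counts.
#' @rdname injectBatchEffect
#' @export
#' @examples
#' m <- matrix(c(7, 3, 0, 5), 2, 2,
#'             dimnames = list(c("f1", "f2"), c("s1", "s2")))
#' sh <- matrix(c(1, 0), 1, 2, dimnames = list("b1", NULL))
#' injectBatchEffect(m, c("b1", "b1"), sh)
setMethod("injectBatchEffect", "matrix", function(x, batches, shift, ...) {
  if (length(batches) != ncol(x))
    stop("need one batch label per sample")
  if (any(!is.finite(shift)))
    stop("batch shift offsets must be finite")
  unknown <- setdiff(unique(batches), rownames(shift))
  if (length(unknown))
    stop("unknown batch label(s): ", paste(unknown, collapse = ", "))
  out <- x
  for (b in unique(batches)) {
    j <- which(batches == b)
    out[, j] <- round(x[, j] * 10^shift[b, ])
  }
  out
})

#' @rdname injectBatchEffect
#' @export
setMethod("injectBatchEffect", "MicrobiomeExperiment",
          function(x, batches, shift, ...) {
  cts <- injectBatchEffect(counts(x), batches, shift)
  assays(x)$counts <- cts
  validObject(x)
  x
})
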