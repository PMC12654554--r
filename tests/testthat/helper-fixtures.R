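## Small in-code fixtures shared across test files.

## A compact two-host design (fewer features, shorter phases) for tests that
## only need study-shaped data, not the full expedition timeline.
smallDesign <- function(seed = 1L, concentration = 200,
                        sequencingDepth = 5000) {
  antarcticStudyDesign(
    seed = seed,
    asvPerPhylum = c(Actinomycetota = 10L, Pseudomonadota = 6L,
                     Bacillota_D = 5L, Bacteroidota = 3L, Bacillota_A = 2L,
                     Bacillota_C = 2L, Cyanobacteria = 1L,
                     Deinococcota = 1L, Fusobacteriota = 1L,
                     Planctomycetota = 1L, Eremiobacterota = 1L,
                     Gemmatimonadota = 1L, Unclassified = 2L),
    concentration = concentration,
    sequencingDepth = sequencingDepth)
}

## One-host design with explicit per-phase compositions over `k` features,
## for resilience/trajectory tests needing controlled divergence/recovery.
trajectoryDesign <- function(comp, sched, seed = 1L, k = ncol(comp),
                             concentration = Inf, depth = 1e5,
                             interval = c(2L, 2L)) {
  colnames(comp) <- sprintf("F%02d", seq_len(k))
  studyDesign(hosts = "H",
              phaseSchedule = list(H = sched),
              phaseComposition = list(H = comp),
              samplingInterval = interval,
              concentration = concentration,
              sequencingDepth = depth,
              missingRate = 0,
              seed = seed)
}

## Per-phase compositions on 10 features interpolating between a baseline
## profile and its reversal: `deltas[phase]` = 0 reproduces baseline,
## larger values move further away, so Bray-Curtis from baseline is
## monotone in delta.
blockComposition <- function(deltas) {
  base <- c(rep(0.16, 5L), rep(0.04, 5L))
  t(vapply(deltas, function(d) {
    p <- base * (1 - d) + rev(base) * d
    p / sum(p)
  }, numeric(10L)))
}

## Naive double-loop Bray-Curtis oracle.
brayOracle <- function(x) {
  n <- ncol(x)
  d <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(x[, i] - x[, j])) / sum(x[, i] + x[, j])
  }
  d
}

## One-way PERMANOVA pseudo-F computed directly from the definition
## (total / within-group partition of squared dissimilarities).
pseudoFOracle <- function(dm, groups) {
  N <- nrow(dm)
  g <- unique(groups)
  sst <- sum(dm[upper.tri(dm)]^2) / N
  ssw <- sum(vapply(g, function(gr) {
    idx <- which(groups == gr)
    sub <- dm[idx, idx, drop = FALSE]
    sum(sub[upper.tri(sub)]^2) / length(idx)
  }, numeric(1L)))
  ssa <- sst - ssw
  (ssa / (length(g) - 1)) / (ssw / (N - length(g)))
}

## Tiny valid metadata + environment frames for I/O and env-prep tests.
toyMetadata <- function() {
  data.frame(
    sample_id = c("H_D000", "H_D002", "H_D004", "H_D006"),
    host_id = "H", day = c(0L, 2L, 4L, 6L),
    trip_status = c("BeforeTrip", "BeforeTrip", "Staying", "AfterTrip"),
    sunblock = c(FALSE, TRUE, TRUE, FALSE),
    cosmetics = FALSE, outdoor = c(TRUE, FALSE, TRUE, TRUE),
    batch = "batch1")
}

toyEnvironment <- function() {
  data.frame(
    sample_id = c("H_D000", "H_D002", "H_D004", "H_D006"),
    host_id = "H", day = c(0L, 2L, 4L, 6L),
    outdoor = c(TRUE, FALSE, TRUE, TRUE),
    temperature = c(10, 5, NA, 20),
    relative_humidity = c(40, NA, 60, 80),
    pressure = c(1000, NA, NA, 1020),
    wind_speed = c(1, 3, 2, 0),
    wind_direction = c(90, NA, 180, 270))
}
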