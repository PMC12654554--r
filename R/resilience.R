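#' @include AllClasses.R tables-io.R
NULL

#' Dissimilarity-from-baseline trajectory of one host
#'
#' For every sample of a host, the mean Bray-Curtis distance to all of that
#' host's `BeforeTrip` (baseline) samples; a baseline sample's distance to
#' itself is excluded from its own mean. The trajectory is ordered by
#' sampling day and carries `similarity = 1 - dissimilarity`, the quantity
#' plotted when asking how far a community has drifted from its
#' pre-expedition state.
#'
#' @param dm distance matrix over all samples (labelled).
#' @param metadata sample metadata data.frame (`sample_id`, `host_id`,
#'   `day`, `trip_status`).
#' @param host host identifier to extract.
#' @return data.frame ordered by day: `sample_id`, `day`, `phase`,
#'   `dissimilarity`, `similarity`.
#' @export
baselineTrajectory <- function(dm, metadata, host) {
  validateDistanceMatrix(dm)
  md <- metadata[metadata$host_id == host, , drop = FALSE]
  if (nrow(md) == 0L) stop("no samples for host '", host, "'")
  missing <- setdiff(md$sample_id, rownames(dm))
  if (length(missing))
    stop("sample(s) absent from distance matrix: ",
         paste(missing, collapse = ", "))
  base <- md$sample_id[md$trip_status == "BeforeTrip"]
  if (length(base) == 0L)
    stop("host '", host, "' has no BeforeTrip baseline samples")
  md <- md[order(md$day), , drop = FALSE]
  diss <- vapply(md$sample_id, function(s) {
    ref <- setdiff(base, s)
    if (length(ref) == 0L) return(0)   # lone baseline sample vs itself
    mean(dm[s, ref])
  }, numeric(1L))
  data.frame(sample_id = md$sample_id, day = md$day,
             phase = md$trip_status, dissimilarity = unname(diss),
             similarity = 1 - unname(diss), row.names = NULL)
}

#' Per-phase resilience index
#'
#' The community resilience index for one trip phase:
#' \deqn{RI = \left[\frac{2 (D_0 - D_L)}{(D_0 - D_L) + (D_0 - D_N)} - 1\right]
#'   \times \frac{1}{T_N - T_L}}
#' where \eqn{D_L} and \eqn{D_N} are the dissimilarities from the baseline
#' community at the first and last sample of the phase, \eqn{T_L} and
#' \eqn{T_N} the corresponding day offsets, and \eqn{D_0} a reference
#' dissimilarity. With the default reference \eqn{D_0 = 0} the bracket
#' collapses to \eqn{(D_L - D_N)/(D_L + D_N)}, so the index is positive
#' exactly when the community moved back toward baseline during the phase,
#' zero when it did not change, and negative when it diverged further —
#' higher values mean a quicker or more complete return to baseline.
#'
#' @param D0 reference dissimilarity.
#' @param DL,DN dissimilarity from baseline at the phase's first / last
#'   sample.
#' @param TL,TN first / last sampling day offsets (days); `TN` must exceed
#'   `TL`.
#' @return The index (1/days).
#' @export
#' @examples
#' resilienceIndex(0, 0.5, 0, 0, 5)        # full recovery in 5 days: 0.2
#' resilienceIndex(0, 0.4, 0.4, 0, 7)      # no change: 0
resilienceIndex <- function(D0, DL, DN, TL, TN) {
  if (TN <= TL)
    stop("phase duration undefined: TN must exceed TL")
  denom <- (D0 - DL) + (D0 - DN)
  if (abs(denom) < 1e-12 * max(1, abs(D0 - DL), abs(D0 - DN)))
    stop("resilience index undefined: (D0-DL) + (D0-DN) is zero")
  (2 * (D0 - DL) / denom - 1) / (TN - TL)
}

#' Resilience index for every phase of a host
#'
#' Walks the host's baseline trajectory and computes one
#' [resilienceIndex()] per phase after `BeforeTrip`, using the trajectory's
#' dissimilarity at the phase's first and last sample as \eqn{D_L} and
#' \eqn{D_N}. Phases with fewer than two samples, or with an undefined
#' index, are flagged rather than dropped.
#'
#' The reference dissimilarity \eqn{D_0} is a required convention choice:
#' \describe{
#'   \item{`"zero"`}{\eqn{D_0 = 0} (default): the index reduces to
#'     \eqn{(D_L - D_N)/(D_L + D_N)} per day and its sign directly encodes
#'     movement toward (positive) or away from (negative) baseline.}
#'   \item{`"baseline_self"`}{mean pairwise Bray-Curtis distance among the
#'     baseline samples themselves (their intrinsic day-to-day wobble).}
#'   \item{`"global_max"`}{the host's maximum trajectory dissimilarity.}
#' }
#'
#' @param dm distance matrix over all samples.
#' @param metadata sample metadata data.frame.
#' @param host host identifier.
#' @param d0Mode reference convention, see Details.
#' @return data.frame with one row per phase after `BeforeTrip`: `phase`,
#'   `D0`, `DL`, `DN`, `TL`, `TN`, `RI` (NA when flagged), `flag` (empty,
#'   `"insufficient samples"` or `"undefined index"`), plus attribute
#'   `"d0Mode"`.
#' @export
perPhaseResilience <- function(dm, metadata, host,
                               d0Mode = c("zero", "baseline_self",
                                          "global_max")) {
  d0Mode <- match.arg(d0Mode)
  traj <- baselineTrajectory(dm, metadata, host)
  base <- traj$sample_id[traj$phase == "BeforeTrip"]
  D0 <- switch(d0Mode,
    zero = 0,
    baseline_self = {
      if (length(base) < 2L) 0
      else mean(dm[base, base][upper.tri(matrix(0, length(base),
                                                length(base)))])
    },
    global_max = max(traj$dissimilarity))
  phases <- intersect(.PHASES[-1L], unique(traj$phase))
  rows <- lapply(phases, function(ph) {
    tr <- traj[traj$phase == ph, , drop = FALSE]
    out <- data.frame(phase = ph, D0 = D0, DL = NA_real_, DN = NA_real_,
                      TL = NA_real_, TN = NA_real_, RI = NA_real_,
                      flag = "")
    if (nrow(tr) < 2L) {
      out$flag <- "insufficient samples"
      if (nrow(tr) == 1L) {
        out$DL <- out$DN <- tr$dissimilarity
        out$TL <- out$TN <- tr$day
      }
      return(out)
    }
    out$DL <- tr$dissimilarity[1L]; out$DN <- tr$dissimilarity[nrow(tr)]
    out$TL <- tr$day[1L]; out$TN <- tr$day[nrow(tr)]
    ri <- tryCatch(resilienceIndex(D0, out$DL, out$DN, out$TL, out$TN),
                   error = function(e) NA_real_)
    if (is.na(ri)) out$flag <- "undefined index" else out$RI <- ri
    out
  })
  res <- do.call(rbind, rows)
  attr(res, "d0Mode") <- d0Mode
  res
}
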