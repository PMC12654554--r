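#' @include AllClasses.R resilience.R
NULL

#' Per-sample beta-diversity shift series
#'
#' The magnitude of community change over time for one host, in one of two
#' modes: `"successive"` — the Bray-Curtis distance between each sample and
#' the host's chronologically previous sample (series starts at the second
#' sample); `"from_baseline"` — the dissimilarity-from-baseline trajectory
#' of [baselineTrajectory()].
#'
#' @param dm distance matrix over all samples.
#' @param metadata sample metadata data.frame.
#' @param host host identifier.
#' @param mode `"successive"` or `"from_baseline"`.
#' @return data.frame ordered by day: `sample_id`, `day`, `phase`, `shift`,
#'   with attribute `"mode"`.
#' @export
betaShiftSeries <- function(dm, metadata, host,
                            mode = c("successive", "from_baseline")) {
  mode <- match.arg(mode)
  if (mode == "from_baseline") {
    tr <- baselineTrajectory(dm, metadata, host)
    out <- data.frame(sample_id = tr$sample_id, day = tr$day,
                      phase = tr$phase, shift = tr$dissimilarity)
  } else {
    validateDistanceMatrix(dm)
    md <- metadata[metadata$host_id == host, , drop = FALSE]
    if (nrow(md) < 2L)
      stop("host '", host, "' has fewer than 2 samples")
    md <- md[order(md$day), , drop = FALSE]
    ids <- md$sample_id
    shift <- vapply(seq_along(ids)[-1L],
                    function(k) dm[ids[k], ids[k - 1L]], numeric(1L))
    out <- data.frame(sample_id = ids[-1L], day = md$day[-1L],
                      phase = md$trip_status[-1L], shift = shift)
  }
  attr(out, "mode") <- mode
  out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties), with a
#' two-sided p-value from the t approximation on n - 2 degrees of freedom.
#' A constant input yields an undefined (NA) coefficient with a flag
#' instead of an error.
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return data.frame row: `method`, `coefficient`, `pValue`, `n`, `flag`.
#' @export
#' @examples
#' spearmanCorrelation(1:4, c(2, 1, 4, 3))$coefficient   # 0.6
spearmanCorrelation <- function(x, y) {
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n != length(y)) stop("x and y differ in length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    return(data.frame(method = "spearman", coefficient = NA_real_,
                      pValue = NA_real_, n = n, flag = "constant input"))
  rho <- stats::cor(rank(x), rank(y))
  p <- .tTestP(rho, n)
  data.frame(method = "spearman", coefficient = rho, pValue = p, n = n,
             flag = "")
}

## two-sided p for a correlation coefficient via the t transform
.tTestP <- function(r, n) {
  if (abs(r) >= 1) return(0)
  tval <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tval), df = n - 2)
}

#' Point-biserial correlation
#'
#' Correlation between a binary variable and a continuous one: numerically
#' identical to the Pearson correlation of `y` with the 0/1 coding of `b`,
#' with a two-sided t-test p-value on n - 2 degrees of freedom. Both binary
#' levels must be present.
#'
#' @param b logical (or two-level) vector.
#' @param y numeric vector of the same length, n >= 3.
#' @return data.frame row: `method`, `coefficient`, `pValue`, `n`, `flag`.
#' @export
pointBiserialCorrelation <- function(b, y) {
  if (!is.logical(b)) {
    lv <- sort(unique(b[!is.na(b)]))
    if (length(lv) > 2L) stop("b must have at most two levels")
    b <- b == lv[length(lv)]
  }
  keep <- stats::complete.cases(b, y)
  b <- b[keep]; y <- y[keep]
  n <- length(b)
  if (n != length(y)) stop("b and y differ in length")
  if (n < 3L) stop("need at least 3 paired observations")
  if (length(unique(b)) < 2L)
    stop("both binary levels must be present")
  if (length(unique(y)) == 1L)
    return(data.frame(method = "point_biserial", coefficient = NA_real_,
                      pValue = NA_real_, n = n, flag = "constant input"))
  r <- stats::cor(as.numeric(b), y)
  data.frame(method = "point_biserial", coefficient = r,
             pValue = .tTestP(r, n), n = n, flag = "")
}

#' Regress the beta-diversity shift on environmental factors
#'
#' One ordinary-least-squares fit of the shift series on each (scaled)
#' environmental factor separately, reporting the slope, \eqn{R^2 = 1 -
#' SS_{res}/SS_{tot}} and the two-sided slope p-value. Zero-variance
#' factors are skipped with a flag.
#'
#' @param shift data.frame from [betaShiftSeries()] (or any data.frame with
#'   `sample_id` and `shift`).
#' @param env environmental data.frame with `sample_id` and the factor
#'   columns (typically the scaled table from [standardScale()]).
#' @param factors which columns of `env` to regress on; defaults to the
#'   five [envVariables()].
#' @return data.frame: `factor`, `slope`, `r_squared`, `pValue`, `n`,
#'   `flag`.
#' @export
regressShiftOnEnv <- function(shift, env, factors = envVariables()) {
  idx <- match(shift$sample_id, env$sample_id)
  if (anyNA(idx))
    stop("shift sample(s) absent from environment table: ",
         paste(shift$sample_id[is.na(idx)], collapse = ", "))
  rows <- lapply(factors, function(v) {
    x <- env[[v]][idx]; y <- shift$shift
    keep <- stats::complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 3L)
      return(data.frame(factor = v, slope = NA_real_, r_squared = NA_real_,
                        pValue = NA_real_, n = length(x),
                        flag = "fewer than 3 points"))
    if (stats::var(x) == 0)
      return(data.frame(factor = v, slope = NA_real_, r_squared = NA_real_,
                        pValue = NA_real_, n = length(x),
                        flag = "zero-variance factor"))
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    data.frame(factor = v, slope = unname(stats::coef(fit)[2L]),
               r_squared = sm$r.squared,
               pValue = sm$coefficients[2L, 4L], n = length(x), flag = "")
  })
  do.call(rbind, rows)
}

#' Taxon-by-factor correlation matrix
#'
#' Correlates every taxon's relative abundance with every environmental and
#' lifestyle factor: Spearman for continuous factors, point-biserial for
#' binary ones. Benjamini-Hochberg adjusted p-values are computed across
#' the whole matrix and reported alongside the raw p-values. Taxa absent in
#' all samples are skipped with a flag.
#'
#' @param relAbund relative abundance matrix, taxa x samples.
#' @param env environmental data.frame (`sample_id` + continuous columns).
#' @param lifestyle data.frame (`sample_id` + logical columns); may be NULL.
#' @param envFactors,lifestyleFactors column selections.
#' @return Long-format data.frame: `taxon`, `factor`, `method`,
#'   `coefficient`, `pValue`, `qValue`, `n`, `flag`.
#' @export
taxonFactorMatrix <- function(relAbund, env, lifestyle = NULL,
                              envFactors = intersect(envVariables(),
                                                     colnames(env)),
                              lifestyleFactors =
                                if (is.null(lifestyle)) character()
                                else intersect(c("sunblock", "cosmetics",
                                                 "outdoor"),
                                               colnames(lifestyle))) {
  samples <- colnames(relAbund)
  envIdx <- match(samples, env$sample_id)
  if (anyNA(envIdx))
    stop("sample(s) absent from environment table: ",
         paste(samples[is.na(envIdx)], collapse = ", "))
  lifeIdx <- if (is.null(lifestyle)) NULL else
    match(samples, lifestyle$sample_id)
  rows <- list()
  for (taxon in rownames(relAbund)) {
    ab <- relAbund[taxon, ]
    if (all(ab == 0)) {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = taxon, factor = NA_character_, method = NA_character_,
        coefficient = NA_real_, pValue = NA_real_, n = length(ab),
        flag = "taxon absent in all samples")
      next
    }
    for (v in envFactors) {
      r <- spearmanCorrelation(env[[v]][envIdx], ab)
      rows[[length(rows) + 1L]] <- data.frame(taxon = taxon, factor = v,
                                              r[, c("method", "coefficient",
                                                    "pValue", "n", "flag")])
    }
    for (v in lifestyleFactors) {
      b <- lifestyle[[v]][lifeIdx]
      r <- if (length(unique(b[!is.na(b)])) < 2L)
        data.frame(method = "point_biserial", coefficient = NA_real_,
                   pValue = NA_real_, n = sum(!is.na(b)),
                   flag = "single level")
      else pointBiserialCorrelation(b, ab)
      rows[[length(rows) + 1L]] <- data.frame(taxon = taxon, factor = v,
                                              r[, c("method", "coefficient",
                                                    "pValue", "n", "flag")])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$qValue <- NA_real_
  ok <- !is.na(out$pValue)
  out$qValue[ok] <- stats::p.adjust(out$pValue[ok], method = "BH")
  out[, c("taxon", "factor", "method", "coefficient", "pValue", "qValue",
          "n", "flag")]
}

#' Per-taxon phase screen
#'
#' A transparent screen for taxa whose abundance varies across trip phases:
#' a Kruskal-Wallis test per taxon across the phase labels, with
#' Benjamini-Hochberg correction across taxa and ranking by the adjusted
#' p-value. This is a deliberately simple stand-in for multivariable
#' association modelling, and outputs are labelled as a screen, not a full
#' model.
#'
#' @param relAbund relative abundance matrix, taxa x samples.
#' @param tripStatus phase label per sample; at least two phases, each with
#'   at least two samples.
#' @return data.frame ranked by `qValue`: `taxon`, `H`, `pValue`, `qValue`.
#' @export
taxonPhaseScreen <- function(relAbund, tripStatus) {
  tripStatus <- as.character(tripStatus)
  if (length(tripStatus) != ncol(relAbund))
    stop("need one trip status per sample")
  sizes <- table(tripStatus)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("need at least two phases with at least two samples each")
  g <- factor(tripStatus)
  res <- t(apply(relAbund, 1L, function(ab) {
    if (length(unique(ab)) == 1L) return(c(H = 0, p = 1))
    kw <- stats::kruskal.test(ab, g)
    c(H = unname(kw$statistic), p = kw$p.value)
  }))
  out <- data.frame(taxon = rownames(relAbund), H = res[, 1L],
                    pValue = res[, 2L],
                    qValue = stats::p.adjust(res[, 2L], method = "BH"),
                    row.names = NULL)
  out[order(out$qValue, out$pValue), ]
}
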