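#' @include AllClasses.R AllGenerics.R microbiome-experiment.R
NULL

#' Filter low-occurrence, low-count features
#'
#' Keeps ASVs whose occurrence (fraction of samples with a non-zero count)
#' is strictly greater than `minOccurrence` AND whose total count across
#' samples is strictly greater than `minTotal`. Defaults are occurrence
#' strictly above 0.1 and total strictly above 5. The sample set and feature order are preserved; the
#' operation is idempotent.
#'
#' @param x count matrix (features x samples) or
#'   [MicrobiomeExperiment-class].
#' @param minOccurrence strict occurrence threshold (fraction of samples).
#' @param minTotal strict total-count threshold.
#' @param ... unused.
#' @return Filtered object of the same class, with attribute `"dropped"`
#'   (matrix input) listing removed feature ids.
#' @rdname filterFeatures
#' @export
#' @examples
#' m <- rbind(keep = c(3, 5, 0, 0), drop = c(6, 0, 0, 0))
#' colnames(m) <- paste0("s", 1:4)
#' filterFeatures(m, minOccurrence = 0.25, minTotal = 5)
setMethod("filterFeatures", "matrix",
          function(x, minOccurrence = 0.1, minTotal = 5, ...) {
  if (nrow(x) == 0L || ncol(x) == 0L)
    stop("empty feature table")
  if (any(x < 0)) stop("counts must be non-negative")
  occurrence <- rowMeans(x > 0)
  total <- rowSums(x)
  keep <- occurrence > minOccurrence & total > minTotal
  out <- x[keep, , drop = FALSE]
  attr(out, "dropped") <- rownames(x)[!keep]
  out
})

#' @rdname filterFeatures
#' @export
setMethod("filterFeatures", "MicrobiomeExperiment",
          function(x, minOccurrence = 0.1, minTotal = 5, ...) {
  kept <- filterFeatures(counts(x), minOccurrence, minTotal)
  x[rownames(kept), ]
})

#' Log10 transform with half-minimum pseudocount
#'
#' Replaces zeros by half the global minimum non-zero value of the matrix,
#' then takes log10 of every entry. The pseudocount used is recorded as the
#' `"pseudocount"` attribute so [delog()] can invert the transform exactly
#' for originally positive entries.
#'
#' @param x non-negative matrix (features x samples) with at least one
#'   non-zero entry.
#' @return log10-scale matrix with attribute `"pseudocount"`.
#' @export
#' @examples
#' logTransform(matrix(c(0, 2, 4, 8), 2))
logTransform <- function(x) {
  if (all(x == 0)) stop("all-zero table cannot be log-transformed")
  if (any(x < 0)) stop("counts must be non-negative")
  pseudo <- min(x[x > 0]) / 2
  y <- x
  y[y == 0] <- pseudo
  out <- log10(y)
  attr(out, "pseudocount") <- pseudo
  out
}

#' Back-transform from log10 scale
#'
#' @param x log10-scale matrix.
#' @return `10^x`, with the `"pseudocount"` attribute removed.
#' @export
delog <- function(x) {
  out <- 10^x
  attr(out, "pseudocount") <- NULL
  out
}

#' Drop multicollinear covariate columns
#'
#' Iteratively removes the later column of any pair whose absolute Pearson
#' correlation reaches `threshold`, until no such pair remains. Factor or
#' logical columns are correlated through their numeric coding.
#'
#' @param covariates data.frame of candidate covariates.
#' @param threshold absolute correlation at or above which the later column
#'   of a pair is dropped.
#' @return list with `covariates` (kept columns), `kept`, `dropped`, and
#'   `log` (one line per removal).
#' @export
removeMulticollinear <- function(covariates, threshold = 0.9) {
  stopifnot(is.data.frame(covariates), ncol(covariates) >= 1L)
  num <- as.data.frame(lapply(covariates, function(col) {
    if (is.numeric(col)) col else as.numeric(as.factor(col))
  }))
  dropped <- character(); log <- character()
  repeat {
    if (ncol(num) < 2L) break
    cm <- suppressWarnings(stats::cor(num))
    cm[is.na(cm)] <- 0
    cm[lower.tri(cm, diag = TRUE)] <- 0
    hit <- which(abs(cm) >= threshold, arr.ind = TRUE)
    if (nrow(hit) == 0L) break
    hit <- hit[order(hit[, 2L], hit[, 1L]), , drop = FALSE]
    j <- hit[1L, 2L]   # later column of the first offending pair
    log <- c(log, sprintf("dropped '%s' (|r| = %.3f with '%s')",
                          colnames(num)[j], abs(cm[hit[1L, 1L], j]),
                          colnames(num)[hit[1L, 1L]]))
    dropped <- c(dropped, colnames(num)[j])
    num <- num[, -j, drop = FALSE]
  }
  kept <- colnames(num)
  list(covariates = covariates[, kept, drop = FALSE], kept = kept,
       dropped = dropped, log = log)
}

#' Per-sample relative abundances
#'
#' Normalizes each sample (column) to proportions summing to 1. A sample
#' with zero total is rejected by name.
#'
#' @param x non-negative matrix (features x samples) or
#'   [MicrobiomeExperiment-class].
#' @param ... unused.
#' @return Matrix of proportions (or an experiment with a `"relabund"`
#'   assay added).
#' @rdname relativeAbundance
#' @export
#' @examples
#' relativeAbundance(matrix(c(2, 3, 5, 1, 1, 2), 3,
#'                   dimnames = list(letters[1:3], c("s1", "s2"))))
setMethod("relativeAbundance", "matrix", function(x, ...) {
  tot <- colSums(x)
  zero <- colnames(x)[tot == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  sweep(x, 2L, tot, "/")
})

#' @rdname relativeAbundance
#' @export
setMethod("relativeAbundance", "MicrobiomeExperiment", function(x, ...) {
  assays(x)$relabund <- relativeAbundance(counts(x))
  x
})

#' Aggregate features at a taxonomic rank
#'
#' Sums feature values sharing the full lineage prefix down to `rank`
#' (keying on the whole prefix, not the bare rank name, so homonymous taxa
#' in different lineages stay separate). Features with no lineage at that
#' rank are pooled into `"Unclassified"`. Per-sample totals are conserved
#' exactly.
#'
#' @param x matrix (features x samples) or [MicrobiomeExperiment-class].
#' @param taxonomy data.frame with `feature_id` and rank columns (`domain`
#'   ... `species`); for the experiment method, defaults to the attached
#'   taxonomy.
#' @param rank one of `"domain"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @param ... unused.
#' @return Aggregated matrix, rows labelled by the rank's taxon name (with
#'   attribute `"lineage"` giving the full prefix keys).
#' @rdname aggregateTaxa
#' @export
setMethod("aggregateTaxa", "matrix", function(x, taxonomy, rank, ...) {
  ranks <- c("domain", "phylum", "class", "order", "family", "genus",
             "species")
  rank <- match.arg(rank, ranks)
  upto <- ranks[seq_len(match(rank, ranks))]
  idx <- match(rownames(x), taxonomy$feature_id)
  key <- rep("Unclassified", nrow(x))
  lab <- rep("Unclassified", nrow(x))
  mapped <- !is.na(idx)
  if (any(mapped)) {
    lin <- taxonomy[idx[mapped], upto, drop = FALSE]
    known <- !is.na(lin[[rank]]) & nzchar(lin[[rank]])
    full <- apply(lin, 1L, paste, collapse = "; ")
    key[mapped][known] <- full[known]
    lab[mapped][known] <- lin[[rank]][known]
  }
  agg <- rowsum(x, group = key, reorder = FALSE)
  labels <- lab[match(rownames(agg), key)]
  out <- agg
  rownames(out) <- labels
  attr(out, "lineage") <- rownames(agg)
  out
})

#' @rdname aggregateTaxa
#' @export
setMethod("aggregateTaxa", "MicrobiomeExperiment",
          function(x, taxonomy = taxonomyTable(x), rank, ...) {
  if (is.null(taxonomy)) stop("experiment carries no taxonomy")
  aggregateTaxa(counts(x), taxonomy, rank)
})

#' Centered moving average
#'
#' Mean over a centered window of odd width; near the edges the window
#' shrinks symmetrically so the output has the input's length (the first
#' and last points are returned unchanged).
#'
#' @param x numeric vector, ordered (e.g. by sampling day).
#' @param window odd positive integer width; default 5.
#' @return Numeric vector, same length as `x`.
#' @export
#' @examples
#' movingAverage(c(1, 2, 3, 4, 5), 5)
movingAverage <- function(x, window = 5L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  n <- length(x)
  if (window > 2L * n)
    stop("window (", window, ") larger than twice the series length (", n,
         ")")
  half <- (window - 1L) %/% 2L
  vapply(seq_len(n), function(i) {
    h <- min(half, i - 1L, n - i)
    mean(x[(i - h):(i + h)])
  }, numeric(1L))
}
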