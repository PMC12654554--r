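#' @include AllClasses.R AllGenerics.R microbiome-experiment.R
NULL

#' Alpha diversity per sample
#'
#' Computes, from integer counts: observed features (number of ASVs with a
#' non-zero count), bias-corrected Chao1 richness
#' \eqn{S + F_1 (F_1 - 1) / (2 (F_2 + 1))} (with \eqn{F_1} singletons and
#' \eqn{F_2} doubletons), Shannon entropy (base 2 by default, i.e. bits)
#' and the Simpson index \eqn{1 - \sum p_i^2}. Richness and entropy are
#' delegated to vegan.
#'
#' @param x count matrix (features x samples) or
#'   [MicrobiomeExperiment-class]; counts must be non-negative integers.
#' @param base logarithm base for the Shannon index (recorded in the
#'   output's `"shannon_base"` attribute).
#' @param ... unused.
#' @return data.frame with one row per sample: `sample_id`,
#'   `observed_features`, `chao1`, `shannon`, `simpson`.
#' @rdname alphaDiversity
#' @export
#' @examples
#' m <- matrix(c(1, 1, 2, 3, 5), 5, 1,
#'             dimnames = list(paste0("f", 1:5), "s1"))
#' alphaDiversity(m)   # chao1 = 5.5
setMethod("alphaDiversity", "matrix", function(x, base = 2, ...) {
  if (any(x < 0) || any(x != round(x)))
    stop("alpha diversity requires non-negative integer counts")
  zero <- colnames(x)[colSums(x) == 0]
  if (length(zero))
    stop("all-zero sample(s): ", paste(zero, collapse = ", "))
  m <- t(x)   # vegan expects samples as rows
  ## estimateR can warn about the (unused) ACE standard error
  est <- suppressWarnings(vegan::estimateR(m))
  out <- data.frame(
    sample_id = colnames(x),
    observed_features = as.integer(colSums(x > 0)),
    chao1 = as.numeric(est["S.chao1", ]),
    shannon = as.numeric(vegan::diversity(m, index = "shannon",
                                          base = base)),
    simpson = as.numeric(vegan::diversity(m, index = "simpson")),
    row.names = NULL)
  attr(out, "shannon_base") <- base
  out
})

#' @rdname alphaDiversity
#' @export
setMethod("alphaDiversity", "MicrobiomeExperiment",
          function(x, base = 2, ...) {
  alphaDiversity(counts(x), base = base)
})

#' Bray-Curtis dissimilarity matrix
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)} between every
#' pair of samples, computed with vegan. Entries lie in `[0,1]` for
#' non-negative data; samples with zero totals are rejected.
#'
#' @param x abundance matrix (features x samples; counts, corrected
#'   abundances or proportions) or [MicrobiomeExperiment-class].
#' @param assay for the experiment method, which assay to use (`"counts"`
#'   or `"relabund"`).
#' @param ... unused.
#' @return Symmetric labelled matrix with zero diagonal.
#' @rdname brayCurtis
#' @export
#' @examples
#' m <- cbind(s1 = c(2, 2), s2 = c(1, 3))
#' brayCurtis(m)["s1", "s2"]   # 0.25
setMethod("brayCurtis", "matrix", function(x, ...) {
  if (ncol(x) < 2L) stop("need at least two samples")
  if (any(x < 0)) stop("abundances must be non-negative")
  zero <- colnames(x)[colSums(x) == 0]
  if (length(zero))
    stop("zero-sum sample(s): ", paste(zero, collapse = ", "))
  dm <- as.matrix(vegan::vegdist(t(x), method = "bray"))
  diag(dm) <- 0
  validateDistanceMatrix(dm)
  dm
})

#' @rdname brayCurtis
#' @export
setMethod("brayCurtis", "MicrobiomeExperiment",
          function(x, assay = "counts", ...) {
  brayCurtis(SummarizedExperiment::assay(x, assay))
})

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix: Gower double-centering of
#' \eqn{-D^2/2}, eigendecomposition, coordinates from the positive
#' eigenvalues only (scaled by the square root of the eigenvalue).
#' Proportion explained is relative to the sum of positive eigenvalues;
#' negative eigenvalues are reported but not used. Axes are defined only up
#' to sign.
#'
#' @param dm symmetric distance matrix.
#' @param nAxes number of axes to return; silently truncated (with a
#'   warning) if fewer positive eigenvalues exist.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), `proportionExplained`, and `negativeEigenvalues`.
#' @export
pcoaOrdination <- function(dm, nAxes = 2L) {
  validateDistanceMatrix(dm)
  n <- nrow(dm)
  A <- -0.5 * dm^2
  G <- A - matrix(rowMeans(A), n, n) -
    matrix(colMeans(A), n, n, byrow = TRUE) + mean(A)
  e <- eigen(G, symmetric = TRUE)
  tolv <- max(abs(e$values)) * 1e-10
  pos <- which(e$values > tolv)
  if (length(pos) == 0L) stop("no positive eigenvalues")
  if (nAxes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalue(s); returning ",
            length(pos), " axes")
    nAxes <- length(pos)
  }
  use <- pos[seq_len(nAxes)]
  coords <- e$vectors[, use, drop = FALSE] %*%
    diag(sqrt(e$values[use]), nAxes)
  dimnames(coords) <- list(rownames(dm), paste0("PCo", seq_len(nAxes)))
  list(coordinates = coords,
       eigenvalues = e$values,
       proportionExplained = e$values[use] / sum(e$values[pos]),
       negativeEigenvalues = e$values[e$values < -tolv])
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F
#' statistic on the partition of squared dissimilarities
#' (\eqn{SS_{total} = \frac{1}{N}\sum_{i<j} d_{ij}^2}, within-group sums
#' over each group), with a label-permutation null. The test is delegated
#' to vegan's `adonis2`; the permutation p-value follows the
#' \eqn{(1 + b)/(1 + m)} convention, so it can never be zero.
#'
#' @param dm symmetric distance matrix.
#' @param groups group label per sample; at least two non-empty groups.
#' @param nPermutations number of label permutations (>= 1).
#' @param seed integer seed for the permutation stream.
#' @return list with `pseudoF`, `pValue`, `nPermutations`, `groupSizes`,
#'   `seed`.
#' @export
permanova <- function(dm, groups, nPermutations = 999L, seed = 1L) {
  validateDistanceMatrix(dm)
  groups <- as.character(groups)
  if (length(groups) != nrow(dm))
    stop("need one group label per sample")
  if (anyNA(groups) || any(!nzchar(groups)))
    stop("empty group label")
  sizes <- table(groups)
  if (length(sizes) < 2L)
    stop("all samples in one group: nothing to test")
  if (nPermutations < 1L)
    stop("nPermutations must be >= 1")
  set.seed(seed)
  df <- data.frame(group = groups)
  fit <- suppressMessages(
    vegan::adonis2(stats::as.dist(dm) ~ group, data = df,
                   permutations = nPermutations))
  list(pseudoF = fit$F[1L],
       pValue = fit[["Pr(>F)"]][1L],
       nPermutations = as.integer(nPermutations),
       groupSizes = as.integer(sizes),
       seed = as.integer(seed))
}

#' Kruskal-Wallis test with Bonferroni-corrected post hocs
#'
#' Rank-based one-way comparison of a numeric variable (e.g. an alpha
#' diversity index) across groups: the Kruskal-Wallis H with tie
#' correction and a chi-square p-value, followed by pairwise two-sided
#' Mann-Whitney U tests whose p-values are multiplied by the number of
#' pairs and capped at 1.
#'
#' @param values numeric observations.
#' @param groups group label per observation; every group non-empty.
#' @return list with `H`, `pValue`, and `pairwise`: a data.frame of
#'   `group1`, `group2`, `U`, `pRaw`, `pBonferroni`.
#' @export
kruskalWallisPosthoc <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups differ in length")
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  sizes <- table(groups)
  if (length(sizes) < 2L || length(values) < 2L)
    stop("need at least two groups and two observations")
  if (any(sizes == 0L))
    stop("empty group")
  if (length(unique(values)) == 1L) {
    ## fully tied data carry no rank information: H is 0 by definition
    kw <- list(statistic = c(H = 0), p.value = 1)
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
  }
  lev <- names(sizes)
  pairs <- utils::combn(lev, 2L)
  res <- lapply(seq_len(ncol(pairs)), function(k) {
    g1 <- pairs[1L, k]; g2 <- pairs[2L, k]
    v1 <- values[groups == g1]; v2 <- values[groups == g2]
    wt <- suppressWarnings(stats::wilcox.test(v1, v2,
                                              alternative = "two.sided"))
    W <- unname(wt$statistic)
    ## report the conventional U = min(U1, U2)
    data.frame(group1 = g1, group2 = g2,
               U = min(W, length(v1) * length(v2) - W),
               pRaw = wt$p.value)
  })
  pw <- do.call(rbind, res)
  pw$pBonferroni <- pmin(pw$pRaw * nrow(pw), 1)
  list(H = unname(kw$statistic), pValue = kw$p.value, pairwise = pw)
}
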