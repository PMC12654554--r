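#' @include AllClasses.R
NULL

.rowVars <- function(m) {
  if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1L)
}

## Method-of-moments hyperpriors of the empirical-Bayes location/scale
## model: gamma_ig ~ N(gamma.bar_i, t2_i), delta2_ig ~ InvGamma(a_i, b_i).
.apriorFun <- function(d) { m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2 }
.bpriorFun <- function(d) { m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2 }

#' Empirical-Bayes batch correction on the log scale
#'
#' Removes additive and multiplicative batch effects from a log10 abundance
#' matrix using the parametric empirical-Bayes location/scale model
#' (feature-wise standardization given the covariate design, shrinkage of
#' per-batch location and scale estimates toward pooled priors by iterated
#' conditional posterior means, then back-transformation restoring the
#' covariate effects). Biological covariates supplied via `covariates` are
#' protected from removal.
#'
#' @param logmat numeric matrix on the log10 scale, features x samples, all
#'   values finite.
#' @param batch character/factor batch label per sample; at least two
#'   batches with at least two samples each.
#' @param covariates optional data.frame of per-sample biological
#'   covariates (factors and numerics); must be full rank jointly with the
#'   batch design — run [removeMulticollinear()] first if unsure.
#' @param tol relative-change convergence tolerance of the posterior
#'   iterations.
#' @param maxIter iteration cap per batch.
#' @return list with `adjusted` (matrix, same dimensions and attributes as
#'   `logmat`) and `model`: per-batch location (`gammaHat`, shrunk
#'   `gammaStar`) and scale (`deltaHat`, `deltaStar`) estimates, the
#'   hyperpriors (`gammaBar`, `t2`, `aPrior`, `bPrior`), the design column
#'   names, iteration counts and any constant-feature flags.
#' @export
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(200), 10, 20)
#' m[, 11:20] <- m[, 11:20] + 1          # additive batch shift
#' b <- rep(c("b1", "b2"), each = 10)
#' fit <- combatAdjust(m, b)
#' # between-batch mean difference is largely removed:
#' mean(rowMeans(fit$adjusted[, 11:20]) - rowMeans(fit$adjusted[, 1:10]))
combatAdjust <- function(logmat, batch, covariates = NULL, tol = 1e-4,
                         maxIter = 500L) {
  dat <- as.matrix(logmat)
  if (any(!is.finite(dat)))
    stop("log abundance matrix must be finite everywhere")
  batch <- factor(batch)
  if (length(batch) != ncol(dat))
    stop("need one batch label per sample")
  if (nlevels(batch) < 2L)
    stop("single batch: nothing to correct")
  ni <- table(batch)
  if (any(ni < 2L))
    stop("batch(es) with fewer than 2 samples: ",
         paste(names(ni)[ni < 2L], collapse = ", "))
  nbatch <- nlevels(batch)
  n <- ncol(dat)

  batchmod <- stats::model.matrix(~ -1 + batch)
  mod <- NULL
  if (!is.null(covariates) && NCOL(covariates) > 0L) {
    covariates <- as.data.frame(covariates)
    mod <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  }
  design <- cbind(batchmod, mod)
  if (qr(design)$rank < ncol(design))
    stop("batch + covariate design is not full rank; remove confounded ",
         "or multicollinear covariates first")

  ## feature-wise standardization given the full design
  B.hat <- solve(crossprod(design), crossprod(design, t(dat)))
  grand.mean <- crossprod(as.numeric(ni) / n,
                          B.hat[seq_len(nbatch), , drop = FALSE])
  resid <- dat - t(design %*% B.hat)
  var.pooled <- rowSums(resid^2) / n
  constant <- var.pooled <= .Machine$double.eps
  var.pooled[constant] <- 1   # placeholder; constant features pass through

  stand.mean <- matrix(grand.mean, nrow(dat), n)
  if (!is.null(mod)) {
    tmp <- design
    tmp[, seq_len(nbatch)] <- 0
    stand.mean <- stand.mean + t(tmp %*% B.hat)
  }
  s.data <- (dat - stand.mean) / sqrt(var.pooled)

  gamma.hat <- solve(crossprod(batchmod), crossprod(batchmod, t(s.data)))
  delta.hat <- t(vapply(levels(batch), function(b)
    .rowVars(s.data[, batch == b, drop = FALSE]), numeric(nrow(dat))))

  gamma.bar <- rowMeans(gamma.hat)
  t2 <- apply(gamma.hat, 1L, stats::var)
  a.prior <- apply(delta.hat, 1L, .apriorFun)
  b.prior <- apply(delta.hat, 1L, .bpriorFun)

  gamma.star <- gamma.hat
  delta.star <- delta.hat
  iters <- integer(nbatch)
  for (i in seq_len(nbatch)) {
    sdat <- s.data[, batch == levels(batch)[i], drop = FALSE]
    nB <- ncol(sdat)
    g.old <- gamma.hat[i, ]; d.old <- delta.hat[i, ]
    count <- 0L
    repeat {
      g.new <- (t2[i] * nB * gamma.hat[i, ] + d.old * gamma.bar[i]) /
        (t2[i] * nB + d.old)
      sum2 <- rowSums((sdat - g.new)^2)
      d.new <- (0.5 * sum2 + b.prior[i]) / (nB / 2 + a.prior[i] - 1)
      change <- max(abs(g.new - g.old) / pmax(abs(g.old), 1e-12),
                    abs(d.new - d.old) / pmax(abs(d.old), 1e-12))
      g.old <- g.new; d.old <- d.new
      count <- count + 1L
      if (change < tol || count >= maxIter) break
    }
    gamma.star[i, ] <- g.old
    delta.star[i, ] <- d.old
    iters[i] <- count
  }

  adjusted <- s.data
  for (i in seq_len(nbatch)) {
    j <- batch == levels(batch)[i]
    adjusted[, j] <- (s.data[, j, drop = FALSE] - gamma.star[i, ]) /
      sqrt(delta.star[i, ])
  }
  adjusted <- adjusted * sqrt(var.pooled) + stand.mean
  adjusted[constant, ] <- dat[constant, , drop = FALSE]
  dimnames(adjusted) <- dimnames(dat)
  attributes(adjusted)[setdiff(names(attributes(logmat)),
                               c("dim", "dimnames"))] <-
    attributes(logmat)[setdiff(names(attributes(logmat)),
                               c("dim", "dimnames"))]

  model <- list(batches = levels(batch), n = as.integer(ni),
                gammaHat = gamma.hat, gammaStar = gamma.star,
                deltaHat = delta.hat, deltaStar = delta.star,
                gammaBar = gamma.bar, t2 = t2,
                aPrior = a.prior, bPrior = b.prior,
                design = colnames(design), iterations = iters,
                constantFeatures = rownames(dat)[constant])
  class(model) <- "BatchModel"
  list(adjusted = adjusted, model = model)
}

#' @export
print.BatchModel <- function(x, ...) {
  cat("Empirical-Bayes batch model:", length(x$batches), "batches (",
      paste(x$batches, x$n, sep = ":", collapse = ", "), ")\n")
  cat("  design columns:", paste(x$design, collapse = ", "), "\n")
  cat("  posterior iterations per batch:",
      paste(x$iterations, collapse = ", "), "\n")
  if (length(x$constantFeatures))
    cat("  constant features passed through:",
        length(x$constantFeatures), "\n")
  invisible(x)
}
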