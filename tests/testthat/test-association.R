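test_that("Spearman is invariant to monotone maps and matches hand ranks", {
  x <- c(0.5, 1.2, 2.0, 3.3, 4.1)
  expect_equal(spearmanCorrelation(x, exp(x))$coefficient, 1)
  expect_equal(spearmanCorrelation(x, -x)$coefficient, -1)
  r <- spearmanCorrelation(1:4, c(2, 1, 4, 3))
  expect_equal(r$coefficient, 0.6)    # 1 - 6*4/(4*15)
  expect_equal(r$n, 4L)
})

test_that("Spearman agrees with independent rank-correlation oracles", {
  set.seed(2)
  for (rep in 1:10) {
    x <- rnorm(25); y <- rnorm(25)
    ours <- spearmanCorrelation(x, y)$coefficient
    expect_equal(ours, cor(x, y, method = "spearman"), tolerance = 1e-12)
    expect_equal(ours, cor(rank(x), rank(y)), tolerance = 1e-12)
  }
  flagged <- spearmanCorrelation(rep(1, 5), rnorm(5))
  expect_true(is.na(flagged$coefficient))
  expect_match(flagged$flag, "constant")
})

test_that("point-biserial equals Pearson on the 0/1 coding", {
  expect_equal(
    pointBiserialCorrelation(c(FALSE, FALSE, TRUE, TRUE),
                             c(0, 0, 1, 1))$coefficient, 1)
  eq <- pointBiserialCorrelation(c(FALSE, TRUE, FALSE, TRUE),
                                 c(3, 3, 5, 5))
  expect_equal(eq$coefficient, 0)
  set.seed(4)
  for (rep in 1:10) {
    b <- sample(c(TRUE, FALSE), 30, replace = TRUE)
    if (length(unique(b)) < 2) next
    y <- rnorm(30)
    res <- pointBiserialCorrelation(b, y)
    expect_equal(res$coefficient, cor(as.numeric(b), y),
                 tolerance = 1e-12)
    expect_equal(res$pValue,
                 cor.test(as.numeric(b), y)$p.value, tolerance = 1e-10)
  }
  expect_error(pointBiserialCorrelation(rep(TRUE, 5), rnorm(5)), "levels")
})

test_that("beta shift series: successive distances and baseline mode", {
  x <- cbind(s1 = c(5, 5), s2 = c(5, 5), s3 = c(1, 9), s4 = c(5, 5))
  rownames(x) <- c("f1", "f2")
  dm <- brayCurtis(x)
  md <- data.frame(sample_id = colnames(x), host_id = "H",
                   day = c(0L, 2L, 4L, 6L),
                   trip_status = c("BeforeTrip", "BeforeTrip", "Staying",
                                   "AfterTrip"))
  sh <- betaShiftSeries(dm, md, "H", mode = "successive")
  expect_equal(nrow(sh), 3L)                  # n - 1 values
  expect_equal(sh$shift[1], 0)                # identical consecutive pair
  expect_equal(sh$shift[2], dm["s2", "s3"])
  base <- betaShiftSeries(dm, md, "H", mode = "from_baseline")
  tr <- baselineTrajectory(dm, md, "H")
  expect_equal(base$shift, tr$dissimilarity)  # shared definition
})

test_that("alternating compositions give a constant successive shift", {
  A <- c(8, 2); B <- c(2, 8)
  x <- cbind(s1 = A, s2 = B, s3 = A, s4 = B)
  rownames(x) <- c("f1", "f2")
  dm <- brayCurtis(x)
  md <- data.frame(sample_id = colnames(x), host_id = "H",
                   day = c(0L, 2L, 4L, 6L),
                   trip_status = "BeforeTrip")
  sh <- betaShiftSeries(dm, md, "H", mode = "successive")
  expect_equal(sh$shift, rep(dm["s1", "s2"], 3))
})

test_that("shift regression recovers exact fits and flags degenerate input", {
  env <- data.frame(sample_id = paste0("s", 1:10),
                    temperature = 1:10, relative_humidity = rep(5, 10),
                    pressure = rnorm(10), wind_speed = runif(10),
                    wind_direction = runif(10, 0, 360))
  shift <- data.frame(sample_id = paste0("s", 1:10),
                      shift = 0.02 * (1:10) + 0.1)
  res <- suppressWarnings(regressShiftOnEnv(shift, env))  # exact fit
  expect_equal(res$r_squared[res$factor == "temperature"], 1)
  expect_equal(res$slope[res$factor == "temperature"], 0.02)
  expect_identical(res$flag[res$factor == "relative_humidity"],
                   "zero-variance factor")
  ## R^2 is invariant to affine rescaling of the factor
  env2 <- env; env2$pressure <- 100 * env2$pressure - 7
  res2 <- suppressWarnings(regressShiftOnEnv(shift, env2))
  expect_equal(res2$r_squared[res2$factor == "pressure"],
               res$r_squared[res$factor == "pressure"], tolerance = 1e-10)
})

test_that("taxon-factor matrix has taxa x factors shape and right methods", {
  set.seed(6)
  n <- 30
  relab <- rbind(taxA = runif(n, 0.1, 0.3), taxB = runif(n, 0.1, 0.3),
                 gone = 0)
  relab <- sweep(relab, 2, colSums(relab), "/")
  relab["gone", ] <- 0
  colnames(relab) <- paste0("s", 1:n)
  env <- data.frame(sample_id = colnames(relab), temperature = rnorm(n),
                    relative_humidity = rnorm(n))
  life <- data.frame(sample_id = colnames(relab),
                     sunblock = rep(c(TRUE, FALSE), n / 2))
  out <- taxonFactorMatrix(relab, env, life)
  done <- out[is.na(out$flag) | out$flag == "", ]
  expect_equal(nrow(done), 2L * 3L)           # 2 live taxa x 3 factors
  expect_setequal(unique(done$method[done$factor == "sunblock"]),
                  "point_biserial")
  expect_setequal(unique(done$method[done$factor == "temperature"]),
                  "spearman")
  expect_true(all(abs(done$coefficient) <= 1))
  expect_true(all(done$pValue > 0 & done$pValue <= 1))
  expect_match(out$flag[out$taxon == "gone"][1], "absent")
})

test_that("a sunblock-suppressed taxon shows a negative point-biserial r", {
  set.seed(9)
  n <- 40
  sunblock <- rep(c(TRUE, FALSE), each = n / 2)
  ab <- ifelse(sunblock, 0.05, 0.25) + rnorm(n, sd = 0.01)
  relab <- rbind(suppressed = ab, filler = 1 - ab)
  colnames(relab) <- paste0("s", 1:n)
  env <- data.frame(sample_id = colnames(relab), temperature = rnorm(n))
  life <- data.frame(sample_id = colnames(relab), sunblock = sunblock)
  out <- taxonFactorMatrix(relab, env, life)
  r <- out[out$taxon == "suppressed" & out$factor == "sunblock", ]
  expect_lt(r$coefficient, -0.9)
  expect_lt(r$qValue, 0.05)
})

test_that("phase screen ranks a Staying-shifted taxon first, null taxa last", {
  set.seed(12)
  n <- 50
  phase <- sample(tripPhases(), n, replace = TRUE)
  while (any(table(factor(phase, tripPhases())) < 2))
    phase <- sample(tripPhases(), n, replace = TRUE)
  relab <- matrix(runif(20 * n, 0.01, 0.05), 20, n,
                  dimnames = list(paste0("t", 1:20), paste0("s", 1:n)))
  relab["t1", phase == "Staying"] <- relab["t1", phase == "Staying"] + 0.5
  out <- taxonPhaseScreen(relab, phase)
  expect_identical(out$taxon[1], "t1")
  expect_lt(out$qValue[1], 0.01)
  flat <- taxonPhaseScreen(rbind(const = rep(0.5, n)), phase)
  expect_equal(flat$qValue, 1)
  ## BH monotonicity in raw-p order
  ord <- out[order(out$pValue), ]
  expect_false(is.unsorted(ord$qValue))
})
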