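## Distance matrix from 1-D community "positions": d(i,j) = |x_i - x_j|,
## a valid dissimilarity in [0,1] for positions in [0,1].
dmFromPositions <- function(pos, ids = names(pos)) {
  d <- abs(outer(pos, pos, "-"))
  dimnames(d) <- list(ids, ids)
  d
}

test_that("resilience index matches direct substitution", {
  expect_equal(resilienceIndex(0, 0.5, 0, 0, 5), 0.2)     # full recovery
  expect_equal(resilienceIndex(0, 0.4, 0.4, 0, 7), 0)     # no change
  expect_equal(resilienceIndex(0.1, 0.5, 0.3, 0, 4), 1 / 12)
  expect_error(resilienceIndex(0, 0.5, 0.3, 2, 2), "TN must exceed")
  expect_error(resilienceIndex(0.4, 0.5, 0.3, 0, 4), "undefined")
})

test_that("index sign tracks movement toward baseline under D0 = 0", {
  expect_gt(resilienceIndex(0, 0.5, 0.2, 0, 5), 0)   # returned toward
  expect_lt(resilienceIndex(0, 0.2, 0.5, 0, 5), 0)   # diverged
  expect_equal(resilienceIndex(0, 0.3, 0.3, 0, 5), 0)
})

test_that("index scales as 1/duration and the bracket is antisymmetric", {
  r1 <- resilienceIndex(0, 0.5, 0.2, 0, 4)
  r2 <- resilienceIndex(0, 0.5, 0.2, 0, 8)
  expect_equal(r1, 2 * r2)
  bracket <- function(D0, DL, DN)
    resilienceIndex(D0, DL, DN, 0, 1)
  expect_equal(bracket(0.05, 0.5, 0.2), -bracket(0.05, 0.2, 0.5))
})

test_that("baseline trajectory averages distances to BeforeTrip samples", {
  pos <- c(s1 = 0, s2 = 0.1, s3 = 0.4, s4 = 0.05)
  dm <- dmFromPositions(pos)
  md <- data.frame(sample_id = names(pos), host_id = "H",
                   day = c(0L, 2L, 4L, 6L),
                   trip_status = c("BeforeTrip", "BeforeTrip", "Staying",
                                   "AfterTrip"))
  tr <- baselineTrajectory(dm, md, "H")
  expect_equal(tr$dissimilarity[1], 0.1)   # s1 vs s2 only (self excluded)
  expect_equal(tr$dissimilarity[3], mean(c(0.4, 0.3)))
  expect_equal(tr$similarity, 1 - tr$dissimilarity)
  expect_true(all(tr$dissimilarity <= max(dm)))
  md0 <- md[md$trip_status != "BeforeTrip", ]
  expect_error(baselineTrajectory(dm, md0, "H"), "no BeforeTrip")
})

test_that("a sample identical to a lone baseline has zero dissimilarity", {
  pos <- c(b = 0, twin = 0, far = 0.6)
  dm <- dmFromPositions(pos)
  md <- data.frame(sample_id = names(pos), host_id = "H",
                   day = c(0L, 2L, 4L),
                   trip_status = c("BeforeTrip", "Staying", "Staying"))
  tr <- baselineTrajectory(dm, md, "H")
  expect_equal(tr$dissimilarity[tr$sample_id == "twin"], 0)
  expect_equal(tr$dissimilarity[tr$sample_id == "b"], 0)
})

test_that("generated Staying-divergent design bottoms out during Staying", {
  deltas <- c(BeforeTrip = 0, OnTheWay = 0.3, Staying = 0.6,
              OnTheWayBack = 0.3, AfterTrip = 0.05)
  comp <- blockComposition(deltas)
  sched <- c(BeforeTrip = 8, OnTheWay = 6, Staying = 12, OnTheWayBack = 6,
             AfterTrip = 8)
  me <- generateStudy(trajectoryDesign(comp, sched, seed = 21L))
  dm <- brayCurtis(relativeAbundance(counts(me)))
  tr <- baselineTrajectory(dm, sampleTable(me), "H")
  expect_identical(tr$phase[which.min(tr$similarity)], "Staying")
})

test_that("per-phase table flags short phases and undefined indices", {
  pos <- c(b1 = 0, b2 = 0.02, w1 = 0.2, w2 = 0.3, st = 0.5,
           a1 = 0.5, a2 = 0.05)
  dm <- dmFromPositions(pos)
  md <- data.frame(sample_id = names(pos), host_id = "H",
                   day = c(0L, 2L, 4L, 6L, 8L, 10L, 12L),
                   trip_status = c("BeforeTrip", "BeforeTrip", "OnTheWay",
                                   "OnTheWay", "Staying", "AfterTrip",
                                   "AfterTrip"))
  res <- perPhaseResilience(dm, md, "H", d0Mode = "zero")
  expect_identical(res$flag[res$phase == "Staying"],
                   "insufficient samples")
  expect_true(is.na(res$RI[res$phase == "Staying"]))
  expect_lt(res$RI[res$phase == "OnTheWay"], 0)   # diverging leg
  expect_gt(res$RI[res$phase == "AfterTrip"], 0)  # recovering leg
  expect_equal(res$RI[res$phase == "AfterTrip"],
               max(res$RI, na.rm = TRUE))
})

test_that("faster recovery earns a strictly larger index", {
  mkHost <- function(endDiss, host) {
    pos <- c(0, 0.01, 0.5, endDiss)
    ids <- paste0(host, c("b1", "b2", "a1", "a2"))
    names(pos) <- ids
    list(dm = dmFromPositions(pos),
         md = data.frame(sample_id = ids, host_id = host,
                         day = c(0L, 2L, 10L, 16L),
                         trip_status = c("BeforeTrip", "BeforeTrip",
                                         "AfterTrip", "AfterTrip")))
  }
  fast <- mkHost(0.05, "F")
  slow <- mkHost(0.30, "S")
  riF <- perPhaseResilience(fast$dm, fast$md, "F")$RI
  riS <- perPhaseResilience(slow$dm, slow$md, "S")$RI
  expect_gt(riF, riS)
})

test_that("baseline_self reference equals the within-baseline mean distance", {
  pos <- c(b1 = 0, b2 = 0.1, b3 = 0.2, a1 = 0.5, a2 = 0.4)
  dm <- dmFromPositions(pos)
  md <- data.frame(sample_id = names(pos), host_id = "H",
                   day = c(0L, 2L, 4L, 6L, 8L),
                   trip_status = c("BeforeTrip", "BeforeTrip", "BeforeTrip",
                                   "AfterTrip", "AfterTrip"))
  res <- perPhaseResilience(dm, md, "H", d0Mode = "baseline_self")
  expect_equal(unique(res$D0), mean(c(0.1, 0.2, 0.1)))
  resMax <- perPhaseResilience(dm, md, "H", d0Mode = "global_max")
  tr <- baselineTrajectory(dm, md, "H")
  expect_equal(unique(resMax$D0), max(tr$dissimilarity))
})
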