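test_that("sampling schedule arithmetic: one phase of 10 days at interval 2", {
  comp <- matrix(rep(0.1, 10), 1, dimnames = list("BeforeTrip", NULL))
  colnames(comp) <- sprintf("F%02d", 1:10)
  d <- studyDesign(hosts = "H",
                   phaseSchedule = list(H = c(BeforeTrip = 10)),
                   phaseComposition = list(H = comp),
                   samplingInterval = c(2L, 2L),
                   sequencingDepth = 100, missingRate = 0, seed = 3L)
  me <- generateStudy(d)
  expect_true(ncol(me) %in% 5:6)
  expect_true(all(tripStatus(me) == "BeforeTrip"))
  expect_identical(sampleDay(me), seq(0L, by = 2L,
                                      length.out = ncol(me)))
})

test_that("zero-duration phases and non-positive depth are rejected", {
  comp <- matrix(rep(0.1, 10), 1, dimnames = list("BeforeTrip", NULL))
  colnames(comp) <- sprintf("F%02d", 1:10)
  expect_error(
    studyDesign(hosts = "H", phaseSchedule = list(H = c(BeforeTrip = 0)),
                phaseComposition = list(H = comp)),
    "zero- or negative-duration")
  expect_error(
    studyDesign(hosts = "H", phaseSchedule = list(H = c(BeforeTrip = 10)),
                phaseComposition = list(H = comp), sequencingDepth = 0),
    "sequencingDepth")
})

test_that("composition rows must be proportions summing to one", {
  comp <- matrix(rep(0.2, 10), 1, dimnames = list("BeforeTrip", NULL))
  colnames(comp) <- sprintf("F%02d", 1:10)
  expect_error(
    studyDesign(hosts = "H", phaseSchedule = list(H = c(BeforeTrip = 10)),
                phaseComposition = list(H = comp)),
    "sum to 1")
})

test_that("infinite concentration at high depth recovers the phase mean", {
  mean10 <- c(0.3, 0.2, 0.15, 0.1, 0.08, 0.07, 0.05, 0.03, 0.015, 0.005)
  comp <- matrix(mean10, 1, dimnames = list("BeforeTrip", NULL))
  colnames(comp) <- sprintf("F%02d", 1:10)
  d <- studyDesign(hosts = "H",
                   phaseSchedule = list(H = c(BeforeTrip = 45)),
                   phaseComposition = list(H = comp),
                   samplingInterval = c(2L, 2L), concentration = Inf,
                   sequencingDepth = 1e6, missingRate = 0, seed = 11L)
  me <- generateStudy(d)
  expect_gte(ncol(me), 20L)
  props <- sweep(counts(me), 2L, colSums(counts(me)), "/")
  expect_lt(max(abs(props - mean10)), 0.01)
})

test_that("generation is bit-identical under a fixed seed", {
  me1 <- generateStudy(smallDesign(seed = 5L))
  me2 <- generateStudy(smallDesign(seed = 5L))
  expect_identical(counts(me1), counts(me2))
  expect_identical(sampleTable(me1), sampleTable(me2))
  me3 <- generateStudy(smallDesign(seed = 6L))
  expect_false(identical(counts(me1), counts(me3)))
})

test_that("a full design carries the five canonical phases in order", {
  me <- generateStudy(smallDesign(seed = 2L))
  for (h in c("A", "B")) {
    ph <- as.character(tripStatus(me)[hostId(me) == h])
    expect_identical(unique(ph), tripPhases())
    expect_false(is.unsorted(match(ph, tripPhases())))
  }
})

test_that("marginal proportions converge to the Dirichlet mean as 1/sqrt(n)", {
  mean10 <- c(0.3, 0.2, 0.15, 0.1, 0.08, 0.07, 0.05, 0.03, 0.015, 0.005)
  comp <- matrix(mean10, 1, dimnames = list("BeforeTrip", NULL))
  colnames(comp) <- sprintf("F%02d", 1:10)
  makeStudy <- function(days, seed) {
    d <- studyDesign(hosts = "H",
                     phaseSchedule = list(H = c(BeforeTrip = days)),
                     phaseComposition = list(H = comp),
                     samplingInterval = c(1L, 1L), concentration = 50,
                     sequencingDepth = 2e4, missingRate = 0, seed = seed)
    props <- {
      cts <- counts(generateStudy(d))
      sweep(cts, 2L, colSums(cts), "/")
    }
    max(abs(rowMeans(props) - mean10))
  }
  devSmall <- mean(vapply(1:3, function(s) makeStudy(10L, s), numeric(1)))
  devLarge <- mean(vapply(1:3, function(s) makeStudy(160L, s), numeric(1)))
  expect_lt(devLarge, devSmall)   # error shrinks with n
  expect_lt(devLarge, 0.02)
})

test_that("batch effect injection multiplies by 10^offset and keeps zeros", {
  m <- matrix(c(7, 0, 3, 2), 2, 2,
              dimnames = list(c("f1", "f2"), c("s1", "s2")))
  sh <- matrix(c(1, 0), 1, 2, dimnames = list("b1", NULL))
  out <- injectBatchEffect(m, c("b1", "b1"), sh)
  expect_identical(out["f1", "s1"], 70)     # 7 x 10^1
  expect_identical(out["f2", "s1"], 0)      # zeros remain zero
  expect_identical(out["f2", "s2"], 2)      # offset 0 row unchanged
  zero <- matrix(0, 1, 2, dimnames = list("b1", NULL))
  expect_identical(injectBatchEffect(m, c("b1", "b1"), zero), m)
  expect_error(injectBatchEffect(m, c("b1", "bX"), sh), "unknown batch")
})
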