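test_that("feature filter applies both rules with strict inequalities", {
  mk <- function(present, total, n = 10L) {
    row <- numeric(n)
    row[seq_len(present)] <- c(rep(1, present - 1L),
                               total - (present - 1L))
    row
  }
  m <- rbind(
    kept    = mk(2L, 8),     # occurrence 0.2 > 0.1, total 8 > 5
    lowOcc  = mk(1L, 100),   # occurrence 0.1, not > 0.1 -> dropped
    lowTot  = mk(5L, 5))     # total 5, not > 5 -> dropped
  colnames(m) <- paste0("s", 1:10)
  out <- filterFeatures(m)
  expect_identical(rownames(out), "kept")
  expect_setequal(attr(out, "dropped"), c("lowOcc", "lowTot"))
  # just past both boundaries -> kept
  m2 <- rbind(edge = mk(2L, 6))
  colnames(m2) <- paste0("s", 1:10)
  expect_identical(rownames(filterFeatures(m2)), "edge")
})

test_that("feature filter is idempotent and preserves samples and order", {
  me <- generateStudy(smallDesign(seed = 4L))
  once <- filterFeatures(counts(me))
  twice <- filterFeatures(once)
  expect_equal(twice, once, ignore_attr = "dropped")
  expect_length(attr(twice, "dropped"), 0L)
  expect_identical(colnames(once), colnames(counts(me)))
  expect_false(is.unsorted(match(rownames(once), rownames(counts(me)))))
  expect_error(filterFeatures(matrix(numeric(0), 0, 0)), "empty")
})

test_that("log transform uses half the minimum non-zero value", {
  m <- matrix(c(0, 2, 4), 1, dimnames = list("f", c("a", "b", "c")))
  lt <- logTransform(m)
  expect_equal(attr(lt, "pseudocount"), 1)
  expect_equal(unname(lt[1, ]), c(log10(1), log10(2), log10(4)))
  # no zeros: pure log10
  m2 <- matrix(c(5, 2, 4), 1)
  expect_equal(unname(logTransform(m2)[1, ]), log10(c(5, 2, 4)))
  expect_error(logTransform(matrix(0, 2, 2)), "all-zero")
})

test_that("delog inverts the log transform exactly for positive entries", {
  me <- generateStudy(smallDesign(seed = 8L))
  x <- filterFeatures(counts(me))
  back <- delog(logTransform(x))
  expect_equal(back[x > 0], x[x > 0], tolerance = 1e-12)
})

test_that("multicollinearity pruning drops the later of correlated pairs", {
  set.seed(1)
  a <- rnorm(30)
  cov <- data.frame(a = a, dup = a, b = rnorm(30))
  out <- removeMulticollinear(cov)
  expect_identical(out$kept, c("a", "b"))
  expect_identical(out$dropped, "dup")
  # orthogonal columns all survive
  ortho <- data.frame(x = c(1, 1, -1, -1), y = c(1, -1, 1, -1))
  expect_identical(removeMulticollinear(ortho)$kept, c("x", "y"))
  # three mutually correlated columns leave one survivor
  base <- rnorm(200)
  tri <- data.frame(c1 = base + rnorm(200, sd = 0.1),
                    c2 = base + rnorm(200, sd = 0.1),
                    c3 = base + rnorm(200, sd = 0.1))
  expect_gt(min(abs(cor(tri)[upper.tri(diag(3))])), 0.9)
  expect_identical(removeMulticollinear(tri)$kept, "c1")
})

test_that("relative abundance puts every sample on the simplex", {
  m <- matrix(c(2, 3, 5, 1, 1, 2), 3,
              dimnames = list(letters[1:3], c("s1", "s2")))
  p <- relativeAbundance(m)
  expect_equal(unname(p[, "s1"]), c(0.2, 0.3, 0.5))
  expect_equal(colSums(p), c(s1 = 1, s2 = 1), tolerance = 1e-9)
  m[, 2] <- 0
  expect_error(relativeAbundance(m), "s2")
})

test_that("taxonomic aggregation sums lineages and pools unmapped features", {
  m <- matrix(c(4, 6, 3, 2), 4, 1,
              dimnames = list(c("a1", "a2", "x1", "u1"), "s1"))
  tax <- data.frame(
    feature_id = c("a1", "a2", "x1"),
    domain = "d__Bacteria",
    phylum = c("p__Actinomycetota", "p__Actinomycetota",
               "p__Pseudomonadota"),
    class = NA, order = NA, family = NA, genus = NA, species = NA)
  agg <- aggregateTaxa(m, tax, "phylum")
  expect_equal(agg["p__Actinomycetota", "s1"], 10)
  expect_equal(agg["p__Pseudomonadota", "s1"], 3)
  expect_equal(agg["Unclassified", "s1"], 2)
  expect_equal(colSums(agg), colSums(m))    # totals conserved exactly
})

test_that("aggregation keys on the full lineage prefix, not the rank name", {
  m <- matrix(c(1, 1), 2, 1, dimnames = list(c("f1", "f2"), "s"))
  tax <- data.frame(feature_id = c("f1", "f2"),
                    domain = c("d__Bacteria", "d__Archaea"),
                    phylum = c("p__Twin", "p__Twin"),
                    class = NA, order = NA, family = NA, genus = NA,
                    species = NA)
  agg <- aggregateTaxa(m, tax, "phylum")
  expect_equal(nrow(agg), 2L)   # homonymous phyla in different domains
})

test_that("moving average is centered, shrinks at edges, keeps length", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(movingAverage(x, 1L), x)
  ma <- movingAverage(x, 5L)
  expect_equal(length(ma), 5L)
  expect_equal(ma[3], 3)                 # full window mean
  expect_equal(ma[1], 1)                 # edge window shrinks to width 1
  expect_equal(ma[2], 2)                 # width 3 at position 2
  expect_equal(movingAverage(rep(7, 9), 5L), rep(7, 9))
  expect_error(movingAverage(x, 4L), "odd")
  expect_error(movingAverage(x, 11L), "larger")
})
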